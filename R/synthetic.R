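#' Simulate a peptide-level EV proteome cohort with known ground truth
#'
#' Generates a cell-line cohort in the study layout (by default 9 cell lines
#' x 2 biological replicates across three prostate cancer subtypes) under an
#' additive-multiplicative error model (Rocke-Durbin): for peptide j of
#' protein p in sample i,
#'
#' \deqn{x = a_i + b_i \, e^{\eta} \, \mu_{pj} + \epsilon,\qquad
#'       \eta \sim N(0, \sigma_{mult}^2),\ \epsilon \sim N(0, \sigma_{add}^2)}
#'
#' where \eqn{\mu_{pj}} is the protein's true linear abundance times a
#' peptide-specific ionisation efficiency, and proteins belonging to a
#' subtype's signature are shifted by `+delta` log2 units in samples of that
#' subtype. Detection is intensity dependent (left-censored, MNAR): a cell
#' is observed with probability `plogis((log2(x) - m0)/k)`; unobserved cells
#' are recorded as intensity 0.
#'
#' @param design A [sample_design()]; defaults to [default_design()].
#' @param n_proteins Number of simulated proteins (>= 50).
#' @param n_signature Signature proteins per subtype (disjoint across
#'   subtypes).
#' @param delta Log2 effect size of signature proteins in their subtype.
#' @param lambda Poisson mean for extra peptides per protein (each protein
#'   gets `rpois(lambda) + 1` peptides).
#' @param a,b Per-sample calibration: additive offsets and multiplicative
#'   factors (recycled to the number of samples). `b` must be positive.
#' @param sigma_add SD of the additive noise term, intensity units.
#' @param sigma_mult SD of the log-multiplicative noise term.
#' @param sigma_line SD (log2) of a per-cell-line abundance effect shared by
#'   replicates; 0 (default) gives exchangeable samples within subtype.
#' @param mu_log2_mean,mu_log2_sd Log2-normal protein abundance parameters.
#' @param peptide_log2_sd SD (log2) of peptide ionisation efficiencies.
#' @param m0 Log2 intensity at 50% detection probability (`-Inf` disables
#'   censoring).
#' @param k Logistic scale of the detection curve (> 0; smaller = sharper).
#' @param seed Integer seed; output is reproducible bit-for-bit.
#' @return List with elements `peptides` ([peptide_table()]), `truth`
#'   (`SyntheticTruth` list: signature membership, calibration, noise,
#'   missingness, true protein log2 levels) and `design`.
#' @export
simulate_cellline_cohort <- function(design = default_design(),
                                     n_proteins = 2000L,
                                     n_signature = 150L,
                                     delta = 1.5,
                                     lambda = 4,
                                     a = 0, b = 1,
                                     sigma_add = 50,
                                     sigma_mult = 0.2,
                                     sigma_line = 0,
                                     mu_log2_mean = 13,
                                     mu_log2_sd = 2,
                                     peptide_log2_sd = 0.5,
                                     m0 = 10, k = 1,
                                     seed = 1L) {
  if (lambda <= 0) stop("lambda must be > 0")
  if (delta < 0) stop("delta must be >= 0")
  if (n_proteins < 50) stop("n_proteins must be >= 50")
  if (3 * n_signature > n_proteins)
    stop("signature sets exceed the number of proteins")
  n_samples <- nrow(design)
  a <- rep_len(a, n_samples)
  b <- rep_len(b, n_samples)
  if (any(b <= 0)) stop("multiplicative factors b must be > 0")
  k <- max(k, 1e-12)

  with_seed(substream_seed(seed, "cellline_cohort"), {
    protein_id <- sprintf("GENE%05d", seq_len(n_proteins))
    mu_log2 <- stats::setNames(
      stats::rnorm(n_proteins, mu_log2_mean, mu_log2_sd), protein_id)

    members <- sample(protein_id, 3L * n_signature)
    membership <- split(members, rep(CELLLINE_SUBTYPES, each = n_signature))
    membership <- lapply(membership, sort)

    # log2 shift matrix: protein x sample, +delta for signature members in
    # samples of their subtype
    shift <- matrix(0, n_proteins, n_samples,
                    dimnames = list(protein_id, design$sample_id))
    for (s in CELLLINE_SUBTYPES)
      shift[membership[[s]], design$subtype == s] <- delta

    if (sigma_line > 0) {
      lines <- unique(design$cell_line)
      line_eff <- matrix(stats::rnorm(n_proteins * length(lines),
                                      0, sigma_line),
                         n_proteins, length(lines),
                         dimnames = list(protein_id, lines))
      shift <- shift + line_eff[, design$cell_line]
    }

    n_pep <- stats::rpois(n_proteins, lambda) + 1L
    pep_protein <- rep(protein_id, n_pep)
    pep_id <- paste0(pep_protein, "_pep", sequence(n_pep))
    n_total <- length(pep_id)
    pep_eff <- stats::rnorm(n_total, 0, peptide_log2_sd)

    # true linear peptide level per cell
    level <- 2^(mu_log2[pep_protein] + pep_eff +
                  shift[pep_protein, , drop = FALSE])
    eta <- matrix(stats::rnorm(n_total * n_samples, 0, sigma_mult),
                  n_total, n_samples)
    eps <- matrix(stats::rnorm(n_total * n_samples, 0, sigma_add),
                  n_total, n_samples)
    x <- rep(a, each = n_total) + rep(b, each = n_total) * exp(eta) * level + eps
    dimnames(x) <- list(pep_id, design$sample_id)

    p_det <- matrix(0, n_total, n_samples)
    pos <- x > 0
    p_det[pos] <- stats::plogis((log2(x[pos]) - m0) / k)
    detected <- matrix(stats::runif(n_total * n_samples), n_total,
                       n_samples) < p_det
    x[!detected] <- 0
    dimnames(detected) <- dimnames(x)

    truth <- structure(list(
      signature_membership = membership,
      delta = delta,
      calibration = list(a = stats::setNames(a, design$sample_id),
                         b = stats::setNames(b, design$sample_id)),
      noise = list(sigma_add = sigma_add, sigma_mult = sigma_mult,
                   sigma_line = sigma_line),
      missingness = list(m0 = m0, k = k),
      protein_mu_log2 = mu_log2,
      patient_mixtures = NULL,
      background_proteins = NULL,
      healthy_plasma = NULL,
      seed = as.integer(seed)), class = "SyntheticTruth")

    list(peptides = peptide_table(x, protein_id = pep_protein,
                                  detected = detected),
         truth = truth,
         design = design)
  })
}

#' Simulate a patient plasma EV cohort as mixtures of subtype profiles
#'
#' Each patient's protein profile is a convex combination of the three
#' cell-line subtype mean profiles plus a shared plasma background profile,
#' with log-multiplicative noise. Background proteins overlap the generated
#' healthy-plasma list by construction, and a fraction of cell-line proteins
#' is marked ubiquitous-in-plasma as well (so that healthy-plasma filtering
#' removes part of every derived signature, as with real cohorts).
#'
#' @param cohort Output of [simulate_cellline_cohort()].
#' @param n_patients Number of patients (default 27).
#' @param mixtures Optional `n_patients x 4` matrix of simplex weights with
#'   columns `AR_POS`, `AR_NEG_NE_POS`, `AR_NEG_NE_NEG`, `background`; rows
#'   must be non-negative and sum to 1. Drawn from a flat Dirichlet when
#'   omitted.
#' @param n_background Number of plasma-background-only proteins.
#' @param detect_frac Fraction of cell-line proteins detected in the patient
#'   cohort (rows of the patient matrix).
#' @param healthy_frac Fraction of detected cell-line proteins additionally
#'   present on the healthy-plasma list.
#' @param sigma_patient SD of per-cell log-multiplicative patient noise.
#' @param seed Integer seed.
#' @return List with `patients` (linear [protein_matrix()]), `healthy`
#'   (single-set [signature_collection()]), `design` (patient
#'   [sample_design()]) and `truth` (the input truth augmented with
#'   `patient_mixtures`, `background_proteins`, `healthy_plasma`).
#' @export
simulate_patient_cohort <- function(cohort,
                                    n_patients = 27L,
                                    mixtures = NULL,
                                    n_background = 300L,
                                    detect_frac = 0.85,
                                    healthy_frac = 0.3,
                                    sigma_patient = 0.3,
                                    seed = 1L) {
  truth <- cohort$truth
  comps <- c(CELLLINE_SUBTYPES, "background")
  if (!is.null(mixtures)) {
    mixtures <- as.matrix(mixtures)
    if (ncol(mixtures) != 4L) stop("mixtures must have 4 columns")
    colnames(mixtures) <- comps
    if (any(mixtures < 0) || any(abs(rowSums(mixtures) - 1) > 1e-8))
      stop("mixture weights must be non-negative and sum to 1")
    n_patients <- nrow(mixtures)
  }

  with_seed(substream_seed(seed, "patient_cohort"), {
    if (is.null(mixtures)) {
      g <- matrix(stats::rgamma(n_patients * 4L, shape = 1), n_patients, 4L)
      mixtures <- g / rowSums(g)
      colnames(mixtures) <- comps
    }
    rownames(mixtures) <- sprintf("patient_%02d", seq_len(nrow(mixtures)))

    # subtype mean linear profiles from the generative truth
    mu <- truth$protein_mu_log2
    profiles <- vapply(CELLLINE_SUBTYPES, function(s) {
      shift <- as.numeric(names(mu) %in% truth$signature_membership[[s]]) *
        truth$delta
      2^(mu + shift)
    }, numeric(length(mu)))
    rownames(profiles) <- names(mu)

    keep <- sort(sample(names(mu), round(detect_frac * length(mu))))
    bg_id <- sprintf("HPEV%04d", seq_len(n_background))
    bg_level <- stats::setNames(
      2^stats::rnorm(n_background, mean(mu), stats::sd(mu)), bg_id)

    healthy <- sort(c(bg_id, sample(keep, round(healthy_frac * length(keep)))))

    rows <- c(keep, bg_id)
    base <- cbind(rbind(profiles[keep, , drop = FALSE],
                        matrix(0, n_background, 3,
                               dimnames = list(bg_id, CELLLINE_SUBTYPES))),
                  background = c(stats::setNames(rep(0, length(keep)), keep),
                                 bg_level))
    vals <- base %*% t(mixtures)
    noise <- matrix(exp(stats::rnorm(length(vals), 0, sigma_patient)),
                    nrow(vals), ncol(vals))
    vals <- vals * noise
    vals[vals <= 0] <- min(vals[vals > 0])
    dimnames(vals) <- list(rows, rownames(mixtures))

    truth$patient_mixtures <- mixtures
    truth$background_proteins <- bg_id
    truth$healthy_plasma <- healthy

    pat_design <- sample_design(rownames(mixtures), rownames(mixtures),
                                rep("PATIENT", nrow(mixtures)),
                                rep(1L, nrow(mixtures)))
    list(patients = protein_matrix(vals, scale = "linear"),
         healthy = signature_collection(list(healthy_plasma = healthy)),
         design = pat_design,
         truth = truth)
  })
}

#' Serialise / deserialise a SyntheticTruth object as JSON
#'
#' @param truth A `SyntheticTruth` (see [simulate_cellline_cohort()]).
#' @param path Output `.json` path.
#' @return `path` invisibly; `read_truth()` returns the `SyntheticTruth`.
#' @export
write_truth <- function(truth, path) {
  out <- truth
  # jsonlite drops names on atomic vectors; store keyed values as objects
  out$protein_mu_log2 <- as.list(truth$protein_mu_log2)
  out$calibration$a <- as.list(truth$calibration$a)
  out$calibration$b <- as.list(truth$calibration$b)
  out$patient_mixtures <- if (!is.null(truth$patient_mixtures)) {
    list(patients = rownames(truth$patient_mixtures),
         components = colnames(truth$patient_mixtures),
         weights = unname(apply(truth$patient_mixtures, 1, as.numeric,
                                simplify = FALSE)))
  }
  jsonlite::write_json(unclass(out), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$signature_membership <- lapply(x$signature_membership, as.character)
  x$protein_mu_log2 <- unlist(x$protein_mu_log2)
  x$calibration$a <- unlist(x$calibration$a)
  x$calibration$b <- unlist(x$calibration$b)
  if (!is.null(x$patient_mixtures)) {
    w <- x$patient_mixtures$weights
    if (!is.matrix(w)) w <- do.call(rbind, w)
    dimnames(w) <- list(x$patient_mixtures$patients,
                        x$patient_mixtures$components)
    x$patient_mixtures <- w
  }
  structure(x, class = "SyntheticTruth")
}
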