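#' Define a subtype contrast
#'
#' The three contrasts of the study design: AR+ vs AR-, double-negative
#' (AR-/NE-) vs rest, and neuroendocrine (AR-/NE+) vs rest.
#'
#' @param name One of `"AR_POS_vs_AR_NEG"`, `"AR_NEG_NE_NEG_vs_rest"`,
#'   `"AR_NEG_NE_POS_vs_rest"`.
#' @return List with `name`, `group_a`, `group_b` (subtype label vectors).
#' @export
subtype_contrast <- function(name = c("AR_POS_vs_AR_NEG",
                                      "AR_NEG_NE_NEG_vs_rest",
                                      "AR_NEG_NE_POS_vs_rest")) {
  name <- match.arg(name)
  switch(name,
    AR_POS_vs_AR_NEG = list(name = name, group_a = "AR_POS",
                            group_b = c("AR_NEG_NE_POS", "AR_NEG_NE_NEG")),
    AR_NEG_NE_NEG_vs_rest = list(name = name, group_a = "AR_NEG_NE_NEG",
                                 group_b = c("AR_POS", "AR_NEG_NE_POS")),
    AR_NEG_NE_POS_vs_rest = list(name = name, group_a = "AR_NEG_NE_POS",
                                 group_b = c("AR_POS", "AR_NEG_NE_NEG")))
}

# vectorised Welch two-sample t-test over matrix rows
welch_rows <- function(xa, xb) {
  na <- ncol(xa); nb <- ncol(xb)
  ma <- rowMeans(xa); mb <- rowMeans(xb)
  va <- row_sds(xa)^2; vb <- row_sds(xb)^2
  se2 <- va / na + vb / nb
  d <- ma - mb
  t <- ifelse(se2 > 0, d / sqrt(se2), 0)
  df <- ifelse(se2 > 0,
               se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1)),
               1)
  p <- ifelse(se2 > 0, 2 * stats::pt(-abs(t), df), 1)
  # zero variance on both sides but non-zero difference: exact separation
  sep <- se2 == 0 & d != 0
  p[sep] <- .Machine$double.xmin
  t[sep] <- sign(d[sep]) * Inf
  list(mean_diff = d, t_stat = t, p_value = p, df = df)
}

# Storey q-values with a fixed lambda = 0.5 pi0 estimate
storey_q <- function(p, lambda = 0.5) {
  pi0 <- min(1, mean(p > lambda) / (1 - lambda))
  pmin(1, pi0 * stats::p.adjust(p, method = "BH"))
}

#' Per-protein differential enrichment between subtype groups
#'
#' Welch two-sample t-tests on glog values per protein, with
#' Benjamini-Hochberg q-values over all tested proteins (Storey's estimate
#' available via `config$qvalue_method`). A protein with identical values
#' everywhere gets p = 1. Significance is `q < config$q_threshold`.
#'
#' @param matrix A glog-scale [protein_matrix()].
#' @param design A [sample_design()].
#' @param contrast A [subtype_contrast()] (or its name).
#' @param config A [run_config()].
#' @return data.frame of class `DiffResult`: `protein_id`, `group_a`,
#'   `group_b`, `mean_diff` (glog units, a minus b), `t_stat`, `p_value`,
#'   `q_value`, `enriched_in`, `significant`; ordered by q then
#'   decreasing |mean_diff|.
#' @export
differential_enrichment <- function(matrix, design, contrast,
                                    config = run_config()) {
  if (is.character(contrast)) contrast <- subtype_contrast(contrast)
  design <- design[match(colnames(matrix$values), design$sample_id), ]
  cols_a <- design$sample_id[design$subtype %in% contrast$group_a]
  cols_b <- design$sample_id[design$subtype %in% contrast$group_b]
  if (length(cols_a) < 2 || length(cols_b) < 2)
    stop("each side of the contrast needs >= 2 samples")
  w <- welch_rows(matrix$values[, cols_a, drop = FALSE],
                  matrix$values[, cols_b, drop = FALSE])
  q <- if (config$qvalue_method == "BH")
    stats::p.adjust(w$p_value, method = "BH") else storey_q(w$p_value)
  lab_a <- paste(contrast$group_a, collapse = "+")
  lab_b <- paste(contrast$group_b, collapse = "+")
  out <- data.frame(protein_id = rownames(matrix$values),
                    group_a = lab_a, group_b = lab_b,
                    mean_diff = w$mean_diff, t_stat = w$t_stat,
                    p_value = pmax(w$p_value, .Machine$double.xmin),
                    q_value = pmax(q, .Machine$double.xmin),
                    enriched_in = ifelse(w$mean_diff > 0, lab_a, lab_b),
                    significant = q < config$q_threshold,
                    row.names = NULL)
  out <- out[order(out$q_value, -abs(out$mean_diff), out$protein_id), ]
  rownames(out) <- NULL
  attr(out, "contrast") <- contrast$name
  class(out) <- c("DiffResult", "data.frame")
  out
}

#' Ternary subtype fractions of protein signal
#'
#' Per protein, the mean linear intensity is computed per cell-line subtype
#' and expressed as a percentage of the summed means: a protein detected
#' only in AR+ samples sits at the AR+ corner (100, 0, 0) of the simplex.
#' A density grid over the triangle (edge subdivided `grid` times, giving
#' `grid^2` triangular bins) counts proteins per bin.
#'
#' @param matrix A linear-scale [protein_matrix()] (pre-glog; percentages
#'   of signal require non-negative values).
#' @param design A [sample_design()] with all three cell-line subtypes.
#' @param grid Edge subdivisions of the density grid (default 6).
#' @return List of class `TernaryTable`: `fractions` (data.frame with
#'   columns `protein_id`, one percentage column per subtype, `bin`),
#'   `density` (data.frame `bin`, `count`), `excluded` (zero-signal
#'   protein ids).
#' @export
ternary_fractions <- function(matrix, design, grid = 6L) {
  if (matrix$scale != "linear")
    stop("ternary fractions are defined on the linear-scale matrix, got ",
         matrix$scale)
  design <- design[match(colnames(matrix$values), design$sample_id), ]
  if (!all(CELLLINE_SUBTYPES %in% design$subtype))
    stop("all three cell-line subtypes must be present")
  means <- vapply(CELLLINE_SUBTYPES, function(s) {
    rowMeans(matrix$values[, design$sample_id[design$subtype == s],
                           drop = FALSE])
  }, numeric(nrow(matrix$values)))
  tot <- rowSums(means)
  excluded <- rownames(matrix$values)[tot == 0]
  if (length(excluded))
    warning(length(excluded), " protein(s) with zero total signal excluded")
  means <- means[tot > 0, , drop = FALSE]
  frac <- 100 * means / rowSums(means)

  bins <- apply(frac / 100, 1, function(f) ternary_bin(f, grid))
  density <- as.data.frame(table(bin = bins), stringsAsFactors = FALSE)
  names(density)[2] <- "count"
  fractions <- data.frame(protein_id = rownames(means), frac, bin = bins,
                          row.names = NULL, check.names = FALSE)
  structure(list(fractions = fractions, density = density,
                 excluded = excluded, grid = grid),
            class = "TernaryTable")
}

# Deterministic triangular bin for a simplex point f (length 3, sums to 1).
# Upright bins have floor coordinates summing to grid-1, inverted to grid-2;
# lattice/edge points are pushed into the adjacent upright bin.
ternary_bin <- function(f, grid) {
  u <- grid * f
  i <- floor(u + 1e-9)
  while (sum(i) > grid - 1) {
    cand <- which(i > 0)
    j <- cand[which.max((u - i)[cand])]
    i[j] <- i[j] - 1
  }
  type <- if (sum(i) == grid - 1) "up" else "down"
  paste0(type, "_", paste(i, collapse = "_"))
}

#' Derive subtype protein signatures with patient and healthy-plasma filters
#'
#' Three-stage derivation per subtype: (1) proteins significantly enriched
#' in the subtype (q below threshold, positive enrichment), ordered by q
#' then |mean difference|; (2) intersection with proteins detected in the
#' patient cohort; (3) removal of proteins also identified in EVs from the
#' plasma of healthy, non-cancer controls. All three counts are reported,
#' and `n_stage1 >= n_stage2 >= n_final` by construction.
#'
#' @param diffs Named list of [differential_enrichment()] results; names
#'   are the subtype labels their `group_a` represents.
#' @param patients A [protein_matrix()] (or character id vector): the
#'   patient-detected protein universe.
#' @param healthy A single-set [signature_collection()] (or character
#'   vector) of healthy-plasma EV proteins; `NULL` skips the filter.
#' @param config A [run_config()].
#' @return List of class `SubtypeSignature`: `signatures` (named list of
#'   ordered protein vectors), `provenance` (data.frame with columns
#'   `subtype`, `n_significant`, `n_patient_detected`, `n_final`).
#' @export
derive_subtype_signatures <- function(diffs, patients, healthy = NULL,
                                      config = run_config()) {
  pat_ids <- if (inherits(patients, "ProteinMatrix"))
    rownames(patients$values) else toupper(as.character(patients))
  healthy_ids <- if (is.null(healthy)) character()
    else if (inherits(healthy, "SignatureCollection"))
      unique(unlist(healthy$sets)) else toupper(as.character(healthy))
  sigs <- list(); prov <- list()
  for (subtype in names(diffs)) {
    d <- diffs[[subtype]]
    lab_a <- d$group_a[1]
    stage1 <- d$protein_id[d$significant & d$enriched_in == lab_a]
    stage2 <- stage1[stage1 %in% pat_ids]
    final <- stage2[!stage2 %in% healthy_ids]
    sigs[[subtype]] <- final
    prov[[subtype]] <- data.frame(subtype = subtype,
                                  n_significant = length(stage1),
                                  n_patient_detected = length(stage2),
                                  n_final = length(final))
  }
  structure(list(signatures = sigs,
                 provenance = do.call(rbind, c(prov,
                                               list(make.row.names = FALSE)))),
            class = "SubtypeSignature")
}

#' Average subtype-signature expression per patient
#'
#' Per patient, the score for a subtype is the mean over its signature
#' proteins of the protein's z-score across patients (raw-level averaging
#' available via `method = "raw"`). Missing proteins are skipped and
#' coverage reported.
#'
#' @param patients A [protein_matrix()] (patients in columns).
#' @param signatures A `SubtypeSignature` from
#'   [derive_subtype_signatures()], or a named list of protein id vectors.
#' @param method `"zscore"` (default) or `"raw"`.
#' @return List: `scores` (patient x subtype matrix, `NA` where no
#'   signature protein is present), `coverage` (data.frame).
#' @export
patient_subtype_score <- function(patients, signatures,
                                  method = c("zscore", "raw")) {
  method <- match.arg(method)
  sets <- if (inherits(signatures, "SubtypeSignature"))
    signatures$signatures else signatures
  vals <- if (method == "zscore") row_zscore(patients$values)
          else patients$values
  scores <- vapply(sets, function(g) {
    found <- intersect(g, rownames(vals))
    if (!length(found)) return(rep(NA_real_, ncol(vals)))
    colMeans(vals[found, , drop = FALSE])
  }, numeric(ncol(patients$values)))
  rownames(scores) <- colnames(patients$values)
  coverage <- data.frame(
    subtype = names(sets),
    n_found = vapply(sets,
                     function(g) length(intersect(g, rownames(vals))), 0L),
    n_total = lengths(sets), row.names = NULL)
  list(scores = scores, coverage = coverage)
}
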