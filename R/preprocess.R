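#' Impute left-censored peptide intensities
#'
#' Missing (undetected) peptide intensities are replaced by random draws from
#' a normal distribution on the log2 scale centred on a low quantile of the
#' detected intensities -- the standard left-censored imputation for LFQ
#' data, where a value is missing mostly because it fell below the detection
#' limit. The centre `q` is the `impute_quantile` (default 1%) quantile of
#' all detected log2 intensities and the spread `s` is the median over
#' peptides (with >= 2 detected values) of the per-peptide SD of detected
#' log2 intensities. Draws are back-transformed to the linear scale;
#' detected cells are untouched and the detection mask is preserved.
#'
#' @param peptides A [peptide_table()].
#' @param config A [run_config()]; `impute_quantile` sets the centre
#'   quantile and `impute_scope` chooses a global (default) or per-sample
#'   quantile.
#' @param seed Integer seed (defaults to the config seed); the same seed
#'   gives an identical imputed table.
#' @return A [peptide_table()] with no zero intensities; attributes
#'   `impute_q` (centre, log2), `impute_s` (SD, log2) and `n_imputed`.
#' @export
impute_missing <- function(peptides, config = run_config(),
                           seed = config$seed) {
  x <- peptides$intensity
  det <- peptides$detected
  if (!any(det)) stop("no detected values to estimate the imputation model")
  lx <- log2(x)
  per_pep_n <- rowSums(det)
  usable <- per_pep_n >= 2
  if (!any(usable))
    stop("no peptide with >= 2 detected values: ",
         "cannot estimate the imputation SD")
  pep_sd <- vapply(which(usable), function(i) {
    stats::sd(lx[i, det[i, ]])
  }, 0)
  s <- stats::median(pep_sd)

  if (config$impute_scope == "global") {
    q <- stats::quantile(lx[det], config$impute_quantile, names = FALSE)
    q_col <- rep(q, ncol(x))
  } else {
    q_col <- vapply(seq_len(ncol(x)), function(j) {
      dj <- det[, j]
      if (!any(dj)) stop("sample ", colnames(x)[j], " has no detected values")
      stats::quantile(lx[dj, j], config$impute_quantile, names = FALSE)
    }, 0)
    q <- stats::median(q_col)
  }

  n_missing <- sum(!det)
  if (n_missing > 0) {
    with_seed(substream_seed(seed, "impute"), {
      for (j in seq_len(ncol(x))) {
        miss <- !det[, j]
        if (any(miss))
          x[miss, j] <- 2^stats::rnorm(sum(miss), q_col[j], s)
      }
    })
  }
  out <- peptide_table(x, protein_id = peptides$protein_id, detected = det)
  # detected mask kept as-is: imputed cells remain flagged undetected
  out$detected <- det
  attr(out, "impute_q") <- q
  attr(out, "impute_s") <- s
  attr(out, "n_imputed") <- n_missing
  out
}

#' Aggregate peptide intensities to protein level
#'
#' Per protein and sample, the protein value is the arithmetic mean of its
#' peptides' linear intensities. Proteins supported by fewer than
#' `config$min_peptides` peptides (default 2) are dropped -- single-peptide
#' quantifications are not considered reliable.
#'
#' @param peptides A fully imputed [peptide_table()] (no zero cells).
#' @param config A [run_config()].
#' @return A linear-scale [protein_matrix()] with `n_peptides` recorded.
#' @export
aggregate_proteins <- function(peptides, config = run_config()) {
  if (any(!peptides$detected & peptides$intensity == 0))
    stop("peptide table still contains missing cells; impute first ",
         "(the pipeline order impute -> aggregate -> normalise is fixed)")
  counts <- table(peptides$protein_id)
  keep <- names(counts)[counts >= config$min_peptides]
  if (!length(keep))
    stop("no protein has >= ", config$min_peptides, " peptides")
  sums <- rowsum(peptides$intensity, group = peptides$protein_id)
  vals <- sums[keep, , drop = FALSE] / as.numeric(counts[keep])
  vals <- vals[order(rownames(vals)), , drop = FALSE]
  np <- stats::setNames(as.integer(counts[rownames(vals)]), rownames(vals))
  protein_matrix(vals, scale = "linear", n_peptides = np)
}

#' Call protein detection per sample from pre-imputation peptide evidence
#'
#' A protein counts as detected in a sample iff at least
#' `config$min_peptides` of its peptides were observed (pre-imputation) in
#' that sample.
#'
#' @param peptides A [peptide_table()] (original detection mask used).
#' @param config A [run_config()].
#' @return Logical protein x sample matrix.
#' @export
detection_call <- function(peptides, config = run_config()) {
  det_counts <- rowsum(peptides$detected + 0, group = peptides$protein_id)
  out <- det_counts >= config$min_peptides
  out[order(rownames(out)), , drop = FALSE]
}
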