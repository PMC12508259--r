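#' Summative z-score signature activity, rescaled to 0-1
#'
#' For each signature gene present in the matrix, values are z-scored across
#' samples; a sample's raw activity is the sum of those z-scores over the
#' found genes, and raw scores are min-max rescaled so the lowest-scoring
#' sample (or cell line) is 0 and the highest is 1. The score is therefore
#' cohort-relative and invariant to per-gene affine rescaling of the input.
#'
#' @param matrix A glog-scale [protein_matrix()] with >= 2 samples.
#' @param signature Character vector of gene symbols (one signature).
#' @param design Optional [sample_design()]; required for
#'   `replicate_policy = "mean_of_replicates"`.
#' @param replicate_policy `"each"` scores every sample; or
#'   `"mean_of_replicates"` averages raw scores per cell line before
#'   rescaling (the form in which cohort scores are usually reported).
#' @return List with `score` (named numeric in \[0,1\], `NA` if no signature
#'   gene was found), `raw` (summed z-scores), `coverage`
#'   (`c(n_found, n_total)`), `found` (gene symbols used) and `degenerate`
#'   (TRUE when all raw scores were equal; scores are then all 0.5).
#' @export
zscore_signature_score <- function(matrix, signature, design = NULL,
                                   replicate_policy = c("each",
                                                        "mean_of_replicates")) {
  replicate_policy <- match.arg(replicate_policy)
  if (ncol(matrix$values) < 2) stop("need >= 2 samples to score")
  signature <- unique(toupper(signature))
  found <- intersect(signature, rownames(matrix$values))
  coverage <- c(n_found = length(found), n_total = length(signature))
  if (!length(found)) {
    return(list(score = stats::setNames(
      rep(NA_real_, ncol(matrix$values)), colnames(matrix$values)),
      raw = NULL, coverage = coverage, found = character(),
      degenerate = FALSE))
  }
  z <- row_zscore(matrix$values[found, , drop = FALSE])
  raw <- colSums(z)
  if (replicate_policy == "mean_of_replicates") {
    if (is.null(design)) stop("mean_of_replicates needs a design")
    grp <- design$cell_line[match(names(raw), design$sample_id)]
    raw <- tapply(raw, grp, mean)
    raw <- stats::setNames(as.numeric(raw), names(raw))
  }
  rng <- range(raw)
  if (diff(rng) == 0) {
    score <- stats::setNames(rep(0.5, length(raw)), names(raw))
    degenerate <- TRUE
  } else {
    score <- (raw - rng[1]) / diff(rng)
    degenerate <- FALSE
  }
  list(score = score, raw = raw, coverage = coverage, found = found,
       degenerate = degenerate)
}

#' Correlation-based neuroendocrine activity score
#'
#' Per sample, the correlation between the sample's z-scored signature-gene
#' values and a reference neuroendocrine profile restricted to the same
#' genes (an integrated NEPC-score style measure). Requires at least 3
#' genes shared between the matrix, the signature and the reference.
#'
#' @param matrix A glog-scale [protein_matrix()].
#' @param signature Character vector of NE signature gene symbols.
#' @param reference_profile Named numeric vector: reference level per gene.
#' @param method Correlation flavour, `"pearson"` (default) or
#'   `"spearman"`.
#' @return List with `score` (named numeric in \[-1,1\], `NA` when fewer
#'   than 3 genes overlap), `coverage` and `found`.
#' @export
correlation_ne_score <- function(matrix, signature, reference_profile,
                                 method = c("pearson", "spearman")) {
  method <- match.arg(method)
  signature <- unique(toupper(signature))
  names(reference_profile) <- toupper(names(reference_profile))
  found <- Reduce(intersect, list(signature, rownames(matrix$values),
                                  names(reference_profile)))
  coverage <- c(n_found = length(found), n_total = length(signature))
  if (length(found) < 3) {
    return(list(score = stats::setNames(
      rep(NA_real_, ncol(matrix$values)), colnames(matrix$values)),
      coverage = coverage, found = found))
  }
  z <- row_zscore(matrix$values[found, , drop = FALSE])
  ref <- reference_profile[found]
  score <- apply(z, 2, stats::cor, y = ref, method = method)
  list(score = score, coverage = coverage, found = found)
}

#' Score a whole signature collection across a cohort
#'
#' Applies [zscore_signature_score()] to every set in a collection and
#' returns a rectangular score table.
#'
#' @inheritParams zscore_signature_score
#' @param collection A [signature_collection()].
#' @return List of class `ScoreTable`: `scores` (sample/cell-line x
#'   signature matrix), `coverage` (data.frame), `degenerate` (named
#'   logical), `score_kind = "RESCALED01"`.
#' @export
score_signatures <- function(matrix, collection, design = NULL,
                             replicate_policy = c("each",
                                                  "mean_of_replicates")) {
  replicate_policy <- match.arg(replicate_policy)
  per_set <- lapply(collection$sets, function(g) {
    zscore_signature_score(matrix, g, design, replicate_policy)
  })
  scores <- do.call(cbind, lapply(per_set, `[[`, "score"))
  colnames(scores) <- names(collection$sets)
  coverage <- data.frame(
    signature = names(collection$sets),
    n_found = vapply(per_set, function(p) p$coverage[["n_found"]], 0L),
    n_total = vapply(per_set, function(p) p$coverage[["n_total"]], 0L),
    row.names = NULL)
  coverage$pct_found <- round(100 * coverage$n_found / coverage$n_total, 1)
  structure(list(scores = scores, coverage = coverage,
                 degenerate = vapply(per_set, `[[`, TRUE, "degenerate"),
                 score_kind = "RESCALED01"),
            class = "ScoreTable")
}

#' Signature coverage of a protein matrix
#'
#' How many genes of each signature are quantified among the matrix rows,
#' with the percentage rounded to one decimal for reporting (the form in
#' which signature coverage is conventionally quoted, e.g. "33/71, 49.2%").
#'
#' @param matrix A [protein_matrix()].
#' @param collection A [signature_collection()].
#' @return data.frame: `signature`, `n_found`, `n_total`, `pct_found`.
#' @export
signature_coverage <- function(matrix, collection) {
  rows <- rownames(matrix$values)
  out <- data.frame(
    signature = names(collection$sets),
    n_found = vapply(collection$sets,
                     function(g) length(intersect(g, rows)), 0L),
    n_total = lengths(collection$sets),
    row.names = NULL)
  out$pct_found <- round(100 * out$n_found / out$n_total, 1)
  out
}
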