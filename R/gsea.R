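#' Signal-to-noise gene ranking for a subtype contrast
#'
#' Per protein, `r = (mu_A - mu_B) / (s_A + s_B)` on glog values, with each
#' group SD floored at `max(0.2 * |mu|, 0.2)` (the minimum-SD convention of
#' the canonical desktop GSEA implementation). The list is sorted by
#' decreasing metric with lexicographic gene-id tie-break.
#'
#' @param matrix A glog-scale [protein_matrix()].
#' @param design A [sample_design()].
#' @param contrast A [subtype_contrast()] (or its name). Each side needs
#'   >= 2 samples.
#' @return Named numeric vector (class `RankedList`), sorted descending.
#' @export
signal2noise_rank <- function(matrix, design, contrast) {
  if (is.character(contrast)) contrast <- subtype_contrast(contrast)
  design <- design[match(colnames(matrix$values), design$sample_id), ]
  cols_a <- design$sample_id[design$subtype %in% contrast$group_a]
  cols_b <- design$sample_id[design$subtype %in% contrast$group_b]
  if (length(cols_a) < 2 || length(cols_b) < 2)
    stop("signal-to-noise is undefined with a one-sample group")
  xa <- matrix$values[, cols_a, drop = FALSE]
  xb <- matrix$values[, cols_b, drop = FALSE]
  ma <- rowMeans(xa); mb <- rowMeans(xb)
  sa <- pmax(row_sds(xa), 0.2 * abs(ma), 0.2)
  sb <- pmax(row_sds(xb), 0.2 * abs(mb), 0.2)
  r <- (ma - mb) / (sa + sb)
  ord <- order(-r, names(r))
  structure(r[ord], class = "RankedList", contrast = contrast$name)
}

#' Weighted Kolmogorov-Smirnov enrichment score
#'
#' Walks the ranked list; genes in the set ("hits") add
#' `|r|^p / sum_hits |r|^p`, genes outside subtract `1/(N - N_H)`. The
#' enrichment score is the signed extremum of the running sum (which starts
#' and ends at 0). With `p = 0` this is the classical KS statistic on hit
#' positions. The leading edge is the hits at or before the extremum for a
#' positive ES, or strictly after it for a negative ES.
#'
#' @param ranked A `RankedList` from [signal2noise_rank()] (or any named,
#'   descending-sorted numeric vector).
#' @param gene_set Character vector of gene symbols; must hit the list at
#'   least once and not cover it entirely.
#' @param weight Exponent p of the weighted statistic (default 1).
#' @return List: `es`, `running` (running-sum vector along the list),
#'   `leading_edge` (gene ids), `n_hits`.
#' @export
enrichment_score <- function(ranked, gene_set, weight = 1) {
  gene_set <- unique(toupper(gene_set))
  hit <- names(ranked) %in% gene_set
  nh <- sum(hit)
  n <- length(ranked)
  if (nh == 0) stop("gene set has no gene in the ranked list")
  if (nh == n) stop("gene set covers the entire ranked list")
  w <- abs(ranked)^weight
  hit_inc <- numeric(n)
  denom <- sum(w[hit])
  hit_inc[hit] <- if (denom > 0) w[hit] / denom else 1 / nh
  miss_dec <- numeric(n)
  miss_dec[!hit] <- 1 / (n - nh)
  running <- cumsum(hit_inc - miss_dec)
  peak <- which.max(abs(running))
  es <- running[peak]
  leading <- if (es > 0) names(ranked)[hit & seq_len(n) <= peak]
             else if (es < 0) names(ranked)[hit & seq_len(n) > peak]
             else character()
  list(es = unname(es), running = unname(running), leading_edge = leading,
       n_hits = nh)
}

#' Gene-set permutation test with NES and FDR
#'
#' For every set, a null distribution of enrichment scores is built from
#' random gene sets of identical size drawn uniformly without replacement
#' from the ranked universe (gene_set permutation, appropriate when the
#' number of samples is too small for phenotype permutation). The nominal p
#' is `(1 + #{null ES at least as extreme, same sign}) / (1 + #{null same
#' sign})`, the NES is the ES divided by the mean |null ES| of the same
#' sign, and the FDR q follows the sign-stratified NES pooling of the
#' original GSEA procedure (`config$gsea_fdr = "bh"` gives BH on nominal p
#' instead). Each (set, permutation) pair consumes an independent
#' substream of the master seed keyed by the set name, so results are
#' independent of set order and duplicated sets score identically.
#'
#' @param ranked A `RankedList`.
#' @param collection A [signature_collection()].
#' @param config A [run_config()] (`n_permutations`, `gsea_weight`,
#'   `gsea_fdr`).
#' @param seed Master seed (defaults to the config seed).
#' @return data.frame of class `GseaResult`: `set`, `size` (hits in the
#'   list), `es`, `nes`, `p_value`, `fdr_q`, `leading_edge`
#'   (';'-separated), `n_permutations`, `p_at_floor`.
#' @export
permutation_test <- function(ranked, collection, config = run_config(),
                             seed = config$seed) {
  universe <- names(ranked)
  nperm <- config$n_permutations
  res <- lapply(names(collection$sets), function(set_name) {
    genes <- collection$sets[[set_name]]
    obs <- enrichment_score(ranked, genes, config$gsea_weight)
    size <- obs$n_hits
    null_es <- vapply(seq_len(nperm), function(j) {
      draw <- with_seed(substream_seed(seed, "gsea", set_name, j),
                        sample(universe, size))
      enrichment_score(ranked, draw, config$gsea_weight)$es
    }, 0)
    same_sign <- null_es[sign(null_es) == sign(obs$es) & null_es != 0]
    p_at_floor <- length(same_sign) == 0
    p <- (1 + sum(abs(same_sign) >= abs(obs$es))) / (1 + length(same_sign))
    nes <- if (length(same_sign)) obs$es / mean(abs(same_sign)) else NA_real_
    pos_mean <- mean(null_es[null_es > 0])
    neg_mean <- mean(abs(null_es[null_es < 0]))
    null_nes <- ifelse(null_es > 0, null_es / pos_mean,
                       ifelse(null_es < 0, null_es / neg_mean, 0))
    list(row = data.frame(set = set_name, size = size, es = obs$es,
                          nes = nes, p_value = p,
                          leading_edge = paste(obs$leading_edge,
                                               collapse = ";"),
                          n_permutations = nperm, p_at_floor = p_at_floor),
         null_nes = null_nes[is.finite(null_nes)])
  })
  out <- do.call(rbind, lapply(res, `[[`, "row"))
  null_nes <- unlist(lapply(res, `[[`, "null_nes"))
  out$fdr_q <- if (config$gsea_fdr == "bh") {
    stats::p.adjust(out$p_value, method = "BH")
  } else {
    vapply(out$nes, gsea_fdr_q, 0, obs_nes = out$nes, null_nes = null_nes)
  }
  out <- out[, c("set", "size", "es", "nes", "p_value", "fdr_q",
                 "leading_edge", "n_permutations", "p_at_floor")]
  rownames(out) <- NULL
  class(out) <- c("GseaResult", "data.frame")
  out
}

# Sign-stratified NES-pooling FDR of the original GSEA method: the ratio of
# the null and observed tail fractions at the set's NES, clipped to [0, 1].
gsea_fdr_q <- function(nes, obs_nes, null_nes) {
  if (is.na(nes)) return(NA_real_)
  if (nes >= 0) {
    null_tail <- sum(null_nes >= nes) / max(1, sum(null_nes >= 0))
    obs_tail <- sum(obs_nes >= nes, na.rm = TRUE) /
      max(1, sum(obs_nes >= 0, na.rm = TRUE))
  } else {
    null_tail <- sum(null_nes <= nes) / max(1, sum(null_nes < 0))
    obs_tail <- sum(obs_nes <= nes, na.rm = TRUE) /
      max(1, sum(obs_nes < 0, na.rm = TRUE))
  }
  min(1, null_tail / max(obs_tail, .Machine$double.eps))
}
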