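# Independent brute-force oracles used to validate the implementation.
# These are deliberately naive re-implementations kept free of any package
# internals.

# Benjamini-Hochberg step-up, literal definition
bh_stepup <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- p[o] * m / seq_len(m)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q <- numeric(m)
  q[o] <- pmin(1, q_sorted)
  q
}

# UPGMA by direct agglomeration on a distance matrix; returns the
# cophenetic distance matrix (label order preserved)
upgma_cophenetic <- function(D) {
  n <- nrow(D)
  labels <- rownames(D)
  clusters <- as.list(seq_len(n))
  coph <- matrix(0, n, n, dimnames = list(labels, labels))
  while (length(clusters) > 1) {
    k <- length(clusters)
    best <- c(Inf, 0, 0)
    for (i in seq_len(k - 1)) for (j in (i + 1):k) {
      d <- mean(D[clusters[[i]], clusters[[j]]])
      if (d < best[1]) best <- c(d, i, j)
    }
    i <- best[2]; j <- best[3]
    for (a in clusters[[i]]) for (b in clusters[[j]]) {
      coph[a, b] <- best[1]; coph[b, a] <- best[1]
    }
    clusters[[i]] <- c(clusters[[i]], clusters[[j]])
    clusters[[j]] <- NULL
  }
  coph
}

# classical two-sample KS-style statistic on hit positions: the signed
# extremum of F_hit - F_miss along the list
ks_hit_statistic <- function(n, hit_positions) {
  hit <- seq_len(n) %in% hit_positions
  nh <- sum(hit)
  running <- cumsum(ifelse(hit, 1 / nh, -1 / (n - nh)))
  running[which.max(abs(running))]
}

# group-by mean of peptide intensities per protein, naive loops
groupby_mean <- function(intensity, protein_id, min_peptides = 2) {
  prots <- sort(unique(protein_id))
  rows <- lapply(prots, function(p) {
    idx <- which(protein_id == p)
    if (length(idx) < min_peptides) return(NULL)
    colMeans(intensity[idx, , drop = FALSE])
  })
  keep <- !vapply(rows, is.null, TRUE)
  out <- do.call(rbind, rows[keep])
  rownames(out) <- prots[keep]
  out
}

# small ready-made cohort shared by several tests (kept tiny for speed)
tiny_cohort <- function(seed = 101, ...) {
  simulate_cellline_cohort(n_proteins = 300, n_signature = 30, seed = seed,
                           ...)
}

# glog matrix for a cohort via the standard pipeline
cohort_glog <- function(cohort, config = run_config(), trim = config$vsn_trim) {
  agg <- aggregate_proteins(impute_missing(cohort$peptides, config), config)
  vsn_normalize(agg, trim = trim)$matrix
}
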