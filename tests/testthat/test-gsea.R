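ranked_fixture <- function(n = 100, seed = 3) {
  set.seed(seed)
  r <- sort(rnorm(n), decreasing = TRUE)
  names(r) <- sprintf("G%03d", sample(n))
  r
}

test_that("signal-to-noise matches the direct formula and its SD floors", {
  design <- default_design()
  ar <- design$subtype == "AR_POS"
  # one gene engineered to mu_A=2, mu_B=1, s_A=s_B=0.5 after flooring
  m <- matrix(rnorm(100 * 18, 5, 1), 100, 18,
              dimnames = list(sprintf("G%03d", 1:100), design$sample_id))
  m["G001", ar] <- c(1.5, 2.5, 1.5, 2.5, 1.5, 2.5, 1.5, 2.5)
  m["G001", !ar] <- rep(c(0.5, 1.5), 5)
  m["G002", ] <- 42                                   # constant everywhere
  pm <- protein_matrix(m, "glog")
  r <- signal2noise_rank(pm, design, "AR_POS_vs_AR_NEG")
  s_floor <- function(v) max(sd(v), 0.2 * abs(mean(v)), 0.2)
  expect_equal(unname(r["G001"]),
               (2 - 1) / (s_floor(m["G001", ar]) + s_floor(m["G001", !ar])),
               tolerance = 1e-12)
  expect_equal(unname(r["G002"]), 0)
  # full brute-force oracle
  oracle <- vapply(rownames(m), function(g) {
    a <- m[g, ar]; b <- m[g, !ar]
    (mean(a) - mean(b)) / (s_floor(a) + s_floor(b))
  }, 0)
  expect_equal(r[names(oracle)], oracle, tolerance = 1e-12)
  # sorted descending with deterministic ordering
  expect_true(all(diff(unname(r)) <= 1e-15))
})

test_that("signal-to-noise refuses one-sample groups", {
  design <- sample_design(c("a", "b", "c"), c("A", "B", "C"),
                          c("AR_POS", "AR_NEG_NE_POS", "AR_NEG_NE_NEG"),
                          c(1, 1, 1))
  m <- matrix(rnorm(15), 5, 3,
              dimnames = list(sprintf("G%d", 1:5), c("a", "b", "c")))
  expect_error(signal2noise_rank(protein_matrix(m, "glog"), design,
                                 "AR_POS_vs_AR_NEG"), "one-sample")
})

test_that("a top-k set under tied weights attains the running-sum closed form", {
  r <- setNames(rep(2, 50), sprintf("G%03d", 1:50))
  top <- names(r)[1:10]
  es <- enrichment_score(r, top, weight = 1)
  expect_equal(es$es, 1)                    # k * (1/k) with no misses before
  expect_equal(es$leading_edge, top)
  # hand-evaluated small case: N=5, hits at 2 and 4, classical weights
  r5 <- setNames(c(5, 4, 3, 2, 1), sprintf("H%d", 1:5))
  es5 <- enrichment_score(r5, c("H2", "H4"), weight = 0)
  expect_equal(es5$running, c(-1/3, 1/6, -1/6, 1/3, 0), tolerance = 1e-12)
  expect_equal(es5$es, 1/3, tolerance = 1e-12)
})

test_that("the running sum terminates at zero", {
  r <- ranked_fixture(200)
  set.seed(5)
  for (k in c(1, 5, 40, 150)) {
    es <- enrichment_score(r, sample(names(r), k), weight = 1)
    expect_lt(abs(es$running[length(es$running)]), 1e-12)
  }
})

test_that("at weight zero the statistic reduces to the KS form on hit positions", {
  r <- ranked_fixture(300, seed = 8)
  set.seed(9)
  for (k in c(3, 20, 100)) {
    genes <- sample(names(r), k)
    es <- enrichment_score(r, genes, weight = 0)
    positions <- which(names(r) %in% genes)
    expect_equal(es$es, ks_hit_statistic(length(r), positions),
                 tolerance = 1e-12)
    # reversing the list negates the unweighted statistic
    rev_r <- rev(r)
    expect_equal(enrichment_score(rev_r, genes, weight = 0)$es, -es$es,
                 tolerance = 1e-12)
    # invariance under order-preserving monotone transforms of the metric
    r2 <- r * 3 + 100
    expect_equal(enrichment_score(r2, genes, weight = 0)$es, es$es,
                 tolerance = 1e-12)
  }
})

test_that("weighted scores agree with an independent GSEA implementation", {
  skip_if_not_installed("fgsea")
  r <- ranked_fixture(250, seed = 12)
  set.seed(13)
  for (k in c(10, 50)) {
    genes <- sample(names(r), k)
    es <- enrichment_score(r, genes, weight = 1)
    ref <- fgsea::calcGseaStat(stats = r,
                               selectedStats = which(names(r) %in% genes),
                               gseaParam = 1, scoreType = "std")
    expect_equal(es$es, ref, tolerance = 1e-9)
  }
})

test_that("degenerate gene sets are rejected", {
  r <- ranked_fixture(20)
  expect_error(enrichment_score(r, "NOT_THERE"), "no gene")
  expect_error(enrichment_score(r, names(r)), "entire")
})

test_that("permutation results are reproducible and order/name independent", {
  r <- ranked_fixture(150, seed = 21)
  set.seed(22)
  sets <- list(S1 = sample(names(r), 15), S2 = sample(names(r), 30),
               S3 = sample(names(r), 8))
  cfg <- run_config(n_permutations = 25)
  g1 <- permutation_test(r, signature_collection(sets), cfg, seed = 5)
  g2 <- permutation_test(r, signature_collection(sets), cfg, seed = 5)
  expect_identical(g1, g2)
  # permuting the collection order leaves per-set results unchanged
  g3 <- permutation_test(r, signature_collection(sets[c(3, 1, 2)]), cfg,
                         seed = 5)
  for (s in names(sets)) {
    expect_equal(g1$es[g1$set == s], g3$es[g3$set == s])
    expect_equal(g1$p_value[g1$set == s], g3$p_value[g3$set == s])
    expect_equal(g1$nes[g1$set == s], g3$nes[g3$set == s])
  }
  # identical membership under the same name gives identical results
  twice <- signature_collection(list(SAME = sets$S1, OTHER = sets$S2))
  twice2 <- signature_collection(list(OTHER = sets$S2, SAME = sets$S1))
  ga <- permutation_test(r, twice, cfg, seed = 5)
  gb <- permutation_test(r, twice2, cfg, seed = 5)
  expect_equal(ga[ga$set == "SAME", ], gb[gb$set == "SAME", ],
               ignore_attr = TRUE)
  # p respects its permutation floor
  expect_true(all(g1$p_value >= 1 / (cfg$n_permutations + 1) - 1e-12))
})

test_that("nominal p-values are calibrated for random gene sets", {
  r <- ranked_fixture(200, seed = 31)
  cfg <- run_config(n_permutations = 19)
  set.seed(32)
  ps <- vapply(1:60, function(i) {
    sets <- setNames(list(sample(names(r), 12)), sprintf("R%02d", i))
    permutation_test(r, signature_collection(sets), cfg, seed = 100 + i)$p_value
  }, 0)
  # uniform-on-grid null: mean about 0.5 with SE ~ 0.29/sqrt(60)
  expect_lt(abs(mean(ps) - 0.5), 4 * 0.29 / sqrt(length(ps)))
  expect_gt(min(ps), 0)
  expect_lte(max(ps), 1)
})

test_that("a planted up-shifted set dominates decoys by NES", {
  cohort <- tiny_cohort(seed = 91)
  glog <- cohort_glog(cohort)
  ranked <- signal2noise_rank(glog, cohort$design, "AR_POS_vs_AR_NEG")
  set.seed(93)
  decoys <- setNames(lapply(1:20, function(i) sample(names(ranked), 30)),
                     sprintf("DECOY_%02d", 1:20))
  coll <- signature_collection(c(
    list(PLANTED = cohort$truth$signature_membership$AR_POS), decoys))
  g <- permutation_test(ranked, coll, run_config(n_permutations = 50),
                        seed = 17)
  expect_equal(g$set[which.max(g$nes)], "PLANTED")
  # no null ES reaches the planted score: p sits at its permutation floor
  expect_true(g$p_at_floor[g$set == "PLANTED"] ||
                g$p_value[g$set == "PLANTED"] <= 0.05)
  expect_lt(g$fdr_q[g$set == "PLANTED"],
            min(g$fdr_q[g$set != "PLANTED"]) + 1e-12)
})

test_that("BH-flavoured GSEA FDR is available as a config switch", {
  r <- ranked_fixture(100, seed = 41)
  set.seed(42)
  sets <- setNames(lapply(1:4, function(i) sample(names(r), 10)),
                   paste0("S", 1:4))
  g <- permutation_test(r, signature_collection(sets),
                        run_config(n_permutations = 19, gsea_fdr = "bh"),
                        seed = 3)
  expect_equal(g$fdr_q, p.adjust(g$p_value, method = "BH"))
})
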