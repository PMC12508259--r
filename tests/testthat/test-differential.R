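toy_glog <- function(seed = 1, n = 40) {
  set.seed(seed)
  design <- default_design()
  m <- matrix(rnorm(n * 18), n, 18,
              dimnames = list(sprintf("P%03d", 1:n), design$sample_id))
  list(pm = protein_matrix(m, "glog"), design = design)
}

test_that("constant proteins get p = 1 and are never significant", {
  t <- toy_glog()
  t$pm$values["P001", ] <- 3
  d <- differential_enrichment(t$pm, t$design, "AR_POS_vs_AR_NEG")
  row <- d[d$protein_id == "P001", ]
  expect_equal(row$p_value, 1)
  expect_false(row$significant)
})

test_that("Welch statistics agree with stats::t.test per protein", {
  t <- toy_glog(seed = 3, n = 25)
  d <- differential_enrichment(t$pm, t$design, "AR_POS_vs_AR_NEG")
  ar <- t$design$subtype == "AR_POS"
  for (p in sample(d$protein_id, 8)) {
    v <- t$pm$values[p, ]
    ref <- stats::t.test(v[ar], v[!ar])
    row <- d[d$protein_id == p, ]
    expect_equal(row$p_value, ref$p.value, tolerance = 1e-12)
    expect_equal(row$t_stat, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(row$mean_diff,
                 unname(ref$estimate[1] - ref$estimate[2]),
                 tolerance = 1e-12)
  }
})

test_that("BH q-values match the worked step-up example and the oracle", {
  expect_equal(p.adjust(c(0.01, 0.02, 0.04), method = "BH"),
               c(0.03, 0.03, 0.04))
  set.seed(7)
  for (n in c(10, 500, 10000)) {
    p <- runif(n)^2
    expect_lt(max(abs(p.adjust(p, method = "BH") - bh_stepup(p))), 1e-12)
  }
})

test_that("BH monotonicity holds in differential output", {
  t <- toy_glog(seed = 5, n = 60)
  d <- differential_enrichment(t$pm, t$design, "AR_NEG_NE_NEG_vs_rest")
  o <- order(d$p_value)
  expect_true(all(diff(d$q_value[o]) >= -1e-12))
  expect_true(all(d$q_value >= d$p_value - 1e-12))
  expect_true(all((d$mean_diff > 0) == (d$enriched_in == d$group_a[1])))
})

test_that("differential recovery on synthetic truth is sensitive and calibrated", {
  cohort <- tiny_cohort(seed = 71)
  glog <- cohort_glog(cohort)
  d <- differential_enrichment(glog, cohort$design, "AR_POS_vs_AR_NEG")
  truth <- intersect(cohort$truth$signature_membership$AR_POS, d$protein_id)
  disc <- d$protein_id[d$significant & d$enriched_in == "AR_POS"]
  expect_gt(length(intersect(disc, truth)) / length(truth), 0.8)
  expect_lt(length(setdiff(disc, truth)) / max(1, length(disc)), 0.1)
})

test_that("Storey q-values are a pi0-shrunk BH", {
  set.seed(9)
  t <- toy_glog(seed = 9, n = 80)
  cfg <- run_config(qvalue_method = "storey")
  d_bh <- differential_enrichment(t$pm, t$design, "AR_POS_vs_AR_NEG")
  d_st <- differential_enrichment(t$pm, t$design, "AR_POS_vs_AR_NEG", cfg)
  expect_true(all(d_st$q_value <= d_bh$q_value + 1e-12))
})

test_that("ternary fractions follow symmetry, corners and the brute-force oracle", {
  design <- default_design()
  set.seed(13)
  m <- matrix(2^rnorm(20 * 18, 10, 1), 20, 18,
              dimnames = list(sprintf("P%02d", 1:20), design$sample_id))
  m["P01", ] <- 50                                        # equal everywhere
  m["P02", design$subtype != "AR_POS"] <- 1e-300          # AR+ exclusive
  pm <- protein_matrix(m, "linear")
  tt <- ternary_fractions(pm, design)
  f <- tt$fractions
  expect_equal(unname(unlist(f[f$protein_id == "P01", CELLLINE_SUBTYPES])),
               rep(100 / 3, 3), tolerance = 1e-9)
  expect_equal(unname(unlist(f[f$protein_id == "P02", CELLLINE_SUBTYPES])),
               c(100, 0, 0), tolerance = 1e-9)
  expect_equal(f$bin[f$protein_id == "P02"], "up_5_0_0")  # the AR+ corner

  # brute-force mean-then-normalise oracle
  for (p in sprintf("P%02d", 3:8)) {
    means <- vapply(CELLLINE_SUBTYPES, function(s)
      mean(m[p, design$subtype == s]), 0)
    expect_equal(unname(unlist(f[f$protein_id == p, CELLLINE_SUBTYPES])),
                 unname(100 * means / sum(means)), tolerance = 1e-9)
  }
  # fractions sum to 100 and density counts account for every protein
  expect_true(all(abs(rowSums(f[, CELLLINE_SUBTYPES]) - 100) < 1e-6))
  expect_equal(sum(tt$density$count), nrow(f))
})

test_that("ternary fractions are invariant to global positive scaling", {
  design <- default_design()
  set.seed(14)
  m <- matrix(2^rnorm(10 * 18, 10, 1), 10, 18,
              dimnames = list(sprintf("P%02d", 1:10), design$sample_id))
  t1 <- ternary_fractions(protein_matrix(m, "linear"), design)
  t2 <- ternary_fractions(protein_matrix(m * 37.5, "linear"), design)
  expect_equal(t1$fractions[CELLLINE_SUBTYPES],
               t2$fractions[CELLLINE_SUBTYPES], tolerance = 1e-9)
  expect_error(ternary_fractions(protein_matrix(log2(m), "glog"), design),
               "linear-scale")
})

test_that("signature derivation applies the three filters in order", {
  d <- data.frame(protein_id = sprintf("P%d", 1:8),
                  group_a = "AR_POS", group_b = "AR_NEG",
                  mean_diff = c(2, 1.5, 1, .8, .6, -1, -2, .1),
                  t_stat = 1, p_value = 0.01,
                  q_value = c(rep(0.01, 5), 0.01, 0.01, 0.5),
                  enriched_in = c(rep("AR_POS", 5), "AR_NEG", "AR_NEG",
                                  "AR_POS"),
                  significant = c(rep(TRUE, 7), FALSE))
  # 5 significant & enriched; 4 patient-detected; 1 healthy-listed
  sig <- derive_subtype_signatures(list(AR_POS = d),
                                   patients = sprintf("P%d", c(1:4, 6:8)),
                                   healthy = "P2")
  expect_equal(sig$provenance$n_significant, 5L)
  expect_equal(sig$provenance$n_patient_detected, 4L)
  expect_equal(sig$provenance$n_final, 3L)
  expect_identical(sig$signatures$AR_POS, c("P1", "P3", "P4"))

  # healthy list covering everything empties the signature
  allh <- derive_subtype_signatures(list(AR_POS = d),
                                    patients = sprintf("P%d", 1:8),
                                    healthy = sprintf("P%d", 1:8))
  expect_equal(allh$provenance$n_final, 0L)
  # no healthy list: final equals patient-detected
  noh <- derive_subtype_signatures(list(AR_POS = d),
                                   patients = sprintf("P%d", c(1:4, 6:8)),
                                   healthy = NULL)
  expect_equal(noh$provenance$n_final, noh$provenance$n_patient_detected)
})

test_that("patient subtype scores average z-scores over signature proteins", {
  set.seed(15)
  m <- matrix(2^rnorm(6 * 5, 8, 1), 6, 5,
              dimnames = list(sprintf("P%d", 1:6), sprintf("pt%d", 1:5)))
  pm <- protein_matrix(m, "linear")
  # single-protein signature: score equals that protein's z-scores
  ps <- patient_subtype_score(pm, list(S = "P3"))
  z <- (m["P3", ] - mean(m["P3", ])) / sd(m["P3", ])
  expect_equal(unname(ps$scores[, "S"]), unname(z), tolerance = 1e-12)
  # patient at the cohort mean for every protein scores 0
  m2 <- m; m2[, "pt5"] <- rowMeans(m[, 1:4])
  m2 <- cbind(m2[, 1:4], pt5 = rowMeans(m2[, 1:4]))
  ps2 <- patient_subtype_score(protein_matrix(m2, "linear"),
                               list(S = sprintf("P%d", 1:6)))
  expect_equal(unname(ps2$scores["pt5", "S"]), 0, tolerance = 1e-12)
  # absent signatures give NA with coverage 0
  ps3 <- patient_subtype_score(pm, list(S = c("NOPE", "NADA")))
  expect_true(all(is.na(ps3$scores)))
  expect_equal(ps3$coverage$n_found, 0L)
})

test_that("pure-mixture patients rank highest on their own subtype score", {
  cohort <- tiny_cohort(seed = 81)
  mix <- rbind(c(1, 0, 0, 0), c(0, 1, 0, 0), c(0, 0, 1, 0),
               c(0.34, 0.33, 0.33, 0))
  pat <- simulate_patient_cohort(cohort, mixtures = mix, n_background = 30,
                                 sigma_patient = 0.1, healthy_frac = 0.1,
                                 seed = 6)
  glog <- cohort_glog(cohort)
  diffs <- lapply(c(AR_POS = "AR_POS_vs_AR_NEG",
                    AR_NEG_NE_NEG = "AR_NEG_NE_NEG_vs_rest",
                    AR_NEG_NE_POS = "AR_NEG_NE_POS_vs_rest"),
                  function(cn) differential_enrichment(glog, cohort$design, cn))
  sig <- derive_subtype_signatures(diffs, pat$patients, pat$healthy)
  ps <- patient_subtype_score(pat$patients, sig)
  for (s in names(sig$signatures)) {
    # mixture columns follow CELLLINE_SUBTYPES order
    expect_equal(unname(which.max(ps$scores[, s])),
                 which(CELLLINE_SUBTYPES == s))
  }
  expect_true(all(sig$provenance$n_significant >=
                    sig$provenance$n_patient_detected))
  expect_true(all(sig$provenance$n_patient_detected >=
                    sig$provenance$n_final))
})
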