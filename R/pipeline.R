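#' Run the full EV subtyping analysis end to end
#'
#' Executes the analysis stages in the fixed order: simulate (or load) a
#' peptide cohort, impute left-censored values, aggregate to proteins,
#' variance-stabilise, call detection, cluster/PCA, subtype-core Venn,
#' signature activity scores, differential enrichment per contrast, GSEA,
#' ternary fractions, patient cohort, subtype-signature derivation with
#' healthy-plasma filtering, and patient projection. Every stochastic stage
#' consumes a named substream of the master seed, so inserting a stage never
#' shifts downstream randomness and identical config + seed gives a
#' byte-identical report.
#'
#' @param config A [run_config()]; `config$seed` is the master seed.
#' @param inputs `NULL` (default) to simulate the study cohort with known
#'   ground truth, or a list with elements `peptides` ([peptide_table()]),
#'   `design`, `signatures` ([signature_collection()]), optional
#'   `ne_reference` (named numeric), `patients` ([protein_matrix()]) and
#'   `healthy`. Recovery metrics against truth are only computed in
#'   simulation mode.
#' @param sim_args List of overrides passed to
#'   [simulate_cellline_cohort()] (e.g. `n_proteins`, `delta`).
#' @param n_decoys Number of random decoy gene sets added to the GSEA
#'   collection in simulation mode.
#' @param n_patients Patients simulated in simulation mode.
#' @param out_dir Optional directory; when given, the report JSON and the
#'   main tables (protein matrices, scores, differential results, GSEA,
#'   ternary, signatures) are written there.
#' @return A list of class `PipelineReport` (all stage outputs and
#'   summaries; see sections in the returned object).
#' @export
run_pipeline <- function(config = run_config(), inputs = NULL,
                         sim_args = list(), n_decoys = 50L,
                         n_patients = 27L, out_dir = NULL) {
  seed <- config$seed
  simulated <- is.null(inputs)

  ## ---- stage: data ----
  if (simulated) {
    cohort <- do.call(simulate_cellline_cohort,
                      c(list(seed = substream_seed(seed, "simulate")),
                        sim_args))
    peptides <- cohort$peptides
    design <- cohort$design
    truth <- cohort$truth
  } else {
    peptides <- inputs$peptides
    design <- inputs$design
    truth <- NULL
  }

  ## ---- stage: preprocess ----
  imputed <- impute_missing(peptides, config,
                            seed = substream_seed(seed, "impute"))
  linear <- aggregate_proteins(imputed, config)
  vsn <- vsn_normalize(linear, trim = config$vsn_trim)
  glog <- vsn$matrix
  detections <- detection_call(peptides, config)
  detections <- detections[intersect(rownames(detections),
                                     rownames(linear$values)), ,
                           drop = FALSE]

  ## ---- stage: structure ----
  clust <- hierarchical_cluster(glog, axis = "samples")
  pca <- pca_project(glog)
  venn <- overlap_counts(detections, design)
  k3 <- cut_clusters(clust, 3)
  purity <- cluster_purity(k3, design)
  sil <- pc_silhouette(pca, design)

  ## ---- stage: signatures in, activity scores ----
  if (simulated) {
    collection <- signature_collection(truth$signature_membership)
    ne_genes <- truth$signature_membership$AR_NEG_NE_POS
    ne_cols <- design$sample_id[design$subtype == "AR_NEG_NE_POS"]
    zs <- row_zscore(glog$values[intersect(ne_genes,
                                           rownames(glog$values)), ,
                                 drop = FALSE])
    ne_reference <- rowMeans(zs[, ne_cols, drop = FALSE])
  } else {
    collection <- inputs$signatures
    ne_genes <- if (!is.null(inputs$ne_reference))
      names(inputs$ne_reference) else character()
    ne_reference <- inputs$ne_reference
  }
  scores <- score_signatures(glog, collection, design)
  ne_score <- if (length(ne_genes) >= 3 && !is.null(ne_reference))
    correlation_ne_score(glog, ne_genes, ne_reference,
                         method = config$ne_method)
  coverage <- signature_coverage(glog, collection)

  ## ---- stage: differential ----
  contrast_names <- c(AR_POS = "AR_POS_vs_AR_NEG",
                      AR_NEG_NE_NEG = "AR_NEG_NE_NEG_vs_rest",
                      AR_NEG_NE_POS = "AR_NEG_NE_POS_vs_rest")
  diffs <- lapply(contrast_names, function(cn) {
    differential_enrichment(glog, design, cn, config)
  })
  diff_summary <- lapply(names(diffs), function(subtype) {
    d <- diffs[[subtype]]
    disc <- d$protein_id[d$significant & d$enriched_in == d$group_a[1]]
    row <- list(contrast = attr(d, "contrast"),
                n_tested = nrow(d), n_enriched = length(disc))
    if (simulated) {
      true_set <- intersect(truth$signature_membership[[subtype]],
                            d$protein_id)
      row$sensitivity <- length(intersect(disc, true_set)) /
        max(1L, length(true_set))
      row$fdr <- length(setdiff(disc, true_set)) / max(1L, length(disc))
    }
    row
  })
  names(diff_summary) <- names(diffs)

  ## ---- stage: gsea ----
  gsea_sets <- collection$sets
  if (simulated && n_decoys > 0) {
    decoys <- with_seed(substream_seed(seed, "decoys"), {
      lapply(seq_len(n_decoys), function(i)
        sample(rownames(glog$values),
               length(truth$signature_membership$AR_POS)))
    })
    names(decoys) <- sprintf("DECOY_%03d", seq_len(n_decoys))
    gsea_sets <- c(gsea_sets, decoys)
  }
  ranked <- signal2noise_rank(glog, design, "AR_POS_vs_AR_NEG")
  gsea <- permutation_test(ranked, signature_collection(gsea_sets),
                           config, seed = substream_seed(seed, "gsea"))

  ## ---- stage: ternary ----
  ternary <- ternary_fractions(linear, design)

  ## ---- stage: patients ----
  if (simulated) {
    pat <- simulate_patient_cohort(cohort, n_patients = n_patients,
                                   seed = substream_seed(seed, "patients"))
    patients <- pat$patients
    healthy <- pat$healthy
    truth <- pat$truth
  } else {
    patients <- inputs$patients
    healthy <- inputs$healthy
  }
  report <- NULL
  signatures <- NULL
  pat_scores <- NULL
  overlap <- NULL
  if (!is.null(patients)) {
    overlap <- cohort_overlap(linear, patients)
    signatures <- derive_subtype_signatures(diffs, patients, healthy, config)
    pat_scores <- patient_subtype_score(patients, signatures)
  }

  report <- structure(list(
    config = unclass(config),
    simulated = simulated,
    data = list(n_peptides = nrow(peptides$intensity),
                n_samples = ncol(peptides$intensity),
                n_proteins_input = length(unique(peptides$protein_id)),
                pct_detected = round(100 * mean(peptides$detected), 2)),
    preprocess = list(n_imputed = attr(imputed, "n_imputed"),
                      impute_q_log2 = attr(imputed, "impute_q"),
                      impute_s_log2 = attr(imputed, "impute_s"),
                      n_proteins_quantified = nrow(linear$values),
                      n_dropped_min_peptides =
                        length(unique(peptides$protein_id)) -
                        nrow(linear$values),
                      vsn_iterations = vsn$calib$iterations,
                      vsn_converged = vsn$calib$converged,
                      vsn_a = as.list(round(vsn$calib$a, 6)),
                      vsn_b = as.list(round(vsn$calib$b, 6))),
    structure = list(leaf_order = clust$order,
                     cluster3_purity = purity,
                     pca_explained = round(pca$explained[1:5], 4),
                     pc12_silhouette = round(sil, 4)),
    venn = list(regions = as.list(venn$regions),
                core_n = length(venn$core),
                core_pct = venn$core_pct),
    scores = list(rescaled = as.data.frame(scores$scores),
                  coverage = coverage,
                  ne = if (!is.null(ne_score))
                    as.list(round(ne_score$score, 4))),
    differential = diff_summary,
    gsea = gsea[, c("set", "size", "es", "nes", "p_value", "fdr_q")],
    ternary = list(n_proteins = nrow(ternary$fractions),
                   n_bins = nrow(ternary$density),
                   n_excluded = length(ternary$excluded)),
    patients = if (!is.null(patients)) list(
      n_patients = ncol(patients$values),
      n_shared = overlap$n_shared,
      signature_provenance = signatures$provenance,
      subtype_scores = as.data.frame(round(pat_scores$scores, 4)))),
    class = "PipelineReport")

  result <- list(report = report, peptides = peptides, design = design,
                 linear = linear, glog = glog, calib = vsn$calib,
                 detections = detections, cluster = clust, pca = pca,
                 scores = scores, ne_score = ne_score, diffs = diffs,
                 ranked = ranked, gsea = gsea, ternary = ternary,
                 patients = patients, healthy = healthy,
                 signatures = signatures, patient_scores = pat_scores,
                 truth = truth)

  if (!is.null(out_dir)) write_pipeline_outputs(result, out_dir)
  result
}

# purity of a k-clustering against subtype labels: fraction of samples in
# the majority subtype of their cluster
cluster_purity <- function(clusters, design) {
  subtype <- design$subtype[match(names(clusters), design$sample_id)]
  sum(vapply(split(subtype, clusters),
             function(s) as.numeric(max(table(s))), 0)) / length(clusters)
}

# mean silhouette width of the subtype labelling in the PC1-PC2 plane
pc_silhouette <- function(pca, design) {
  subtype <- design$subtype[match(rownames(pca$coords), design$sample_id)]
  sil <- cluster::silhouette(as.integer(factor(subtype)),
                             stats::dist(pca$coords[, 1:2]))
  mean(sil[, "sil_width"])
}

# serialise the report and main tables
write_pipeline_outputs <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(unclass(result$report),
                       file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = 10, pretty = TRUE,
                       null = "null")
  write_protein_matrix(result$linear, file.path(out_dir, "protein_linear.tsv"))
  write_protein_matrix(result$glog, file.path(out_dir, "protein_glog.tsv"))
  utils::write.table(data.frame(sample_id = rownames(result$scores$scores),
                                result$scores$scores, check.names = FALSE),
                     file.path(out_dir, "scores.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  for (nm in names(result$diffs))
    utils::write.table(result$diffs[[nm]],
                       file.path(out_dir, paste0("diff_", nm, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(result$gsea, file.path(out_dir, "gsea.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(result$ternary$fractions,
                     file.path(out_dir, "ternary.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(cluster_to_newick(result$cluster),
             file.path(out_dir, "dendrogram.nwk"))
  if (!is.null(result$signatures)) {
    keep <- lengths(result$signatures$signatures) >= 2
    if (any(keep))
      write_gmt(signature_collection(result$signatures$signatures[keep]),
                file.path(out_dir, "subtype_signatures.gmt"))
    utils::write.table(result$signatures$provenance,
                       file.path(out_dir, "signature_provenance.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(out_dir)
}

#' Write a small self-contained fixture bundle
#'
#' Generates a reduced synthetic study (peptide TSV, design TSV, GMT of the
#' true signatures plus decoys, healthy-plasma list, patient matrix TSV,
#' truth JSON, run config YAML) so that every reader and every pipeline
#' stage can be exercised from files.
#'
#' @param dir Output directory (created if needed).
#' @param seed Integer seed.
#' @param n_proteins Proteins in the reduced cohort (<= 200).
#' @return Named character vector of the written file paths.
#' @export
make_fixture <- function(dir, seed = 42L, n_proteins = 150L) {
  stopifnot(n_proteins <= 200)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cohort <- simulate_cellline_cohort(n_proteins = n_proteins,
                                     n_signature = 20L,
                                     seed = substream_seed(seed, "fixture"))
  pat <- simulate_patient_cohort(cohort, n_patients = 8L,
                                 n_background = 40L,
                                 seed = substream_seed(seed, "fixture_pat"))
  decoys <- with_seed(substream_seed(seed, "fixture_decoys"), {
    lapply(1:3, function(i)
      sample(names(cohort$truth$protein_mu_log2), 20))
  })
  names(decoys) <- sprintf("DECOY_%02d", 1:3)
  gmt <- signature_collection(c(cohort$truth$signature_membership, decoys))

  paths <- c(peptides = file.path(dir, "peptides.tsv"),
             design = file.path(dir, "design.tsv"),
             gmt = file.path(dir, "signatures.gmt"),
             healthy = file.path(dir, "healthy_plasma.txt"),
             patients = file.path(dir, "patients.tsv"),
             truth = file.path(dir, "truth.json"),
             config = file.path(dir, "config.yaml"))
  write_peptide_table(cohort$peptides, paths["peptides"])
  write_design(cohort$design, paths["design"])
  write_gmt(gmt, paths["gmt"])
  writeLines(pat$truth$healthy_plasma, paths["healthy"])
  write_protein_matrix(pat$patients, paths["patients"])
  write_truth(pat$truth, paths["truth"])
  yaml::write_yaml(unclass(run_config(seed = seed, n_permutations = 20L)),
                   paths["config"])
  invisible(paths)
}
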