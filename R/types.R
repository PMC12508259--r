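#' Molecular subtype labels used throughout the package
#'
#' The three cell-line-derived prostate cancer subtypes (AR-driven
#' adenocarcinoma, neuroendocrine, double negative) plus labels for patient
#' samples and unannotated samples.
#'
#' @format Character vector of length 5.
#' @export
SUBTYPE_LEVELS <- c("AR_POS", "AR_NEG_NE_POS", "AR_NEG_NE_NEG",
                    "PATIENT", "UNKNOWN")

#' Cell-line subtype labels (the three modelled subtypes)
#' @rdname SUBTYPE_LEVELS
#' @export
CELLLINE_SUBTYPES <- c("AR_POS", "AR_NEG_NE_POS", "AR_NEG_NE_NEG")

#' Construct a sample design table
#'
#' One row per quantified sample, linking the intensity column name to its
#' cell line (or patient id), molecular subtype and biological replicate.
#'
#' @param sample_id Character vector of unique sample (column) ids.
#' @param cell_line Character vector, cell line or donor id per sample.
#' @param subtype Character vector; each element one of [SUBTYPE_LEVELS].
#' @param replicate Integer vector (>= 1), biological replicate index.
#' @return A `data.frame` of class `SampleDesign`.
#' @export
sample_design <- function(sample_id, cell_line, subtype, replicate) {
  subtype <- as.character(subtype)
  replicate <- as.integer(replicate)
  if (anyDuplicated(sample_id))
    stop("sample ids must be unique")
  if (!all(subtype %in% SUBTYPE_LEVELS))
    stop("unknown subtype label(s): ",
         paste(setdiff(subtype, SUBTYPE_LEVELS), collapse = ", "))
  if (any(replicate < 1L))
    stop("replicate indices must be >= 1")
  if (anyDuplicated(paste(cell_line, replicate)))
    stop("(cell_line, replicate) pairs must be unique")
  d <- data.frame(sample_id = as.character(sample_id),
                  cell_line = as.character(cell_line),
                  subtype = subtype,
                  replicate = replicate,
                  stringsAsFactors = FALSE)
  class(d) <- c("SampleDesign", "data.frame")
  d
}

#' The default cell-line study layout
#'
#' Nine prostate cancer cell lines in three molecular subtypes, two
#' biological EV isolations each: AR+ (LNCaP, LNCaP95, C4-2, 22RV1),
#' AR-/NE+ (NCI-H660, EF1, LASCPC-01) and AR-/NE- (PC3, DU145).
#'
#' @return A [sample_design()] table with 18 rows.
#' @export
default_design <- function() {
  lines <- c(LNCaP = "AR_POS", LNCaP95 = "AR_POS", `C4-2` = "AR_POS",
             `22RV1` = "AR_POS",
             `NCI-H660` = "AR_NEG_NE_POS", EF1 = "AR_NEG_NE_POS",
             `LASCPC-01` = "AR_NEG_NE_POS",
             PC3 = "AR_NEG_NE_NEG", DU145 = "AR_NEG_NE_NEG")
  cl <- rep(names(lines), each = 2L)
  rep_i <- rep(1:2, times = length(lines))
  sample_design(sample_id = paste0(cl, "_", rep_i),
                cell_line = cl,
                subtype = rep(unname(lines), each = 2L),
                replicate = rep_i)
}

#' Construct a peptide-level intensity table
#'
#' Linear-scale peptide x sample intensities with an explicit detection mask.
#' A recorded intensity of 0 (or blank on file) means "not detected": LFQ
#' zeros are left-censoring, not measurements.
#'
#' @param intensity Numeric matrix, peptides in rows, samples in columns;
#'   rownames are peptide ids, colnames sample ids. Non-negative.
#' @param protein_id Character vector, one gene symbol per peptide row.
#' @param detected Optional logical matrix of the same shape; defaults to
#'   `intensity > 0`.
#' @return An object of class `PeptideTable`: list with elements
#'   `intensity`, `detected`, `peptide_id`, `protein_id`.
#' @export
peptide_table <- function(intensity, protein_id, detected = NULL) {
  intensity <- as.matrix(intensity)
  if (is.null(rownames(intensity)))
    stop("intensity matrix needs peptide ids as rownames")
  if (is.null(colnames(intensity)))
    stop("intensity matrix needs sample ids as colnames")
  if (anyDuplicated(colnames(intensity)))
    stop("sample ids must be unique")
  if (anyDuplicated(rownames(intensity)))
    stop("peptide ids must be unique")
  if (length(protein_id) != nrow(intensity))
    stop("protein_id must have one entry per peptide")
  if (is.null(detected)) detected <- intensity > 0
  detected <- as.matrix(detected)
  storage.mode(detected) <- "logical"
  if (!identical(dim(detected), dim(intensity)))
    stop("detected mask must match intensity dimensions")
  dimnames(detected) <- dimnames(intensity)
  if (any(intensity < 0, na.rm = TRUE))
    stop("negative intensities are not a valid LFQ measurement")
  if (any(intensity[detected] <= 0))
    stop("detected entries must have positive intensity")
  pt <- list(intensity = intensity,
             detected = detected,
             peptide_id = rownames(intensity),
             protein_id = toupper(as.character(protein_id)))
  class(pt) <- "PeptideTable"
  pt
}

#' @export
print.PeptideTable <- function(x, ...) {
  cat(sprintf("PeptideTable: %d peptides x %d samples, %d proteins, %.1f%% detected\n",
              nrow(x$intensity), ncol(x$intensity),
              length(unique(x$protein_id)),
              100 * mean(x$detected)))
  invisible(x)
}

#' Construct a protein x sample matrix with an explicit scale tag
#'
#' @param values Numeric matrix, proteins in rows (gene-symbol rownames),
#'   samples in columns.
#' @param scale One of `"linear"`, `"log2"`, `"glog"`.
#' @param n_peptides Named integer vector: peptides supporting each protein.
#' @return An object of class `ProteinMatrix`.
#' @export
protein_matrix <- function(values, scale = c("linear", "log2", "glog"),
                           n_peptides = NULL) {
  scale <- match.arg(scale)
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("values need protein rownames and sample colnames")
  if (scale == "linear" && any(values <= 0))
    stop("linear-scale protein values must be positive")
  if (is.null(n_peptides)) {
    n_peptides <- setNames(rep(NA_integer_, nrow(values)), rownames(values))
  } else {
    n_peptides <- n_peptides[rownames(values)]
  }
  pm <- list(values = values, scale = scale, n_peptides = n_peptides)
  class(pm) <- "ProteinMatrix"
  pm
}

#' @export
print.ProteinMatrix <- function(x, ...) {
  cat(sprintf("ProteinMatrix [%s]: %d proteins x %d samples\n",
              x$scale, nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Construct a collection of named gene sets
#'
#' @param sets Named list of character vectors (gene symbols). Duplicates
#'   within a set are removed; symbols are upper-cased.
#' @param reference_profile Optional named numeric vector giving a reference
#'   expression level per gene (used by the correlation-based NE score).
#' @return An object of class `SignatureCollection`.
#' @export
signature_collection <- function(sets, reference_profile = NULL) {
  if (is.null(names(sets)) || any(names(sets) == ""))
    stop("every gene set needs a name")
  sets <- lapply(sets, function(g) unique(toupper(as.character(g))))
  sizes <- lengths(sets)
  if (any(sizes < 2))
    stop("gene sets must contain at least 2 genes: ",
         paste(names(sets)[sizes < 2], collapse = ", "))
  if (!is.null(reference_profile)) {
    if (is.null(names(reference_profile)))
      stop("reference_profile must be a named numeric vector")
    names(reference_profile) <- toupper(names(reference_profile))
  }
  sc <- list(sets = sets, reference_profile = reference_profile)
  class(sc) <- "SignatureCollection"
  sc
}

#' @export
print.SignatureCollection <- function(x, ...) {
  cat(sprintf("SignatureCollection: %d sets (sizes %s)%s\n",
              length(x$sets),
              paste(range(lengths(x$sets)), collapse = "-"),
              if (is.null(x$reference_profile)) "" else ", with reference profile"))
  invisible(x)
}

#' Run configuration defaults
#'
#' Central container for the tunable analysis parameters.
#'
#' @param seed Master seed; every stochastic stage derives a named substream
#'   from it (see [substream_seed()]).
#' @param impute_quantile Quantile of detected log2 intensities used as the
#'   imputation centre (default 0.01, the 1% quantile).
#' @param impute_scope `"global"` (quantile over all samples, the default) or
#'   `"sample"` (per-sample quantile).
#' @param min_peptides Minimum peptides for a protein to be quantified /
#'   called detected (default 2).
#' @param q_threshold FDR threshold for differential significance
#'   (default 0.05).
#' @param n_permutations Gene-set permutations for GSEA (default 100).
#' @param gsea_weight Weight exponent of the enrichment statistic
#'   (default 1, the weighted statistic; 0 gives the classical KS form).
#' @param vsn_trim Fraction of proteins with the largest within-protein
#'   residuals excluded per calibration iteration (default 0.1).
#' @param ne_method Correlation flavour of the NE score, `"pearson"` or
#'   `"spearman"`.
#' @param gsea_fdr `"gsea"` (sign-stratified NES pooling) or `"bh"`
#'   (Benjamini-Hochberg on nominal p).
#' @param qvalue_method `"BH"` (default) or `"storey"` for differential
#'   q-values.
#' @return A list of class `RunConfig`.
#' @export
run_config <- function(seed = 1L,
                       impute_quantile = 0.01,
                       impute_scope = c("global", "sample"),
                       min_peptides = 2L,
                       q_threshold = 0.05,
                       n_permutations = 100L,
                       gsea_weight = 1,
                       vsn_trim = 0.1,
                       ne_method = c("pearson", "spearman"),
                       gsea_fdr = c("gsea", "bh"),
                       qvalue_method = c("BH", "storey")) {
  stopifnot(impute_quantile > 0, impute_quantile < 1,
            min_peptides >= 1, n_permutations >= 1,
            q_threshold > 0, q_threshold < 1,
            vsn_trim >= 0, vsn_trim < 0.5)
  cfg <- list(seed = as.integer(seed),
              impute_quantile = impute_quantile,
              impute_scope = match.arg(impute_scope),
              min_peptides = as.integer(min_peptides),
              q_threshold = q_threshold,
              n_permutations = as.integer(n_permutations),
              gsea_weight = gsea_weight,
              vsn_trim = vsn_trim,
              ne_method = match.arg(ne_method),
              gsea_fdr = match.arg(gsea_fdr),
              qvalue_method = match.arg(qvalue_method))
  class(cfg) <- "RunConfig"
  cfg
}
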