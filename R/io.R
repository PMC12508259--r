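#' Read a peptide-level LFQ table
#'
#' Parses a MaxQuant-style tab-separated peptide table: one row per peptide,
#' a peptide id column, a protein/gene symbol column, and one intensity
#' column per sample. Zero or blank intensities are recorded as "not
#' detected" (LFQ censoring), every other entry must parse as a positive
#' number.
#'
#' @param path Path to a TSV file with a header line.
#' @param design A [sample_design()] table; its `sample_id`s must all be
#'   present as columns.
#' @param peptide_col,protein_col Column names for the peptide id and the
#'   gene symbol (defaults `"peptide_id"`, `"protein_id"`).
#' @return A [peptide_table()].
#' @export
read_peptide_table <- function(path, design,
                               peptide_col = "peptide_id",
                               protein_col = "protein_id") {
  raw <- utils::read.delim(path, check.names = FALSE, colClasses = "character",
                           na.strings = c("", "NA"))
  for (col in c(peptide_col, protein_col))
    if (!col %in% names(raw))
      stop("column '", col, "' not found in ", path)
  missing_samples <- setdiff(design$sample_id, names(raw))
  if (length(missing_samples))
    stop("design sample(s) absent from table: ",
         paste(missing_samples, collapse = ", "))
  vals <- raw[, design$sample_id, drop = FALSE]
  mat <- vapply(vals, function(col) {
    col[is.na(col)] <- "0"
    x <- suppressWarnings(as.numeric(col))
    if (anyNA(x)) stop("non-numeric intensity value in ", path)
    x
  }, numeric(nrow(raw)))
  mat <- matrix(mat, nrow = nrow(raw),
                dimnames = list(raw[[peptide_col]], design$sample_id))
  if (any(mat < 0)) stop("negative intensity in ", path)
  peptide_table(mat, protein_id = raw[[protein_col]])
}

#' Write a peptide table as TSV
#'
#' Inverse of [read_peptide_table()]: undetected cells are written as 0.
#'
#' @param peptides A [peptide_table()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_peptide_table <- function(peptides, path) {
  mat <- peptides$intensity
  mat[!peptides$detected] <- 0
  out <- data.frame(peptide_id = peptides$peptide_id,
                    protein_id = peptides$protein_id,
                    mat, check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample design TSV
#'
#' Columns: `sample_id`, `cell_line`, `subtype`, `replicate`.
#'
#' @param path TSV path.
#' @return A [sample_design()] table.
#' @export
read_design <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "cell_line", "subtype", "replicate")
  if (!all(need %in% names(d)))
    stop("design file must have columns: ", paste(need, collapse = ", "))
  sample_design(d$sample_id, d$cell_line, d$subtype, d$replicate)
}

#' @rdname read_design
#' @param design A [sample_design()] table.
#' @export
write_design <- function(design, path) {
  utils::write.table(as.data.frame(design), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read gene sets in GMT format
#'
#' Each line holds a set name, a description field, then tab-separated gene
#' symbols. Duplicate genes within a line are dropped with a warning; set
#' order is preserved.
#'
#' @param path GMT file path.
#' @return A [signature_collection()].
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty GMT file: ", path)
  sets <- list()
  for (ln in lines) {
    fields <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3)
      stop("malformed GMT line (needs name, description, >=1 gene): ",
           substr(ln, 1, 60))
    genes <- toupper(fields[-(1:2)])
    genes <- genes[nzchar(genes)]
    if (anyDuplicated(genes))
      warning("duplicate genes in set '", fields[1], "' deduplicated")
    sets[[fields[1]]] <- unique(genes)
  }
  signature_collection(sets)
}

#' Write gene sets in GMT format
#'
#' @param collection A [signature_collection()].
#' @param path Output path.
#' @param description Description field written per line.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(collection, path, description = "na") {
  lines <- vapply(names(collection$sets), function(nm) {
    paste(c(nm, description, collection$sets[[nm]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Read a plain gene list (one symbol per line) as a single gene set
#'
#' Blank lines are skipped and symbols upper-cased, matching the symbol
#' convention used throughout (healthy-plasma EV background lists are
#' distributed in this form).
#'
#' @param path Text file path.
#' @param name Name to give the resulting set.
#' @return A [signature_collection()] with one set.
#' @export
read_gene_list <- function(path, name = "gene_list") {
  genes <- trimws(readLines(path, warn = FALSE))
  genes <- genes[nzchar(genes)]
  if (!length(genes)) stop("empty gene list: ", path)
  signature_collection(setNames(list(unique(toupper(genes))), name))
}

#' Read / write a protein x sample matrix TSV
#'
#' First column `protein_id`, optional `n_peptides` column, remaining
#' columns one per sample.
#'
#' @param path TSV path.
#' @param scale Scale tag of the stored values.
#' @return A [protein_matrix()].
#' @export
read_protein_matrix <- function(path, scale = c("linear", "log2", "glog")) {
  scale <- match.arg(scale)
  d <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!"protein_id" %in% names(d))
    stop("protein matrix file must have a protein_id column")
  np <- NULL
  if ("n_peptides" %in% names(d)) {
    np <- setNames(as.integer(d$n_peptides), toupper(d$protein_id))
    d$n_peptides <- NULL
  }
  mat <- as.matrix(d[, setdiff(names(d), "protein_id"), drop = FALSE])
  rownames(mat) <- toupper(d$protein_id)
  protein_matrix(mat, scale = scale, n_peptides = np)
}

#' @rdname read_protein_matrix
#' @param matrix A [protein_matrix()].
#' @export
write_protein_matrix <- function(matrix, path) {
  out <- data.frame(protein_id = rownames(matrix$values),
                    matrix$values, check.names = FALSE,
                    stringsAsFactors = FALSE)
  if (!all(is.na(matrix$n_peptides)))
    out <- cbind(out[1], n_peptides = unname(matrix$n_peptides), out[-1])
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a run configuration from YAML or JSON
#'
#' Unknown keys are rejected; missing keys take the [run_config()] defaults.
#'
#' @param path `.yaml`/`.yml` or `.json` file.
#' @return A [run_config()].
#' @export
read_config <- function(path) {
  vals <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  allowed <- names(formals(run_config))
  extra <- setdiff(names(vals), c(allowed, "stages", "paths", "simulate"))
  if (length(extra))
    stop("unknown config key(s): ", paste(extra, collapse = ", "))
  do.call(run_config, vals[intersect(names(vals), allowed)])
}
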