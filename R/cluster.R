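#' Hierarchical clustering with Pearson-correlation distance, average linkage
#'
#' Items (samples or proteins) are clustered by UPGMA (average linkage) on
#' the distance `d = 1 - Pearson r` between their profiles. Items are
#' ordered lexicographically before agglomeration so that exact ties in
#' merge heights resolve deterministically. Zero-variance items have their
#' correlations defined as 0 (distance 1) and are flagged.
#'
#' @param matrix A [protein_matrix()].
#' @param axis `"samples"` (cluster columns, default) or `"proteins"`.
#' @return List of class `ClusterResult`: `hclust` (the merge tree),
#'   `order` (leaf labels in dendrogram order), `distance` (the `dist`
#'   used), `flagged` (zero-variance item ids).
#' @export
hierarchical_cluster <- function(matrix, axis = c("samples", "proteins")) {
  axis <- match.arg(axis)
  profiles <- if (axis == "samples") matrix$values else t(matrix$values)
  profiles <- profiles[, order(colnames(profiles)), drop = FALSE]
  if (ncol(profiles) < 3) stop("need >= 3 items to cluster")
  sds <- apply(profiles, 2, stats::sd)
  flagged <- colnames(profiles)[sds == 0]
  r <- suppressWarnings(stats::cor(profiles))
  r[!is.finite(r)] <- 0
  diag(r) <- 1
  d <- stats::as.dist(1 - r)
  hc <- stats::hclust(d, method = "average")
  structure(list(hclust = hc, order = hc$labels[hc$order], distance = d,
                 flagged = flagged),
            class = "ClusterResult")
}

#' Cut a ClusterResult into k groups
#'
#' @param cluster A `ClusterResult` from [hierarchical_cluster()].
#' @param k Number of groups.
#' @return Named integer vector of group memberships.
#' @export
cut_clusters <- function(cluster, k) stats::cutree(cluster$hclust, k = k)

#' Serialise a ClusterResult dendrogram as a Newick string
#'
#' @param cluster A `ClusterResult`.
#' @return Newick string (branch lengths from merge heights).
#' @export
cluster_to_newick <- function(cluster) {
  ape::write.tree(ape::as.phylo(cluster$hclust))
}

#' Principal component projection of samples
#'
#' Samples are projected on the principal axes of the protein x sample
#' matrix after row (protein) centering.
#'
#' @param matrix A [protein_matrix()] with >= 3 samples.
#' @return List: `coords` (sample x PC matrix), `explained`
#'   (non-increasing fractions of variance), `sdev`.
#' @export
pca_project <- function(matrix) {
  if (ncol(matrix$values) < 3) stop("need >= 3 samples for PCA")
  p <- stats::prcomp(t(matrix$values), center = TRUE, scale. = FALSE)
  explained <- p$sdev^2 / sum(p$sdev^2)
  list(coords = p$x, explained = explained, sdev = p$sdev)
}

#' Subtype-core Venn summary of protein detection
#'
#' For each cell-line subtype, the subtype set is the proteins detected in
#' every EV isolation (sample) of that subtype. The seven Venn regions of
#' the three subtype sets are reported, together with the all-subtype core
#' and its percentage of the total number of proteins in the detection
#' matrix.
#'
#' @param detections Logical protein x sample matrix
#'   (see [detection_call()]).
#' @param design A [sample_design()] covering the columns.
#' @return List of class `VennSummary`: `sets` (per-subtype protein sets),
#'   `regions` (named counts of the 7 exclusive regions), `core`
#'   (all-subtype protein ids), `core_pct`, `n_total`.
#' @export
overlap_counts <- function(detections, design) {
  design <- design[match(colnames(detections), design$sample_id), ]
  subtypes <- intersect(CELLLINE_SUBTYPES, unique(design$subtype))
  absent <- setdiff(CELLLINE_SUBTYPES, subtypes)
  if (length(absent))
    warning("subtype(s) with zero samples excluded: ",
            paste(absent, collapse = ", "))
  sets <- lapply(subtypes, function(s) {
    cols <- design$sample_id[design$subtype == s]
    rownames(detections)[rowSums(detections[, cols, drop = FALSE]) ==
                           length(cols)]
  })
  names(sets) <- subtypes
  membership <- vapply(sets, function(s) rownames(detections) %in% s,
                       logical(nrow(detections)))
  key <- apply(membership, 1, function(m) paste(subtypes[m], collapse = "&"))
  key <- key[key != ""]
  regions <- table(key)
  core_key <- paste(subtypes, collapse = "&")
  core <- if (length(subtypes) == 3)
    Reduce(intersect, sets) else character()
  structure(list(sets = sets,
                 regions = stats::setNames(as.integer(regions),
                                           names(regions)),
                 core = core,
                 core_pct = round(100 * length(core) / nrow(detections), 1),
                 n_total = nrow(detections)),
            class = "VennSummary")
}

#' Overlap between two protein cohorts
#'
#' @param a,b [protein_matrix()] objects or character vectors of protein
#'   ids.
#' @return List: `shared`, `a_only`, `b_only` (sorted id vectors) and
#'   `n_shared`.
#' @export
cohort_overlap <- function(a, b) {
  ids <- function(x) if (inherits(x, "ProteinMatrix")) rownames(x$values)
                     else toupper(as.character(x))
  a <- unique(ids(a)); b <- unique(ids(b))
  list(shared = sort(intersect(a, b)),
       a_only = sort(setdiff(a, b)),
       b_only = sort(setdiff(b, a)),
       n_shared = length(intersect(a, b)))
}
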