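# Comparison metrics and unsupervised views used to judge integration
# quality: sample-sample correlation, correlation-distance clustering and
# MDS, cross-platform fold-change concordance, most-variable-gene
# selection, and nearest-centroid subtype assignment.

#' Pairwise Pearson correlation between samples
#'
#' @param matrix Gene-by-sample matrix (>= 2 genes, >= 2 samples).
#' @return Symmetric sample-by-sample correlation matrix with unit
#'   diagonal. Zero-variance samples get NA correlations and are listed in
#'   the `undefined_samples` attribute rather than propagating errors.
#' @export
pairwise_correlation <- function(matrix) {
  stopifnot(is.matrix(matrix), nrow(matrix) >= 2L, ncol(matrix) >= 2L)
  sds <- apply(matrix, 2L, stats::sd)
  flat <- if (is.null(colnames(matrix))) which(sds == 0) else
    colnames(matrix)[sds == 0]
  r <- suppressWarnings(stats::cor(matrix))
  diag(r) <- 1
  attr(r, "undefined_samples") <- flat
  r
}

cor_dist <- function(matrix, on = c("samples", "genes")) {
  on <- match.arg(on)
  m <- if (on == "samples") matrix else t(matrix)
  sds <- apply(m, 2L, stats::sd)
  if (any(sds == 0))
    stop("constant item(s): ",
         paste(colnames(m)[sds == 0], collapse = ", "))
  stats::as.dist(1 - stats::cor(m))
}

#' Hierarchical clustering with correlation distance
#'
#' Agglomerative clustering with distance 1 - Pearson r and average
#' linkage (the convention of the classic Cluster/TreeView tools).
#'
#' @param matrix Gene-by-sample matrix.
#' @param on Cluster `"samples"` (default) or `"genes"`.
#' @return An `hclust` object.
#' @export
hcluster <- function(matrix, on = c("samples", "genes")) {
  stats::hclust(cor_dist(matrix, on), method = "average")
}

#' Classical multidimensional scaling of samples
#'
#' Torgerson MDS on the 1 - Pearson correlation distance. Coordinates are
#' centered at the origin; reflection ambiguity is fixed by requiring the
#' first sample's coordinate to be non-negative in every dimension.
#'
#' @param matrix Gene-by-sample matrix with > `dims` samples.
#' @param dims Number of embedding dimensions (default 2).
#' @return Sample-by-dims coordinate matrix (fewer columns, with a
#'   warning, if the distance matrix has lower rank).
#' @export
mds_embed <- function(matrix, dims = 2L) {
  stopifnot(ncol(matrix) >= dims + 1L)
  d <- cor_dist(matrix, "samples")
  fit <- stats::cmdscale(d, k = dims, eig = TRUE)
  coords <- fit$points
  if (ncol(coords) < dims)
    warning("distance matrix rank supports only ", ncol(coords),
            " dimensions")
  for (j in seq_len(ncol(coords)))
    if (coords[1L, j] < 0) coords[, j] <- -coords[, j]
  coords
}

#' Per-gene fold-change concordance between two platforms
#'
#' Computes, in each platform, the per-gene log2 fold change (mean of the
#' second class minus mean of the first) and their Pearson correlation —
#' the standard view of whether two platforms report the same biology.
#'
#' @param a,b Gene-aligned matrices from the two platforms.
#' @param classes_a,classes_b Two-level class labels for the columns of
#'   each platform (both platforms must contain both classes).
#' @return List with `fc` (per-gene data frame of both fold changes) and
#'   `r` (their Pearson correlation).
#' @export
foldchange_concordance <- function(a, b, classes_a, classes_b) {
  stopifnot(identical(rownames(a), rownames(b)))
  fc_of <- function(m, cl) {
    f <- sam_class_factor(m, cl)
    if (any(table(f) == 0L)) stop("a class is missing in one platform")
    rowMeans(m[, f == levels(f)[2L], drop = FALSE]) -
      rowMeans(m[, f == levels(f)[1L], drop = FALSE])
  }
  fa <- fc_of(a, classes_a)
  fb <- fc_of(b, classes_b)
  list(fc = data.frame(gene_id = rownames(a), fc_a = fa, fc_b = fb,
                       stringsAsFactors = FALSE),
       r = stats::cor(fa, fb))
}

#' Most variable genes
#'
#' @param matrix Gene-by-sample matrix.
#' @param n Number of genes to return (<= number of genes).
#' @return Gene IDs of the n largest across-sample variances, ties broken
#'   lexicographically.
#' @export
most_variable_genes <- function(matrix, n) {
  if (n > nrow(matrix)) stop("n exceeds the number of genes")
  v <- apply(matrix, 1L, stats::var)
  ids <- rownames(matrix) %||% as.character(seq_len(nrow(matrix)))
  ids[order(-v, ids)][seq_len(n)]
}

#' Nearest-centroid subtype assignment
#'
#' Each sample is correlated (Spearman by default, the intrinsic-centroid
#' convention; set `method = "pearson"` to switch) with every subtype
#' centroid over the genes shared between matrix and centroid set, after
#' per-gene median-centering of the expression matrix. The assigned
#' subtype is the centroid with the highest correlation; exact ties leave
#' the sample unassigned (NA).
#'
#' @param matrix Gene-by-sample matrix.
#' @param centroids Gene-by-subtype centroid matrix (>= 10 genes must be
#'   shared with `matrix`).
#' @param method Correlation type.
#' @return List with `assignment` (per-sample subtype, NA on ties) and
#'   `scores` (sample-by-subtype correlation matrix).
#' @export
assign_subtypes <- function(matrix, centroids,
                            method = c("spearman", "pearson")) {
  method <- match.arg(method)
  shared <- intersect(rownames(matrix), rownames(centroids))
  if (length(shared) < 10L)
    stop("fewer than 10 genes shared with the centroid set")
  m <- matrix[shared, , drop = FALSE]
  m <- m - apply(m, 1L, stats::median)
  scores <- stats::cor(m, centroids[shared, , drop = FALSE], method = method)
  assignment <- apply(scores, 1L, function(row) {
    top <- which(row == max(row))
    if (length(top) > 1L) NA_character_ else colnames(scores)[top]
  })
  list(assignment = assignment, scores = scores)
}

#' Agreement between two subtype assignments
#'
#' @param labels_a,labels_b Equal-length assignment vectors.
#' @return Percent of positions where both agree (NA counts as
#'   disagreement unless both are NA).
#' @export
subtype_agreement <- function(labels_a, labels_b) {
  stopifnot(length(labels_a) == length(labels_b))
  same <- (!is.na(labels_a) & !is.na(labels_b) & labels_a == labels_b) |
    (is.na(labels_a) & is.na(labels_b))
  100 * mean(same)
}
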