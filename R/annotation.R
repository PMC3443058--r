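#' Build a consensus probe-to-gene map from several annotation resources
#'
#' Microarray probes are re-annotated against current gene models by several
#' independent resources (re-annotation databases, BioMart exports, sequence
#' searches). A probe is retained only when at least `min_agree` resources
#' assign it to the same gene. A probe whose mappings reach the agreement
#' threshold for two *different* genes is ambiguous and is discarded, so the
#' consensus map is a function from probe to gene.
#'
#' @param resources A list of `probe_map_resource` objects (see
#'   [probe_map_resource()]); at least `min_agree` of them.
#' @param min_agree Minimum number of resources that must agree on the same
#'   (probe, gene) pair; must be >= 2.
#' @return A `consensus_map` object: data frame with columns `probe_id`,
#'   `gene_id` and `support` (number of agreeing resources), sorted by
#'   probe_id.
#' @export
build_consensus_map <- function(resources, min_agree = 2L) {
  min_agree <- as.integer(min_agree)
  if (min_agree < 2L) stop("min_agree must be at least 2")
  if (!is.list(resources) || length(resources) < min_agree)
    stop("need at least ", min_agree, " mapping resources, got ",
         length(resources))
  pairs <- do.call(rbind, lapply(resources, function(r) {
    if (!all(c("probe_id", "gene_id") %in% colnames(r)))
      stop("each resource needs probe_id and gene_id columns")
    # within-resource duplicates must not inflate support
    unique(data.frame(probe_id = as.character(r$probe_id),
                      gene_id = as.character(r$gene_id),
                      stringsAsFactors = FALSE))
  }))
  counts <- stats::aggregate(list(support = rep(1L, nrow(pairs))),
                             by = pairs[c("probe_id", "gene_id")], FUN = sum)
  counts <- counts[counts$support >= min_agree, , drop = FALSE]
  # discard probes supported at threshold for more than one gene
  multi <- names(which(table(counts$probe_id) > 1L))
  counts <- counts[!counts$probe_id %in% multi, , drop = FALSE]
  counts <- counts[order(counts$probe_id), c("probe_id", "gene_id", "support")]
  rownames(counts) <- NULL
  class(counts) <- c("consensus_map", "data.frame")
  counts
}

#' Collapse a probe-level matrix to gene level
#'
#' Probes are translated to genes through a consensus map; where several
#' probes represent the same gene their arithmetic mean (on the log2 scale)
#' is taken column-wise. Probes absent from the map are dropped. Output gene
#' rows are in lexicographic order.
#'
#' @param matrix Probe-by-sample numeric matrix (probe IDs as rownames).
#' @param map A `consensus_map` from [build_consensus_map()].
#' @param method Collapsing rule; only `"mean"` is supported.
#' @return Gene-by-sample matrix.
#' @export
collapse_to_genes <- function(matrix, map, method = c("mean")) {
  method <- match.arg(method)
  stopifnot(is.matrix(matrix), !is.null(rownames(matrix)))
  if (nrow(map) == 0L) stop("consensus map is empty")
  keep <- rownames(matrix) %in% map$probe_id
  if (!any(keep))
    stop("no probe in the matrix appears in the consensus map")
  m <- matrix[keep, , drop = FALSE]
  gene <- map$gene_id[match(rownames(m), map$probe_id)]
  out <- rowsum(m, group = gene, reorder = TRUE) /
    as.vector(table(gene)[sort(unique(gene))])
  out <- out[order(rownames(out)), , drop = FALSE]
  out
}

#' Restrict two gene-level matrices to their common gene space
#'
#' Cross-platform integration can only use genes probed by both platforms;
#' both matrices are cut down to the intersection of their gene IDs and
#' returned with identical, lexicographically sorted row order.
#'
#' @param a,b Gene-by-sample matrices with gene IDs as rownames.
#' @return A list with elements `a` and `b`, row-aligned.
#' @export
align_gene_space <- function(a, b) {
  stopifnot(is.matrix(a), is.matrix(b))
  common <- sort(intersect(rownames(a), rownames(b)))
  if (length(common) == 0L)
    stop("no genes in common between the two matrices")
  list(a = a[common, , drop = FALSE], b = b[common, , drop = FALSE])
}
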