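#' Read a gene-by-sample expression matrix from tab-delimited text
#'
#' The expected layout is the one used throughout the pipeline: the first
#' column holds gene (or probe) identifiers, remaining columns hold one
#' sample each, values are log2-scale intensities unless stated otherwise.
#'
#' @param path Path to a TSV file whose first column is `gene_id` (or
#'   `probe_id`) and whose remaining columns are samples.
#' @return A numeric matrix with gene IDs as rownames and sample IDs as
#'   colnames.
#' @export
read_expression_tsv <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L)
    stop("expression table must have an ID column plus at least one sample")
  ids <- as.character(df[[1L]])
  if (anyDuplicated(ids))
    stop("duplicate row identifiers in ", path)
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  m
}

#' Write an expression matrix as tab-delimited text
#'
#' @param matrix Numeric matrix with row and column names.
#' @param path Output path.
#' @param id_column Name for the identifier column (default `"gene_id"`).
#' @export
write_expression_tsv <- function(matrix, path, id_column = "gene_id") {
  stopifnot(is.matrix(matrix), !is.null(rownames(matrix)))
  df <- data.frame(rownames(matrix), matrix, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df)[1L] <- id_column
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a probe-to-gene mapping resource
#'
#' One mapping file per annotation resource (e.g. a re-annotation project,
#' BioMart, or a BLAST search), two tab-separated columns `probe_id` and
#' `gene_id`. A probe may map to several genes within one resource.
#'
#' @param path Path to a two-column TSV with header `probe_id<TAB>gene_id`.
#' @param resource_name Label for the resource; defaults to the file name.
#' @return A `probe_map_resource` object: a data frame of unique
#'   (probe_id, gene_id) pairs with a `resource_name` attribute.
#' @export
read_probe_map <- function(path, resource_name = basename(path)) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  if (!all(c("probe_id", "gene_id") %in% colnames(df)))
    stop("mapping file must have columns 'probe_id' and 'gene_id': ", path)
  probe_map_resource(df$probe_id, df$gene_id, resource_name)
}

#' Construct a probe-mapping resource in memory
#'
#' @param probe_id,gene_id Character vectors of equal length.
#' @param resource_name Label for the resource.
#' @return A `probe_map_resource` data frame of unique pairs.
#' @export
probe_map_resource <- function(probe_id, gene_id, resource_name = "resource") {
  probe_id <- as.character(probe_id)
  gene_id <- as.character(gene_id)
  if (length(probe_id) != length(gene_id))
    stop("probe_id and gene_id must have equal length")
  if (any(!nzchar(probe_id)) || any(!nzchar(gene_id)))
    stop("empty probe or gene identifiers are not allowed")
  df <- unique(data.frame(probe_id = probe_id, gene_id = gene_id,
                          stringsAsFactors = FALSE))
  rownames(df) <- NULL
  attr(df, "resource_name") <- resource_name
  class(df) <- c("probe_map_resource", "data.frame")
  df
}

#' Read a sample design table
#'
#' @param path TSV with a `sample_id` column plus any of `sample_type`,
#'   `platform`, `lab`, `replicate`, `timepoint`, `class`, `pair_id`.
#' @return A data frame keyed by `sample_id`.
#' @export
read_design_tsv <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  if (!"sample_id" %in% colnames(df))
    stop("design table must contain a 'sample_id' column")
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample_id in design table")
  df
}

#' Read a subtype centroid matrix
#'
#' @param path TSV with first column `gene_id` and one column per subtype.
#' @return A numeric gene-by-subtype matrix.
#' @export
read_centroids_tsv <- function(path) read_expression_tsv(path)
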