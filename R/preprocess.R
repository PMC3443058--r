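#' Log2-transform a linear-scale expression matrix
#'
#' @param matrix Linear-scale matrix.
#' @param offset Non-negative constant added before taking logs. With the
#'   default 0, any non-positive value is an error (a silent offset would
#'   change fold changes); the offset must be chosen explicitly.
#' @return `log2(matrix + offset)`.
#' @export
log2_transform <- function(matrix, offset = 0) {
  stopifnot(is.matrix(matrix), offset >= 0)
  bad <- which(matrix + offset <= 0, arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop(sprintf(
      "non-positive value at gene '%s', sample '%s' (value %g, offset %g)",
      rownames(matrix)[bad[1, 1]] %||% bad[1, 1],
      colnames(matrix)[bad[1, 2]] %||% bad[1, 2],
      matrix[bad[1, , drop = FALSE]], offset))
  }
  log2(matrix + offset)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Quantile-normalize the columns of an expression matrix
#'
#' Forces every sample (column) onto the same empirical distribution: the
#' vector of row means of the column-sorted matrix. Ties within a column
#' receive the mean of the reference values at their tied ranks, so the
#' operation is deterministic and rank-preserving. Applied within each
#' platform separately, before any cross-platform correction.
#'
#' @param matrix Gene-by-sample matrix with >= 2 columns. A single-column
#'   matrix is returned unchanged with a warning.
#' @return Matrix of the same shape; all column means equal afterwards.
#' @export
quantile_normalize <- function(matrix) {
  stopifnot(is.matrix(matrix))
  if (ncol(matrix) < 2L) {
    warning("single-column matrix: quantile normalization is a no-op")
    return(matrix)
  }
  out <- limma::normalizeQuantiles(matrix, ties = TRUE)
  dimnames(out) <- dimnames(matrix)
  out
}

#' Filter genes by detection p-value support
#'
#' Single-channel arrays report a per-probe detection p-value (probability
#' the signal is background). A gene is removed when it is undetected
#' (p > `alpha`) in at least `n - margin` of the n samples — equivalently,
#' kept only when detected in at least `margin + 1` samples.
#'
#' @param matrix Gene-by-sample expression matrix.
#' @param detect Matching matrix of detection p-values in [0, 1].
#' @param alpha Detection threshold (default 0.05).
#' @param margin Looseness of the filter (default 3): a gene survives if it
#'   is detected in more than `margin` samples.
#' @return The expression matrix restricted to retained genes.
#' @export
detection_filter <- function(matrix, detect, alpha = 0.05, margin = 3L) {
  stopifnot(is.matrix(matrix), is.matrix(detect),
            alpha >= 0, alpha <= 1, margin >= 0, margin < ncol(matrix))
  if (!identical(dim(matrix), dim(detect)) ||
      !identical(rownames(matrix), rownames(detect)) ||
      !identical(colnames(matrix), colnames(detect)))
    stop("expression and detection matrices must have identical layout")
  n <- ncol(matrix)
  undetected <- rowSums(detect > alpha)
  keep <- undetected < (n - margin)
  matrix[keep, , drop = FALSE]
}
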