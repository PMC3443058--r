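check_batches <- function(matrix, batches, min_per_batch = 1L) {
  if (is.null(names(batches)))
    names(batches) <- colnames(matrix)
  if (!setequal(names(batches), colnames(matrix)))
    stop("every sample column must carry a batch label")
  batches <- batches[colnames(matrix)]
  f <- factor(as.character(batches))
  sizes <- table(f)
  if (any(sizes < min_per_batch))
    stop("each batch needs at least ", min_per_batch, " samples; got: ",
         paste(names(sizes), sizes, sep = "=", collapse = ", "))
  f
}

#' Standardize arrays (columns) of an expression matrix
#'
#' Scales every sample to zero mean and common spread across genes — the
#' per-array standardization that the distance-weighted-discrimination
#' batch-adjustment procedure applies before fitting its direction. To keep
#' values in interpretable log2-like units the standardized columns are
#' rescaled by the pooled (average) column standard deviation and shifted
#' back to the grand mean.
#'
#' @param matrix Gene-by-sample matrix.
#' @return Matrix of the same shape; every column has the same mean and
#'   standard deviation.
#' @export
standardize_arrays <- function(matrix) {
  stopifnot(is.matrix(matrix))
  mu <- colMeans(matrix)
  sds <- apply(matrix, 2L, stats::sd)
  if (any(sds == 0)) stop("constant sample column(s); cannot standardize")
  out <- sweep(sweep(matrix, 2L, mu), 2L, sds, "/")
  out * mean(sds) + mean(mu)
}

#' Mean-center an expression matrix within batches
#'
#' The simplest cross-platform adjustment: for each gene, subtract the
#' within-batch gene mean, so every per-gene per-batch mean is exactly zero
#' afterwards. Removes a constant per-gene platform offset but nothing that
#' varies within a platform.
#'
#' @param matrix Gene-by-sample matrix.
#' @param batches Vector of batch (platform) labels, named by sample ID or
#'   in column order.
#' @return Centered matrix of the same shape.
#' @export
mean_center <- function(matrix, batches) {
  stopifnot(is.matrix(matrix))
  f <- check_batches(matrix, batches, min_per_batch = 1L)
  out <- matrix
  for (b in levels(f)) {
    idx <- which(f == b)
    out[, idx] <- matrix[, idx, drop = FALSE] -
      rowMeans(matrix[, idx, drop = FALSE])
  }
  out
}

#' Empirical-Bayes location/scale batch adjustment
#'
#' Parametric empirical-Bayes batch correction in the ComBat family. Per
#' gene, the model is X_gij = alpha_g + gamma_gi + delta_gi * eps with a
#' normal prior on the per-batch location gamma_gi and an inverse-gamma
#' prior on the squared scale delta^2_gi; hyperparameters are estimated by
#' moments across genes, posterior estimates by iterating the conditional
#' updates to convergence, and the data are adjusted by removing the
#' shrunken location and rescaling the shrunken scale. The shrinkage
#' ("variance moderation") is what lets the method remove platform bias
#' without destroying per-gene biological signal.
#'
#' @param matrix Gene-by-sample matrix, >= 25 genes (the across-gene moment
#'   estimates need many genes to be meaningful).
#' @param batches Batch labels (>= 2 batches, each >= 2 samples).
#' @param max_iter,tol Convergence controls for the posterior iteration.
#' @return List with `corrected` (adjusted matrix) and `model` (a
#'   `combat_model`: grand means, pooled scales, posterior gamma/delta per
#'   batch, hyperparameters, iteration counts, convergence flags).
#' @export
combat_adjust <- function(matrix, batches, max_iter = 100L, tol = 1e-6) {
  stopifnot(is.matrix(matrix))
  f <- check_batches(matrix, batches, min_per_batch = 2L)
  if (nlevels(f) < 2L) stop("need at least two batches")
  if (nrow(matrix) < 25L)
    stop("need at least 25 genes for stable hyperparameter estimation")
  G <- nrow(matrix); N <- ncol(matrix)
  lv <- levels(f); nb <- length(lv)
  n_i <- as.vector(table(f)[lv])

  batch_means <- vapply(lv, function(b)
    rowMeans(matrix[, f == b, drop = FALSE]), numeric(G))
  # weighted grand mean with sum_i (n_i/N) gamma_i = 0
  alpha_hat <- as.vector(batch_means %*% (n_i / N))
  gamma_ls <- batch_means - alpha_hat
  fitted <- alpha_hat + gamma_ls[, as.integer(f), drop = FALSE]
  resid <- matrix - fitted
  sigma2_hat <- rowMeans(resid^2)
  sigma_hat <- sqrt(pmax(sigma2_hat, 1e-16))

  # standardize leaving the batch effects in place
  Z <- (matrix - alpha_hat) / sigma_hat

  gamma_hat <- vapply(lv, function(b)
    rowMeans(Z[, f == b, drop = FALSE]), numeric(G))
  delta2_hat <- vapply(lv, function(b)
    apply(Z[, f == b, drop = FALSE], 1L, stats::var), numeric(G))

  gamma_bar <- colMeans(gamma_hat)
  tau2_bar <- apply(gamma_hat, 2L, stats::var)
  V_bar <- colMeans(delta2_hat)
  S2 <- apply(delta2_hat, 2L, stats::var)
  lambda_hat <- (V_bar^2 + 2 * S2) / S2
  theta_hat <- (V_bar^3 + V_bar * S2) / S2

  gamma_star <- gamma_hat
  delta2_star <- delta2_hat
  iters <- integer(nb)
  converged <- logical(nb)
  for (b in seq_len(nb)) {
    Zb <- Z[, f == lv[b], drop = FALSE]
    n <- n_i[b]
    g <- gamma_hat[, b]; d2 <- delta2_hat[, b]
    for (it in seq_len(max_iter)) {
      g_new <- (n * tau2_bar[b] * gamma_hat[, b] + d2 * gamma_bar[b]) /
        (n * tau2_bar[b] + d2)
      ss <- rowSums((Zb - g_new)^2)
      d2_new <- (theta_hat[b] + 0.5 * ss) / (n / 2 + lambda_hat[b] - 1)
      change <- max(abs(g_new - g), abs(d2_new - d2))
      g <- g_new; d2 <- d2_new
      if (change < tol) break
    }
    iters[b] <- it
    converged[b] <- change < tol
    if (!converged[b])
      warning("posterior iteration did not converge for batch ", lv[b])
    gamma_star[, b] <- g
    delta2_star[, b] <- d2
  }

  corrected <- matrix
  for (b in seq_len(nb)) {
    idx <- which(f == lv[b])
    corrected[, idx] <- (sigma_hat / sqrt(delta2_star[, b])) *
      (Z[, idx, drop = FALSE] - gamma_star[, b]) + alpha_hat
  }
  model <- structure(list(
    batches = lv, n_per_batch = n_i,
    alpha_hat = alpha_hat, sigma_hat = sigma_hat,
    gamma_hat = gamma_hat, delta2_hat = delta2_hat,
    gamma_star = gamma_star, delta2_star = delta2_star,
    gamma_bar = gamma_bar, tau2_bar = tau2_bar,
    lambda_hat = lambda_hat, theta_hat = theta_hat,
    iterations = iters, converged = converged
  ), class = "combat_model")
  list(corrected = corrected, model = model)
}
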