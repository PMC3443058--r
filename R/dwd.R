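# Distance-weighted discrimination for two-batch adjustment.
#
# DWD finds a separating direction w (unit gene-vector) and intercept beta
# minimizing sum_i 1/r_i + C sum_i xi_i with r_i = y_i (w'x_i + beta) + xi_i,
# xi_i >= 0, ||w|| <= 1. Unlike the SVM it pays attention to *all* samples,
# which makes the direction a stable estimate of the systematic batch
# difference. Eliminating xi gives the equivalent smooth objective
#   f(w, beta) = sum_i V(y_i (w'x_i + beta)),
#   V(eta) = 1/eta        for eta >= 1/sqrt(C)
#          = 2*sqrt(C) - C*eta  otherwise,
# which is convex in (w, beta) and differentiable everywhere. With genes >>
# samples the minimizer lies in the span of the samples, so the search runs
# in the <= n_samples-dimensional SVD basis.

dwd_value <- function(eta, C) {
  thr <- 1 / sqrt(C)
  ifelse(eta >= thr, 1 / eta, 2 * sqrt(C) - C * eta)
}

dwd_vprime <- function(eta, C) {
  thr <- 1 / sqrt(C)
  ifelse(eta >= thr, -1 / eta^2, -C)
}

#' Batch adjustment by distance-weighted discrimination
#'
#' Fits the DWD separating direction between exactly two batches and then
#' translates each batch along that direction so that both batch-mean
#' projections coincide at the pooled mean projection (identical batches
#' are therefore left untouched). Only the component of the batch
#' difference lying along the single direction w is removed; anything
#' orthogonal to it stays.
#'
#' @param matrix Gene-by-sample matrix.
#' @param batches Batch labels with exactly 2 levels, each >= 2 samples.
#' @param penalty The DWD penalty C, or `"auto"` (default) for
#'   `100 / median(pairwise inter-batch distance)^2`.
#' @return List with `corrected` and `direction` (a `dwd_direction`: unit
#'   gene-vector `w`, intercept `beta`, per-batch mean projections before
#'   and after adjustment, penalty used, objective value).
#' @export
dwd_adjust <- function(matrix, batches, penalty = "auto") {
  stopifnot(is.matrix(matrix))
  f <- check_batches(matrix, batches, min_per_batch = 2L)
  if (nlevels(f) != 2L)
    stop("DWD adjustment needs exactly 2 batches (apply pairwise for more)")
  y <- ifelse(f == levels(f)[1L], 1, -1)
  n <- ncol(matrix)

  if (identical(penalty, "auto")) {
    i1 <- which(y > 0); i2 <- which(y < 0)
    d2 <- outer(colSums(matrix[, i1, drop = FALSE]^2),
                colSums(matrix[, i2, drop = FALSE]^2), "+") -
      2 * crossprod(matrix[, i1, drop = FALSE], matrix[, i2, drop = FALSE])
    C <- 100 / stats::median(pmax(d2, 1e-12))
  } else {
    C <- as.numeric(penalty)
    if (!is.finite(C) || C <= 0) stop("penalty must be positive")
  }

  # reduce to the span of the (gene-centered) samples
  Xc <- matrix - rowMeans(matrix)
  sv <- svd(Xc, nu = min(n, nrow(matrix)))
  r <- sum(sv$d > max(sv$d[1], 1) * 1e-10)
  if (r < 1L) stop("matrix has no variation; DWD direction undefined")
  U <- sv$u[, seq_len(r), drop = FALSE]
  S <- crossprod(U, matrix)               # r x n coordinates

  obj <- function(par) {
    v <- par[-length(par)]; beta <- par[length(par)]
    nv <- sqrt(sum(v^2)); if (nv < 1e-12) return(1e12)
    u <- v / nv
    eta <- y * (drop(crossprod(u, S)) + beta)
    sum(dwd_value(eta, C))
  }
  grad <- function(par) {
    v <- par[-length(par)]; beta <- par[length(par)]
    nv <- sqrt(sum(v^2)); u <- v / nv
    proj <- drop(crossprod(u, S))
    eta <- y * (proj + beta)
    vp <- dwd_vprime(eta, C)
    gu <- S %*% (vp * y)                   # d f / d u
    gv <- (gu - u * sum(u * gu)) / nv      # chain rule through normalization
    c(as.vector(gv), sum(vp * y))
  }

  m1 <- rowMeans(S[, y > 0, drop = FALSE])
  m2 <- rowMeans(S[, y < 0, drop = FALSE])
  v0 <- m1 - m2
  if (sqrt(sum(v0^2)) < 1e-10) v0 <- rep(1, r)
  u0 <- v0 / sqrt(sum(v0^2))
  starts <- list(c(u0, -sum(u0 * (m1 + m2)) / 2),
                 c(-u0, sum(u0 * (m1 + m2)) / 2))
  fits <- lapply(starts, function(p0)
    stats::optim(p0, obj, grad, method = "BFGS",
                 control = list(maxit = 1000, reltol = 1e-14)))
  best <- fits[[which.min(vapply(fits, `[[`, numeric(1), "value"))]]
  if (!best$convergence %in% c(0L, 1L))
    stop("DWD solver failed: optim convergence code ", best$convergence,
         " (", best$message %||% "no message", ")")
  v <- best$par[-length(best$par)]
  beta <- best$par[length(best$par)]
  u <- v / sqrt(sum(v^2))
  w <- drop(U %*% u)
  w <- w / sqrt(sum(w^2))

  proj <- drop(crossprod(w, matrix))
  # sign convention: batch 1 projects positively before adjustment
  if (mean(proj[f == levels(f)[1L]]) < 0) {
    w <- -w; beta <- -beta; proj <- -proj
  }
  before <- tapply(proj, f, mean)
  grand <- mean(proj)
  corrected <- matrix
  for (b in levels(f)) {
    idx <- which(f == b)
    corrected[, idx] <- corrected[, idx, drop = FALSE] -
      outer(w, rep(before[[b]] - grand, length(idx)))
  }
  after <- tapply(drop(crossprod(w, corrected)), f, mean) - grand
  direction <- structure(list(
    w = w, beta = beta, penalty = C,
    proj_before = before, proj_after = after, proj_center = grand,
    objective = best$value
  ), class = "dwd_direction")
  list(corrected = corrected, direction = direction)
}
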