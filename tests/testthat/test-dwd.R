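# Independent small-instance oracle: minimize the same eliminated-slack DWD
# objective by direct search over the raw (w, beta) parameters (spherical
# parameterization of the unit sphere, many Nelder-Mead restarts), with no
# SVD reduction and no gradient.
dwd_oracle <- function(x, y, C) {
  stopifnot(nrow(x) == 3L)
  vfun <- function(eta) {
    thr <- 1 / sqrt(C)
    ifelse(eta >= thr, 1 / eta, 2 * sqrt(C) - C * eta)
  }
  obj <- function(par) {
    th <- par[1]; ph <- par[2]; beta <- par[3]
    w <- c(sin(th) * cos(ph), sin(th) * sin(ph), cos(th))
    sum(vfun(y * (drop(crossprod(w, x)) + beta)))
  }
  best <- NULL
  set.seed(99)
  for (i in 1:40) {
    p0 <- c(runif(1, 0, pi), runif(1, -pi, pi), rnorm(1))
    fit <- optim(p0, obj, method = "Nelder-Mead",
                 control = list(maxit = 5000, reltol = 1e-12))
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  th <- best$par[1]; ph <- best$par[2]
  list(w = c(sin(th) * cos(ph), sin(th) * sin(ph), cos(th)),
       beta = best$par[3], value = best$value)
}

test_that("dwd direction matches a brute-force small-instance solver", {
  set.seed(8)
  x <- cbind(matrix(c(2, 0, 0), 3, 3) + rnorm(9, 0, 0.3),
             matrix(c(-2, 0, 0), 3, 3) + rnorm(9, 0, 0.3))
  dimnames(x) <- list(paste0("G", 1:3), paste0("S", 1:6))
  b <- two_batch_labels(x, 3)
  fit <- dwd_adjust(x, b, penalty = 1)
  orc <- dwd_oracle(x, ifelse(b == "b1", 1, -1), C = 1)
  expect_lt(abs(fit$direction$objective - orc$value), 1e-4)
  expect_gt(abs(sum(fit$direction$w * orc$w)), 0.999)
})

test_that("dwd finds the separating axis and satisfies its postconditions", {
  set.seed(13)
  G <- 60; n <- 16
  x <- matrix(rnorm(G * n, 0, 0.05), G, n,
              dimnames = list(sprintf("G%03d", 1:G), sprintf("S%03d", 1:n)))
  x[1, 1:8] <- x[1, 1:8] + 3       # batches differ along gene 1 only
  b <- two_batch_labels(x, 8)
  fit <- dwd_adjust(x, b)
  expect_gt(abs(fit$direction$w[1]), 0.99)
  expect_equal(sqrt(sum(fit$direction$w^2)), 1, tolerance = 1e-8)
  expect_lt(max(abs(fit$direction$proj_after)), 1e-6)
  # sign convention: first batch projects positively before adjustment
  expect_gt(fit$direction$proj_before[["b1"]], 0)
  expect_identical(dimnames(fit$corrected), dimnames(x))
})

test_that("dwd leaves identical batches essentially unchanged", {
  base <- random_matrix(80, 6, seed = 17)
  x <- cbind(base, base)
  colnames(x) <- sprintf("S%02d", 1:12)
  b <- two_batch_labels(x, 6)
  fit <- dwd_adjust(x, b)
  expect_lt(max(abs(fit$corrected - x)), 1e-6)
})

test_that("dwd rejects more than two batches and degenerate input", {
  m <- random_matrix(30, 9, seed = 2)
  b3 <- stats::setNames(rep(c("b1", "b2", "b3"), each = 3), colnames(m))
  expect_error(dwd_adjust(m, b3), "exactly 2")
  expect_error(dwd_adjust(matrix(1, 5, 6,
                                 dimnames = list(paste0("G", 1:5),
                                                 paste0("S", 1:6))),
                          stats::setNames(rep(c("a", "b"), each = 3),
                                          paste0("S", 1:6))),
               "no variation")
})

test_that("dwd suppresses biology when batches are class-confounded", {
  # one platform ran only class-A samples, the other only class-B (two
  # single-condition studies merged): the batch means then carry the class
  # signal, the discriminating direction aligns with the biological axis,
  # and translating the batches together erases genuine class separation
  set.seed(31)
  G <- 300
  class_shift <- rnorm(G, 0, 1.5)
  x <- cbind(matrix(rnorm(G * 10, 8, 0.3), G, 10),
             matrix(rnorm(G * 10, 8, 0.3), G, 10) + class_shift)
  dimnames(x) <- list(sprintf("G%03d", 1:G), sprintf("S%03d", 1:20))
  cls <- rep(c("A", "B"), each = 10)
  b <- two_batch_labels(x, 10)
  fit <- dwd_adjust(x, b)
  sep <- function(m) mean(abs(rowMeans(m[, cls == "B", drop = FALSE]) -
                                rowMeans(m[, cls == "A", drop = FALSE])))
  expect_lt(sep(fit$corrected), 0.5 * sep(x))
})
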