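# Cross-platform normalization (XPN): a block-model harmonization.
#
# Genes are clustered into K row-clusters and samples (both platforms
# pooled) into L column-clusters; within each platform the data are modelled
# as x_gi = A[alpha(g), beta(i)] * b_g + c_g + sigma_g * eps_gi, i.e. a
# block mean surface entering each gene through its own sensitivity b_g and
# offset c_g. The per-platform parameters are then replaced by their
# sample-size-weighted cross-platform consensus and each sample is rebuilt
# from the consensus parameters plus its own standardized residual, so
# platform-specific location, sensitivity and scale are harmonized while
# sample-specific signal survives in the residuals. Averaging over repeated
# random clusterings removes dependence on any single k-means solution.

kmeans_safe <- function(x, centers) {
  centers <- min(centers, nrow(unique(x)))
  if (centers <= 1L) return(rep(1L, nrow(x)))
  stats::kmeans(x, centers = centers, nstart = 1L,
                iter.max = 50L)$cluster
}

xpn_fit_platform <- function(x, gcl, scl, K, L, max_iter = 30L, tol = 1e-6) {
  G <- nrow(x); n <- ncol(x)
  cols_l <- split(seq_len(n), factor(scl, levels = seq_len(L)))
  present <- which(lengths(cols_l) > 0L)
  n_l <- lengths(cols_l)
  b <- rep(1, G); c0 <- rep(0, G)
  A <- matrix(0, K, L)
  gidx <- factor(gcl, levels = seq_len(K))
  for (it in seq_len(max_iter)) {
    A_old <- A; b_old <- b; c_old <- c0
    # block means: A_kl = sum_{g in k, i in l} b_g (x_gi - c_g) / (n_l sum b_g^2)
    xc <- x - c0
    sum_b2 <- as.vector(rowsum(b^2, gidx))
    for (l in present) {
      s <- rowSums(xc[, cols_l[[l]], drop = FALSE])
      num <- as.vector(rowsum(b * s, gidx))
      A[, l] <- ifelse(sum_b2 > 1e-12, num / (n_l[l] * sum_b2), 0)
    }
    # gene-wise regression on the block predictor z_gi = A[alpha(g), beta(i)];
    # ridge-stabilized so genes with a flat block profile fall back to a
    # pure location fit instead of an exploding slope
    Z <- A[cbind(rep(gcl, n), rep(scl, each = G))]
    dim(Z) <- c(G, n)
    zbar <- rowMeans(Z); xbar <- rowMeans(x)
    vz <- rowMeans(Z^2) - zbar^2
    cv <- rowMeans(x * Z) - xbar * zbar
    ridge <- 0.01 * mean(vz)
    b <- if (ridge > 1e-12) cv / (vz + ridge) else rep(1, G)
    c0 <- xbar - b * zbar
    # identifiability: mean of b within each row-cluster equals 1
    mk <- as.vector(rowsum(b, gidx)) / as.vector(table(gidx))
    ok <- is.finite(mk) & abs(mk) > 1e-8
    scale_g <- ifelse(ok[gcl], mk[gcl], 1)
    b <- b / scale_g
    A[ok, ] <- A[ok, , drop = FALSE] * mk[ok]
    if (max(abs(A - A_old), abs(b - b_old), abs(c0 - c_old)) < tol) break
  }
  Z <- A[cbind(rep(gcl, n), rep(scl, each = G))]
  dim(Z) <- c(G, n)
  resid <- x - (Z * b + c0)
  sigma <- sqrt(rowMeans(resid^2))
  if (any(sigma < 1e-8)) {
    warning("zero-variance gene(s): residual scale floored at 1e-8")
    sigma <- pmax(sigma, 1e-8)
  }
  list(A = A, b = b, c = c0, sigma = sigma, eps = resid / sigma,
       iterations = it)
}

#' Cross-platform normalization of two gene-aligned matrices
#'
#' @param a,b Gene-by-sample matrices with identical rownames (use
#'   [align_gene_space()] first). Each platform must have at least `L`
#'   samples.
#' @param K Number of gene (row) clusters.
#' @param L Number of sample (column) clusters.
#' @param reps Number of random clustering repetitions averaged.
#' @param seed Master seed; per-repetition seeds are derived from it.
#' @return List with `corrected` (the combined gene x (n_a + n_b) matrix,
#'   columns of `a` first) and `model` (an `xpn_model` with the last
#'   repetition's cluster assignments, consensus parameters, and the
#'   per-repetition seeds).
#' @export
xpn_normalize <- function(a, b, K = 25L, L = 5L, reps = 30L, seed = 1L) {
  stopifnot(is.matrix(a), is.matrix(b))
  if (!identical(rownames(a), rownames(b)))
    stop("gene spaces must be aligned (identical rownames)")
  G <- nrow(a); n1 <- ncol(a); n2 <- ncol(b); n <- n1 + n2
  if (K > G) stop("K exceeds the number of genes")
  if (L > min(n1, n2))
    stop("each platform needs at least L samples")
  combined <- cbind(a, b)
  plat <- rep(1:2, c(n1, n2))

  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(as.integer(seed))
  rep_seeds <- sample.int(.Machine$integer.max, reps)

  acc <- matrix(0, G, n)
  last <- NULL
  # clustering must reflect biology, not the platform difference the method
  # is about to remove: cluster on per-gene platform-centered data
  centered <- combined
  centered[, plat == 1] <- combined[, plat == 1, drop = FALSE] -
    rowMeans(combined[, plat == 1, drop = FALSE])
  centered[, plat == 2] <- combined[, plat == 2, drop = FALSE] -
    rowMeans(combined[, plat == 2, drop = FALSE])
  for (r in seq_len(reps)) {
    set.seed(rep_seeds[r])
    # sample clustering on column-standardized platform-centered data
    cs <- scale(centered)
    cs[!is.finite(cs)] <- 0
    scl <- kmeans_safe(t(cs), L)
    # gene clustering on row-standardized platform-centered profiles
    rs <- t(scale(t(centered)))
    rs[!is.finite(rs)] <- 0
    gcl <- kmeans_safe(rs, K)
    Ku <- max(gcl); Lu <- max(scl)

    fit1 <- xpn_fit_platform(a, gcl, scl[plat == 1], Ku, Lu)
    fit2 <- xpn_fit_platform(b, gcl, scl[plat == 2], Ku, Lu)

    # sample-size weighted consensus; blocks absent from a platform take
    # the other platform's value
    w1 <- n1 / n; w2 <- n2 / n
    has1 <- matrix(tabulate(scl[plat == 1], Lu) > 0, Ku, Lu, byrow = TRUE)
    has2 <- matrix(tabulate(scl[plat == 2], Lu) > 0, Ku, Lu, byrow = TRUE)
    wA1 <- ifelse(has1 & has2, w1, as.numeric(has1))
    wA2 <- ifelse(has1 & has2, w2, as.numeric(has2))
    A_star <- wA1 * fit1$A + wA2 * fit2$A
    b_star <- w1 * fit1$b + w2 * fit2$b
    c_star <- w1 * fit1$c + w2 * fit2$c
    sigma_star <- w1 * fit1$sigma + w2 * fit2$sigma

    rebuild <- function(fit, scl_p) {
      np <- length(scl_p)
      Z <- A_star[cbind(rep(gcl, np), rep(scl_p, each = G))]
      dim(Z) <- c(G, np)
      Z * b_star + c_star + sigma_star * fit$eps
    }
    acc <- acc + cbind(rebuild(fit1, scl[plat == 1]),
                       rebuild(fit2, scl[plat == 2]))
    last <- list(gene_clusters = gcl, sample_clusters = scl,
                 A_consensus = A_star, b_consensus = b_star,
                 c_consensus = c_star, sigma_consensus = sigma_star)
  }
  corrected <- acc / reps
  dimnames(corrected) <- list(rownames(a), c(colnames(a), colnames(b)))
  model <- structure(c(list(K = K, L = L, reps = reps, seed = seed,
                            rep_seeds = rep_seeds, n_a = n1, n_b = n2),
                       last), class = "xpn_model")
  list(corrected = corrected, model = model)
}
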