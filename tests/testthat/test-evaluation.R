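test_that("pairwise correlation matches the direct formula", {
  m <- toy_matrix(c(1, 2, 4, 2, 4, 7, 9, 3, 1), samples = paste0("s", 1:3))
  r <- pairwise_correlation(m)
  manual <- function(x, y) {
    xd <- x - mean(x); yd <- y - mean(y)
    sum(xd * yd) / sqrt(sum(xd^2) * sum(yd^2))
  }
  expect_equal(r["s1", "s2"], manual(m[, 1], m[, 2]), tolerance = 1e-12)
  expect_equal(r["s1", "s3"], manual(m[, 1], m[, 3]), tolerance = 1e-12)
  expect_true(isSymmetric(unname(r)))
  expect_equal(unname(diag(r)), rep(1, 3))
  # duplicated and negated samples
  m2 <- cbind(m, s4 = m[, 1], s5 = -m[, 1])
  r2 <- pairwise_correlation(m2)
  expect_equal(unname(r2["s1", "s4"]), 1)
  expect_equal(unname(r2["s1", "s5"]), -1)
  # zero-variance sample flagged, not fatal
  m3 <- cbind(m, flat = c(2, 2, 2))
  r3 <- pairwise_correlation(m3)
  expect_identical(attr(r3, "undefined_samples"), "flat")
})

test_that("hierarchical clustering merges by correlation distance", {
  set.seed(101)
  m <- random_matrix(50, 4, seed = 101)
  m <- cbind(m, twin = m[, 2] + 1e-9 * rnorm(50))
  hc <- hcluster(m)
  # the identical pair merges first
  first <- sort(abs(hc$merge[1, ]))
  expect_identical(sort(hc$labels[first]), sort(c("S002", "twin")))
  # two-block structure splits at the top
  pattern <- rep(c(5, -5), each = 10)
  blk <- cbind(a1 = pattern, a2 = pattern, b1 = -pattern, b2 = -pattern) +
    matrix(rnorm(80, 0, 0.1), 20)
  rownames(blk) <- paste0("g", 1:20)
  hc2 <- hcluster(blk)
  top <- cutree(hc2, 2)
  expect_equal(unname(top), c(1, 1, 2, 2))
  expect_error(hcluster(cbind(blk, flat = rep(1, 20))), "flat")
})

test_that("hcluster reproduces a brute-force average-linkage oracle", {
  set.seed(103)
  m <- random_matrix(30, 5, seed = 103)
  d <- as.matrix(1 - cor(m)); diag(d) <- NA
  # naive agglomeration: track merge heights of average linkage
  active <- as.list(seq_len(5)); heights <- numeric(0)
  dm <- d
  while (length(active) > 1) {
    n <- length(active)
    best <- c(Inf, 0, 0)
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      h <- mean(d[active[[i]], active[[j]]])
      if (h < best[1]) best <- c(h, i, j)
    }
    heights <- c(heights, best[1])
    active[[best[2]]] <- c(active[[best[2]]], active[[best[3]]])
    active[[best[3]]] <- NULL
  }
  hc <- hcluster(m)
  expect_equal(hc$height, heights, tolerance = 1e-12)
})

test_that("classical MDS embeds correlation distances faithfully", {
  # three samples: any 3-point metric embeds exactly in the plane
  m <- random_matrix(40, 3, seed = 105)
  coords <- mds_embed(m, dims = 2)
  d_in <- as.matrix(1 - cor(m))
  d_out <- as.matrix(dist(coords))
  expect_equal(unname(d_out), unname(d_in), tolerance = 1e-8)
  # orientation convention: first sample non-negative in every dimension
  expect_true(all(coords[1, ] >= 0))
  # samples on a 1-D gradient: second coordinate negligible
  g <- seq(0, 1, length.out = 6)
  grad <- outer(rnorm(100), rep(1, 6)) + outer(rnorm(100, 0, 1), g)
  colnames(grad) <- paste0("s", 1:6); rownames(grad) <- paste0("g", 1:100)
  cg <- mds_embed(grad, dims = 2)
  expect_lt(sd(cg[, 2]) / sd(cg[, 1]), 0.3)
})

test_that("fold-change concordance shows the expected attenuation", {
  set.seed(107)
  G <- 10000
  fc_true <- rnorm(G, 0, 1)
  build <- function(fc) {
    m <- matrix(8, G, 8) + outer(fc / 2, c(-1, -1, -1, -1, 1, 1, 1, 1))
    dimnames(m) <- list(sprintf("g%05d", 1:G), paste0("s", 1:8))
    m
  }
  cls <- rep(c("c1", "c2"), each = 4)
  a <- build(fc_true)
  b <- build(fc_true + rnorm(G, 0, 1))      # equal-variance noise added
  expect_equal(foldchange_concordance(a, a, cls, cls)$r, 1)
  expect_equal(foldchange_concordance(a, b, cls, cls)$r, 1 / sqrt(2),
               tolerance = 0.03)
  noise <- build(rnorm(G))
  expect_lt(abs(foldchange_concordance(a, noise, cls, cls)$r), 0.05)
})

test_that("most variable genes are ranked with deterministic ties", {
  m <- toy_matrix(c(1, 1, 5, 2, 1, 1, 5, 0), genes = c("gB", "gFlat",
                                                       "gA", "gC"),
                  samples = c("s1", "s2"))
  # variances: gB 0, gFlat 0, gA 0, gC 2 -> gC first, then ties by ID
  expect_identical(most_variable_genes(m, 2), c("gC", "gA"))
  expect_identical(most_variable_genes(m, 4), c("gC", "gA", "gB", "gFlat"))
  expect_error(most_variable_genes(m, 5), "exceeds")
})

test_that("subtype assignment follows the nearest centroid", {
  set.seed(109)
  G <- 60
  cents <- matrix(rnorm(G * 3), G, 3,
                  dimnames = list(sprintf("g%03d", 1:G),
                                  c("basal", "lumA", "lumB")))
  m <- cbind(s1 = cents[, "lumA"] + 5,          # centroid plus a constant
             s2 = -cents[, "basal"] * 2 + rnorm(G, 0, 0.01))
  m <- cbind(m, s3 = cents[, "basal"] + rnorm(G, 0, 0.05))
  rownames(m) <- rownames(cents)
  out <- assign_subtypes(m, cents)
  expect_equal(unname(out$assignment["s1"]), "lumA")
  expect_equal(unname(out$assignment["s3"]), "basal")
  expect_equal(subtype_agreement(out$assignment, out$assignment), 100)
  expect_error(assign_subtypes(m[1:5, ], cents), "fewer than 10")
})

test_that("metrics are invariant to sample order", {
  m <- random_matrix(80, 6, seed = 111)
  perm <- c(4, 2, 6, 1, 3, 5)
  r1 <- pairwise_correlation(m)
  r2 <- pairwise_correlation(m[, perm])
  expect_equal(r1[colnames(m), colnames(m)],
               r2[colnames(m), colnames(m)])
  expect_identical(most_variable_genes(m, 10),
                   most_variable_genes(m[, perm], 10))
})
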