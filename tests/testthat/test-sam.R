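test_that("unpaired statistic matches its closed forms", {
  m <- toy_matrix(rep(c(1, 3), each = 3), genes = "g1",
                  samples = paste0("s", 1:6))
  m <- rbind(m, g2 = c(2, 2, 2, 2, 2, 2))
  cls <- rep(c("c1", "c2"), each = 3)
  out <- sam_statistic(m, cls, s0 = 0.5)
  # zero within-group scatter: r = 2, s = 0, d = 2 / 0.5 = 4
  expect_equal(out$r[1], 2)
  expect_equal(out$s[1], 0)
  expect_equal(out$d[1], 4)
  # equal group means -> d = 0
  expect_equal(out$d[2], 0)
  expect_error(sam_statistic(m[, 1:4], rep(c("a", "b"), c(3, 1))),
               "at least 2")
})

test_that("d reconciles with the two-sample t statistic", {
  m <- random_matrix(50, 12, seed = 81)
  cls <- rep(c("c1", "c2"), each = 6)
  out <- sam_statistic(m, cls, s0 = 0.3)
  tstats <- unname(apply(m, 1L, function(y)
    unname(t.test(y[7:12], y[1:6], var.equal = TRUE)$statistic)))
  # r / s is exactly the equal-variance t statistic
  expect_equal(out$r / out$s, tstats, tolerance = 1e-10)
  expect_equal(out$d, tstats * out$s / (out$s + 0.3), tolerance = 1e-10)
})

test_that("paired statistic works on differences", {
  m <- random_matrix(30, 8, seed = 83)
  cls <- rep(c("t1_pre", "t2_post"), 4)   # sort order fixes the contrast
  prs <- rep(paste0("p", 1:4), each = 2)
  # identical pre/post -> d = 0
  m_same <- m; m_same[, cls == "t2_post"] <- m_same[, cls == "t1_pre"]
  expect_true(all(sam_paired(m_same, cls, prs, s0 = 0.1)$d == 0))
  # constant +1 shift in every pair, s0 = 0.1 -> r = 1, s = 0, d = 10
  m_shift <- m_same
  m_shift[, cls == "t2_post"] <- m_shift[, cls == "t1_pre"] + 1
  out <- sam_paired(m_shift, cls, prs, s0 = 0.1)
  expect_true(all(abs(out$r - 1) < 1e-12))
  expect_equal(out$d, rep(10, nrow(m)), tolerance = 1e-12)
  # agreement with the one-sample t on differences: r / s = t
  out2 <- sam_paired(m, cls, prs, s0 = 0)
  z <- m[, c(2, 4, 6, 8)] - m[, c(1, 3, 5, 7)]
  tstats <- unname(apply(z, 1L, function(y) unname(t.test(y)$statistic)))
  expect_equal(out2$r / out2$s, tstats, tolerance = 1e-10)
  expect_error(sam_paired(m[, 1:7], cls[1:7], prs[1:7]), "incomplete")
})

test_that("choose_s0 behaves on degenerate and heteroscedastic data", {
  set.seed(85)
  expect_warning(s0c <- choose_s0(rnorm(200), rep(2, 200)), "equal")
  expect_equal(s0c, 2)
  # heteroscedastic: d spread blows up at small s unless s0 > 0
  s <- runif(2000, 0.01, 1)
  r <- rnorm(2000, 0, 0.5 + s)      # extra spread at small s relative to s
  expect_gt(choose_s0(r, s), 0)
})

test_that("permutation FDR: enumeration, monotonicity, null behavior", {
  set.seed(87)
  m <- random_matrix(100, 6, seed = 87)
  m[1:10, 4:6] <- m[1:10, 4:6] + 3
  cls <- rep(c("c1", "c2"), each = 3)
  # 3v3: permutation space is choose(6,3) = 20 -> always enumerated
  r20 <- sam_fdr(m, cls, s0 = 0.2, n_perm = 20, seed = 1)
  r50 <- sam_fdr(m, cls, s0 = 0.2, n_perm = 50, seed = 999)
  expect_true(r20$enumerated)
  expect_equal(r20$fdr_table$fdr, r50$fdr_table$fdr)
  expect_equal(r20$n_perm_used, 20)
  # n_called non-increasing in delta
  expect_true(all(diff(r20$fdr_table$n_called) <= 0))
  # pure null at large delta calls nothing
  null <- random_matrix(300, 12, seed = 88)
  rn <- sam_fdr(null, rep(c("a", "b"), each = 6), s0 = 0.2,
                n_perm = 100, delta_grid = c(0.5, 5), seed = 2)
  expect_equal(rn$fdr_table$n_called[rn$fdr_table$delta == 5], 0)
  expect_equal(rn$fdr_table$fdr[rn$fdr_table$delta == 5], 0)
  expect_error(sam_fdr(m, cls, delta_grid = numeric(0)), "non-empty")
})

test_that("top lists are deterministic prefixes and overlap is exact", {
  tab <- data.frame(gene_id = c("gB", "gA", "gC", "gD"),
                    d = c(2, -2, 1, 0.5))
  expect_identical(top_genes(tab, 2), c("gA", "gB"))   # tie -> lexicographic
  expect_identical(top_genes(tab, 4), c("gA", "gB", "gC", "gD"))
  for (k in 1:3)
    expect_true(all(top_genes(tab, k) %in% top_genes(tab, k + 1)))
  expect_error(top_genes(tab, 5), "exceeds")
  expect_equal(gene_list_overlap(c("a", "b"), c("a", "b"), 2)$percent, 100)
  expect_equal(gene_list_overlap(c("a", "b"), c("c", "d"), 2)$percent, 0)
  ab <- paste0("g", 1:1000)
  cd <- c(paste0("g", 1:500), paste0("x", 1:500))
  expect_equal(gene_list_overlap(ab, cd, 1000)$percent, 50)
  expect_error(gene_list_overlap(ab, cd, 0), "positive")
})

test_that("power grows with the number of pairs at fixed FDR", {
  called_at_fdr <- function(n_pairs) {
    sim <- simulate_clinical(n_genes = 600, n_pairs = n_pairs,
                             n_common = 0, offset_sd = 0, slope_sdlog = 0,
                             seed = 91)
    cls <- clinical_classes(sim, "P1")
    m <- sim$platform1
    res <- sam_fdr(m, cls[colnames(m)], pairs = clinical_pairs(sim, colnames(m)),
                   n_perm = 100, seed = 5)
    ok <- res$fdr_table$fdr <= 0.05
    if (!any(ok)) 0L else max(res$fdr_table$n_called[ok])
  }
  counts <- vapply(c(6, 12, 24), called_at_fdr, numeric(1))
  expect_true(all(diff(counts) > 0))
})
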