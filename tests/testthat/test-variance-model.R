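# Independent EMS oracle: nested mean squares computed with explicit loops.
ems_oracle <- function(y, des) {
  s <- unique(des$sample_type); t <- unique(des$platform)
  u <- unique(des$lab); v <- length(unique(des$replicate))
  grand <- mean(y)
  m_i <- sapply(s, function(i) mean(y[des$sample_type == i]))
  ss_a <- length(t) * length(u) * v * sum((m_i - grand)^2)
  ss_b <- 0; ss_c <- 0; ss_e <- 0
  for (i in s) for (j in t) {
    sel_ij <- des$sample_type == i & des$platform == j
    m_ij <- mean(y[sel_ij])
    ss_b <- ss_b + length(u) * v * (m_ij - m_i[i])^2
    for (k in u) {
      sel <- sel_ij & des$lab == k
      m_ijk <- mean(y[sel])
      ss_c <- ss_c + v * (m_ijk - m_ij)^2
      ss_e <- ss_e + sum((y[sel] - m_ijk)^2)
    }
  }
  ns <- length(s); nt <- length(t); nu <- length(u)
  ms_a <- ss_a / (ns - 1); ms_b <- ss_b / (ns * (nt - 1))
  ms_c <- ss_c / (ns * nt * (nu - 1)); ms_e <- ss_e / (ns * nt * nu * (v - 1))
  c(sample = (ms_a - ms_b) / (nt * nu * v),
    platform = (ms_b - ms_c) / (nu * v),
    lab = (ms_c - ms_e) / v,
    residual = ms_e)
}

balanced_toy_design <- function(s = 2, t = 2, u = 2, v = 2) {
  g <- expand.grid(replicate = paste0("R", 1:v), lab = paste0("L", 1:u),
                   platform = paste0("P", 1:t),
                   sample_type = LETTERS[1:s], stringsAsFactors = FALSE)
  nested_design(paste0("s", seq_len(nrow(g))), g$sample_type, g$platform,
                g$lab, g$replicate)
}

test_that("anova estimates match the hand-computed EMS solution", {
  des <- balanced_toy_design()
  set.seed(61)
  # large, well-separated components so the solution is interior
  y <- 10 + rnorm(2, 0, 3)[match(des$sample_type, c("A", "B"))] +
    rnorm(4, 0, 2)[as.integer(interaction(des$sample_type, des$platform))] +
    rnorm(8, 0, 1)[as.integer(interaction(des$sample_type, des$platform,
                                          des$lab))] +
    rnorm(16, 0, 0.2)
  m <- matrix(y, 1, dimnames = list("g1", des$sample_id))
  fit <- fit_nested_components(m, des, method = "anova")
  oracle <- ems_oracle(y, des)
  expect_true(all(oracle > 0))        # interior instance
  expect_equal(unname(as.matrix(fit[1, 2:5])[1, ]), unname(oracle),
               tolerance = 1e-10)
  # REML agrees on the same interior data
  reml <- fit_nested_components(m, des, method = "reml")
  expect_lt(max(abs(as.matrix(reml[1, 2:5]) - as.matrix(fit[1, 2:5]))), 1e-6)
})

test_that("constant genes yield all-zero components", {
  des <- balanced_toy_design()
  m <- matrix(5, 2, 16, dimnames = list(c("g1", "g2"), des$sample_id))
  for (meth in c("anova", "reml")) {
    fit <- fit_nested_components(m, des, method = meth)
    expect_true(all(as.matrix(fit[, 2:5]) == 0))
  }
})

test_that("balanced REML agrees with the lme4 oracle", {
  sim <- simulate_maqc(n_genes = 20, seed = 71)
  fit <- fit_nested_components(sim$matrix, sim$design, method = "reml")
  des <- as.data.frame(sim$design)
  dat <- data.frame(
    st = factor(des$sample_type),
    pl = interaction(des$sample_type, des$platform, drop = TRUE),
    lb = interaction(des$sample_type, des$platform, des$lab, drop = TRUE))
  for (g in c(1, 7, 20)) {
    dat$y <- sim$matrix[g, ]
    lf <- suppressMessages(lme4::lmer(
      y ~ 1 + (1 | st) + (1 | pl) + (1 | lb), data = dat, REML = TRUE,
      control = lme4::lmerControl(check.conv.singular = "ignore")))
    vc <- as.data.frame(lme4::VarCorr(lf))
    oracle <- c(vc$vcov[vc$grp == "st"], vc$vcov[vc$grp == "pl"],
                vc$vcov[vc$grp == "lb"], vc$vcov[vc$grp == "Residual"])
    expect_equal(unname(as.matrix(fit[g, 2:5])[1, ]), oracle,
                 tolerance = 1e-3)
  }
})

test_that("unbalanced designs are refused by anova and handled by reml", {
  sim <- simulate_maqc(n_genes = 5, seed = 73)
  keep <- colnames(sim$matrix)[-1]     # drop one column -> unbalanced
  m <- sim$matrix[, keep]
  des <- sim$design[sim$design$sample_id %in% keep, ]
  class(des) <- c("nested_design", "data.frame")
  expect_error(fit_nested_components(m, des, method = "anova"), "reml")
  fit <- fit_nested_components(m, des, method = "reml")
  expect_true(all(as.matrix(fit[, 2:5]) >= 0))
  expect_true(all(fit$total > 0))
})

test_that("pooled fractions obey their algebra", {
  vc <- data.frame(gene_id = c("g1", "g2"),
                   sigma2_sample = c(3, 1), sigma2_platform = c(1, 3),
                   sigma2_lab = c(0, 0), sigma2_residual = c(0, 0))
  vc$total <- rowSums(vc[, 2:5]); vc$converged <- TRUE
  class(vc) <- c("variance_components", "data.frame")
  one <- pool_fractions(vc[1, ])
  expect_equal(unname(one$fractions), c(0.75, 0.25, 0, 0))
  # equal totals, mirrored components: pooled = mean of per-gene fractions
  both <- pool_fractions(vc)
  expect_equal(unname(both$fractions),
               unname(colMeans(as.matrix(both$per_gene[, -1]))))
  expect_equal(sum(both$fractions), 1, tolerance = 1e-12)
  vc0 <- vc; vc0$total <- 0
  expect_error(pool_fractions(vc0), "positive total")
})

test_that("platform fraction rises monotonically with platform variance", {
  fr <- vapply(c(0.5, 1, 2), function(s2b) {
    sim <- simulate_maqc(n_genes = 300,
                         sigma2 = c(sample = 4, platform = s2b,
                                    lab = 0.25, residual = 0.04),
                         seed = 77)
    pool_fractions(fit_nested_components(sim$matrix, sim$design,
                                         method = "anova"))$fractions[["platform"]]
  }, numeric(1))
  expect_true(all(diff(fr) > 0))
})
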