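# Per-gene nested random-effects variance decomposition.
#
# The measurement model for a gene is
#   X_ijkl = mu + A_i + B_ij + C_ijk + e_ijkl
# with sample type i, platform j nested in sample type, laboratory k nested
# in platform, and replicate hybridization l. All effects are independent
# zero-mean random draws, so the variance of an observation splits into
# sigma2_sample + sigma2_platform + sigma2_lab + sigma2_residual. Each
# replicate is hybridized once, so the replicate effect and the residual
# measurement error are not separately identifiable and are estimated as a
# single residual ("inter-replicate") component.

#' Describe the nested design of an expression matrix
#'
#' @param sample_id,sample_type,platform,lab,replicate Equal-length vectors,
#'   one entry per sample. `lab` labels are interpreted within platform and
#'   `platform` labels within sample type (strict nesting is imposed by
#'   construction).
#' @return A `nested_design` data frame with a `balanced` attribute.
#' @export
nested_design <- function(sample_id, sample_type, platform, lab, replicate) {
  df <- data.frame(sample_id = as.character(sample_id),
                   sample_type = as.character(sample_type),
                   platform = as.character(platform),
                   lab = as.character(lab),
                   replicate = as.character(replicate),
                   stringsAsFactors = FALSE)
  if (anyDuplicated(df$sample_id)) stop("duplicate sample_id in design")
  attr(df, "balanced") <- design_is_balanced(df)
  class(df) <- c("nested_design", "data.frame")
  df
}

design_is_balanced <- function(df) {
  t_per_s <- tapply(df$platform, df$sample_type,
                    function(x) length(unique(x)))
  u_per_sp <- tapply(df$lab, interaction(df$sample_type, df$platform,
                                         drop = TRUE),
                     function(x) length(unique(x)))
  v_per_spl <- table(interaction(df$sample_type, df$platform, df$lab,
                                 drop = TRUE))
  length(unique(t_per_s)) == 1L && length(unique(u_per_sp)) == 1L &&
    length(unique(as.vector(v_per_spl))) == 1L
}

balanced_strata <- function(design) {
  s <- length(unique(design$sample_type))
  t <- length(unique(design$platform[design$sample_type ==
                                       design$sample_type[1]]))
  u <- length(unique(design$lab[design$sample_type == design$sample_type[1] &
                                  design$platform == design$platform[1]]))
  v <- nrow(design) / (s * t * u)
  list(s = s, t = t, u = u, v = v)
}

# Sums of squares per nesting stratum, vectorized over genes.
nested_ss <- function(matrix, design) {
  dims <- balanced_strata(design)
  s <- dims$s; t <- dims$t; u <- dims$u; v <- dims$v
  f_s <- factor(design$sample_type)
  f_sp <- interaction(design$sample_type, design$platform, drop = TRUE)
  f_spl <- interaction(design$sample_type, design$platform, design$lab,
                       drop = TRUE)
  group_means <- function(f) {
    counts <- as.vector(table(f))
    t(rowsum(t(matrix), f) / counts)
  }
  m_s <- group_means(f_s)
  m_sp <- group_means(f_sp)
  m_spl <- group_means(f_spl)
  grand <- rowMeans(matrix)
  # expand cell means back to (coarser) groupings for differences
  sp_to_s <- tapply(as.character(f_s), f_sp, `[`, 1L)[colnames(m_sp)]
  spl_to_sp <- tapply(as.character(f_sp), f_spl, `[`, 1L)[colnames(m_spl)]
  ss_A <- t * u * v * rowSums((m_s - grand)^2)
  ss_B <- u * v * rowSums((m_sp - m_s[, sp_to_s, drop = FALSE])^2)
  ss_C <- v * rowSums((m_spl - m_sp[, spl_to_sp, drop = FALSE])^2)
  m_cell_expanded <- m_spl[, as.character(f_spl), drop = FALSE]
  ss_res <- rowSums((matrix - m_cell_expanded)^2)
  list(ss = cbind(A = ss_A, B = ss_B, C = ss_C, res = ss_res),
       df = c(A = s - 1, B = s * (t - 1), C = s * t * (u - 1),
              res = s * t * u * (v - 1)),
       mult = rbind(A = c(t * u * v, u * v, v, 1),
                    B = c(0, u * v, v, 1),
                    C = c(0, 0, v, 1),
                    res = c(0, 0, 0, 1)),
       dims = dims)
}

reml_balanced_gene <- function(ss, df, mult, start_list, tol = 1e-10) {
  # restricted log-likelihood (up to a constant) of a balanced nested
  # design is a function of the stratum variances lambda = mult %*% sigma2
  nll <- function(theta) {
    lam <- drop(mult %*% exp(theta))
    if (any(lam <= 0)) return(1e12)
    0.5 * sum(df * log(lam) + ss / lam)
  }
  gr <- function(theta) {
    s2 <- exp(theta)
    lam <- drop(mult %*% s2)
    dlam <- 0.5 * (df / lam - ss / lam^2)
    drop(crossprod(mult, dlam)) * s2
  }
  best <- NULL
  for (st in start_list) {
    fit <- try(stats::optim(log(pmax(st, 1e-6)), nll, gr, method = "BFGS",
                            control = list(maxit = 500, reltol = 1e-15)),
               silent = TRUE)
    if (inherits(fit, "try-error")) next
    # a later start must improve genuinely, not by floating-point noise,
    # so an exact stationary first start (the EMS solution) is kept
    if (is.null(best) ||
        fit$value < best$value - 1e-9 * (1 + abs(best$value))) best <- fit
  }
  if (is.null(best)) return(list(sigma2 = rep(NA_real_, 4), converged = FALSE))
  s2 <- exp(best$par)
  s2[s2 < 1e-8] <- 0       # boundary components reported as zero
  list(sigma2 = s2, converged = best$convergence == 0L)
}

#' Fit per-gene nested variance components
#'
#' Decomposes each gene's variance into inter-sample, inter-platform,
#' inter-laboratory and residual (inter-replicate) components under the
#' nested random-effects model. Two estimators are available: `"anova"`
#' solves the expected-mean-squares equations on a balanced design
#' (negative solutions truncated to zero), `"reml"` maximizes the
#' restricted likelihood (natively constrained to non-negative components;
#' on balanced designs via the closed-form stratum likelihood, on
#' unbalanced designs via \pkg{lme4}).
#'
#' @param matrix Gene-by-sample matrix.
#' @param design A `nested_design` covering every column of `matrix`.
#' @param method `"reml"` (default) or `"anova"`.
#' @return A `variance_components` data frame with one row per gene:
#'   `sigma2_sample`, `sigma2_platform`, `sigma2_lab`, `sigma2_residual`,
#'   `total`, `converged`; the estimator is recorded in the `method`
#'   attribute.
#' @export
fit_nested_components <- function(matrix, design,
                                  method = c("reml", "anova")) {
  method <- match.arg(method)
  stopifnot(is.matrix(matrix))
  if (!all(colnames(matrix) %in% design$sample_id))
    stop("design does not cover every sample column")
  design <- design[match(colnames(matrix), design$sample_id), , drop = FALSE]
  balanced <- design_is_balanced(design)
  G <- nrow(matrix)

  const <- rowSums(abs(matrix - rowMeans(matrix))) < 1e-12

  if (method == "anova") {
    if (!balanced)
      stop("ANOVA estimator requires a balanced design; use method = 'reml'")
    parts <- nested_ss(matrix, design)
    ms <- sweep(parts$ss, 2L, parts$df, "/")
    d <- parts$dims
    s2_res <- ms[, "res"]
    s2_C <- (ms[, "C"] - ms[, "res"]) / d$v
    s2_B <- (ms[, "B"] - ms[, "C"]) / (d$u * d$v)
    s2_A <- (ms[, "A"] - ms[, "B"]) / (d$t * d$u * d$v)
    out <- cbind(sigma2_sample = pmax(s2_A, 0),
                 sigma2_platform = pmax(s2_B, 0),
                 sigma2_lab = pmax(s2_C, 0),
                 sigma2_residual = pmax(s2_res, 0))
    converged <- rep(TRUE, G)
  } else if (balanced) {
    parts <- nested_ss(matrix, design)
    ms <- sweep(parts$ss, 2L, parts$df, "/")
    d <- parts$dims
    ems <- cbind((ms[, "A"] - ms[, "B"]) / (d$t * d$u * d$v),
                 (ms[, "B"] - ms[, "C"]) / (d$u * d$v),
                 (ms[, "C"] - ms[, "res"]) / d$v,
                 ms[, "res"])
    out <- matrix(0, G, 4)
    converged <- rep(TRUE, G)
    for (g in seq_len(G)) {
      if (const[g]) next
      tot <- sum(pmax(ems[g, ], 0))
      if (tot <= 0) tot <- ms[g, "res"] + 1e-8
      starts <- list(pmax(ems[g, ], tot * 1e-4),
                     rep(tot / 4, 4))
      fit <- reml_balanced_gene(parts$ss[g, ], parts$df, parts$mult, starts)
      out[g, ] <- fit$sigma2
      converged[g] <- fit$converged
    }
    colnames(out) <- c("sigma2_sample", "sigma2_platform", "sigma2_lab",
                       "sigma2_residual")
  } else {
    out <- matrix(NA_real_, G, 4,
                  dimnames = list(NULL, c("sigma2_sample", "sigma2_platform",
                                          "sigma2_lab", "sigma2_residual")))
    converged <- rep(TRUE, G)
    st <- factor(design$sample_type)
    pl <- interaction(design$sample_type, design$platform, drop = TRUE)
    lb <- interaction(design$sample_type, design$platform, design$lab,
                      drop = TRUE)
    dat <- data.frame(st = st, pl = pl, lb = lb)
    for (g in seq_len(G)) {
      if (const[g]) { out[g, ] <- 0; next }
      dat$y <- matrix[g, ]
      fit <- try(suppressMessages(suppressWarnings(
        lme4::lmer(y ~ 1 + (1 | st) + (1 | pl) + (1 | lb), data = dat,
                   REML = TRUE,
                   control = lme4::lmerControl(
                     check.conv.singular = "ignore")))), silent = TRUE)
      if (inherits(fit, "try-error")) { converged[g] <- FALSE; next }
      vc <- as.data.frame(lme4::VarCorr(fit))
      get_vc <- function(grp) {
        v <- vc$vcov[vc$grp == grp]
        if (length(v)) v else 0
      }
      out[g, ] <- c(get_vc("st"), get_vc("pl"), get_vc("lb"),
                    get_vc("Residual"))
      converged[g] <- length(fit@optinfo$conv$lme4$messages) == 0L
    }
  }

  out[const, ] <- 0
  res <- data.frame(gene_id = rownames(matrix) %||% as.character(seq_len(G)),
                    out, total = rowSums(out), converged = converged,
                    stringsAsFactors = FALSE)
  attr(res, "method") <- method
  class(res) <- c("variance_components", "data.frame")
  res
}

#' Pool per-gene variance components into level fractions
#'
#' The pooled fraction of a level is the sum of that level's component over
#' genes divided by the sum of totals (sums-based pooling is stable when
#' many genes have tiny totals; set `how = "mean"` for the mean of per-gene
#' fractions instead).
#'
#' @param components A `variance_components` data frame.
#' @param how `"sums"` (default) or `"mean"`.
#' @return List with `fractions` (named numeric summing to 1), `per_gene`
#'   (per-gene fraction data frame over genes with positive total), and the
#'   pooling rule used.
#' @export
pool_fractions <- function(components, how = c("sums", "mean")) {
  how <- match.arg(how)
  cols <- c("sigma2_sample", "sigma2_platform", "sigma2_lab",
            "sigma2_residual")
  pos <- components$total > 0
  if (!any(pos)) stop("no gene has positive total variance")
  m <- as.matrix(components[pos, cols])
  per_gene <- m / components$total[pos]
  fr <- if (how == "sums") colSums(m) / sum(m) else colMeans(per_gene)
  names(fr) <- c("sample", "platform", "lab", "residual")
  pg <- data.frame(gene_id = components$gene_id[pos], per_gene,
                   stringsAsFactors = FALSE)
  colnames(pg)[-1] <- names(fr)
  list(fractions = fr, per_gene = pg, how = how)
}
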