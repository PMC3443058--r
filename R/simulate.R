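# Synthetic-data generators reproducing the two benchmark designs:
#
# * a reference-RNA titration experiment: four sample types (A = 100% UHRR,
#   B = 100% HBRR, C = 75/25, D = 25/75 mixes, mixed on the linear scale)
#   hybridized on 2 platforms x 3 labs x 5 replicates, with independent
#   log2-scale random effects at the sample, platform, lab and replicate
#   levels;
# * a paired clinical study: patients measured at baseline and after
#   treatment on two platforms, a treatment effect on a subset of genes,
#   and gene-wise platform bias (additive offset plus multiplicative
#   sensitivity slope — the bias structure location-only corrections cannot
#   fully remove).
#
# Every draw is recorded in a truth list so recovery metrics can be
# computed without re-deriving parameters.

#' Simulate a reference-RNA titration (MAQC-like) experiment
#'
#' @param n_genes Number of genes.
#' @param sigma2 Named numeric: variances of the `sample`, `platform`,
#'   `lab` and `residual` random effects on the log2 scale.
#' @param n_platforms,n_labs,n_reps Platforms, labs per platform, and
#'   replicates per lab.
#' @param baseline_mean,baseline_sd Gene-level log2 baselines for the two
#'   pure reference pools are drawn N(baseline_mean, baseline_sd^2).
#' @param platform_offset_sd Optional gene-wise additive offset applied to
#'   the second platform, drawn N(0, platform_offset_sd^2) (0 = no bias).
#' @param platform_slope_sdlog Optional gene-wise multiplicative
#'   sensitivity of the second platform, drawn LogNormal(0, sdlog^2)
#'   (0 = no bias).
#' @param seed Seed for all draws.
#' @return List with `matrix` (gene x sample), `design` (a
#'   [nested_design()]), and `truth` (all drawn effects and bias
#'   parameters).
#' @export
simulate_maqc <- function(n_genes = 1000L,
                          sigma2 = c(sample = 4, platform = 1,
                                     lab = 0.25, residual = 0.04),
                          n_platforms = 2L, n_labs = 3L, n_reps = 5L,
                          baseline_mean = 8, baseline_sd = 2,
                          platform_offset_sd = 0,
                          platform_slope_sdlog = 0,
                          seed = 1L) {
  stopifnot(all(sigma2 >= 0), n_genes >= 1, n_platforms >= 1,
            n_labs >= 1, n_reps >= 1)
  set.seed(as.integer(seed))
  G <- n_genes
  types <- c("A", "B", "C", "D")
  s <- length(types); t <- n_platforms; u <- n_labs; v <- n_reps

  mu_A <- stats::rnorm(G, baseline_mean, baseline_sd)
  mu_B <- stats::rnorm(G, baseline_mean, baseline_sd)
  mix <- c(A = 1, B = 0, C = 0.75, D = 0.25)   # fraction of pool A, linear
  base <- vapply(types, function(ty)
    log2(mix[[ty]] * 2^mu_A + (1 - mix[[ty]]) * 2^mu_B), numeric(G))
  sample_eff <- matrix(stats::rnorm(G * s, 0, sqrt(sigma2[["sample"]])), G, s,
                       dimnames = list(NULL, types))
  sample_means <- base + sample_eff

  plat_eff <- array(stats::rnorm(G * s * t, 0, sqrt(sigma2[["platform"]])),
                    c(G, s, t))
  lab_eff <- array(stats::rnorm(G * s * t * u, 0, sqrt(sigma2[["lab"]])),
                   c(G, s, t, u))

  design <- expand.grid(replicate = paste0("R", seq_len(v)),
                        lab = paste0("L", seq_len(u)),
                        platform = paste0("P", seq_len(t)),
                        sample_type = types,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  design <- design[, c("sample_type", "platform", "lab", "replicate")]
  design$sample_id <- do.call(paste, c(design, sep = "_"))

  si <- match(design$sample_type, types)
  pi_ <- as.integer(sub("P", "", design$platform))
  li <- as.integer(sub("L", "", design$lab))
  n <- nrow(design)
  x <- sample_means[, si, drop = FALSE] +
    plat_eff[cbind(rep(seq_len(G), n), rep(si, each = G),
                   rep(pi_, each = G))] +
    lab_eff[cbind(rep(seq_len(G), n), rep(si, each = G),
                  rep(pi_, each = G), rep(li, each = G))] +
    stats::rnorm(G * n, 0, sqrt(sigma2[["residual"]]))
  dim(x) <- c(G, n)

  offsets <- if (platform_offset_sd > 0)
    stats::rnorm(G, 0, platform_offset_sd) else rep(0, G)
  slopes <- if (platform_slope_sdlog > 0)
    stats::rlnorm(G, 0, platform_slope_sdlog) else rep(1, G)
  second <- pi_ == 2L
  if (t >= 2L && (platform_offset_sd > 0 || platform_slope_sdlog > 0))
    x[, second] <- slopes * x[, second, drop = FALSE] + offsets

  gene_ids <- sprintf("G%05d", seq_len(G))
  dimnames(x) <- list(gene_ids, design$sample_id)
  des <- nested_design(design$sample_id, design$sample_type,
                       design$platform, design$lab, design$replicate)
  truth <- list(sigma2 = sigma2, gene_ids = gene_ids,
                baseline = base, sample_effects = sample_eff,
                sample_means = sample_means,
                platform_effects = plat_eff, lab_effects = lab_eff,
                platform_offsets = offsets, platform_slopes = slopes,
                dims = c(s = s, t = t, u = u, v = v), seed = seed)
  list(matrix = x, design = des, truth = truth)
}

#' Realized variance components of a titration simulation
#'
#' Converts the drawn effects in a `simulate_maqc()` truth record into the
#' per-gene variance components actually realized in that draw (empirical
#' variances of the drawn effect values), in the same layout as
#' [fit_nested_components()] so recovery can be assessed with
#' [pool_fractions()].
#'
#' @param truth The `truth` element of a [simulate_maqc()] result.
#' @return A `variance_components` data frame.
#' @export
realized_components <- function(truth) {
  G <- length(truth$gene_ids)
  var_rows <- function(m) apply(m, 1L, stats::var)
  s2_sample <- var_rows(truth$sample_means)
  s2_platform <- var_rows(matrix(truth$platform_effects, nrow = G))
  s2_lab <- var_rows(matrix(truth$lab_effects, nrow = G))
  s2_res <- rep(truth$sigma2[["residual"]], G)
  out <- data.frame(gene_id = truth$gene_ids,
                    sigma2_sample = s2_sample,
                    sigma2_platform = s2_platform,
                    sigma2_lab = s2_lab,
                    sigma2_residual = s2_res,
                    stringsAsFactors = FALSE)
  out$total <- rowSums(out[, 2:5])
  out$converged <- TRUE
  attr(out, "method") <- "realized"
  class(out) <- c("variance_components", "data.frame")
  out
}

#' Simulate a paired two-platform clinical study
#'
#' Patients are measured at baseline and after treatment; a subset of genes
#' carries a treatment effect. The second platform reads each gene through
#' its own sensitivity slope and additive offset plus replicate noise, and
#' per-platform detection p-values mark a configurable fraction of genes as
#' silent.
#'
#' @param n_genes Number of genes.
#' @param n_pairs Patients (baseline/post-treatment pairs) per platform.
#' @param n_common Patients assayed on both platforms (<= n_pairs); the
#'   remaining patients of each platform are independent, as in a study
#'   that extends an existing cohort on a second platform.
#' @param frac_affected Fraction of expressed genes with a treatment
#'   effect.
#' @param effect_sd Treatment effect sizes are drawn N(0, effect_sd^2)
#'   (log2 scale).
#' @param response_sd Per-patient heterogeneity of the treatment effect on
#'   affected genes, N(0, response_sd^2).
#' @param patient_sd Patient-level baseline deviations N(0, patient_sd^2).
#' @param noise_sd Replicate noise per measurement.
#' @param offset_sd Gene-wise platform-2 additive offset N(0, offset_sd^2).
#' @param slope_sdlog Gene-wise platform-2 sensitivity LogNormal(0,
#'   slope_sdlog^2).
#' @param silent_frac Fraction of genes undetected on both platforms.
#' @param baseline_mean,baseline_sd Gene-level log2 baselines.
#' @param seed Seed for all draws.
#' @return List with `platform1`, `platform2` (gene x sample matrices),
#'   `detection1`, `detection2`, `design` (sample metadata incl. pair and
#'   class), and `truth`.
#' @export
simulate_clinical <- function(n_genes = 2000L, n_pairs = 30L, n_common = 6L,
                              frac_affected = 0.25, effect_sd = 1,
                              response_sd = 0.25,
                              patient_sd = 0.5, noise_sd = 0.3,
                              offset_sd = 1, slope_sdlog = 0.4,
                              silent_frac = 0.1,
                              baseline_mean = 8, baseline_sd = 2,
                              seed = 1L) {
  stopifnot(n_pairs >= 2, frac_affected >= 0, frac_affected <= 1,
            n_common >= 0, n_common <= n_pairs, slope_sdlog >= 0)
  set.seed(as.integer(seed))
  G <- n_genes
  n_patients <- 2L * n_pairs - n_common
  gene_ids <- sprintf("G%05d", seq_len(G))
  mu <- stats::rnorm(G, baseline_mean, baseline_sd)
  silent <- sort(sample.int(G, round(silent_frac * G)))
  expressed <- setdiff(seq_len(G), silent)
  affected <- sort(sample(expressed, round(frac_affected * length(expressed))))
  delta <- rep(0, G)
  delta[affected] <- stats::rnorm(length(affected), 0, effect_sd)

  baseline <- mu +
    matrix(stats::rnorm(G * n_patients, 0, patient_sd), G, n_patients)
  effect <- matrix(0, G, n_patients)
  effect[affected, ] <- delta[affected] +
    stats::rnorm(length(affected) * n_patients, 0, response_sd)
  truth_signal <- array(0, c(G, n_patients, 2))
  truth_signal[, , 1] <- baseline
  truth_signal[, , 2] <- baseline + effect

  offsets <- stats::rnorm(G, 0, offset_sd)
  slopes <- stats::rlnorm(G, 0, slope_sdlog)

  common <- seq_len(n_common)
  pat1 <- c(common, n_common + seq_len(n_pairs - n_common))
  pat2 <- c(common, n_pairs + seq_len(n_pairs - n_common))

  build <- function(patients, platform) {
    n <- length(patients) * 2L
    sig <- cbind(truth_signal[, patients, 1, drop = TRUE],
                 truth_signal[, patients, 2, drop = TRUE])
    dim(sig) <- c(G, n)
    x <- sig + stats::rnorm(G * n, 0, noise_sd)
    if (platform == 2L) x <- slopes * x + offsets
    ids <- c(paste0("Pt", patients, "_base_P", platform),
             paste0("Pt", patients, "_3mo_P", platform))
    dimnames(x) <- list(gene_ids, ids)
    det <- matrix(stats::runif(G * n, 0.2, 1), G, n, dimnames = dimnames(x))
    det[expressed, ] <- stats::runif(length(expressed) * n, 0, 0.01)
    design <- data.frame(sample_id = ids,
                         patient = rep(paste0("Pt", patients), 2L),
                         timepoint = rep(c("baseline", "3month"),
                                         each = length(patients)),
                         platform = paste0("P", platform),
                         pair_id = rep(paste0("Pt", patients), 2L),
                         stringsAsFactors = FALSE)
    list(x = x, det = det, design = design)
  }
  d1 <- build(pat1, 1L)
  d2 <- build(pat2, 2L)
  truth <- list(gene_ids = gene_ids, baseline = baseline, delta = delta,
                patient_effects = effect,
                affected = gene_ids[affected], silent = gene_ids[silent],
                platform_offsets = offsets, platform_slopes = slopes,
                patients_platform1 = pat1, patients_platform2 = pat2,
                noise_sd = noise_sd, seed = seed)
  list(platform1 = d1$x, platform2 = d2$x,
       detection1 = d1$det, detection2 = d2$det,
       design = rbind(d1$design, d2$design), truth = truth)
}
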