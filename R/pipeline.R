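# End-to-end orchestration: simulate (or read) a two-platform dataset,
# preprocess, apply the requested cross-platform corrections, and run the
# downstream analyses (variance decomposition, SAM, evaluation metrics),
# collecting every result in a machine-readable report.

#' Run the integration pipeline from a configuration
#'
#' The configuration is a nested list (or a path to a YAML file with the
#' same structure):
#' \describe{
#'   \item{seed}{Master seed; every stochastic stage derives its seed from
#'     it.}
#'   \item{out_dir}{Output directory; intermediate matrices and
#'     `report.json` are written there (omit to skip writing).}
#'   \item{dataset}{Either `list(type = "maqc", args = list(...))` /
#'     `list(type = "clinical", args = list(...))` forwarding to the
#'     simulators, or `list(type = "files", expression =, design =)` with
#'     TSV paths.}
#'   \item{stages}{Toggles and parameters: `quantile` (logical),
#'     `corrections` (subset of `"mean_center"`, `"dwd"`, `"combat"`,
#'     `"xpn"`), `varcomp` (logical or list with `method`), `sam` (logical
#'     or list with `n_perm`, `delta_grid`, `top_n`), `evaluate`
#'     (logical).}
#' }
#'
#' @param config Configuration list or YAML path.
#' @return A `run_report` list with provenance, per-state pooled variance
#'   fractions, SAM summaries and correlation summaries; written to
#'   `out_dir/report.json` when an output directory is configured. On
#'   stage failure a `FAILED` marker naming the stage is left in
#'   `out_dir` and the error is rethrown.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("reading YAML configs requires the 'yaml' package")
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config), !is.null(config$dataset))
  seed <- as.integer(config$seed %||% 1L)
  out_dir <- config$out_dir
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  stages <- config$stages %||% list()
  corrections <- stages$corrections %||%
    c("mean_center", "dwd", "combat")
  stage <- "dataset"
  on_fail <- function(e) {
    if (!is.null(out_dir))
      writeLines(paste("stage:", stage, "-", conditionMessage(e)),
                 file.path(out_dir, "FAILED"))
    stop(e)
  }
  tryCatch({
    ds <- pipeline_dataset(config$dataset, seed)
    matrix <- ds$matrix
    design <- ds$design
    batches <- stats::setNames(design$platform, design$sample_id)

    stage <- "preprocess"
    if (isTRUE(stages$quantile_within)) {
      # within-platform quantile normalization of the input matrices
      for (p in unique(design$platform)) {
        idx <- design$sample_id[design$platform == p]
        matrix[, idx] <- quantile_normalize(matrix[, idx, drop = FALSE])
      }
    }
    states <- list(raw = matrix)
    if (isTRUE(stages$quantile %||% TRUE)) {
      # pooled cross-platform quantile normalization: the naive
      # distribution-matching baseline among the correction states
      states$quantile <- quantile_normalize(matrix)
    }

    stage <- "correction"
    split_cols <- split(design$sample_id, design$platform)
    for (m in corrections) {
      states[[m]] <- switch(
        m,
        mean_center = mean_center(matrix, batches),
        combat = combat_adjust(matrix, batches)$corrected,
        # DWD as practiced: per-array standardization, then translation
        # of each batch along the discriminating direction
        dwd = dwd_adjust(standardize_arrays(matrix), batches)$corrected,
        xpn = {
          if (length(split_cols) != 2L)
            stop("xpn needs exactly two platforms")
          xc <- xpn_normalize(matrix[, split_cols[[1L]], drop = FALSE],
                              matrix[, split_cols[[2L]], drop = FALSE],
                              seed = seed + 1L)$corrected
          xc[, colnames(matrix), drop = FALSE]
        },
        stop("unknown correction method: ", m))
    }

    report <- list(provenance = list(
      seed = seed, dataset = config$dataset$type,
      corrections = corrections,
      states = names(states),
      package_version = as.character(utils::packageVersion("crossnorm"))))

    stage <- "varcomp"
    varcomp_cfg <- stages$varcomp %||% TRUE
    if (!isFALSE(varcomp_cfg) && !is.null(design$lab)) {
      method <- if (is.list(varcomp_cfg)) varcomp_cfg$method %||% "anova"
        else "anova"
      nd <- nested_design(design$sample_id, design$sample_type,
                          design$platform, design$lab, design$replicate)
      report$variance_fractions <- lapply(states, function(x)
        as.list(pool_fractions(
          fit_nested_components(x, nd, method = method))$fractions))
    }

    stage <- "sam"
    sam_cfg <- stages$sam %||% TRUE
    if (!isFALSE(sam_cfg)) {
      sam_cfg <- if (is.list(sam_cfg)) sam_cfg else list()
      classes <- pipeline_classes(design)
      if (!is.null(classes)) {
        keep <- !is.na(classes)
        top_n <- sam_cfg$top_n %||% min(1000L, nrow(matrix))
        report$sam <- lapply(states, function(x) {
          res <- sam_fdr(x[, design$sample_id[keep], drop = FALSE],
                         classes[keep],
                         n_perm = sam_cfg$n_perm %||% 100L,
                         delta_grid = sam_cfg$delta_grid %||%
                           seq(0.1, 2, by = 0.1),
                         seed = seed + 2L)
          list(s0 = res$s0,
               fdr_table = res$fdr_table[, c("delta", "n_called", "fdr")],
               top = top_genes(res, top_n))
        })
      }
    }

    stage <- "evaluate"
    if (!isFALSE(stages$evaluate %||% TRUE)) {
      plat <- stats::setNames(design$platform, design$sample_id)
      report$correlation <- lapply(states, function(x) {
        r <- pairwise_correlation(x)
        same <- outer(plat[colnames(x)], plat[colnames(x)], "==")
        off <- upper.tri(r)
        list(within_platform = mean(r[off & same]),
             between_platform = mean(r[off & !same]))
      })
    }

    stage <- "write"
    if (!is.null(out_dir)) {
      for (nm in names(states))
        write_expression_tsv(states[[nm]],
                             file.path(out_dir, paste0(nm, ".tsv")))
      tmp <- file.path(out_dir, "report.json.tmp")
      jsonlite::write_json(report, tmp, auto_unbox = TRUE, digits = NA,
                           pretty = TRUE)
      file.rename(tmp, file.path(out_dir, "report.json"))
    }
    class(report) <- "run_report"
    report
  }, error = on_fail)
}

pipeline_dataset <- function(dataset, seed) {
  type <- dataset$type %||% stop("dataset$type is required")
  if (type == "maqc") {
    sim <- do.call(simulate_maqc,
                   c(dataset$args %||% list(), list(seed = seed)))
    list(matrix = sim$matrix, design = as.data.frame(sim$design),
         truth = sim$truth)
  } else if (type == "clinical") {
    sim <- do.call(simulate_clinical,
                   c(dataset$args %||% list(), list(seed = seed)))
    list(matrix = cbind(sim$platform1, sim$platform2),
         design = sim$design, truth = sim$truth)
  } else if (type == "files") {
    m <- read_expression_tsv(dataset$expression)
    list(matrix = m, design = read_design_tsv(dataset$design), truth = NULL)
  } else stop("unknown dataset type: ", type)
}

# Two-class labels for differential expression: titration pools A vs B
# when present, otherwise baseline vs post-treatment timepoints.
pipeline_classes <- function(design) {
  if (!is.null(design$sample_type) &&
      all(c("A", "B") %in% design$sample_type)) {
    cl <- ifelse(design$sample_type %in% c("A", "B"),
                 design$sample_type, NA_character_)
    stats::setNames(cl, design$sample_id)
  } else if (!is.null(design$timepoint)) {
    stats::setNames(design$timepoint, design$sample_id)
  } else NULL
}

#' Rank processing states by variance-fraction profile
#'
#' Orders the processing states of a pipeline report by their pooled
#' inter-platform variance fraction (ascending: best correction first) and
#' reports the retained inter-sample fraction, flagging any state whose
#' inter-sample fraction dropped by more than 50% relative to the raw
#' state — the signature of a correction that removes biology along with
#' the batch effect.
#'
#' @param report A `run_report` containing a `variance_fractions` block
#'   with at least two states.
#' @return Data frame with columns `state`, `platform_fraction`,
#'   `sample_fraction`, `sample_drop_rel` and `flagged`.
#' @export
compare_states <- function(report) {
  vf <- report$variance_fractions
  if (is.null(vf)) stop("report has no variance_fractions block")
  if (length(vf) < 2L) stop("need at least two processing states")
  tab <- data.frame(
    state = names(vf),
    platform_fraction = vapply(vf, function(x) x$platform, numeric(1)),
    sample_fraction = vapply(vf, function(x) x$sample, numeric(1)),
    stringsAsFactors = FALSE)
  ref <- tab$sample_fraction[tab$state == "raw"]
  if (length(ref) == 0L) ref <- max(tab$sample_fraction)
  tab$sample_drop_rel <- 1 - tab$sample_fraction / ref
  tab$flagged <- tab$sample_drop_rel > 0.5
  tab <- tab[order(tab$platform_fraction), , drop = FALSE]
  rownames(tab) <- NULL
  tab
}
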