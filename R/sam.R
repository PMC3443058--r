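# Significance Analysis of Microarrays: a moderated difference statistic
# d = r / (s + s0) with permutation-based FDR estimation. The fudge factor
# s0 keeps low-scatter genes from dominating the ranking; the FDR for a
# calling threshold delta is estimated from the number of permuted
# statistics falling beyond the thresholds, with pi0 fixed at 1
# (conservative).

sam_class_factor <- function(matrix, classes) {
  if (!is.null(names(classes))) {
    if (!setequal(names(classes), colnames(matrix)))
      stop("class labels do not cover the sample columns")
    classes <- classes[colnames(matrix)]
  }
  f <- factor(as.character(classes))
  if (nlevels(f) != 2L) stop("exactly two classes required")
  f
}

sam_d_unpaired <- function(matrix, f, s0) {
  i1 <- which(f == levels(f)[1L]); i2 <- which(f == levels(f)[2L])
  n1 <- length(i1); n2 <- length(i2)
  m1 <- rowMeans(matrix[, i1, drop = FALSE])
  m2 <- rowMeans(matrix[, i2, drop = FALSE])
  ss1 <- rowSums((matrix[, i1, drop = FALSE] - m1)^2)
  ss2 <- rowSums((matrix[, i2, drop = FALSE] - m2)^2)
  r <- m2 - m1
  s <- sqrt((1 / n1 + 1 / n2) * (ss1 + ss2) / (n1 + n2 - 2))
  d <- ifelse(s + s0 > 0, r / (s + s0), 0)
  list(r = r, s = s, d = d, flagged = s + s0 == 0)
}

#' Unpaired SAM statistic
#'
#' @param matrix Gene-by-sample matrix.
#' @param classes Two-level class labels (named by sample ID or in column
#'   order); the statistic is mean(second level) minus mean(first level),
#'   levels in sort order. Each class needs >= 2 samples.
#' @param s0 Fudge factor added to the gene scatter (>= 0).
#' @return Data frame with per-gene `r` (numerator), `s` (scatter), `d`.
#' @export
sam_statistic <- function(matrix, classes, s0 = 0) {
  stopifnot(is.matrix(matrix), s0 >= 0)
  f <- sam_class_factor(matrix, classes)
  if (any(table(f) < 2L)) stop("each class needs at least 2 samples")
  parts <- sam_d_unpaired(matrix, f, s0)
  data.frame(gene_id = rownames(matrix) %||% seq_len(nrow(matrix)),
             r = parts$r, s = parts$s, d = parts$d,
             stringsAsFactors = FALSE)
}

sam_pair_diffs <- function(matrix, f, pairs) {
  pairs <- as.character(pairs)
  tab <- table(pairs, f)
  bad <- rownames(tab)[tab[, 1L] != 1L | tab[, 2L] != 1L]
  if (length(bad))
    stop("incomplete or unbalanced pairs: ", paste(bad, collapse = ", "))
  ids <- rownames(tab)
  i1 <- match(paste(ids, levels(f)[1L]), paste(pairs, f))
  i2 <- match(paste(ids, levels(f)[2L]), paste(pairs, f))
  matrix[, i2, drop = FALSE] - matrix[, i1, drop = FALSE]
}

sam_d_paired <- function(z, s0, signs = NULL) {
  if (!is.null(signs)) z <- sweep(z, 2L, signs, "*")
  np <- ncol(z)
  r <- rowMeans(z)
  s <- sqrt(rowSums((z - r)^2) / (np - 1)) / sqrt(np)
  d <- ifelse(s + s0 > 0, r / (s + s0), 0)
  list(r = r, s = s, d = d)
}

#' Paired SAM statistic
#'
#' Computes per-gene within-pair differences (second class minus first) and
#' a one-sample moderated statistic on them.
#'
#' @inheritParams sam_statistic
#' @param pairs Pair identifiers (e.g. patient IDs), one per sample; each
#'   pair must contain exactly one sample of each class; >= 2 pairs.
#' @return Data frame with per-gene `r`, `s`, `d`.
#' @export
sam_paired <- function(matrix, classes, pairs, s0 = 0) {
  stopifnot(is.matrix(matrix), s0 >= 0)
  f <- sam_class_factor(matrix, classes)
  z <- sam_pair_diffs(matrix, f, pairs)
  if (ncol(z) < 2L) stop("need at least 2 complete pairs")
  parts <- sam_d_paired(z, s0)
  data.frame(gene_id = rownames(matrix) %||% seq_len(nrow(matrix)),
             r = parts$r, s = parts$s, d = parts$d,
             stringsAsFactors = FALSE)
}

#' Choose the SAM fudge factor
#'
#' Evaluates candidate values of `s0` at the percentiles 0, 5, ..., 100 of
#' the gene scatters `s`. For each candidate the genes are split into up to
#' 100 equal-count bins of `s` and the coefficient of variation of the
#' bin-wise median |d| is computed; the candidate with the smallest CV wins
#' (ties broken towards the smaller s0), making |d| roughly exchangeable
#' across the scatter range.
#'
#' @param r Per-gene numerators.
#' @param s Per-gene scatters.
#' @return The chosen s0 (a scalar).
#' @export
choose_s0 <- function(r, s) {
  stopifnot(length(r) == length(s))
  cand <- unname(stats::quantile(s, seq(0, 1, by = 0.05), type = 7))
  if (max(s) - min(s) < 1e-12) {
    warning("gene scatters are all equal; any s0 is equivalent")
    return(unname(stats::quantile(s, 0.05)))
  }
  nbin <- min(100L, max(2L, floor(length(s) / 2)))
  bins <- ceiling(rank(s, ties.method = "first") / (length(s) / nbin))
  cv <- vapply(cand, function(s0) {
    d <- r / (s + s0)
    med <- tapply(abs(d), bins, stats::median)
    m <- mean(med)
    if (m <= 0) return(Inf)
    stats::sd(med) / m
  }, numeric(1))
  cand[which(cv <= min(cv) + 1e-12)][1L]
}

sam_permutations <- function(f, pairs, n_perm, seed) {
  set.seed(as.integer(seed))
  if (is.null(pairs)) {
    n <- length(f)
    n1 <- sum(f == levels(f)[1L])
    total <- choose(n, n1)
    if (total <= n_perm) {
      idx <- utils::combn(n, n1, simplify = FALSE)
      lapply(idx, function(i) {
        g <- factor(rep(levels(f)[2L], n), levels = levels(f))
        g[i] <- levels(f)[1L]
        g
      })
    } else {
      replicate(n_perm, sample(f), simplify = FALSE)
    }
  } else {
    np <- length(unique(as.character(pairs)))
    if (2^np <= n_perm) {
      lapply(seq_len(2^np) - 1L,
             function(k) 1 - 2 * as.integer(intToBits(k)[seq_len(np)]))
    } else {
      replicate(n_perm, sample(c(-1, 1), np, replace = TRUE),
                simplify = FALSE)
    }
  }
}

#' SAM with permutation-based FDR estimation
#'
#' Computes the observed statistics, the expected order statistics from
#' permutations (label permutations, or sign flips of the within-pair
#' differences in paired mode; full enumeration whenever the permutation
#' space is no larger than `n_perm`), and for every `delta` in the grid the
#' asymmetric calling thresholds, the number of called genes, the median
#' permutation false-positive count and the FDR estimate (capped at 1,
#' pi0 = 1).
#'
#' @inheritParams sam_statistic
#' @param pairs Optional pair identifiers; switches to the paired statistic
#'   and sign-flip permutations.
#' @param s0 Fudge factor; `"auto"` chooses it with [choose_s0()].
#' @param n_perm Number of permutations (>= 50 recommended).
#' @param delta_grid Non-empty vector of calling thresholds.
#' @param seed Seed for the permutation draws.
#' @return A `sam_result` list: `table` (per-gene r, s, d), `ranking`
#'   (gene IDs by decreasing |d|), `dbar` (expected order statistics),
#'   `fdr_table`, `perm_fp` (per-delta by per-permutation false-positive
#'   counts, for Monte-Carlo diagnostics), `s0`, `n_perm_used`,
#'   `enumerated`, `seed`, `paired`.
#' @export
sam_fdr <- function(matrix, classes, pairs = NULL, s0 = "auto",
                    n_perm = 200L, delta_grid = seq(0.1, 2, by = 0.1),
                    seed = 1L) {
  stopifnot(is.matrix(matrix))
  if (length(delta_grid) == 0L) stop("delta grid must be non-empty")
  f <- sam_class_factor(matrix, classes)
  paired <- !is.null(pairs)
  if (paired) {
    z <- sam_pair_diffs(matrix, f, pairs)
    obs <- sam_d_paired(z, 0)
  } else {
    obs <- sam_d_unpaired(matrix, f, 0)
  }
  if (identical(s0, "auto")) s0 <- choose_s0(obs$r, obs$s)
  s0 <- as.numeric(s0)
  obs_d <- if (paired) sam_d_paired(z, s0)$d else
    sam_d_unpaired(matrix, f, s0)$d

  perms <- sam_permutations(f, if (paired) pairs else NULL, n_perm, seed)
  perm_d <- vapply(perms, function(p) {
    if (paired) sam_d_paired(z, s0, signs = p)$d
    else sam_d_unpaired(matrix, p, s0)$d
  }, numeric(nrow(matrix)))
  perm_sorted <- apply(perm_d, 2L, sort)
  dbar <- rowMeans(perm_sorted)

  ord <- order(obs_d)
  d_sorted <- obs_d[ord]
  G <- length(d_sorted)
  origin <- which.min(abs(dbar))
  fdr_rows <- lapply(delta_grid, function(delta) {
    up <- which(d_sorted - dbar >= delta)
    up <- up[up >= origin]
    cutup <- if (length(up)) d_sorted[min(up)] else Inf
    lo <- which(dbar - d_sorted >= delta)
    lo <- lo[lo <= origin]
    cutlow <- if (length(lo)) d_sorted[max(lo)] else -Inf
    called <- obs_d >= cutup | obs_d <= cutlow
    n_called <- sum(called)
    fp <- apply(perm_d, 2L, function(d) sum(d >= cutup | d <= cutlow))
    med_fp <- stats::median(fp)
    fdr <- if (n_called > 0) min(med_fp / n_called, 1) else 0
    list(row = data.frame(delta = delta, n_called = n_called,
                          median_fp = med_fp, fdr = fdr,
                          cutup = cutup, cutlow = cutlow),
         fp = fp)
  })
  perm_fp <- do.call(rbind, lapply(fdr_rows, `[[`, "fp"))
  fdr_rows <- lapply(fdr_rows, `[[`, "row")
  gene_ids <- rownames(matrix) %||% as.character(seq_len(G))
  tab <- data.frame(gene_id = gene_ids, r = obs$r, s = obs$s, d = obs_d,
                    stringsAsFactors = FALSE)
  ranking <- tab$gene_id[order(-abs(tab$d), tab$gene_id)]
  enumerated <- if (paired) 2^ncol(z) <= n_perm else
    choose(length(f), sum(f == levels(f)[1L])) <= n_perm
  structure(list(table = tab, ranking = ranking, dbar = dbar,
                 fdr_table = do.call(rbind, fdr_rows),
                 perm_fp = perm_fp, s0 = s0,
                 n_perm_used = length(perms), enumerated = enumerated,
                 seed = seed, paired = paired),
            class = "sam_result")
}

#' Top-n genes of a SAM result
#'
#' Genes ordered by decreasing |d|, ties broken lexicographically by gene
#' ID, so `top_genes(res, k)` is always a prefix of `top_genes(res, k + 1)`.
#'
#' @param result A `sam_result` (or any data frame with `gene_id` and `d`).
#' @param n Number of genes (<= number of genes in the result).
#' @return Character vector of gene IDs.
#' @export
top_genes <- function(result, n) {
  tab <- if (inherits(result, "sam_result")) result$table else result
  if (n > nrow(tab)) stop("n exceeds the number of genes")
  ord <- order(-abs(tab$d), tab$gene_id)
  tab$gene_id[ord][seq_len(n)]
}

#' Overlap of two ranked gene lists
#'
#' @param list_a,list_b Ranked gene ID vectors, each of length >= n.
#' @param n Depth at which to compare (> 0).
#' @return List with `count` and `percent` (100 * count / n).
#' @export
gene_list_overlap <- function(list_a, list_b, n) {
  if (n <= 0L) stop("n must be positive")
  if (length(list_a) < n || length(list_b) < n)
    stop("both lists must have at least n entries")
  count <- length(intersect(list_a[seq_len(n)], list_b[seq_len(n)]))
  list(count = count, percent = 100 * count / n)
}
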