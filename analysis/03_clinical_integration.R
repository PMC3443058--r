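#!/usr/bin/env Rscript

# Integrating a paired clinical study measured on two platforms.
#
# Thirty patients per platform (six assayed on both) with baseline and
# three-month samples; the second platform reads each gene through its own
# sensitivity slope and offset. We ask (i) whether the per-gene treatment
# fold changes agree across platforms before and after XPN, (ii) whether
# the integrated dataset localizes matched samples together in an MDS
# embedding, and (iii) how much paired-SAM power integration adds.

library(crossnorm)

out_dir <- "results"
dir.create(out_dir, showWarnings = FALSE)
seed <- 3

sim <- simulate_clinical(seed = seed)
al <- align_gene_space(sim$platform1, sim$platform2)
cls <- stats::setNames(sim$design$timepoint, sim$design$sample_id)
prs <- stats::setNames(paste(sim$design$pair_id, sim$design$platform),
                       sim$design$sample_id)

## fold-change concordance (the scatterplot view)
fc0 <- foldchange_concordance(al$a, al$b, cls[colnames(al$a)],
                              cls[colnames(al$b)])
xp <- xpn_normalize(al$a, al$b, seed = seed + 1)
fc1 <- foldchange_concordance(xp$corrected[, colnames(al$a)],
                              xp$corrected[, colnames(al$b)],
                              cls[colnames(al$a)], cls[colnames(al$b)])
cat(sprintf("Fold-change concordance across platforms: R = %.2f raw, R = %.2f after XPN\n",
            fc0$r, fc1$r))
write.table(cbind(fc0$fc, fc_b_xpn = fc1$fc$fc_b),
            file.path(out_dir, "clinical_fold_changes.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

## MDS of the integrated data before/after correction
combined_raw <- cbind(al$a, al$b)
coords_raw <- mds_embed(combined_raw)
coords_xpn <- mds_embed(xp$corrected)
write.table(data.frame(sample_id = rownames(coords_raw),
                       dim1_raw = coords_raw[, 1], dim2_raw = coords_raw[, 2],
                       dim1_xpn = coords_xpn[, 1], dim2_xpn = coords_xpn[, 2]),
            file.path(out_dir, "clinical_mds.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
plat <- stats::setNames(sim$design$platform, sim$design$sample_id)
sep_ratio <- function(coords) {
  g <- plat[rownames(coords)]
  between <- sqrt(sum((colMeans(coords[g == "P1", ]) -
                         colMeans(coords[g == "P2", ]))^2))
  within <- mean(apply(coords, 2, sd))
  between / within
}
cat(sprintf("Platform separation in MDS (between/within ratio): %.2f raw, %.2f after XPN\n",
            sep_ratio(coords_raw), sep_ratio(coords_xpn)))

## within-patient cross-platform correlation for the shared patients
shared <- intersect(colnames(al$a), sub("_P2$", "_P1", colnames(al$b)))
match_cor <- function(a, b) {
  mean(vapply(shared, function(s) {
    cor(a[, s], b[, sub("_P1$", "_P2", s)])
  }, numeric(1)))
}
cat(sprintf("Mean matched-sample correlation: %.3f raw, %.3f after XPN\n",
            match_cor(al$a, al$b),
            match_cor(xp$corrected[, colnames(al$a)],
                      xp$corrected[, colnames(al$b)])))

## paired SAM power: platforms alone vs integrated
power <- function(m, tag) {
  res <- sam_fdr(m, cls[colnames(m)], pairs = prs[colnames(m)],
                 n_perm = 100, delta_grid = seq(0.1, 3, 0.1), seed = seed)
  ok <- res$fdr_table$fdr <= 0.05
  n <- if (any(ok)) max(res$fdr_table$n_called[ok]) else 0
  cat(sprintf("%-22s genes at FDR<=0.05: %d\n", tag, n))
  n
}
n1 <- power(sim$platform1, "platform 1 alone")
n2 <- power(sim$platform2, "platform 2 alone")
nc <- power(xp$corrected, "integrated (XPN)")
write.table(data.frame(dataset = c("platform1", "platform2", "combined_xpn"),
                       n_called_fdr05 = c(n1, n2, nc)),
            file.path(out_dir, "clinical_sam_power.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
cat("\nIntegration doubles the number of pairs, and the paired statistic\n")
cat("turns the extra consistency into more genes at the same FDR.\n")
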