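# Shared fixture builders. Everything is generated in code; no data files.

toy_matrix <- function(values, genes = NULL, samples = NULL) {
  m <- matrix(values, nrow = length(values) / (length(samples) %||% 2))
  if (is.null(genes)) genes <- sprintf("G%02d", seq_len(nrow(m)))
  if (is.null(samples)) samples <- sprintf("S%02d", seq_len(ncol(m)))
  dimnames(m) <- list(genes, samples)
  m
}

`%||%` <- function(a, b) if (is.null(a)) b else a

random_matrix <- function(G, n, seed = 1, mean = 8, sd = 1) {
  set.seed(seed)
  matrix(rnorm(G * n, mean, sd), G, n,
         dimnames = list(sprintf("G%04d", seq_len(G)),
                         sprintf("S%03d", seq_len(n))))
}

two_batch_labels <- function(m, n1 = ncol(m) / 2) {
  stats::setNames(rep(c("b1", "b2"), c(n1, ncol(m) - n1)), colnames(m))
}

# classes/pairs helpers for clinical simulations
clinical_classes <- function(sim, platform = NULL) {
  des <- sim$design
  if (!is.null(platform)) des <- des[des$platform == platform, ]
  stats::setNames(des$timepoint, des$sample_id)
}

clinical_pairs <- function(sim, cols) {
  des <- sim$design
  des$pair_id[match(cols, des$sample_id)]
}
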