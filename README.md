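# crossnorm

Direct integration of intensity-level gene expression data measured on two
single-channel microarray platforms (e.g. Affymetrix GeneChips and Illumina
BeadArrays).

Merging such datasets sample-by-sample — rather than meta-analytically —
promises real statistical power: more arrays per biological question. But
each platform imprints a gene-wise additive offset and a gene-wise
sensitivity distortion on everything it measures, and a merge is only
useful if that bias is removed *without* removing biology. `crossnorm`
provides the full workflow for researchers attempting such an integration
and, just as importantly, the instruments for judging whether it worked:

* **consensus re-annotation** — probe→gene maps retained only where at
  least two independent annotation resources agree, probe-to-gene
  collapsing by the log2-scale mean, alignment of two platforms onto their
  common gene space;
* **preprocessing** — quantile normalization (deterministic tie handling)
  and the detection-p-value filter (keep a gene only if detected, p ≤ 0.05,
  in more than 3 samples);
* **four cross-platform corrections** — per-batch mean centering;
  parametric empirical-Bayes location/scale adjustment (ComBat family);
  distance-weighted discrimination (DWD) translation; and cross-platform
  normalization (XPN), a gene-cluster × sample-cluster block model whose
  per-platform parameters are replaced by cross-platform consensus values;
* **a per-gene nested variance decomposition** — for each gene,
  `X_ijkl = mu + A_i + B_ij + C_ijk + e_ijkl` (sample type, platform nested
  in sample, lab nested in platform, replicate), estimated by
  expected-mean-squares ANOVA or REML, pooled into the fraction of total
  variance each level explains — the single most direct readout of
  platform bias;
* **significance analysis of microarrays** — moderated statistic
  `d = r / (s + s0)` (unpaired and paired), automatic fudge-factor
  selection, permutation FDR with full enumeration on small designs,
  top-N lists and list overlaps;
* **evaluation metrics** — sample correlation heatmaps' numbers,
  correlation-distance clustering, classical MDS, cross-platform
  fold-change concordance, most-variable-gene selection, nearest-centroid
  subtype assignment (Spearman after per-gene median centering);
* **synthetic study designs** — a reference-RNA titration experiment
  (A/B pure pools, C/D 75/25 and 25/75 linear mixes, 2 platforms × 3 labs
  × 5 replicates, log-scale random effects per level) and a paired
  clinical cohort (30 patients per platform, 6 on both, baseline vs
  3-month samples, gene-wise platform offset + sensitivity slope), with
  complete truth records.

The methods vignette (`vignettes/crossplatform-methods.Rmd`) documents the
models, defaults, numerical choices and known limitations.

## Worked example

How much variance does the platform explain before and after
empirical-Bayes correction, on the titration design with gene-wise
platform bias?

```r
library(crossnorm)

sim <- simulate_maqc(n_genes = 500, platform_offset_sd = 2,
                     platform_slope_sdlog = 0.2, seed = 42)
batches <- setNames(sim$design$platform, sim$design$sample_id)

raw_fr <- pool_fractions(fit_nested_components(sim$matrix, sim$design,
                                               method = "anova"))$fractions
cb <- combat_adjust(sim$matrix, batches)
cb_fr <- pool_fractions(fit_nested_components(cb$corrected, sim$design,
                                              method = "anova"))$fractions
round(rbind(raw = raw_fr, combat = cb_fr), 3)
#>        sample platform   lab residual
#> raw     0.477    0.492 0.027    0.004
#> combat  0.873    0.081 0.039    0.006
```

In the raw merge, the platform is responsible for about half of the pooled
per-gene variance — more than the biological samples themselves. After the
empirical-Bayes adjustment the platform share drops to 8% while the
inter-sample share rises to 87%: the bias is gone and the biology is
intact. `run_pipeline()` runs the same comparison across all correction
methods from one seeded configuration, and `compare_states()` ranks the
methods and flags any correction that destroys inter-sample variance.

The numbered scripts under `analysis/` are complete narrative analyses
built on these functions: `01_titration_variance.R` (variance fractions by
processing state), `02_differential_expression_maqc.R` (top-1000 overlap
of single-platform vs integrated SAM), `03_clinical_integration.R`
(fold-change concordance, MDS and paired-SAM power on the clinical
design), `04_subtype_cohorts.R` (centroid subtype stability under XPN).
Each writes its tables under `results/`.

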