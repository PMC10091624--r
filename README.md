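# copdclust

Integrative multi-omics clustering of lung tissue, built around a concrete
scientific question: when you cluster paired gene-expression and DNA
methylation profiles from the same tissue samples without looking at the
phenotype, do the clusters recover clinically defined disease — here, severe
chronic obstructive pulmonary disease (COPD) versus normal spirometry in
former smokers — or are they driven by other sources of molecular variation?

The package is aimed at computational biologists analysing paired
feature-by-sample omics blocks (log-intensity expression arrays and
450K-style methylation beta values), and at methodologists who want a
self-contained, fully seeded testbed for multi-omics clustering behaviour.

## What it implements

**Two integration engines, fit like models.**

* `snf_fit()` — *similarity network fusion* with spectral clustering.  Each
  omic block is turned into a sample affinity network with the scaled
  exponential kernel
  `W_ij = exp(-d_ij / (alpha * eps_ij))`, `eps_ij = (d̄_i + d̄_j + d_ij)/3`,
  where `d_ij` is the squared Euclidean distance between standardized sample
  profiles and `d̄_i` is the mean distance to the `n_neighbors` nearest
  samples.  The per-omic networks are fused by iterative cross-diffusion
  (`P_v ← S_v · mean(P_other) · S_vᵀ` with row-stochastic status matrices
  `P` and sparse local kernels `S`), and the fused network is partitioned by
  normalized-Laplacian spectral clustering into `k = 2` clusters, with a
  seeded repeat-stability check.

* `ecc_fit()` — *entropy-based consensus clustering*.  Thousands of "basic
  partitions" are generated per omic block (random feature subspace, random
  cluster count, seeded k-means), and the consensus partition maximizes the
  mean entropy utility — the mutual information `I(π, π_i)` between the
  candidate and each basic partition — via its k-means equivalence under the
  KL divergence on one-hot membership encodings.

**Evaluation statistics.**  `nmi()` (normalized mutual information with
sqrt/max/mean normalizers), the case-enrichment classification accuracy
`classification_accuracy()` (cases in the case-enriched cluster plus
controls in the other, over n), table-one style `compare_clusters()`
(t / Wilcoxon / continuity-corrected chi-squared per declared variable
type), and `overlap_table()` cross-tabulations.

**Molecular characterisation.**  Covariate-adjusted per-feature OLS
(`fit_feature_models()`), empirical-Bayes variance moderation with the
closed-form moments estimator of the variance prior (`moderate()`),
Benjamini-Hochberg correction (`bh_adjust()`), and hypergeometric
over-representation analysis against GMT gene sets (`ora()`).

**Feature-selection sensitivity analysis.**  `run_sensitivity()` traces the
classification accuracy of consensus clustering when the inputs are
pre-filtered to disease-associated features at FDR thresholds
0.05/0.10/0.25/0.50/1 per view (expression, methylation, merged).

**Synthetic cohorts.**  `simulate_cohort()` generates paired
expression/methylation blocks with a planted two-cluster structure, a binary
phenotype only partially aligned with it, clinical covariates, and an
optional dominant nuisance factor — so every stage above is testable without
access to patient-level data.

## Worked example

```r
library(copdclust)

cfg <- simulation_config(n_samples = 78,
                         n_features_expr = 1000, n_features_meth = 1000,
                         n_informative_expr = 150, n_informative_meth = 150,
                         effect_expr = 1.5, effect_meth = 1.5,
                         phenotype_flip_prob = 0.2, seed = 1)
cohort <- simulate_cohort(cfg)
snf <- snf_fit(cohort$expression, cohort$methylation, seed = 1)
ecc <- ecc_fit(cohort$expression, cohort$methylation, n_bp = 1000, seed = 1)
snf
#> Similarity network fusion fit
#>   views: expression + methylation
#>   n_neighbors = 30, alpha = 0.8, iterations = 15, k = 2
#>   cluster sizes: 45/33
#>   stability: 10 repeats, identical memberships (min NMI 1.000)
nmi(snf$partition, ecc$partition)
#> [1] 1
classification_accuracy(ecc$partition, cohort$clinical$copd_status)
#> [1] 0.8333333
de <- moderated_diffexp(cohort$expression, cohort$clinical, ecc$partition)
sum(de$fdr < 0.05)
#> [1] 153
```

Both engines find the same two clusters (NMI = 1), sized 45/33.  Because
20% of the COPD labels were deliberately flipped away from the planted
molecular clusters, the classification accuracy tops out near 0.83 rather
than 1: the clusters track the molecular structure, not the noisy label.
`compare_clusters()` then reports the table-one style contrast — in this
run the case-enriched cluster holds 77.8% cases vs 9.1%
(chi-squared p = 8.1e-09) and median FEV1 28 vs 94 percent predicted — and
153 transcripts are differentially expressed between clusters at FDR < 5%.

The full pipeline (simulate → cluster → evaluate → differential expression →
enrichment → sensitivity) can also be driven from a single YAML config via
`run_pipeline()`, which writes every stage's tables plus a reproducibility
manifest into a run directory.

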