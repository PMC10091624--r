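# Small cohort factories shared across test files.

# strong, well-separated two-cluster structure in both omic blocks
strong_cohort <- function(seed = 11, n = 78, n_feat = 600) {
  simulate_cohort(simulation_config(
    n_samples = n, n_features_expr = n_feat, n_features_meth = n_feat,
    n_informative_expr = n_feat %/% 2, n_informative_meth = n_feat %/% 2,
    effect_expr = 3, effect_meth = 3, phenotype_flip_prob = 0,
    covariate_effects = list(), seed = seed))
}

# no signal anywhere: clusters, nuisance and covariates all silent
null_cohort <- function(seed = 21, n = 78, n_feat = 2000) {
  simulate_cohort(simulation_config(
    n_samples = n, n_features_expr = n_feat, n_features_meth = 200,
    n_informative_expr = 0, n_informative_meth = 0,
    effect_expr = 0, effect_meth = 0, nuisance_effect = 0,
    covariate_effects = list(), seed = seed))
}

# tiny omics matrix with named dims
toy_matrix <- function(nf = 4, ns = 3, kind = "expression", seed = 1) {
  set.seed(seed)
  v <- matrix(rnorm(nf * ns), nf, ns,
              dimnames = list(sprintf("f%02d", seq_len(nf)),
                              sprintf("s%02d", seq_len(ns))))
  if (kind == "methylation") v <- plogis(v)
  omics_matrix(v, kind)
}

# hand-rolled basic_partitions object from a label matrix
manual_bps <- function(labels, ids = sprintf("s%02d", seq_len(nrow(labels)))) {
  structure(list(sample_ids = ids, labels = labels,
                 k = apply(labels, 2, max),
                 view = rep("manual", ncol(labels))),
            class = "basic_partitions")
}

# pooled-variance two-sample t-test p-values for every row of a matrix;
# independent of the package's model-fitting path
row_ttest_p <- function(x, g) {
  n1 <- sum(g == 1); n2 <- sum(g == 2)
  m1 <- rowMeans(x[, g == 1, drop = FALSE])
  m2 <- rowMeans(x[, g == 2, drop = FALSE])
  v1 <- apply(x[, g == 1, drop = FALSE], 1, var)
  v2 <- apply(x[, g == 2, drop = FALSE], 1, var)
  sp <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
  tt <- (m1 - m2) / sqrt(sp * (1 / n1 + 1 / n2))
  2 * pt(-abs(tt), df = n1 + n2 - 2)
}
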