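#' Configuration for the synthetic multi-omics cohort generator
#'
#' Captures every knob of [simulate_cohort()].  Defaults emulate the study
#' design the package targets: 78 lung-tissue samples from former smokers,
#' paired expression (log-intensity) and methylation (beta value) blocks on
#' the same samples, a binary COPD phenotype at 58% prevalence only partially
#' aligned with the planted molecular clusters, and clinical covariates drawn
#' from ranges typical of a severe-COPD vs normal-spirometry surgical cohort.
#'
#' @param n_samples Number of samples.
#' @param n_features_expr,n_features_meth Features per omic block.  Defaults
#'   (2000 each) are a desk-scale stand-in for genome-wide arrays.
#' @param n_informative_expr,n_informative_meth Number of features carrying
#'   the planted cluster signal in each block.
#' @param effect_expr Mean shift between planted clusters for informative
#'   expression features, in log-intensity units.
#' @param effect_meth Mean shift between planted clusters for informative
#'   methylation features, on the logit-beta scale.
#' @param phenotype_flip_prob Probability that a sample's COPD label disagrees
#'   with its planted cluster.
#' @param copd_prevalence Probability that a sample is a COPD case.
#' @param exact_counts If `TRUE`, force exactly `round(n * prevalence)` cases
#'   (and the matching planted-cluster margins) instead of binomial sampling.
#' @param nuisance_effect Mean shift driven by a second latent factor
#'   independent of the phenotype (0 disables it).  Applied to its own feature
#'   block, disjoint from the informative one.
#' @param noise_sd_expr Residual SD of expression features.
#' @param noise_sd_meth_logit Residual SD of methylation features on the logit
#'   scale.
#' @param covariate_effects Named list mapping covariate names (`age`, `sex`,
#'   `pack_years`) to the per-feature effect scale (in feature SD units per
#'   covariate SD) injected into a random 5% of features in each block.
#' @param seed Integer seed; identical config + seed reproduces the cohort
#'   bit-identically.
#'
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(n_samples = 78L,
                              n_features_expr = 2000L,
                              n_features_meth = 2000L,
                              n_informative_expr = 200L,
                              n_informative_meth = 200L,
                              effect_expr = 1,
                              effect_meth = 1,
                              phenotype_flip_prob = 0.3,
                              copd_prevalence = 0.58,
                              exact_counts = FALSE,
                              nuisance_effect = 0,
                              noise_sd_expr = 1,
                              noise_sd_meth_logit = 0.8,
                              covariate_effects = list(age = 0.05, sex = 0.1,
                                                       pack_years = 0.05),
                              seed = 1L) {
  cfg <- list(n_samples = as.integer(n_samples),
              n_features_expr = as.integer(n_features_expr),
              n_features_meth = as.integer(n_features_meth),
              n_informative_expr = as.integer(n_informative_expr),
              n_informative_meth = as.integer(n_informative_meth),
              effect_expr = effect_expr, effect_meth = effect_meth,
              phenotype_flip_prob = phenotype_flip_prob,
              copd_prevalence = copd_prevalence,
              exact_counts = isTRUE(exact_counts),
              nuisance_effect = nuisance_effect,
              noise_sd_expr = noise_sd_expr,
              noise_sd_meth_logit = noise_sd_meth_logit,
              covariate_effects = covariate_effects,
              seed = as.integer(seed))
  validate_simulation_config(cfg)
  structure(cfg, class = "simulation_config")
}

validate_simulation_config <- function(cfg) {
  counts <- c("n_samples", "n_features_expr", "n_features_meth",
              "n_informative_expr", "n_informative_meth")
  for (f in counts) {
    if (is.na(cfg[[f]]) || cfg[[f]] < 0) stop(f, " must be a non-negative count")
  }
  if (cfg$n_samples < 4) stop("n_samples must be at least 4")
  if (cfg$n_features_expr < 1 || cfg$n_features_meth < 1) {
    stop("feature counts must be positive")
  }
  if (cfg$n_informative_expr > cfg$n_features_expr ||
      cfg$n_informative_meth > cfg$n_features_meth) {
    stop("informative feature counts cannot exceed total feature counts")
  }
  for (f in c("phenotype_flip_prob", "copd_prevalence")) {
    if (cfg[[f]] < 0 || cfg[[f]] > 1) stop(f, " must lie in [0,1]")
  }
  if (cfg$nuisance_effect < 0) stop("nuisance_effect must be >= 0")
  if (cfg$noise_sd_expr <= 0 || cfg$noise_sd_meth_logit <= 0) {
    stop("noise SDs must be positive")
  }
  invisible(cfg)
}

#' Simulate a paired expression/methylation cohort with planted structure
#'
#' Generates two omics blocks over one set of samples.  Samples belong to one
#' of two planted molecular clusters; informative features in each block are
#' shifted between clusters by the configured effect (on the log-intensity
#' scale for expression, on the logit scale for methylation, mapped back
#' through the inverse logit so beta values stay strictly inside (0, 1)).
#' The COPD label equals the planted cluster with probability
#' `1 - phenotype_flip_prob`, so the phenotype is only partially aligned with
#' the molecular structure.  An optional second latent factor (the "nuisance"
#' partition) shifts a disjoint feature block by `nuisance_effect`,
#' independent of the phenotype; clinical covariates are drawn conditionally
#' on case status and injected additively into a small random feature subset.
#'
#' @param config A [simulation_config()].
#' @return A list of class `synthetic_cohort` with elements `expression` and
#'   `methylation` ([omics_matrix]), `clinical` (data frame),
#'   `planted_partition` and `nuisance_partition` ([partition]), and `config`.
#' @examples
#' cohort <- simulate_cohort(simulation_config(n_samples = 20,
#'   n_features_expr = 50, n_features_meth = 50,
#'   n_informative_expr = 10, n_informative_meth = 10, seed = 7))
#' cohort
#' @export
simulate_cohort <- function(config = simulation_config()) {
  validate_simulation_config(config)
  set.seed(config$seed)
  n <- config$n_samples
  ids <- sprintf("S%03d", seq_len(n))

  # planted cluster 2 is the "disease-like" cluster at prevalence rate
  if (config$exact_counts) {
    n2 <- round(n * config$copd_prevalence)
    planted <- sample(rep(c(1L, 2L), c(n - n2, n2)))
  } else {
    planted <- 1L + rbinom(n, 1, config$copd_prevalence)
  }
  flip <- runif(n) < config$phenotype_flip_prob
  copd <- ifelse(flip, 3L - planted, planted) - 1L   # 0 = control, 1 = case
  nuis <- 1L + rbinom(n, 1, 0.5)

  clinical <- simulate_clinical(ids, copd)
  cov_z <- cbind(age = as.numeric(scale(clinical$age)),
                 sex = as.numeric(scale(as.integer(clinical$sex == "male"))),
                 pack_years = as.numeric(scale(clinical$pack_years)))

  expr <- simulate_block(n_features = config$n_features_expr,
                         n_informative = config$n_informative_expr,
                         planted = planted, nuis = nuis,
                         effect = config$effect_expr,
                         nuisance_effect = config$nuisance_effect,
                         noise_sd = config$noise_sd_expr,
                         baseline_mean = 7, baseline_sd = 1.5,
                         cov_z = cov_z,
                         covariate_effects = config$covariate_effects,
                         prefix = "expr")
  meth_logit <- simulate_block(n_features = config$n_features_meth,
                               n_informative = config$n_informative_meth,
                               planted = planted, nuis = nuis,
                               effect = config$effect_meth,
                               nuisance_effect = config$nuisance_effect,
                               noise_sd = config$noise_sd_meth_logit,
                               baseline_mean = 0, baseline_sd = 2,
                               cov_z = cov_z,
                               covariate_effects = config$covariate_effects,
                               prefix = "cg")
  beta <- plogis(meth_logit)   # inverse logit keeps beta strictly in (0,1)
  colnames(expr) <- colnames(beta) <- ids

  structure(list(
    expression = omics_matrix(expr, "expression"),
    methylation = omics_matrix(beta, "methylation"),
    clinical = clinical,
    planted_partition = partition(planted, ids, k = 2L),
    nuisance_partition = partition(nuis, ids, k = 2L),
    config = config
  ), class = "synthetic_cohort")
}

# One omic block: informative features get +/- effect/2 between planted
# clusters, a disjoint block of the same size reacts to the nuisance factor,
# covariates are injected into a random 5% of features, the rest is noise.
simulate_block <- function(n_features, n_informative, planted, nuis,
                           effect, nuisance_effect, noise_sd,
                           baseline_mean, baseline_sd,
                           cov_z, covariate_effects, prefix) {
  n <- length(planted)
  base <- rnorm(n_features, baseline_mean, baseline_sd)
  x <- matrix(rnorm(n_features * n, 0, noise_sd), n_features, n) + base
  if (n_informative > 0 && effect != 0) {
    sgn <- sample(c(-1, 1), n_informative, replace = TRUE)
    shift <- outer(sgn * effect, as.numeric(planted == 2L))
    x[seq_len(n_informative), ] <- x[seq_len(n_informative), ] + shift
  }
  if (nuisance_effect > 0) {
    i0 <- n_informative
    n_nuis <- min(n_informative, n_features - i0)
    if (n_nuis > 0) {
      idx <- i0 + seq_len(n_nuis)
      sgn <- sample(c(-1, 1), n_nuis, replace = TRUE)
      x[idx, ] <- x[idx, ] + outer(sgn * nuisance_effect,
                                   as.numeric(nuis == 2L))
    }
  }
  for (nm in names(covariate_effects)) {
    s <- covariate_effects[[nm]]
    if (is.null(s) || s == 0 || !nm %in% colnames(cov_z)) next
    n_cov <- max(1L, round(0.05 * n_features))
    idx <- sample.int(n_features, n_cov)
    x[idx, ] <- x[idx, ] + s * noise_sd * rep(cov_z[, nm], each = n_cov)
  }
  rownames(x) <- sprintf("%s_%05d", prefix, seq_len(n_features))
  x
}

# Clinical covariates conditional on case status, on scales typical of a
# former-smoker surgical lung-tissue cohort (ages in years, pack-years,
# spirometry as percent predicted and FEV1/FVC ratio, CT emphysema measures).
simulate_clinical <- function(ids, copd) {
  n <- length(ids)
  case <- copd == 1L
  pick <- function(ctrl, cs) ifelse(case, cs, ctrl)
  clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)
  data.frame(
    sample_id = ids,
    copd_status = as.integer(copd),
    age = round(rnorm(n, pick(65, 64), pick(9.5, 7.6)), 1),
    sex = ifelse(runif(n) < pick(0.33, 0.49), "male", "female"),
    race = ifelse(runif(n) < pick(0.88, 0.98), "caucasian", "other"),
    bmi = round(clamp(rnorm(n, pick(28.5, 26), pick(6.1, 4.8)), 15, 55), 2),
    pack_years = round(clamp(rnorm(n, pick(33, 58), pick(21, 25)), 1, 200), 1),
    months_quit = round(clamp(rlnorm(n, log(pick(143, 72)), pick(1.1, 0.8)),
                              1, 700)),
    fev1pp = round(ifelse(case,
                          clamp(rlnorm(n, log(25), 0.35), 10, 49),
                          clamp(rnorm(n, 97, 13), 80, 140))),
    fev1_fvc = round(ifelse(case,
                            clamp(rnorm(n, 0.31, 0.10), 0.10, 0.69),
                            clamp(rnorm(n, 0.79, 0.05), 0.70, 0.95)), 2),
    pct_laa950 = round(ifelse(case,
                              clamp(rnorm(n, 0.30, 0.13), 0.01, 0.70),
                              clamp(abs(rnorm(n, 0.02, 0.04)), 0, 0.30)), 3),
    perc15 = round(rnorm(n, pick(-909, -966), pick(36, 30)), 1),
    pi10 = round(rnorm(n, pick(3.98, 4.21), pick(0.44, 0.39)), 2),
    stringsAsFactors = FALSE
  )
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("synthetic cohort: %d samples, %d expression / %d methylation features\n",
              nrow(x$clinical), nrow(x$expression), nrow(x$methylation)))
  cat(sprintf("COPD cases: %d (%.0f%%); planted cluster sizes: %s\n",
              sum(x$clinical$copd_status),
              100 * mean(x$clinical$copd_status),
              paste(cluster_sizes(x$planted_partition), collapse = "/")))
  invisible(x)
}

#' Write a synthetic cohort to a directory
#'
#' Writes `expression.tsv`, `methylation.tsv` (tab-delimited feature-by-sample
#' matrices), `clinical.csv`, and the planted/nuisance partitions as
#' two-column CSVs.
#'
#' @param cohort A [simulate_cohort()] result.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_omics_matrix(cohort$expression, file.path(dir, "expression.tsv"))
  write_omics_matrix(cohort$methylation, file.path(dir, "methylation.tsv"))
  write_cohort_table(cohort$clinical, file.path(dir, "clinical.csv"))
  write_partition(cohort$planted_partition, file.path(dir, "planted_partition.csv"))
  write_partition(cohort$nuisance_partition, file.path(dir, "nuisance_partition.csv"))
  invisible(dir)
}

#' Association statistics of every feature against COPD status
#'
#' Fits the package's per-feature linear model (optionally covariate
#' adjusted) of one omic block against the cohort's COPD labels, applies
#' empirical-Bayes moderation and BH correction, and returns the resulting
#' stat table.  On synthetic cohorts this plays the role of the external
#' disease-association results used to pre-filter features in the
#' sensitivity analysis.
#'
#' @param cohort A [simulate_cohort()] result.
#' @param omic `"expression"` or `"methylation"`.
#' @param covariates Clinical covariate columns to adjust for (default none).
#' @return A stat table (see [read_stat_table()]).
#' @export
reference_association_table <- function(cohort,
                                        omic = c("expression", "methylation"),
                                        covariates = character(0)) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  omic <- match.arg(omic)
  m <- cohort[[omic]]
  if (omic == "methylation") {
    # model methylation on the logit scale, standard for beta values
    v <- qlogis(pmin(pmax(unclass(m), 1e-6), 1 - 1e-6))
    m <- omics_matrix(v, "expression")
  }
  lab <- cohort$clinical$copd_status
  if (min(table(lab)) < 2) stop("need at least 2 samples per COPD class")
  p <- partition(lab + 1L, cohort$clinical$sample_id, k = 2L)
  fits <- fit_feature_models(m, cohort$clinical, p, covariates = covariates)
  moderate(fits)
}
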