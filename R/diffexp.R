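#' Per-feature linear models of an omics matrix against a cluster contrast
#'
#' Fits one ordinary-least-squares model per feature on a shared design
#' matrix containing the two-cluster contrast plus declared clinical
#' covariates (categorical covariates are dummy-coded against declared
#' reference levels).  Samples with missing covariate values are dropped and
#' counted.  The contrast coefficient is the (log-scale) difference between
#' cluster 2 and cluster 1.
#'
#' @param matrix An [omics_matrix] (features x samples).
#' @param clinical Clinical data frame with `sample_id` and the covariate
#'   columns.
#' @param partition A two-cluster [partition] providing the contrast.
#' @param covariates Character vector of clinical column names (e.g.
#'   `c("age", "sex", "race", "pack_years")`).
#' @param reference_levels Named list mapping categorical covariates to their
#'   reference level.
#' @return A list of class `feature_fits` with per-feature `coefficients`,
#'   `sigma2` (residual variance), `df_residual`, `stdev_unscaled` (the
#'   contrast coefficient's scale factor, i.e. its SE divided by the
#'   residual SD), plus `design`, `n_used` and `n_dropped`.
#' @export
fit_feature_models <- function(matrix, clinical, partition,
                               covariates = character(0),
                               reference_levels = list()) {
  stopifnot(inherits(matrix, "omics_matrix"))
  clinical <- validate_cohort_table(clinical)
  p <- as_partition(partition)
  if (p$k != 2) stop("differential expression expects a two-cluster contrast")
  if (any(covariates == "cluster")) stop("the contrast cannot also be a covariate")
  idx <- match(colnames(matrix), clinical$sample_id)
  if (any(is.na(idx))) stop("matrix contains samples absent from the clinical table")
  clin <- clinical[idx, , drop = FALSE]
  if (!identical(p$sample_ids, colnames(matrix))) {
    stop("partition and matrix must cover identical samples in the same order")
  }
  df <- data.frame(cluster = factor(p$labels), clin[, covariates, drop = FALSE])
  for (v in covariates) {
    if (is.character(df[[v]])) df[[v]] <- factor(df[[v]])
    if (is.factor(df[[v]]) && !is.null(reference_levels[[v]])) {
      df[[v]] <- stats::relevel(df[[v]], ref = reference_levels[[v]])
    }
    if (all(is.na(df[[v]]))) stop("covariate is entirely missing: ", v)
  }
  keep <- complete.cases(df)
  n_dropped <- sum(!keep)
  if (n_dropped) {
    message(sprintf("fit_feature_models: dropped %d sample(s) with missing covariates",
                    n_dropped))
  }
  df <- df[keep, , drop = FALSE]
  y <- unclass(matrix)[, keep, drop = FALSE]
  design <- model.matrix(~ ., data = df)
  qrd <- qr(design)
  if (qrd$rank < ncol(design)) {
    stop("design matrix is rank deficient (collinear covariates?)")
  }
  n <- nrow(design); pcol <- ncol(design)
  df_residual <- n - pcol
  if (df_residual < 1) stop("no residual degrees of freedom")
  fit <- lm.fit(design, t(y))
  coefs <- t(fit$coefficients)                # features x pcol
  res <- t(fit$residuals)                     # features x n
  sigma2 <- rowSums(res^2) / df_residual
  xtxinv <- chol2inv(qr.R(qrd))
  ccol <- which(colnames(design) == "cluster2")
  structure(list(
    feature_ids = rownames(y),
    coefficients = coefs[, ccol],
    sigma2 = sigma2,
    df_residual = df_residual,
    stdev_unscaled = rep(sqrt(xtxinv[ccol, ccol]), nrow(y)),
    design = design, n_used = n, n_dropped = n_dropped
  ), class = "feature_fits")
}

# Solve trigamma(y) = x by Newton iteration on the stable scale.
trigamma_inverse <- function(x) {
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in 1:75) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, deriv = 2)
    y <- y + dif
    if (abs(dif / y) < 1e-10) break
  }
  y
}

#' Empirical-Bayes moderation of per-feature variances
#'
#' Shrinks each feature's residual variance towards a common prior estimated
#' from the ensemble of features, then forms moderated t-statistics.  The
#' prior degrees of freedom \eqn{d_0} and prior variance \eqn{s_0^2} are
#' estimated by the closed-form moments method on the log residual
#' variances: with \eqn{e_g = \log s_g^2 - \psi(d_g/2) + \log(d_g/2)},
#' \eqn{d_0} solves \eqn{\psi'(d_0/2) = \mathrm{var}(e) - \psi'(d_g/2)} and
#' \eqn{s_0^2 = \exp\{\bar e + \psi(d_0/2) - \log(d_0/2)\}}.  The posterior
#' variance is the df-weighted blend
#' \eqn{\tilde s_g^2 = (d_0 s_0^2 + d_g s_g^2)/(d_0 + d_g)}, the moderated t
#' is the coefficient over \eqn{\tilde s_g \times} scale factor with
#' \eqn{d_g + d_0} degrees of freedom, and FDR is Benjamini-Hochberg across
#' features.  When the log-variances are underdispersed the prior df is
#' infinite; it is capped at `df_prior_cap` so downstream df stay finite.
#'
#' @param fits A `feature_fits` object from [fit_feature_models()].
#' @param prior_df Optional forced prior df (0 reproduces ordinary t-tests).
#' @param df_prior_cap Cap on the estimated prior df (default 1e6).
#' @return A stat table data frame (`feature_id, effect, t_stat, p_value,
#'   fdr`, plus `abs_lfc_gt1` flagging |effect| > 1), with the estimated
#'   `df_prior` and `s2_prior` as attributes.
#' @export
moderate <- function(fits, prior_df = NULL, df_prior_cap = 1e6) {
  stopifnot(inherits(fits, "feature_fits"))
  s2 <- fits$sigma2
  dfr <- fits$df_residual
  if (length(s2) < 10 && is.null(prior_df)) {
    stop("variance-prior estimation needs at least 10 features")
  }
  if (all(s2 <= 0)) stop("all residual variances are zero")
  if (is.null(prior_df)) {
    ok <- s2 > 0
    z <- log(s2[ok])
    e <- z - digamma(dfr / 2) + log(dfr / 2)
    emean <- mean(e)
    evar <- var(e) - trigamma(dfr / 2)
    if (is.finite(evar) && evar > 0) {
      df_prior <- 2 * trigamma_inverse(evar)
      s2_prior <- exp(emean + digamma(df_prior / 2) - log(df_prior / 2))
    } else {
      # underdispersed log-variances: infinite prior df, arithmetic-mean prior
      df_prior <- Inf
      s2_prior <- mean(s2)
    }
  } else {
    df_prior <- prior_df
    s2_prior <- if (prior_df > 0) mean(s2[s2 > 0]) else 0
  }
  df_prior <- min(df_prior, df_prior_cap)
  s2_post <- if (df_prior == 0) s2 else {
    (df_prior * s2_prior + dfr * s2) / (df_prior + dfr)
  }
  tstat <- fits$coefficients / (sqrt(s2_post) * fits$stdev_unscaled)
  df_total <- dfr + df_prior
  pval <- 2 * pt(-abs(tstat), df = df_total)
  out <- data.frame(feature_id = fits$feature_ids,
                    effect = fits$coefficients,
                    t_stat = tstat, p_value = pval,
                    fdr = bh_adjust(pval),
                    abs_lfc_gt1 = abs(fits$coefficients) > 1,
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "df_prior") <- df_prior
  attr(out, "s2_prior") <- s2_prior
  attr(out, "df_total") <- df_total
  out
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Adjusted value for the i-th order statistic is
#' `min_j>=i (m * p_(j) / j)` capped at 1, returned in the original order.
#'
#' @param p_values Numeric vector of p-values in \[0, 1\].
#' @return Adjusted values of the same length.
#' @export
bh_adjust <- function(p_values) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0,1]")
  }
  p.adjust(p_values, method = "BH")
}

#' Hypergeometric over-representation analysis against gene sets
#'
#' For each gene set, tests whether the significant list overlaps the set
#' more than expected by chance when drawing `length(list)` genes from the
#' universe without replacement: the p-value is the upper tail
#' `P(overlap >= observed)` of the hypergeometric distribution, with the
#' gene set first intersected with the universe.  Features are translated to
#' genes through the optional `id_map` before testing.  FDR is BH across
#' sets; rows are sorted by p-value.
#'
#' @param significant Character vector of significant feature ids.
#' @param universe Character vector of all tested feature ids (superset of
#'   `significant` after mapping).
#' @param gene_sets Named list of character vectors ([read_gmt()]).
#' @param id_map Optional data frame with columns `feature_id` and `gene`
#'   mapping features to gene symbols; by default ids are used as-is.
#' @return A data frame with columns `set_name, overlap, set_size,
#'   list_size, universe_size, p_value, fdr`.
#' @export
ora <- function(significant, universe, gene_sets, id_map = NULL) {
  map <- function(ids) {
    if (is.null(id_map)) return(unique(ids))
    unique(id_map$gene[match(ids, id_map$feature_id)][!is.na(
      id_map$gene[match(ids, id_map$feature_id)])])
  }
  uni <- map(universe)
  sig <- map(significant)
  if (length(uni) == 0) stop("empty universe")
  if (length(sig) == 0) stop("empty significant list")
  if (!all(sig %in% uni)) stop("significant list must be a subset of the universe")
  rows <- lapply(names(gene_sets), function(nm) {
    set <- intersect(gene_sets[[nm]], uni)
    ov <- length(intersect(set, sig))
    pv <- phyper(ov - 1, length(set), length(uni) - length(set),
                 length(sig), lower.tail = FALSE)
    data.frame(set_name = nm, overlap = ov, set_size = length(set),
               list_size = length(sig), universe_size = length(uni),
               p_value = pv, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$fdr <- bh_adjust(out$p_value)
  out[order(out$p_value, out$set_name), , drop = FALSE]
}

#' Moderated differential expression between two clusters
#'
#' Convenience wrapper chaining [fit_feature_models()] and [moderate()].
#'
#' @inheritParams fit_feature_models
#' @return A stat table (see [moderate()]).
#' @export
moderated_diffexp <- function(matrix, clinical, partition,
                              covariates = c("age", "sex", "race",
                                             "pack_years"),
                              reference_levels = list()) {
  covariates <- intersect(covariates, names(clinical))
  moderate(fit_feature_models(matrix, clinical, partition,
                              covariates = covariates,
                              reference_levels = reference_levels))
}
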