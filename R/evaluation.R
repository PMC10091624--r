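#' Normalized mutual information between two partitions
#'
#' Mutual information of the label contingency table divided by a normalizer
#' built from the two label entropies.  The default normalizer is the square
#' root of the entropy product; `"max"` and `"mean"` variants are provided
#' since all three give 1 for identical partitions (up to relabelling).
#' Degenerate conventions: if both partitions are single-cluster (both
#' entropies zero) the value is 1; if exactly one is, the value is 0.
#'
#' @param a,b [partition] objects (or labelled vectors) over the same
#'   samples.
#' @param normalizer `"sqrt"` (default), `"max"` or `"mean"`.
#' @return A number in \[0, 1\]; 1 means identical clustering solutions.
#' @examples
#' p <- partition(c(s1 = 1, s2 = 1, s3 = 2, s4 = 2))
#' nmi(p, p)       # 1
#' @export
nmi <- function(a, b, normalizer = c("sqrt", "max", "mean")) {
  normalizer <- match.arg(normalizer)
  a <- as_partition(a); b <- as_partition(b, a$sample_ids)
  check_same_samples(a, b)
  tab <- table(a$labels, b$labels)
  p <- tab / sum(tab)
  pa <- rowSums(p); pb <- colSums(p)
  ent <- function(q) { q <- q[q > 0]; -sum(q * log(q)) }
  ha <- ent(pa); hb <- ent(pb)
  if (ha == 0 && hb == 0) return(1)
  if (ha == 0 || hb == 0) return(0)
  nz <- p > 0
  mi <- sum(p[nz] * log(p[nz] / (pa[row(p)[nz]] * pb[col(p)[nz]])))
  denom <- switch(normalizer,
                  sqrt = sqrt(ha * hb),
                  max = max(ha, hb),
                  mean = (ha + hb) / 2)
  min(max(mi / denom, 0), 1)
}

# coerce a phenotype vector to 0/1 with 1 = case
as_case_indicator <- function(phenotype) {
  if (is.logical(phenotype)) return(as.integer(phenotype))
  if (is.factor(phenotype)) return(as.integer(phenotype == levels(phenotype)[2]))
  if (is.numeric(phenotype)) {
    u <- sort(unique(phenotype))
    if (!all(u %in% c(0, 1))) stop("numeric phenotype must be coded 0/1")
    return(as.integer(phenotype))
  }
  stop("phenotype must be logical, 0/1 numeric, or a two-level factor")
}

#' Case-enrichment classification accuracy of a two-cluster solution
#'
#' The accuracy statistic used throughout the package to score how well a
#' two-cluster solution recovers a binary phenotype: identify the cluster
#' with the larger percentage of cases (tie: the larger cluster), then
#' return (cases in that cluster + controls in the other cluster) / n.
#' Because the case cluster is chosen by case *percentage* rather than by
#' case count, the statistic can fall below the majority-class rate.
#'
#' @param partition A two-cluster [partition].
#' @param phenotype Binary labels (logical, 0/1, or two-level factor; 1/TRUE/
#'   second level = case), aligned with the partition samples.
#' @return A fraction in \[0, 1\].
#' @examples
#' # one cluster of 35 samples with 24 cases, one of 43 with 22 controls:
#' p <- partition(rep(1:2, c(35, 43)), sprintf("s%02d", 1:78))
#' y <- c(rep(1, 24), rep(0, 11), rep(1, 21), rep(0, 22))
#' classification_accuracy(p, y)   # 46/78 = 0.59
#' @export
classification_accuracy <- function(partition, phenotype) {
  p <- as_partition(partition)
  if (p$k != 2) stop("classification accuracy is defined for exactly 2 clusters")
  y <- as_case_indicator(phenotype)
  if (length(y) != length(p$labels)) stop("phenotype length mismatch")
  n <- length(y)
  cases <- c(sum(y[p$labels == 1]), sum(y[p$labels == 2]))
  sizes <- cluster_sizes(p)
  pct <- cases / sizes
  case_cluster <- if (pct[1] == pct[2]) which.max(sizes) else which.max(pct)
  other <- 3L - case_cluster
  (cases[case_cluster] + (sizes[other] - cases[other])) / n
}

#' Per-cluster case counts and percentages
#'
#' @param partition A [partition].
#' @param phenotype Binary labels (1/TRUE/second level = case).
#' @return A data frame with one row per cluster: `cluster`, `n`, `cases`,
#'   `controls`, `case_pct` (percent of the cluster that are cases).
#' @export
cluster_case_summary <- function(partition, phenotype) {
  p <- as_partition(partition)
  y <- as_case_indicator(phenotype)
  if (length(y) != length(p$labels)) stop("phenotype length mismatch")
  cases <- vapply(seq_len(p$k), function(l) sum(y[p$labels == l]), numeric(1))
  sizes <- cluster_sizes(p)
  data.frame(cluster = seq_len(p$k), n = sizes, cases = cases,
             controls = sizes - cases, case_pct = 100 * cases / sizes)
}

#' Table-one style clinical comparison of two clusters
#'
#' For each declared variable, produces per-cluster summaries and a
#' two-sided p-value: mean (sd) with a t-test for normally distributed
#' variables, median \[IQR\] with a Wilcoxon rank-sum test (tie-corrected
#' normal approximation) for non-normal ones, and N (%) with a chi-squared
#' test (continuity-corrected for 2x2 tables) for categorical ones.  Whether
#' a variable is treated as normal is declared per variable, not auto-tested.
#' Missing values are dropped per variable and counted.
#'
#' @param clinical Clinical data frame with a `sample_id` column.
#' @param partition A two-cluster [partition] over the clinical samples.
#' @param variable_specs Data frame with columns `variable` and `type`
#'   (`"normal"`, `"nonnormal"` or `"categorical"`); defaults cover the
#'   standard cohort columns.
#' @param var_equal Use the pooled-variance t-test instead of Welch
#'   (default `FALSE`).
#' @return A data frame of class `cluster_comparison` with one row per
#'   variable: summaries per cluster, test used, p-value and missing count.
#' @export
compare_clusters <- function(clinical, partition,
                             variable_specs = default_variable_specs(clinical),
                             var_equal = FALSE) {
  clinical <- validate_cohort_table(clinical)
  p <- as_partition(partition)
  if (p$k != 2) stop("clinical comparison expects exactly 2 clusters")
  idx <- match(p$sample_ids, clinical$sample_id)
  if (any(is.na(idx))) stop("partition contains samples absent from the clinical table")
  clinical <- clinical[idx, , drop = FALSE]
  grp <- p$labels
  rows <- lapply(seq_len(nrow(variable_specs)), function(i) {
    v <- variable_specs$variable[i]
    type <- variable_specs$type[i]
    if (!v %in% names(clinical)) stop("variable not in clinical table: ", v)
    x <- clinical[[v]]
    ok <- !is.na(x)
    if (any(tapply(ok, grp, sum) == 0)) {
      stop(sprintf("variable '%s' has no non-missing values in one cluster", v))
    }
    x1 <- x[ok & grp == 1]; x2 <- x[ok & grp == 2]
    out <- switch(type,
      normal = {
        s <- function(z) sprintf("%.2f (%.2f)", mean(z), sd(z))
        pv <- t.test(x1, x2, var.equal = var_equal)$p.value
        list(s(x1), s(x2), "t", pv)
      },
      nonnormal = {
        s <- function(z) sprintf("%.2f [%.2f, %.2f]", median(z),
                                 quantile(z, 0.25), quantile(z, 0.75))
        pv <- suppressWarnings(
          wilcox.test(x1, x2, exact = FALSE, correct = TRUE)$p.value)
        list(s(x1), s(x2), "wilcoxon", pv)
      },
      categorical = {
        f <- factor(x[ok])
        tab <- table(grp[ok], f)
        lvl <- levels(f)[length(levels(f))]   # summarise the last level
        s <- function(z) sprintf("%d (%.1f%%)", sum(z == lvl),
                                 100 * mean(z == lvl))
        pv <- suppressWarnings(chisq.test(tab, correct = TRUE)$p.value)
        list(s(x1), s(x2), "chisq", pv)
      },
      stop("unknown variable type: ", type))
    data.frame(variable = v, type = type,
               cluster1 = out[[1]], cluster2 = out[[2]],
               test_used = out[[3]], p_value = out[[4]],
               n_missing = sum(!ok), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("cluster_comparison", "data.frame")
  out
}

#' Default variable specification for the clinical comparison
#'
#' Continuous variables with roughly symmetric distributions (age, BMI,
#' pack-years, CT density summaries) are compared with t-tests; skewed ones
#' (spirometry, emphysema fraction, months since quitting) with rank-sum
#' tests; binary ones with chi-squared tests.
#'
#' @param clinical Clinical data frame; only variables present are kept.
#' @return A data frame with columns `variable` and `type`.
#' @export
default_variable_specs <- function(clinical) {
  spec <- data.frame(
    variable = c("copd_status", "sex", "race", "age", "bmi", "pack_years",
                 "perc15", "pi10", "fev1pp", "fev1_fvc", "pct_laa950",
                 "months_quit"),
    type = c("categorical", "categorical", "categorical", "normal", "normal",
             "normal", "normal", "normal", "nonnormal", "nonnormal",
             "nonnormal", "nonnormal"),
    stringsAsFactors = FALSE)
  spec[spec$variable %in% names(clinical), , drop = FALSE]
}

#' @export
print.cluster_comparison <- function(x, ...) {
  d <- as.data.frame(x)
  d$p_value <- signif(d$p_value, 2)
  print(d, row.names = FALSE)
  invisible(x)
}

#' Cross-tabulate two cluster solutions against a binary phenotype
#'
#' Produces the full (cluster A x cluster B x phenotype) contingency array
#' plus derived concordance counts.  Each partition's clusters are mapped to
#' the phenotype by the case-enrichment rule of
#' [classification_accuracy()]; a sample is "correctly" placed when it sits
#' in the cluster matching its phenotype.  Concordant-correct samples are
#' placed correctly by both solutions, concordant-incorrect ones incorrectly
#' by both, and discordant ones are split between the two solutions.
#'
#' @param a,b Two-cluster [partition]s over the same samples.
#' @param phenotype Binary labels (1/TRUE/second level = case).
#' @return A list of class `overlap_counts` with `table` (3-way array) and
#'   `concordance` (named counts summing to n).
#' @export
overlap_table <- function(a, b, phenotype) {
  a <- as_partition(a); b <- as_partition(b, a$sample_ids)
  check_same_samples(a, b)
  y <- as_case_indicator(phenotype)
  if (length(y) != length(a$labels)) stop("phenotype length mismatch")
  tab <- table(A = a$labels, B = b$labels,
               phenotype = factor(y, c(0, 1), c("control", "case")))
  if (a$k == 2 && b$k == 2) {
    correct <- function(p) {
      cases <- vapply(1:2, function(l) sum(y[p$labels == l]), numeric(1))
      sizes <- cluster_sizes(p)
      pct <- cases / sizes
      cc <- if (pct[1] == pct[2]) which.max(sizes) else which.max(pct)
      (p$labels == cc) == (y == 1)
    }
    ca <- correct(a); cb <- correct(b)
    conc <- c(concordant_correct = sum(ca & cb),
              concordant_incorrect = sum(!ca & !cb),
              discordant = sum(ca != cb))
  } else {
    conc <- c(concordant_correct = NA_integer_,
              concordant_incorrect = NA_integer_, discordant = NA_integer_)
  }
  structure(list(table = tab, concordance = conc), class = "overlap_counts")
}

#' @export
print.overlap_counts <- function(x, ...) {
  print(x$table)
  cat("\nconcordance:", paste(names(x$concordance), x$concordance,
                              sep = " = ", collapse = ", "), "\n")
  invisible(x)
}
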