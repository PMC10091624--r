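test_that("NMI is 1 for identical solutions, relabel-invariant, and 0 for independent ones", {
  ids <- letters[1:4]
  p <- partition(c(1, 1, 2, 2), ids)
  expect_equal(nmi(p, p), 1)
  expect_equal(nmi(p, partition(c(2, 2, 1, 1), ids)), 1)
  expect_equal(nmi(p, partition(c(1, 2, 1, 2), ids)), 0)
  for (norm in c("sqrt", "max", "mean")) {
    expect_equal(nmi(p, p, normalizer = norm), 1)
  }
  # degenerate conventions
  one <- partition(rep(1, 4), ids, k = 1)
  expect_equal(nmi(one, one), 1)
  expect_equal(nmi(one, p), 0)
})

test_that("NMI is symmetric, bounded, and matches an independent implementation", {
  set.seed(12)
  ids <- sprintf("s%02d", 1:40)
  for (i in 1:15) {
    a <- partition(sample(1:3, 40, replace = TRUE), ids)
    b <- partition(sample(1:4, 40, replace = TRUE), ids)
    ab <- nmi(a, b); ba <- nmi(b, a)
    expect_equal(ab, ba)
    expect_gte(ab, 0); expect_lte(ab, 1)
    # igraph implements the entropy-mean normalization
    expect_equal(nmi(a, b, normalizer = "mean"),
                 igraph::compare(a$labels, b$labels, method = "nmi"),
                 tolerance = 1e-12)
  }
  expect_error(nmi(partition(c(x = 1, y = 2)), partition(c(p = 1, q = 2))),
               "same samples")
})

test_that("classification accuracy reproduces the worked two-cluster examples", {
  ids <- sprintf("s%02d", 1:78)
  # cluster 1: 35 samples with 24 cases; cluster 2: 43 samples with 22 controls
  p <- partition(rep(c(1, 2), c(35, 43)), ids)
  y <- c(rep(1, 24), rep(0, 11), rep(1, 21), rep(0, 22))
  expect_equal(classification_accuracy(p, y), 46 / 78)
  expect_equal(round(100 * classification_accuracy(p, y)), 59)

  # 56-sample cluster with 27 cases vs 22-sample cluster with 18 cases
  p2 <- partition(rep(c(1, 2), c(56, 22)), ids)
  y2 <- c(rep(1, 27), rep(0, 29), rep(1, 18), rep(0, 4))
  expect_equal(classification_accuracy(p2, y2), 47 / 78)
  expect_equal(round(100 * classification_accuracy(p2, y2)), 60)

  # perfect alignment
  yp <- as.integer(p$labels == 2)
  expect_equal(classification_accuracy(p, yp), 1)
})

test_that("accuracy tie-breaks to the larger cluster and can drop below the majority rate", {
  ids <- sprintf("s%02d", 1:10)
  # equal case percentages: the larger cluster is taken as the case cluster
  p <- partition(rep(c(1, 2), c(6, 4)), ids)
  y <- c(rep(1, 3), rep(0, 3), rep(1, 2), rep(0, 2))  # 50% in both
  expect_equal(classification_accuracy(p, y), (3 + 2) / 10)

  # a small pure-case cluster wins on percentage, dragging accuracy below
  # the majority-class rate (6/10 here)
  p2 <- partition(rep(c(1, 2), c(2, 8)), ids)
  y2 <- c(1, 1, rep(1, 4), rep(0, 4))
  acc <- classification_accuracy(p2, y2)
  expect_equal(acc, (2 + 4) / 10)
  expect_lt(acc, max(mean(y2), 1 - mean(y2)) + 1e-12)
  expect_error(classification_accuracy(partition(rep(1:3, len = 10), ids), y2),
               "2 clusters")
})

test_that("cluster case summaries report the printed-style percentages", {
  ids <- sprintf("s%02d", 1:78)
  p <- partition(rep(c(1, 2), c(56, 22)), ids)
  y <- c(rep(1, 27), rep(0, 29), rep(1, 18), rep(0, 4))
  s <- cluster_case_summary(p, y)
  expect_equal(s$case_pct, c(100 * 27 / 56, 100 * 18 / 22))
  expect_equal(round(s$case_pct, 1), c(48.2, 81.8))
})

test_that("clinical comparison applies the declared test per variable", {
  set.seed(44)
  n <- 40
  ids <- sprintf("s%02d", 1:n)
  grp <- rep(1:2, each = n / 2)
  clin <- data.frame(sample_id = ids,
                     copd_status = rbinom(n, 1, 0.5),
                     age = rnorm(n, 60, 8),
                     fev1pp = exp(rnorm(n, 4, 0.5)),
                     sex = sample(c("male", "female"), n, TRUE))
  part <- partition(grp, ids)
  spec <- data.frame(variable = c("age", "fev1pp", "copd_status"),
                     type = c("normal", "nonnormal", "categorical"))
  cmp <- compare_clusters(clin, part, spec)
  expect_identical(cmp$test_used, c("t", "wilcoxon", "chisq"))
  expect_equal(cmp$p_value[1],
               t.test(clin$age[grp == 1], clin$age[grp == 2])$p.value)
  expect_equal(cmp$p_value[2],
               wilcox.test(clin$fev1pp[grp == 1], clin$fev1pp[grp == 2],
                           exact = FALSE, correct = TRUE)$p.value)
  expect_equal(cmp$p_value[3],
               chisq.test(table(grp, clin$copd_status), correct = TRUE)$p.value)

  # identical values in both groups: no difference, p = 1
  clin$age <- rep(c(50, 60, 70, 80), 10)
  cmp2 <- compare_clusters(clin, part, data.frame(variable = "age",
                                                  type = "normal"))
  expect_equal(cmp2$p_value, 1)

  # missing values are dropped and counted
  clin$fev1pp[1:3] <- NA
  cmp3 <- compare_clusters(clin, part, data.frame(variable = "fev1pp",
                                                  type = "nonnormal"))
  expect_identical(cmp3$n_missing, 3L)
})

test_that("the continuity-corrected chi-squared path matches a hand oracle", {
  # 2x2 cluster-by-phenotype table (29,27 / 4,18)
  ids <- sprintf("s%02d", 1:78)
  grp <- rep(c(1, 2), c(56, 22))
  y <- c(rep(0, 29), rep(1, 27), rep(0, 4), rep(1, 18))
  clin <- data.frame(sample_id = ids, copd_status = y)
  cmp <- compare_clusters(clin, partition(grp, ids),
                          data.frame(variable = "copd_status",
                                     type = "categorical"))
  # independent evaluation of the Yates-corrected statistic and its tail
  tab <- table(grp, y)
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  stat <- sum((abs(tab - E) - 0.5)^2 / E)
  expect_equal(cmp$p_value, pchisq(stat, df = 1, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_equal(round(cmp$p_value, 3), 0.014)
})

test_that("on tiny tables the Yates p is close to exact conditional enumeration", {
  # enumerate the hypergeometric null of a 2x2 table with fixed margins and
  # compare P(stat >= observed) with the asymptotic Yates tail
  yates_p <- function(tab) {
    E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    pchisq(sum((abs(tab - E) - 0.5)^2 / E), 1, lower.tail = FALSE)
  }
  exact_p <- function(tab) {
    r <- rowSums(tab); c1 <- colSums(tab)[1]
    obs <- yates_p(tab)
    ps <- 0
    for (a in max(0, c1 - r[2]):min(r[1], c1)) {
      t2 <- matrix(c(a, c1 - a, r[1] - a, r[2] - c1 + a), 2, 2)
      if (yates_p(t2) <= obs + 1e-12) {
        ps <- ps + dhyper(a, r[1], r[2], c1)
      }
    }
    ps
  }
  tabs <- list(matrix(c(7, 2, 3, 8), 2, 2), matrix(c(5, 5, 4, 6), 2, 2),
               matrix(c(9, 1, 2, 8), 2, 2))
  for (tab in tabs) {
    expect_lt(abs(yates_p(tab) - exact_p(tab)), 0.08)
  }
})

test_that("overlap tables cross-tabulate correctly and conserve the sample count", {
  ids <- sprintf("s%02d", 1:30)
  y <- rep(c(0, 1), 15)
  pa <- partition(y + 1, ids)
  ov <- overlap_table(pa, pa, y)
  expect_equal(sum(ov$table), 30)
  expect_equal(unname(ov$concordance["concordant_correct"]), 30L)
  expect_equal(unname(ov$concordance["discordant"]), 0L)

  set.seed(6)
  a <- partition(sample(1:2, 30, replace = TRUE), ids)
  b <- partition(sample(1:2, 30, replace = TRUE), ids)
  ov2 <- overlap_table(a, b, y)
  expect_equal(sum(ov2$table), 30)
  expect_equal(sum(ov2$concordance), 30)
  # brute-force cross-check of one cell
  expect_equal(ov2$table["1", "2", "case"],
               sum(a$labels == 1 & b$labels == 2 & y == 1))
})
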