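test_that("standardization uses the population SD and is idempotent", {
  m <- omics_matrix(matrix(c(1, 2, 3), 1, 3,
                           dimnames = list("f1", c("a", "b", "c"))),
                    "expression")
  z <- standardize_features(m)
  expect_equal(as.numeric(z), c(-1.2247449, 0, 1.2247449), tolerance = 1e-6)
  expect_equal(unclass(standardize_features(z)), unclass(z), tolerance = 1e-12)

  v2 <- rbind(f1 = c(1, 2, 3), f2 = c(5, 5, 5))
  colnames(v2) <- c("a", "b", "c")
  m2 <- omics_matrix(v2, "expression")
  expect_warning(z2 <- standardize_features(m2), "zero-variance")
  expect_identical(rownames(z2), "f1")
})

test_that("the affinity kernel matches a brute-force evaluation on a toy set", {
  x <- matrix(c(0, 0, 1, 0, 0, 2, 4, 4), nrow = 2,
              dimnames = list(c("f1", "f2"), c("a", "b", "c", "d")))
  K <- 2; alpha <- 0.8
  w <- snf_affinity(x, n_neighbors = K, alpha = alpha)
  # independent evaluation with explicit loops
  n <- 4
  d2 <- matrix(0, n, n)
  for (i in 1:n) for (j in 1:n) d2[i, j] <- sum((x[, i] - x[, j])^2)
  mu <- sapply(1:n, function(i) mean(sort(d2[i, -i])[1:K]))
  ref <- matrix(0, n, n)
  for (i in 1:n) for (j in 1:n) {
    eps <- (mu[i] + mu[j] + d2[i, j]) / 3
    ref[i, j] <- exp(-d2[i, j] / (alpha * eps))
  }
  expect_equal(unclass(w), ref, tolerance = 1e-10, ignore_attr = TRUE)
  expect_equal(unclass(w), t(unclass(w)))
  expect_true(all(is.finite(w)) && all(w > 0))
})

test_that("duplicate samples attain the maximal affinity", {
  set.seed(5)
  x <- matrix(rnorm(10 * 6), 10, 6,
              dimnames = list(NULL, sprintf("s%d", 1:6)))
  x[, 6] <- x[, 1]   # s6 duplicates s1
  w <- snf_affinity(x, n_neighbors = 3, alpha = 0.8)
  expect_equal(max(w[1, -1]), w[1, 6])
  expect_equal(w[1, 6], max(w[upper.tri(w)]))
})

test_that("status normalization makes every row sum to one", {
  set.seed(7)
  x <- matrix(rnorm(20 * 10), 20, 10, dimnames = list(NULL, sprintf("s%d", 1:10)))
  w <- snf_affinity(x, n_neighbors = 4)
  p <- copdclust:::snf_status(unclass(w))
  expect_equal(unname(rowSums(p)), rep(1, 10), tolerance = 1e-12)
  expect_equal(unname(diag(p)), rep(0.5, 10))
})

test_that("fusion of a single view is a no-op and identical views agree with either alone", {
  co <- strong_cohort(seed = 9, n = 40, n_feat = 200)
  w <- snf_affinity(standardize_features(co$expression), n_neighbors = 10)
  f1 <- snf_fuse(list(w), n_neighbors = 10)
  p0 <- copdclust:::snf_status(unclass(w))
  expect_equal(unclass(f1), (p0 + t(p0)) / 2, tolerance = 1e-12,
               ignore_attr = TRUE)

  f2 <- snf_fuse(list(w, w), n_neighbors = 10, iterations = 5)
  part_single <- spectral_cluster(w, k = 2, seed = 1)
  part_fused <- spectral_cluster(f2, k = 2, seed = 1)
  expect_equal(nmi(part_single, part_fused), 1)
  expect_true(all(unclass(f2) > 0))
  expect_equal(unclass(f2), t(unclass(f2)), tolerance = 1e-12)
})

test_that("fusing two noisy views recovers planted structure that one noisier view misses", {
  set.seed(31)
  n <- 80
  planted <- rep(1:2, each = n / 2)
  ids <- sprintf("s%02d", 1:n)
  make_view <- function(noise, seed) {
    set.seed(seed)
    x <- matrix(rnorm(150 * n, sd = noise), 150, n) +
      outer(rep(c(1, 0), each = 75), as.numeric(planted == 2))
    dimnames(x) <- list(sprintf("f%03d", 1:150), ids)
    x
  }
  truth <- partition(planted, ids)
  v1 <- make_view(noise = 2.0, seed = 1)
  v2 <- make_view(noise = 2.0, seed = 2)
  aff <- lapply(list(v1, v2), function(v) {
    snf_affinity(standardize_features(v), n_neighbors = 15)
  })
  fused <- snf_fuse(aff, n_neighbors = 15)
  expect_gte(nmi(spectral_cluster(fused, 2, seed = 3), truth), 0.9)

  lone <- make_view(noise = 3.0, seed = 4)
  wl <- snf_affinity(standardize_features(lone), n_neighbors = 15)
  expect_lt(nmi(spectral_cluster(wl, 2, seed = 3), truth), 0.9)
})

test_that("fusion commutes with a simultaneous permutation of samples", {
  co <- strong_cohort(seed = 15, n = 30, n_feat = 100)
  aff <- lapply(list(co$expression, co$methylation), function(v) {
    snf_affinity(standardize_features(v), n_neighbors = 8)
  })
  fused <- snf_fuse(aff, n_neighbors = 8, iterations = 5)
  set.seed(2); perm <- sample(30)
  aff_p <- lapply(list(co$expression[, perm], co$methylation[, perm]),
                  function(v) snf_affinity(standardize_features(v),
                                           n_neighbors = 8))
  fused_p <- snf_fuse(aff_p, n_neighbors = 8, iterations = 5)
  expect_equal(unclass(fused_p), unclass(fused)[perm, perm],
               tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("spectral clustering separates clean blocks and degenerates sensibly", {
  ids <- sprintf("s%02d", 1:12)
  w <- matrix(0.01, 12, 12, dimnames = list(ids, ids))
  w[1:5, 1:5] <- 0.9; w[6:12, 6:12] <- 0.9
  diag(w) <- 1
  p <- spectral_cluster(w, k = 2, seed = 1)
  expect_equal(nmi(p, partition(rep(c(1, 2), c(5, 7)), ids)), 1)
  expect_identical(cluster_sizes(p), c(7L, 5L))   # largest cluster first

  pn <- spectral_cluster(w, k = 12, seed = 1)
  expect_identical(sort(unique(pn$labels)), 1:12)
  expect_error(spectral_cluster(w, k = 13), "exceed")
})

test_that("spectral memberships are reproducible across repeated seeded runs", {
  co <- strong_cohort(seed = 19, n = 50, n_feat = 200)
  fit <- snf_fit(co$expression, co$methylation, n_neighbors = 15, seed = 4,
                 n_stability_repeats = 10)
  expect_true(fit$stability$all_identical)
  expect_equal(fit$stability$pairwise_nmi_min, 1)
  expect_gte(nmi(fit$partition, co$planted_partition), 0.9)
})

test_that("hyperparameter selection maximizes off-diagonal affinity variance", {
  co <- strong_cohort(seed = 23, n = 60, n_feat = 150)
  single <- select_snf_hyperparameters(co$expression, co$methylation,
                                       data.frame(n_neighbors = 10, alpha = 0.5))
  expect_equal(single$n_neighbors, 10)

  grid <- data.frame(n_neighbors = c(30, 30, 55), alpha = c(0.8, 200, 500))
  best <- select_snf_hyperparameters(co$expression, co$methylation, grid)
  expect_equal(c(best$n_neighbors, best$alpha), c(30, 0.8))

  # objective invariant to sample permutation
  set.seed(3); perm <- sample(60)
  best_p <- select_snf_hyperparameters(co$expression[, perm],
                                       co$methylation[, perm], grid)
  expect_equal(best_p$score, best$score, tolerance = 1e-9)

  infeasible <- data.frame(n_neighbors = c(60, 100), alpha = c(0.8, 0.8))
  expect_error(select_snf_hyperparameters(co$expression, co$methylation,
                                          infeasible), "feasible")
})
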