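# shared fixture: a small cohort with a 2-cluster contrast and covariates
make_de_fixture <- function(seed = 3, n = 40, nf = 120, hetero = TRUE) {
  set.seed(seed)
  ids <- sprintf("s%02d", seq_len(n))
  cl <- rep(1:2, each = n / 2)
  clin <- data.frame(sample_id = ids,
                     age = rnorm(n, 62, 8),
                     sex = sample(c("male", "female"), n, TRUE),
                     pack_years = rnorm(n, 45, 20))
  sdev <- if (hetero) sqrt(1 / rgamma(nf, shape = 3, rate = 3)) else rep(1, nf)
  y <- matrix(rnorm(nf * n), nf, n) * sdev
  # planted shift scales with each feature's own SD so all 10 are clear hits
  y[1:10, cl == 2] <- y[1:10, cl == 2] + 2 * sdev[1:10]
  dimnames(y) <- list(sprintf("f%03d", seq_len(nf)), ids)
  list(matrix = omics_matrix(y, "expression"), clinical = clin,
       partition = partition(cl, ids), y = y, cl = cl)
}

test_that("per-feature OLS recovers exact coefficients in the noise-free case", {
  n <- 20
  ids <- sprintf("s%02d", 1:n)
  cl <- rep(1:2, each = n / 2)
  y <- matrix(rnorm(n), 1, n, dimnames = list("flat", ids))
  y <- rbind(y, pure = 2 * (cl == 2))
  rownames(y) <- c("flat", "pure")
  fits <- fit_feature_models(omics_matrix(y, "expression"),
                             data.frame(sample_id = ids),
                             partition(cl, ids))
  expect_equal(unname(fits$coefficients["pure"]), 2, tolerance = 1e-10)
  expect_equal(unname(fits$sigma2["pure"]), 0, tolerance = 1e-10)
})

test_that("rank-deficient designs are rejected", {
  fx <- make_de_fixture()
  fx$clinical$copy <- as.integer(fx$cl == 2)  # perfectly collinear with contrast
  expect_error(fit_feature_models(fx$matrix, fx$clinical, fx$partition,
                                  covariates = "copy"), "rank deficient")
  fx$clinical$gone <- NA_real_
  expect_error(fit_feature_models(fx$matrix, fx$clinical, fx$partition,
                                  covariates = "gone"), "entirely missing")
})

test_that("OLS fits match an explicit normal-equations oracle", {
  fx <- make_de_fixture(seed = 8)
  fits <- fit_feature_models(fx$matrix, fx$clinical, fx$partition,
                             covariates = c("age", "sex", "pack_years"))
  X <- model.matrix(~ factor(fx$cl) + age + factor(sex) + pack_years,
                    data = fx$clinical)
  xtx_inv <- solve(t(X) %*% X)
  ccol <- 2
  for (f in c(1, 7, 60, 120)) {
    beta <- xtx_inv %*% t(X) %*% fx$y[f, ]
    res <- fx$y[f, ] - X %*% beta
    s2 <- sum(res^2) / (nrow(X) - ncol(X))
    expect_equal(unname(fits$coefficients[f]), beta[ccol], tolerance = 1e-9)
    expect_equal(unname(fits$sigma2[f]), s2, tolerance = 1e-9)
    expect_equal(fits$stdev_unscaled[f], sqrt(xtx_inv[ccol, ccol]),
                 tolerance = 1e-9)
  }
})

test_that("empirical-Bayes moderation matches the reference implementation", {
  fx <- make_de_fixture(seed = 12, hetero = TRUE)
  fits <- fit_feature_models(fx$matrix, fx$clinical, fx$partition,
                             covariates = "age")
  mod <- moderate(fits)
  design <- model.matrix(~ factor(fx$cl) + age, data = fx$clinical)
  ref <- limma::eBayes(limma::lmFit(fx$y, design))
  expect_equal(attr(mod, "df_prior"), ref$df.prior, tolerance = 1e-6)
  expect_equal(attr(mod, "s2_prior"), ref$s2.prior, tolerance = 1e-6)
  expect_equal(mod$t_stat, unname(ref$t[, 2]), tolerance = 1e-8)
  expect_equal(mod$p_value, unname(ref$p.value[, 2]), tolerance = 1e-8)

  # homoskedastic features: underdispersed log-variances, near-infinite prior
  fx2 <- make_de_fixture(seed = 13, hetero = FALSE)
  fits2 <- fit_feature_models(fx2$matrix, fx2$clinical, fx2$partition)
  mod2 <- moderate(fits2)
  design2 <- model.matrix(~ factor(fx2$cl))
  ref2 <- limma::eBayes(limma::lmFit(fx2$y, design2))
  expect_gt(attr(mod2, "df_prior"), 1e3)
  expect_equal(mod2$t_stat, unname(ref2$t[, 2]), tolerance = 1e-3)
})

test_that("zero prior df reproduces the ordinary t-test; shrinkage is bounded", {
  fx <- make_de_fixture(seed = 5)
  fits <- fit_feature_models(fx$matrix, fx$clinical, fx$partition)
  raw <- moderate(fits, prior_df = 0)
  t_classic <- fits$coefficients / (sqrt(fits$sigma2) * fits$stdev_unscaled)
  expect_equal(raw$t_stat, unname(t_classic), tolerance = 1e-12)
  expect_equal(raw$p_value,
               unname(2 * pt(-abs(t_classic), df = fits$df_residual)),
               tolerance = 1e-12)

  mod <- moderate(fits)
  d0 <- attr(mod, "df_prior"); s20 <- attr(mod, "s2_prior")
  s2_post <- (d0 * s20 + fits$df_residual * fits$sigma2) /
    (d0 + fits$df_residual)
  lo <- pmin(fits$sigma2, s20); hi <- pmax(fits$sigma2, s20)
  expect_true(all(s2_post >= lo - 1e-12 & s2_post <= hi + 1e-12))
})

test_that("planted signal is recovered and FDR thresholds nest", {
  fx <- make_de_fixture(seed = 21, n = 40, nf = 300)
  mod <- moderated_diffexp(fx$matrix, fx$clinical, fx$partition,
                           covariates = c("age", "sex", "pack_years"))
  hits5 <- mod$feature_id[mod$fdr < 0.05]
  hits10 <- mod$feature_id[mod$fdr < 0.10]
  expect_true(all(sprintf("f%03d", 1:10) %in% hits5))
  expect_true(all(hits5 %in% hits10))
  expect_identical(mod$abs_lfc_gt1, abs(mod$effect) > 1)
})

test_that("BH adjustment matches hand-computed step-up values", {
  # step-up by hand: p_(i) * m / i with running minima from the top
  hand_bh <- function(p) {
    m <- length(p)
    o <- order(p)
    adj <- p[o] * m / seq_len(m)
    adj <- rev(cummin(rev(adj)))
    pmin(adj, 1)[order(o)]
  }
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_equal(bh_adjust(0.2), 0.2)
  set.seed(2)
  p <- runif(50)
  expect_equal(bh_adjust(p), hand_bh(p))
  # idempotent on already-adjusted monotone sequences
  expect_equal(bh_adjust(bh_adjust(p))[order(p)][50],
               bh_adjust(p)[order(p)][50])
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0,1\\]")
})

test_that("hypergeometric ORA matches exhaustive subset enumeration on a small universe", {
  uni <- sprintf("g%02d", 1:12)
  sig <- uni[1:4]
  sets <- list(exact = uni[1:4], half = uni[3:8], none = uni[9:12],
               all = uni)
  res <- ora(sig, uni, sets)
  res <- res[match(names(sets), res$set_name), ]
  # brute force: enumerate all 4-subsets of the universe
  combos <- combn(12, 4)
  brute <- function(set_idx, min_ov) {
    mean(apply(combos, 2, function(s) sum(s %in% set_idx) >= min_ov))
  }
  expect_equal(res$p_value[res$set_name == "exact"], brute(1:4, 4))
  expect_equal(res$p_value[res$set_name == "exact"], 1 / choose(12, 4))
  ov_half <- res$overlap[res$set_name == "half"]
  expect_equal(res$p_value[res$set_name == "half"], brute(3:8, ov_half))
  expect_equal(res$p_value[res$set_name == "none"], 1)  # zero overlap
  expect_equal(res$p_value[res$set_name == "all"], 1)   # set = universe
  expect_true(all(res$overlap <= pmin(res$set_size, res$list_size)))

  # id mapping: features translate to genes before testing
  map <- data.frame(feature_id = c("f1", "f2", "f3"), gene = c("g01", "g01", "g02"))
  r2 <- ora(c("f1", "f2"), c("f1", "f2", "f3"), list(s = "g01"), id_map = map)
  expect_identical(r2$overlap, 1L)
  expect_identical(r2$universe_size, 2L)

  expect_error(ora(character(0), uni, sets), "empty significant")
  expect_error(ora(c("zzz"), uni, sets), "subset")
})
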