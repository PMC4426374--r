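# Imputation-uncertainty diagnostics: standardization, consistency
# regressions, AMI, the arcsin(gamma) factor model, pairwise r2, and
# significance differentials.

test_that("trait-wise standardization produces z-scores per trait", {
  z <- standardize_by_trait(c(1, 2, 3))
  expect_equal(z, c(-1, 0, 1))
  eff <- c(1, 2, 3, 10, 30, 50)
  tr <- rep(c("a", "b"), each = 3)
  z2 <- standardize_by_trait(eff, tr)
  for (t0 in c("a", "b")) {
    expect_equal(mean(z2[tr == t0]), 0)
    expect_equal(stats::sd(z2[tr == t0]), 1)
  }
  expect_error(standardize_by_trait(c(1, 1, 1)), "zero effect SD")
  expect_error(standardize_by_trait(c(1)), "fewer than 2")
})

test_that("an exact identity gives slope 1, intercept 0, R2 1", {
  x <- rnorm(50)
  fit <- consistency_regression(x, x, model_tag = "cc_on_ad")
  expect_equal(fit$coefficients$estimate[2], 1, tolerance = 1e-10)
  expect_equal(fit$coefficients$estimate[1], 0, tolerance = 1e-10)
  expect_equal(fit$r2, 1)
})

test_that("gamma-dependent noise inflates the high-gamma stratum's residual variance", {
  set.seed(41)
  n <- 2000
  beta_ad <- rnorm(n)
  gamma <- runif(n)
  beta_cc <- beta_ad + rnorm(n, sd = 0.05 + 0.8 * (gamma > 0.2))
  fit <- consistency_regression(beta_cc, beta_ad, gamma, "cc_on_ad")
  expect_equal(fit$coefficients$estimate[2], 1, tolerance = 0.05)
  lo <- fit$strata[fit$strata$stratum == "gamma<0.2", ]
  hi <- fit$strata[fit$strata$stratum == "gamma>0.2", ]
  expect_gt(hi$sigma2_e, lo$sigma2_e)
  expect_gt(lo$r2, hi$r2)
})

test_that("the AD-on-MI interaction model recovers generative coefficients", {
  set.seed(43)
  n <- 3000
  beta_mi <- rnorm(n)
  gamma <- runif(n, 0, 0.8)
  beta_ad <- (1 + 5 * gamma) * beta_mi + rnorm(n, sd = 0.2)
  fit <- consistency_regression(beta_ad, beta_mi, gamma, "ad_on_mi")
  co <- fit$coefficients
  b1 <- co[co$term == "b1", ]
  b3 <- co[co$term == "b3", ]
  expect_lt(abs(b1$estimate - 1), 2 * b1$se)
  expect_lt(abs(b3$estimate - 5), 2 * b3$se)
  expect_gt(b3$estimate, 0)
  expect_error(consistency_regression(beta_ad, beta_mi, NULL, "ad_on_mi"),
               "requires gamma")
})

test_that("AMI equals the mean of the pairwise MI values", {
  pan <- random_panel(n = 60, q = 5, pmv = 0.2, seed = 45)
  X <- pan$observed
  by_hand <- mean(sapply(2:5, function(j) {
    suppressWarnings(mutual_information(X[, 1], X[, j]))
  }))
  expect_equal(average_mutual_information(X, 1), by_hand)
  # an independent marker in a large panel has AMI near 0
  set.seed(46)
  Xi <- matrix(sample(c(-1, 0, 1), 4000 * 6, replace = TRUE), 4000, 6)
  expect_lt(average_mutual_information(Xi, 1), 0.01)
  # perfect duplicates of a balanced binary marker give AMI near 1 bit
  b <- rep(c(-1, 1), 50)
  Xd <- cbind(b, b, b)
  expect_equal(average_mutual_information(Xd, 1), 1)
})

test_that("the arcsin(gamma) factor model recovers generative signs and effects", {
  set.seed(47)
  n <- 1500
  pmv <- runif(n, 0, 0.9)
  maf <- runif(n, 0.05, 0.5)
  ami <- runif(n, 0, 0.3)
  y <- 0.09 + 0.48 * pmv + 0.01 * maf - 0.18 * ami + rnorm(n, sd = 0.08)
  gamma <- sin(pmin(pmax(y, 0), pi / 2))
  fit <- gamma_factor_model(gamma, pmv, maf, ami, seed = 48)
  co <- fit$coefficients
  b1 <- co[co$term == "b1_pmv", ]
  b3 <- co[co$term == "b3_ami", ]
  expect_lt(abs(b1$estimate - 0.48), 4 * b1$se)
  expect_gt(b1$estimate, 0)
  expect_lt(b3$estimate, 0)
  # folds partition the indices exactly once each
  expect_equal(sort(unique(fit$fold)), 1:10)
  expect_equal(length(fit$fold), n)
  expect_gt(fit$cv_r2, 0.5)
  expect_lt(fit$cv_mse, fit$cv_mse_null)
  expect_error(gamma_factor_model(rep(0.3, 20), runif(20), runif(20),
                                  runif(20)), "constant")
  expect_error(gamma_factor_model(c(-0.1, 0.5), c(0, 0.5), c(0.1, 0.2),
                                  c(0, 0)), "\\[0, 1\\]")
})

test_that("pairwise r2 matches direct correlation and flags degeneracy", {
  set.seed(49)
  Xbar <- matrix(runif(40 * 4, -1, 1), 40, 4,
                 dimnames = list(NULL, paste0("M", 1:4)))
  Xbar[, 4] <- Xbar[, 1]
  out <- pairwise_r2(Xbar)
  expect_equal(out$r2[1, 4], 1)
  brute <- stats::cor(Xbar[, 2], Xbar[, 3])^2
  expect_equal(out$r2[2, 3], brute)
  ct <- stats::cor.test(Xbar[, 2], Xbar[, 3])
  expect_equal(out$p[2, 3], ct$p.value)
  # orthogonal pair
  Xo <- cbind(a = rep(c(-1, 1), 10), b = rep(c(-1, -1, 1, 1), 5))
  expect_equal(pairwise_r2(Xo)$r2[1, 2], 0, tolerance = 1e-12)
})

test_that("significance differentials are arithmetic in -log10(p)", {
  expect_equal(delta_significance(0.01, 0.01)$delta, 0)
  expect_equal(delta_significance(1e-3, 1e-5)$delta, 2)
  # p = 0 is clipped, not infinite
  expect_true(is.finite(delta_significance(1e-3, 0)$delta))
  out <- delta_significance(c(1e-3, 1e-2), c(1e-5, 1e-1), c(0.1, 0.5))
  expect_equal(sort(out$summary$stratum), c("gamma<0.2", "gamma>=0.2"))
  expect_equal(out$summary$median[out$summary$stratum == "gamma<0.2"], 2)
})
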