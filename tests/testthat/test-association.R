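# Mixed-model association: REML null fit, P3D marker tests, the four
# schemes, and their degenerate limits.

test_that("with sigma2_u = 0 the marker test is exactly OLS", {
  x <- c(-1, -1, 0, 0, 1, 1)
  g <- 2 * x + c(0.1, -0.1, 0.1, -0.1, 0.1, -0.1)
  vc <- fit_null(g, Q = NULL, K = NULL)
  res <- marker_test_gls(g, x, Q = NULL, vc = vc)
  sm <- summary(stats::lm(g ~ x))
  expect_equal(res$beta, sm$coefficients["x", 1])
  expect_equal(res$var_beta, sm$coefficients["x", 2]^2)
  expect_equal(res$p, sm$coefficients["x", 4])
  expect_equal(res$df, sm$df[2])
})

test_that("a constant marker is flagged untestable", {
  g <- rnorm(20)
  vc <- fit_null(g)
  res <- marker_test_gls(g, rep(1, 20), vc = vc)
  expect_true(res$untestable)
  expect_true(is.na(res$p))
})

test_that("REML recovers simulated variance components", {
  pan <- random_panel(n = 500, q = 400, pmv = 0, seed = 61)
  K <- kinship(pan$complete)
  R <- chol(K + diag(1e-8, 500))
  set.seed(62)
  est <- replicate(20, {
    g <- as.vector(crossprod(R, rnorm(500)) * sqrt(2)) + rnorm(500)
    vc <- fit_null(g, K = K)
    c(vc$sigma2_u, vc$sigma2_e)
  })
  expect_lt(abs(stats::median(est[1, ]) - 2) / 2, 0.3)
  expect_lt(abs(stats::median(est[2, ]) - 1), 0.3)
})

test_that("a heritability-free trait drives sigma2_u to the boundary", {
  pan <- random_panel(n = 300, q = 300, pmv = 0, seed = 63)
  K <- kinship(pan$complete)
  set.seed(64)
  h2 <- replicate(20, {
    g <- rnorm(300)
    vc <- suppressWarnings(fit_null(g, K = K))
    vc$sigma2_u / (vc$sigma2_u + vc$sigma2_e)
  })
  expect_gte(mean(h2 <= 0.1), 0.9)
  expect_error(fit_null(rep(1, 50), K = K[1:50, 1:50]), "constant")
})

test_that("the cached spectral path equals a direct dense-GLS refit", {
  cfg <- sim_config(n_individuals = 80, n_markers = 40, n_subpops = 2,
                    fst = 0.1, ld_block_size = 2, block_r = 0.8,
                    n_causal = 2, effect_sizes = 1, seed = 65)
  pan <- simulate_panel(cfg)
  X <- pan$complete
  K <- kinship(X)
  Q <- pca_scores(X, 1)$Q
  g <- pan$traits[, 1]
  vc <- fit_null(g, Q, K)
  res <- gls_scan_dense_oracle(g, X, Q, vc$ratio, K)
  fast <- run_scheme("ad", g, Xbar = X, Q = Q, K = K, vc = vc)
  expect_equal(fast$beta, res$beta, tolerance = 1e-10)
  expect_equal(fast$p, res$p, tolerance = 1e-10)
})

test_that("null p-values are uniform when structure is modeled", {
  cfg <- sim_config(n_individuals = 250, n_markers = 1000, n_subpops = 2,
                    fst = 0.1, ld_block_size = 1, n_causal = 0,
                    var_u = 1, var_e = 1, seed = 67)
  sim <- simulate_genotypes(cfg)
  g <- simulate_phenotype(sim$truth, cfg)
  K <- kinship(sim$genotypes)
  Q <- pca_scores(sim$genotypes, 1)$Q
  vc <- fit_null(g, Q, K)
  res <- run_scheme("ad", g, Xbar = sim$genotypes, Q = Q, K = K, vc = vc)
  expect_gt(stats::ks.test(res$p[!res$untestable], "punif")$p.value, 0.01)
})

test_that("complete markers give identical CC and AD results", {
  cfg <- sim_config(n_individuals = 100, n_markers = 30, n_subpops = 2,
                    fst = 0.1, ld_block_size = 1, n_causal = 2,
                    effect_sizes = 1, seed = 68)
  pan <- simulate_panel(cfg)
  X <- pan$complete
  K <- kinship(X)
  Q <- pca_scores(X, 1)$Q
  g <- pan$traits[, 1]
  cc <- run_scheme("cc", g, X = X, Q = Q, K = K)
  ad <- run_scheme("ad", g, Xbar = X, Q = Q, K = K)
  expect_equal(cc$beta, ad$beta, tolerance = 1e-8)
  expect_equal(cc$p, ad$p, tolerance = 1e-6)
  expect_true(all(cc$n_used == 100))
})

test_that("CC uses exactly the observed rows of each marker", {
  pan <- random_panel(n = 80, q = 10, pmv = 0.4, seed = 69)
  g <- rnorm(80)
  cc <- run_scheme("cc", g, X = pan$observed)
  expect_equal(cc$n_used, unname(colSums(!is.na(pan$observed))))
})

test_that("without Q and K the model is single-marker regression", {
  pan <- random_panel(n = 60, q = 8, pmv = 0, seed = 70)
  g <- rnorm(60) + pan$complete[, 1]
  ad <- run_scheme("ad", g, Xbar = pan$complete)
  for (j in c(1, 5)) {
    sm <- summary(stats::lm(g ~ pan$complete[, j]))
    expect_equal(ad$beta[j], sm$coefficients[2, 1])
    expect_equal(ad$p[j], sm$coefficients[2, 4])
  }
})

test_that("identical imputes make every MI result equal the AD result", {
  pan <- random_panel(n = 50, q = 12, pmv = 0, seed = 71)
  g <- rnorm(50) + 0.5 * pan$complete[, 2]
  S <- fcs_impute(pan$complete, m = 3, L = 1, qsel = 5, seed = 72)
  K <- kinship(pan$complete)
  Q <- pca_scores(pan$complete, 1)$Q
  mi <- run_scheme("mi", g, S = S, Q = Q, K = K)
  ad <- run_scheme("ad", g, Xbar = pan$complete, Q = Q, K = K)
  for (r in 1:3) {
    expect_equal(mi$beta[mi$impute == r], ad$beta, tolerance = 1e-12)
  }
})

test_that("scheme inputs are validated", {
  g <- rnorm(20)
  expect_error(run_scheme("cc", g), "requires")
  expect_error(run_scheme("mi", g), "requires")
})
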