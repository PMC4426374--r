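# Mutual information, predictor selection, CART donor pools, and the
# chained-equation sampler.

test_that("mutual information matches hand-computed values", {
  # perfect dependence over two classes: 1 bit
  expect_equal(mutual_information(rep(c(-1, 1), each = 5),
                                  rep(c(-1, 1), each = 5)), 1)
  # independence: 0 bits
  expect_equal(mutual_information(rep(c(-1, -1, 1, 1), 2),
                                  rep(c(-1, 1), 4)), 0)
  # joint counts [[3,1],[1,3]]: 0.75*log2(1.5) + 0.25*log2(0.5)
  x <- c(-1, -1, -1, 1, -1, 1, 1, 1)
  y <- c(-1, -1, -1, -1, 1, 1, 1, 1)
  expect_equal(mutual_information(x, y), 0.1887219, tolerance = 1e-6)
  expect_equal(mutual_information(x, y), mutual_information(y, x))
  expect_warning(mutual_information(c(1, NA), c(NA, 1)), "no overlapping")
})

test_that("the vectorized MI matrix agrees with the pairwise scalar", {
  pan <- random_panel(n = 50, q = 8, pmv = 0.3, seed = 4)
  mi <- mi_matrix(pan$observed)
  for (j in 2:8) {
    expect_equal(mi[1, j],
                 suppressWarnings(mutual_information(pan$observed[, 1],
                                                     pan$observed[, j])),
                 tolerance = 1e-12)
  }
  expect_true(all(mi[upper.tri(mi)] >= 0, na.rm = TRUE))
  expect_equal(mi, t(mi), ignore_attr = TRUE)
})

test_that("predictor selection ranks by MI with brute-force agreement", {
  pan <- random_panel(n = 60, q = 6, pmv = 0.2, seed = 6)
  X <- pan$observed
  sel <- select_predictors(X, 3, qsel = 5)
  brute <- sapply(seq_len(6), function(j) {
    if (j == 3) NA else suppressWarnings(mutual_information(X[, 3], X[, j]))
  })
  cand <- setdiff(1:6, 3)
  expect_equal(sel$indices, cand[order(-brute[cand], cand)])
  # fewer markers than qsel: all others returned
  expect_length(select_predictors(X, 1, qsel = 500)$indices, 5)
  # a duplicate of the target ranks first
  Xd <- cbind(X, dup = X[, 3])
  expect_equal(select_predictors(Xd, 3, qsel = 3)$indices[1], 7)
})

test_that("CART splits match an exhaustive Gini-gain search", {
  set.seed(15)
  n <- 30
  X <- matrix(sample(c(-1, 0, 1), n * 4, replace = TRUE), n, 4,
              dimnames = list(NULL, paste0("P", 1:4)))
  y <- ifelse(X[, 2] >= 0.5, 1, -1)
  y[sample(n, 4)] <- 0                       # noise so leaves are impure
  tree <- cart_fit(y, X, min_leaf = 5)
  oracle <- gini_best_split(factor(y), X, min_leaf = 5)
  frame <- tree$fit$frame
  root_var <- as.character(frame$var[1])
  expect_equal(root_var, paste0("P", oracle$var))
  split_cut <- tree$fit$splits[1, "index"]
  expect_equal(split_cut, oracle$cut, tolerance = 1e-8)
})

test_that("a perfect binary predictor yields pure leaves", {
  x <- rep(c(-1, 1), each = 20)
  y <- x
  tree <- cart_fit(y, matrix(x, ncol = 1, dimnames = list(NULL, "x")),
                   min_leaf = 5)
  draws <- cart_sample(tree, matrix(c(-1, 1), ncol = 1,
                                    dimnames = list(NULL, "x")))
  expect_equal(draws, c(-1, 1))
})

test_that("constant targets give single-leaf marginal trees", {
  tree <- cart_fit(rep(1, 12), matrix(rnorm(12), ncol = 1), min_leaf = 5)
  expect_equal(tree$type, "marginal")
  expect_true(all(cart_sample(tree, n = 50) == 1))
})

test_that("donor draws reproduce the leaf composition", {
  # marginal pool {-1,-1,0,1,1}: draw frequencies (0.4, 0.2, 0.4)
  tree <- cart_fit(c(-1, -1, 0, 1, 1), NULL, min_leaf = 5)
  set.seed(99)
  draws <- cart_sample(tree, n = 1e4)
  tab <- table(factor(draws, c(-1, 0, 1)))
  expect_gt(stats::chisq.test(tab, p = c(0.4, 0.2, 0.4))$p.value, 0.01)
})

test_that("imputing complete data returns the data unchanged", {
  pan <- random_panel(n = 40, q = 15, pmv = 0, seed = 8)
  S <- fcs_impute(pan$complete, m = 3, L = 2, qsel = 10, seed = 2)
  for (r in 1:3) expect_identical(S$imputes[[r]], pan$complete)
  expect_identical(average_dosage(S), pan$complete)
})

test_that("observed cells are preserved and imputed cells stay in the dosage domain", {
  pan <- random_panel(n = 60, q = 20, pmv = 0.4, seed = 10)
  S <- fcs_impute(pan$observed, m = 3, L = 3, qsel = 10, seed = 3)
  obs <- !is.na(pan$observed)
  for (r in 1:3) {
    Xr <- S$imputes[[r]]
    expect_false(anyNA(Xr))
    expect_true(all(Xr %in% c(-1, 0, 1)))
    expect_true(all(Xr[obs] == pan$observed[obs]))
  }
  Xbar <- average_dosage(S)
  expect_true(all(Xbar[obs] == pan$observed[obs]))
  expect_true(all(Xbar >= -1 & Xbar <= 1))
  # determinism under the seed
  S2 <- fcs_impute(pan$observed, m = 3, L = 3, qsel = 10, seed = 3)
  expect_identical(S$imputes, S2$imputes)
})

test_that("a perfectly duplicated complete predictor restores masked calls", {
  set.seed(20)
  n <- 200
  base <- sample(c(-1, 0, 1), n, replace = TRUE, prob = c(0.3, 0.4, 0.3))
  X <- dosage_mat(target = base, twin = base,
                  noise1 = sample(c(-1, 0, 1), n, replace = TRUE),
                  noise2 = sample(c(-1, 0, 1), n, replace = TRUE))
  mask <- sample(n, round(0.3 * n))
  X[mask, "target"] <- NA
  S <- fcs_impute(X, m = 3, L = 3, qsel = 3, seed = 6)
  acc <- sapply(S$imputes, function(Xr) mean(Xr[mask, "target"] == base[mask]))
  expect_true(all(acc >= 0.9))
})

test_that("recovery accuracy increases with within-block LD strength", {
  accs <- sapply(c(0, 0.5, 0.9, 1.0), function(r) {
    cfg <- sim_config(n_individuals = 150, n_markers = 30, n_subpops = 1,
                      fst = 0, ld_block_size = 3, block_r = r,
                      pmv_dist = pmv_dist_point(0.4), seed = 33)
    pan <- simulate_panel(cfg)
    S <- fcs_impute(pan$observed, m = 2, L = 4, qsel = 10, seed = 34)
    mask <- is.na(pan$observed)
    mean(sapply(S$imputes, function(Xr) mean(Xr[mask] == pan$complete[mask])))
  })
  expect_true(all(diff(accs) > -0.02))   # monotone up to MC noise
  expect_gt(accs[4], accs[1] + 0.2)
})

test_that("without LD, imputation reduces to calibrated marginal draws", {
  pan <- random_panel(n = 300, q = 20, pmv = 0.5, seed = 44)
  S <- fcs_impute(pan$observed, m = 4, L = 3, qsel = 10, seed = 45)
  mask <- is.na(pan$observed)
  obs_freq <- colMeans(pan$observed, na.rm = TRUE)
  imp_freq <- sapply(seq_len(20), function(j) {
    mean(sapply(S$imputes, function(Xr) mean(Xr[mask[, j], j])))
  })
  expect_equal(unname(imp_freq), unname(obs_freq), tolerance = 0.12)
  expect_lt(mean(abs(imp_freq - obs_freq)), 0.06)
})

test_that("chains are insensitive to doubling the burn-in", {
  pan <- random_panel(n = 100, q = 16, pmv = 0.4, seed = 55)
  S10 <- fcs_impute(pan$observed, m = 3, L = 10, qsel = 8, seed = 56)
  S20 <- fcs_impute(pan$observed, m = 3, L = 20, qsel = 8, seed = 57)
  mask <- is.na(pan$observed)
  m10 <- mean(average_dosage(S10)[mask])
  m20 <- mean(average_dosage(S20)[mask])
  expect_lt(abs(m10 - m20), 0.05)
})

test_that("markers without observed calls are rejected", {
  X <- dosage_mat(a = c(1, -1, 0, 1), b = rep(NA_real_, 4))
  expect_error(fcs_impute(X, m = 2, L = 1), "zero observed")
})
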