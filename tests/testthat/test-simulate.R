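# Synthetic GBS panel generator: missingness calibration, LD structure,
# population structure, and trait construction.

test_that("PMV distributions validate and report their means", {
  expect_equal(pmv_mean(pmv_dist_default()), 0.78)
  expect_equal(pmv_mean(pmv_dist_point(0.5)), 0.5)
  expect_equal(pmv_mean(pmv_dist_beta(2, 2, scale = 0.8)), 0.4)
  expect_error(pmv_dist_point(1), "\\[0, 1\\)")
  expect_error(pmv_dist_point(-0.1), "\\[0, 1\\)")
  expect_error(pmv_dist_beta(-1, 2), "positive")
})

test_that("masking with a zero point mass is the identity", {
  pan <- random_panel(n = 30, q = 15, pmv = 0, seed = 2)
  masked <- apply_mcar_mask(pan$complete, pmv_dist_point(0), seed = 9)
  expect_identical(masked, pan$complete)
})

test_that("masking never alters unmasked cells and hits the target count", {
  cfg <- sim_config(n_individuals = 200, n_markers = 1000, n_subpops = 1,
                    fst = 0, ld_block_size = 1, seed = 11)
  G <- simulate_genotypes(cfg)$genotypes
  M <- apply_mcar_mask(G, pmv_dist_point(0.5), seed = 12)
  obs <- !is.na(M)
  expect_true(all(M[obs] == G[obs]))
  # point mass at 0.5: exactly 100 missing cells per marker
  expect_true(all(colSums(is.na(M)) == 100))
  # masked positions are uniform over individuals (chi-square GOF)
  counts <- rowSums(is.na(M))
  expect_gt(stats::chisq.test(counts, p = rep(1 / 200, 200))$p.value, 0.01)
})

test_that("realized mean PMV matches the distribution mean on wide panels", {
  cfg <- sim_config(n_individuals = 100, n_markers = 2000, n_subpops = 1,
                    fst = 0, ld_block_size = 1, seed = 21)
  G <- simulate_genotypes(cfg)$genotypes
  M <- apply_mcar_mask(G, pmv_dist_default(), seed = 22)
  expect_equal(mean(colMeans(is.na(M))), 0.78, tolerance = 0.02)
})

test_that("perfect-LD blocks give pairwise dosage correlation 1", {
  cfg <- sim_config(n_individuals = 80, n_markers = 12, n_subpops = 1,
                    fst = 0, ld_block_size = 4, block_r = 1, seed = 5)
  G <- simulate_genotypes(cfg)$genotypes
  for (b in 0:2) {
    block <- G[, (4 * b + 1):(4 * b + 4)]
    expect_true(all(abs(stats::cor(block)) > 1 - 1e-12))
  }
})

test_that("within-block correlation dominates between-block correlation", {
  cfg <- sim_config(n_individuals = 500, n_markers = 2000, n_subpops = 3,
                    fst = 0.1, ld_block_size = 5, block_r = 0.9, seed = 7)
  sim <- simulate_genotypes(cfg)
  r2 <- stats::cor(sim$genotypes)^2
  same <- outer(sim$truth$block_id, sim$truth$block_id, `==`)
  diag(same) <- NA
  within <- mean(r2[same & upper.tri(r2)], na.rm = TRUE)
  between <- mean(r2[!same & upper.tri(r2)], na.rm = TRUE)
  expect_gt(within, 0.5)
  expect_gt(within, 10 * between)
})

test_that("structured panels separate subpopulations on leading PCs", {
  cfg <- sim_config(n_individuals = 300, n_markers = 600, n_subpops = 3,
                    fst = 0.15, ld_block_size = 1, seed = 13)
  sim <- simulate_genotypes(cfg)
  pc <- pca_scores(sim$genotypes, 2)
  grp <- factor(sim$truth$subpop_labels)
  for (j in 1:2) {
    fit <- stats::aov(pc$Q[, j] ~ grp)
    expect_lt(summary(fit)[[1]][["Pr(>F)"]][1], 0.01)
  }
})

test_that("noiseless trait equals intercept plus causal dosage", {
  cfg <- sim_config(n_individuals = 50, n_markers = 20, n_subpops = 1,
                    fst = 0, ld_block_size = 1, n_causal = 1,
                    effect_sizes = 1, mu = 3, var_u = 0, var_e = 0, seed = 31)
  sim <- simulate_genotypes(cfg)
  g <- simulate_phenotype(sim$truth, cfg)
  expect_equal(unname(g),
               3 + sim$genotypes[, sim$truth$causal_indices], ignore_attr = TRUE)
})

test_that("trait variance matches its polygenic + residual construction", {
  cfg <- sim_config(n_individuals = 500, n_markers = 400, n_subpops = 1,
                    fst = 0, ld_block_size = 1, n_causal = 0,
                    var_u = 1, var_e = 1, seed = 41)
  sim <- simulate_genotypes(cfg)
  K <- kinship(sim$genotypes)
  g <- simulate_phenotype(sim$truth, cfg)
  expect_equal(stats::var(g), mean(diag(K)) + 1, tolerance = 0.25)
})

test_that("OLS on the causal dosage recovers the simulated effect", {
  cfg <- sim_config(n_individuals = 800, n_markers = 50, n_subpops = 1,
                    fst = 0, ld_block_size = 1, n_causal = 1,
                    effect_sizes = 1, var_u = 0, var_e = 1, seed = 51)
  sim <- simulate_genotypes(cfg)
  g <- simulate_phenotype(sim$truth, cfg)
  fit <- summary(stats::lm(g ~ sim$genotypes[, sim$truth$causal_indices]))
  est <- fit$coefficients[2, 1]
  se <- fit$coefficients[2, 2]
  expect_lt(abs(est - 1), 2 * se)
})

test_that("simulation is deterministic given the seed and validates input", {
  cfg <- sim_config(n_individuals = 40, n_markers = 30, seed = 77)
  a <- simulate_panel(cfg, n_traits = 2)
  b <- simulate_panel(cfg, n_traits = 2)
  expect_identical(a$observed, b$observed)
  expect_identical(a$traits, b$traits)
  expect_error(sim_config(n_causal = 10, n_markers = 5), "n_causal")
  expect_error(sim_config(fst = 1), "fst")
  expect_error(sim_config(var_e = -1), "variances")
})
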