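# Rubin's-rules pooling of per-impute marker tests, the Barnard-Rubin
# denominator degrees of freedom, the gamma fraction-of-missing-
# information statistic, and Storey q-values for FDR control.

#' Classify the gamma fraction of missing information
#'
#' `[0, 0.2)` modest, `[0.2, 0.3)` moderately large, `[0.3, 0.5)` high;
#' values of 0.5 and above are labelled extreme.
#'
#' @param gamma numeric vector in `[0, 1]`.
#' @return character vector of classes.
#' @export
classify_gamma <- function(gamma) {
  if (any(gamma < 0 | gamma > 1, na.rm = TRUE)) stopf("gamma must lie in [0, 1]")
  as.character(cut(gamma, c(-Inf, 0.2, 0.3, 0.5, Inf), right = FALSE,
                   labels = c("modest", "moderately large", "high",
                              "extreme")))
}

#' Pool per-impute marker estimates by Rubin's rules
#'
#' Combines the `m` per-impute effect estimates and their sampling
#' variances: pooled effect `beta_bar` (the mean), within-impute variance
#' `W_bar` (mean of the variances), among-impute variance
#' `B* = (m + 1) / m * Var_r(beta)`, total variance `T = W_bar + B*`,
#' among-impute fraction `lambda = B* / T`, and the pooled 1-df F-test
#' `p = Pr(F(1, v) > beta_bar^2 / T)` with Barnard-Rubin denominator
#' degrees of freedom `v = v_m v_obs / (v_m + v_obs)` where
#' `v_m = (m - 1) / lambda^2`,
#' `v_obs = (v_com + 1) / (v_com + 3) * v_com * (1 - lambda)` and
#' `v_com = n - (2 + t)`. The fraction of information about the effect
#' lost to missingness is `gamma = (s + 2 / (v + 3)) / (1 + s)` with
#' `s = B* / W_bar`. When `B* = 0` the degenerate limit is handled
#' analytically: `lambda = 0`, `v = v_obs`, `gamma = 2 / (v_obs + 3)`.
#'
#' @param betas per-impute effect estimates (length m >= 2).
#' @param vars per-impute sampling variances (positive).
#' @param n number of individuals in the fits.
#' @param t number of structure covariates (PCs) in the model.
#' @return one-row data frame with `beta_bar`, `W_bar`, `B_star`, `T`,
#'   `lambda`, `s`, `v_m`, `v_obs`, `v_com`, `v`, `F`, `p_value`,
#'   `gamma`, `gamma_class`, `m`.
#' @export
pool_estimates <- function(betas, vars, n, t) {
  m <- length(betas)
  if (m < 2) stopf("pooling needs m >= 2 imputes")
  if (length(vars) != m) stopf("betas and vars must have equal length")
  if (anyNA(betas) || anyNA(vars)) stopf("missing per-impute estimates")
  if (any(vars <= 0)) stopf("within-impute variances must be positive")
  beta_bar <- mean(betas)
  W <- mean(vars)
  B <- (m + 1) / m * stats::var(betas)
  Tv <- W + B
  if (Tv <= 0) stopf("total variance is zero; pooled test undefined")
  v_com <- n - (2 + t)
  if (v_com <= 0) stopf("non-positive complete-data degrees of freedom")
  if (B == 0) {
    lambda <- 0
    v_m <- Inf
    v_obs <- (v_com + 1) / (v_com + 3) * v_com
    v <- v_obs
    s <- 0
  } else {
    lambda <- B / Tv
    v_m <- (m - 1) / lambda^2
    v_obs <- (v_com + 1) / (v_com + 3) * v_com * (1 - lambda)
    v <- v_m * v_obs / (v_m + v_obs)
    s <- B / W
  }
  gamma <- (s + 2 / (v + 3)) / (1 + s)
  Fstat <- beta_bar^2 / Tv
  data.frame(beta_bar = beta_bar, W_bar = W, B_star = B, T = Tv,
             lambda = lambda, s = s, v_m = v_m, v_obs = v_obs,
             v_com = v_com, v = v, F = Fstat,
             p_value = stats::pf(Fstat, 1, v, lower.tail = FALSE),
             gamma = gamma, gamma_class = classify_gamma(gamma), m = m,
             stringsAsFactors = FALSE)
}

#' Pool a per-impute scan into per-marker results
#'
#' Applies [pool_estimates()] marker-by-marker to the output of
#' [run_scheme()] for the MI or MI* scheme. Markers untestable in any
#' impute are returned with `NA` fields.
#'
#' @param results data frame from [run_scheme()] (schemes `mi`/`mistar`).
#' @param n number of individuals.
#' @param t number of structure covariates.
#' @return data frame, one row per marker, of pooled results.
#' @export
pool_scheme <- function(results, n, t) {
  stopifnot(all(c("marker_id", "beta", "var_beta", "impute") %in%
                  names(results)))
  ids <- unique(results$marker_id)
  rows <- lapply(ids, function(id) {
    sub <- results[results$marker_id == id, ]
    if (any(sub$untestable) || anyNA(sub$beta)) {
      out <- pool_estimates(c(0, 1), c(1, 1), n, t)  # template for columns
      out[1, ] <- NA
      out$gamma_class <- NA_character_
    } else {
      out <- pool_estimates(sub$beta, sub$var_beta, n, t)
    }
    cbind(marker_id = id, out, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Storey q-values with smoother-based pi0 estimation
#'
#' Estimates the null proportion `pi0` by evaluating
#' `pi0(l) = mean(p > l) / (1 - l)` on the grid `l = 0.05, ..., 0.95`
#' (step 0.05), smoothing with a cubic smoothing spline (3 df) and taking
#' the smoothed value at the last grid point (clamped to `(0, 1]`).
#' Q-values are the step-up `pi0 * n * p_(i) / i`, made monotone by a
#' cumulative minimum from the largest p-value down.
#'
#' @param p vector of p-values in `[0, 1]`.
#' @param fdr_level threshold for the significance flags (default 0.1).
#' @return an object of class `fdr_result`: `qvalues`, `pi0`,
#'   `significant` (logical at `fdr_level`), `fdr_level`.
#' @export
qvalues <- function(p, fdr_level = 0.1) {
  if (length(p) == 0) stopf("empty p-value vector")
  if (anyNA(p) || any(p < 0 | p > 1)) stopf("p-values must lie in [0, 1]")
  n <- length(p)
  grid <- seq(0.05, 0.95, by = 0.05)
  pi0_grid <- vapply(grid, function(l) mean(p > l) / (1 - l), numeric(1))
  pi0 <- if (n < 30 || stats::sd(pi0_grid) == 0) {
    min(1, max(pi0_grid[length(grid)], .Machine$double.eps))
  } else {
    fit <- stats::smooth.spline(grid, pi0_grid, df = 3)
    min(1, max(stats::predict(fit, x = max(grid))$y, .Machine$double.eps))
  }
  ord <- order(p, decreasing = TRUE)
  ranks <- n:1
  q_ord <- pmin(1, cummin(pi0 * n * p[ord] / ranks))
  q <- numeric(n)
  q[ord] <- q_ord
  structure(list(qvalues = q, pi0 = pi0, significant = q < fdr_level,
                 fdr_level = fdr_level),
            class = "fdr_result")
}

#' @export
print.fdr_result <- function(x, ...) {
  cat(sprintf("fdr_result: %d tests, pi0 = %.3f, %d significant at FDR < %g\n",
              length(x$qvalues), x$pi0, sum(x$significant), x$fdr_level))
  invisible(x)
}

#' Bonferroni-corrected per-test significance threshold
#'
#' @param alpha family-wise error rate, in `(0, 1)`.
#' @param n_tests number of tests (>= 1).
#' @return `alpha / n_tests`.
#' @export
bonferroni_threshold <- function(alpha, n_tests) {
  if (!(alpha > 0 && alpha < 1)) stopf("alpha must lie in (0, 1)")
  if (!is_count(n_tests) || n_tests < 1) stopf("n_tests must be a count >= 1")
  alpha / n_tests
}
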