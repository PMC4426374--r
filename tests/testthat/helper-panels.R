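# Small panel builders shared across test files. All fixtures are built
# in code; nothing is read from disk.

# A masked random dosage matrix with independent markers.
random_panel <- function(n = 60, q = 20, pmv = 0.3, seed = 1) {
  cfg <- sim_config(n_individuals = n, n_markers = q, n_subpops = 1, fst = 0,
                    ld_block_size = 1, pmv_dist = pmv_dist_point(pmv),
                    seed = seed)
  sim <- simulate_genotypes(cfg)
  list(complete = sim$genotypes,
       observed = apply_mcar_mask(sim$genotypes, pmv_dist_point(pmv),
                                  seed = seed + 1),
       truth = sim$truth)
}

# Dosage matrix from explicit columns.
dosage_mat <- function(...) {
  cols <- list(...)
  X <- do.call(cbind, cols)
  colnames(X) <- if (is.null(names(cols)) || any(names(cols) == "")) {
    paste0("M", seq_along(cols))
  } else names(cols)
  rownames(X) <- paste0("ind", seq_len(nrow(X)))
  X
}

# Independent dense-GLS oracle: per marker, solve the full V = r*K + I
# system explicitly (no spectral shortcut) with the residual scale
# re-estimated per marker, mirroring the model definition directly.
gls_scan_dense_oracle <- function(g, X, Q, ratio, K) {
  n <- length(g)
  Vinv_half <- solve(chol(ratio * K + diag(n)))   # V^{-1/2}, upper-tri inverse
  yt <- crossprod(Vinv_half, g)
  Ct <- crossprod(Vinv_half, cbind(1, Q))
  out <- data.frame(beta = numeric(ncol(X)), p = numeric(ncol(X)))
  for (j in seq_len(ncol(X))) {
    xt <- crossprod(Vinv_half, X[, j])
    fit <- stats::lm(yt ~ 0 + Ct + xt)
    sm <- summary(fit)$coefficients
    out$beta[j] <- sm["xt", 1]
    out$p[j] <- sm["xt", 4]
  }
  out
}

# Exhaustive best first Gini split over numeric predictors: returns the
# (variable, threshold, gain) maximizing the decrease in Gini impurity.
gini_best_split <- function(y, X, min_leaf = 5) {
  gini <- function(v) {
    p <- table(v) / length(v)
    1 - sum(p^2)
  }
  n <- length(y)
  best <- list(gain = -Inf, var = NA, cut = NA)
  for (j in seq_len(ncol(X))) {
    vals <- sort(unique(X[, j]))
    if (length(vals) < 2) next
    cuts <- (vals[-1] + vals[-length(vals)]) / 2
    for (cu in cuts) {
      left <- X[, j] < cu
      if (sum(left) < min_leaf || sum(!left) < min_leaf) next
      gain <- gini(y) - (sum(left) / n) * gini(y[left]) -
        (sum(!left) / n) * gini(y[!left])
      if (gain > best$gain) best <- list(gain = gain, var = j, cut = cu)
    }
  }
  best
}
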