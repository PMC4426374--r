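# Single-marker mixed-model association with the P3D approximation:
# variance components are estimated once under the null (REML on the
# spectral decomposition of K) and the variance ratio is then held fixed
# for every marker test, where generalized least squares reduces to
# ordinary least squares on decorrelated data.

#' REML fit of the null polygenic model
#'
#' Fits `g = mu + Q v + u + e`, `u ~ N(0, K sigma_u^2)`,
#' `e ~ N(0, I sigma_e^2)` by restricted maximum likelihood, profiling
#' the residual variance and optimizing the one-dimensional variance
#' ratio `sigma_u^2 / sigma_e^2` on the spectral decomposition of `K`.
#' With `K = NULL` the model degenerates to fixed effects only
#' (`sigma_u^2 = 0`), the single-marker-regression mode used for
#' biparental panels.
#'
#' @param g trait vector (no missing values).
#' @param Q n x t matrix of structure covariates, or `NULL`.
#' @param K relationship matrix (positive semidefinite), or `NULL`.
#' @param K_eigen optional precomputed `eigen(K, symmetric = TRUE)`,
#'   reused across traits for speed.
#' @return an object of class `var_components`: `sigma2_u`, `sigma2_e`,
#'   `ratio`, `loglik` (restricted, up to a constant), `eigen` (spectral
#'   cache, or `NULL`), `n`, `t`.
#' @export
fit_null <- function(g, Q = NULL, K = NULL, K_eigen = NULL) {
  if (anyNA(g)) stopf("trait vector must be complete")
  n <- length(g)
  if (stats::sd(g) == 0) stopf("trait is constant; variance components undefined")
  W <- cbind(`(Intercept)` = rep(1, n), Q)
  t_pc <- ncol(W) - 1L
  if (is.null(K)) {
    fit <- stats::lm.fit(W, g)
    s2 <- sum(fit$residuals^2) / (n - ncol(W))
    return(structure(list(sigma2_u = 0, sigma2_e = s2, ratio = 0,
                          loglik = NA_real_, eigen = NULL, n = n, t = t_pc),
                     class = "var_components"))
  }
  if (nrow(K) != n) stopf("dimensions of g and K disagree")
  eig <- if (is.null(K_eigen)) eigen(K, symmetric = TRUE) else K_eigen
  d <- pmax(eig$values, 0)
  if (min(eig$values) < -1e-6 * max(d)) stopf("K is not positive semidefinite")
  U <- eig$vectors
  gt <- crossprod(U, g)
  Wt <- crossprod(U, W)
  p <- ncol(W)
  neg2_reml <- function(log_ratio) {
    r <- exp(log_ratio)
    wts <- 1 / (r * d + 1)
    sw <- sqrt(wts)
    A <- Wt * sw
    y <- gt * sw
    qrA <- qr(A)
    rss <- sum(qr.resid(qrA, y)^2)
    ldet_wvw <- 2 * sum(log(abs(diag(qr.R(qrA)))))
    (n - p) * log(rss) + sum(log(r * d + 1)) + ldet_wvw
  }
  opt <- stats::optimize(neg2_reml, interval = c(-14, 14), tol = 1e-8)
  r <- exp(opt$minimum)
  boundary <- opt$minimum <= -14 + 1e-4
  if (boundary) r <- 0
  wts <- 1 / (r * d + 1)
  sw <- sqrt(wts)
  qrA <- qr(Wt * sw)
  rss <- sum(qr.resid(qrA, gt * sw)^2)
  s2e <- rss / (n - p)
  if (boundary) warning("REML optimum at the sigma2_u = 0 boundary")
  structure(list(sigma2_u = max(r * s2e, 0), sigma2_e = max(s2e, 1e-8),
                 ratio = r, loglik = -0.5 * opt$objective,
                 eigen = list(U = U, d = d), n = n, t = t_pc),
            class = "var_components")
}

#' @export
print.var_components <- function(x, ...) {
  cat(sprintf("var_components: sigma2_u = %.4g, sigma2_e = %.4g (n = %d, t = %d)\n",
              x$sigma2_u, x$sigma2_e, x$n, x$t))
  invisible(x)
}

# Batched GLS marker scan with the variance ratio held fixed (P3D).
# Decorrelates through the cached spectral transform, projects out the
# intercept and Q, then tests each marker by a 1-df F-test with the
# residual scale re-estimated per marker (so ratio = 0 is exactly OLS).
gls_scan <- function(g, Xmat, Q, vc) {
  n <- length(g)
  stopifnot(nrow(Xmat) == n)
  if (is.null(vc$eigen) || vc$ratio == 0) {
    yt <- g; Ct <- cbind(rep(1, n), Q); Xt <- Xmat
  } else {
    sw <- sqrt(1 / (vc$ratio * vc$eigen$d + 1))
    U <- vc$eigen$U
    yt <- crossprod(U, g) * sw
    Ct <- crossprod(U, cbind(rep(1, n), Q)) * sw
    Xt <- crossprod(U, Xmat) * sw
  }
  qrC <- qr(Ct)
  ry <- qr.resid(qrC, yt)
  RX <- qr.resid(qrC, Xt)
  sxx <- colSums(RX^2)
  sxy <- as.vector(crossprod(RX, ry))
  syy <- sum(ry^2)
  df <- n - ncol(Ct) - 1L
  untestable <- sxx <= max(sxx, 1) * 1e-12
  beta <- sxy / sxx
  rss <- pmax(syy - sxy^2 / sxx, 0)
  sigma2 <- rss / df
  var_beta <- sigma2 / sxx
  Fstat <- beta^2 / var_beta
  p <- stats::pf(Fstat, 1, df, lower.tail = FALSE)
  beta[untestable] <- NA; var_beta[untestable] <- NA; p[untestable] <- NA
  data.frame(marker_id = marker_ids(Xmat), beta = beta, var_beta = var_beta,
             df = df, p = p, n_used = n, untestable = untestable,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Test one marker by GLS under fixed variance components
#'
#' Generalized least squares of `g` on `(1, x, Q)` under
#' `V = sigma_u^2 K + sigma_e^2 I` with the variance ratio fixed at the
#' null REML estimate (P3D); the 1-df F-test for the marker coefficient
#' uses denominator degrees of freedom `n - 2 - t`. With
#' `sigma_u^2 = 0` this is exactly ordinary least squares.
#'
#' @param g trait vector.
#' @param x marker dosage vector (complete for the rows used).
#' @param Q structure covariates or `NULL`.
#' @param vc a [fit_null()] result.
#' @return one-row data frame: `beta`, `var_beta`, `df`, `p`, `n_used`,
#'   `untestable` (set when `x` is collinear with the covariates).
#' @export
marker_test_gls <- function(g, x, Q = NULL, vc) {
  stopifnot(inherits(vc, "var_components"))
  gls_scan(g, matrix(x, ncol = 1, dimnames = list(NULL, "x")), Q, vc)
}

# Complete-case scan: per marker, subset to the rows observed at that
# marker, decorrelate with V = ratio * K[obs, obs] + I (ratio from the
# full-panel null fit, P3D), and run the same 1-df F-test.
cc_scan <- function(g, X, Q, K, ratio) {
  n <- length(g)
  ids <- marker_ids(X)
  t_pc <- if (is.null(Q)) 0L else ncol(Q)
  out <- data.frame(marker_id = ids, beta = NA_real_, var_beta = NA_real_,
                    df = NA_real_, p = NA_real_, n_used = NA_integer_,
                    untestable = FALSE, row.names = NULL,
                    stringsAsFactors = FALSE)
  for (j in seq_len(ncol(X))) {
    rows <- which(!is.na(X[, j]))
    n_obs <- length(rows)
    out$n_used[j] <- n_obs
    if (n_obs < t_pc + 4L) { out$untestable[j] <- TRUE; next }
    x <- X[rows, j]
    yv <- g[rows]
    C <- cbind(rep(1, n_obs), if (is.null(Q)) NULL else Q[rows, , drop = FALSE])
    if (!is.null(K) && ratio > 0) {
      R <- chol(ratio * K[rows, rows, drop = FALSE] + diag(n_obs))
      yv <- backsolve(R, yv, transpose = TRUE)
      x <- backsolve(R, x, transpose = TRUE)
      C <- backsolve(R, C, transpose = TRUE)
    }
    qrC <- qr(C)
    rx <- qr.resid(qrC, x)
    ry <- qr.resid(qrC, yv)
    sxx <- sum(rx^2)
    if (sxx <= 1e-12 * max(sum(x^2), 1)) { out$untestable[j] <- TRUE; next }
    beta <- sum(rx * ry) / sxx
    df <- n_obs - ncol(C) - 1L
    rss <- max(sum(ry^2) - sum(rx * ry)^2 / sxx, 0)
    var_beta <- (rss / df) / sxx
    out$beta[j] <- beta
    out$var_beta[j] <- var_beta
    out$df[j] <- df
    out$p[j] <- stats::pf(beta^2 / var_beta, 1, df, lower.tail = FALSE)
  }
  out
}

#' Per-impute structure and kinship for the MI* scheme
#'
#' Computes, for each impute, the first `t` PC scores, the relationship
#' matrix, and its spectral decomposition, for reuse across traits.
#'
#' @param S an [fcs_impute()] result or a plain list of complete
#'   matrices.
#' @param t number of PCs (0 for none).
#' @return list of per-impute lists `(Q, K, K_eigen)`.
#' @export
mistar_structures <- function(S, t) {
  imputes <- if (inherits(S, "impute_set")) S$imputes else S
  lapply(imputes, function(Xr) {
    Q <- if (t > 0) pca_scores(Xr, t)$Q else NULL
    K <- kinship(Xr)
    list(Q = Q, K = K, K_eigen = eigen(K, symmetric = TRUE))
  })
}

#' Run a genome-wide marker scan under one association scheme
#'
#' The four schemes differ in which genotype matrix and which structure
#' estimates they use:
#' \describe{
#'   \item{CC}{the raw (incomplete) matrix, each marker tested on its
#'     observed rows, with `Q` and `K` from the average-dosage matrix
#'     held fixed and the full-panel variance ratio reused (P3D).}
#'   \item{AD}{the average-dosage matrix, `Q`/`K` fixed; one null fit.}
#'   \item{MI}{each impute in turn, `Q`/`K` fixed; the AD null fit is
#'     reused; returns `m` results per marker for pooling.}
#'   \item{MI*}{each impute with its own `Q`, `K` and null REML fit, so
#'     imputation uncertainty in the structure estimates is propagated.}
#' }
#'
#' @param scheme one of `"cc"`, `"ad"`, `"mi"`, `"mistar"`.
#' @param g trait vector.
#' @param X raw dosage matrix with missing values (CC only).
#' @param Xbar average-dosage matrix (AD/MI null fit; see
#'   [average_dosage()]).
#' @param S an [fcs_impute()] impute set (MI/MI*).
#' @param Q,K structure estimates from the average-dosage matrix, or
#'   `NULL` for the no-structure (biparental) mode.
#' @param t number of PCs for MI* per-impute structure (defaults to
#'   `ncol(Q)`, or 0 when `Q` is `NULL`).
#' @param structures optional precomputed [mistar_structures()].
#' @param vc optional precomputed [fit_null()] on `(g, Q, K)`.
#' @return data frame of per-marker (and per-impute, for MI/MI*) test
#'   results: `marker_id`, `scheme`, `impute`, `beta`, `var_beta`, `df`,
#'   `p`, `n_used`, `untestable`.
#' @export
run_scheme <- function(scheme = c("cc", "ad", "mi", "mistar"), g,
                       X = NULL, Xbar = NULL, S = NULL, Q = NULL, K = NULL,
                       t = if (is.null(Q)) 0L else ncol(Q),
                       structures = NULL, vc = NULL) {
  scheme <- match.arg(scheme)
  need <- function(obj, what) {
    if (is.null(obj)) stopf("scheme '%s' requires %s", scheme, what)
    obj
  }
  if (scheme %in% c("cc", "ad", "mi") && is.null(vc)) {
    vc <- fit_null(g, Q, K)
  }
  res <- switch(scheme,
    cc = {
      need(X, "the raw dosage matrix X")
      cbind(cc_scan(g, X, Q, K, vc$ratio), impute = NA_integer_)
    },
    ad = {
      need(Xbar, "the average-dosage matrix Xbar")
      cbind(gls_scan(g, Xbar, Q, vc), impute = NA_integer_)
    },
    mi = {
      need(S, "an impute set")
      imputes <- if (inherits(S, "impute_set")) S$imputes else S
      do.call(rbind, lapply(seq_along(imputes), function(r) {
        cbind(gls_scan(g, imputes[[r]], Q, vc), impute = r)
      }))
    },
    mistar = {
      need(S, "an impute set")
      imputes <- if (inherits(S, "impute_set")) S$imputes else S
      if (is.null(structures)) structures <- mistar_structures(S, t)
      do.call(rbind, lapply(seq_along(imputes), function(r) {
        st <- structures[[r]]
        vcr <- fit_null(g, st$Q, st$K, K_eigen = st$K_eigen)
        cbind(gls_scan(g, imputes[[r]], st$Q, vcr), impute = r)
      }))
    })
  res$scheme <- scheme
  res[, c("marker_id", "scheme", "impute", "beta", "var_beta", "df",
          "p", "n_used", "untestable")]
}
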