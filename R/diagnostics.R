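# Imputation-uncertainty diagnostics: scheme-consistency regressions,
# the arcsin(gamma) factor model with cross-validation, average mutual
# information, trait-wise standardization, pairwise r-squared on average
# dosages, and significance differentials.

#' Standardize effect estimates within traits
#'
#' Centers and scales effects to zero mean and unit SD within each trait,
#' so estimates are comparable across traits of different scales (as used
#' for cross-trait concordance plots).
#'
#' @param effects numeric vector of effect estimates.
#' @param trait trait label per effect (single trait if `NULL`).
#' @return numeric vector of standardized effects.
#' @export
standardize_by_trait <- function(effects, trait = NULL) {
  if (is.null(trait)) trait <- rep("trait", length(effects))
  if (length(trait) != length(effects)) stopf("one trait label per effect required")
  out <- effects
  for (tr in unique(trait)) {
    i <- trait == tr
    if (sum(i) < 2) stopf("trait '%s' has fewer than 2 effects", tr)
    s <- stats::sd(effects[i])
    if (s == 0) stopf("trait '%s' has zero effect SD", tr)
    out[i] <- (effects[i] - mean(effects[i])) / s
  }
  out
}

diag_regression <- function(fit, model_tag, extra = list()) {
  sm <- summary(fit)
  co <- sm$coefficients
  structure(c(list(model_tag = model_tag,
                   coefficients = data.frame(term = rownames(co),
                                             estimate = co[, 1], se = co[, 2],
                                             p = co[, 4], row.names = NULL,
                                             stringsAsFactors = FALSE),
                   sigma2_e = sm$sigma^2, r2 = sm$r.squared, fit = fit),
              extra),
            class = "diag_regression")
}

#' @export
print.diag_regression <- function(x, ...) {
  cat(sprintf("diag_regression [%s]: R^2 = %.3f, residual variance = %.4g\n",
              x$model_tag, x$r2, x$sigma2_e))
  print(x$coefficients, digits = 4)
  invisible(x)
}

#' Cross-scheme consistency regression of effect estimates
#'
#' Two model forms:
#' \describe{
#'   \item{`cc_on_ad`}{`y = intercept + slope * x + e`; a slope of 1 and
#'     a null intercept indicate no systematic bias between schemes. When
#'     `gamma` is supplied the fit is repeated within the `gamma < 0.2`
#'     and `gamma > 0.2` strata, whose residual variances show how much
#'     noisier the estimates become under high imputation uncertainty.}
#'   \item{`ad_on_mi`}{`y = intercept + (b1 + b3 gamma) x + b2 gamma + e`;
#'     `b1 = 1` means agreement at `gamma = 0`, and `b3 > 0` means the
#'     multiply-imputed estimates shrink toward zero as uncertainty
#'     grows.}
#' }
#'
#' @param y_effects response effects (e.g. complete-case betas).
#' @param x_effects regressor effects (e.g. average-dosage betas).
#' @param gamma per-pair fraction of missing information (required for
#'   `ad_on_mi`, optional strata for `cc_on_ad`).
#' @param model_tag `"cc_on_ad"` or `"ad_on_mi"`.
#' @return a `diag_regression` (with a `strata` data frame for stratified
#'   `cc_on_ad` fits).
#' @export
consistency_regression <- function(y_effects, x_effects, gamma = NULL,
                                   model_tag = c("cc_on_ad", "ad_on_mi")) {
  model_tag <- match.arg(model_tag)
  ok <- !(is.na(y_effects) | is.na(x_effects) |
            (if (is.null(gamma)) FALSE else is.na(gamma)))
  y <- y_effects[ok]; x <- x_effects[ok]
  g <- if (is.null(gamma)) NULL else gamma[ok]
  if (model_tag == "cc_on_ad") {
    if (length(y) < 3) stopf("fewer observations than parameters")
    fit <- stats::lm(y ~ x)
    strata <- NULL
    if (!is.null(g)) {
      strata <- do.call(rbind, lapply(
        list(c("gamma<0.2", -Inf, 0.2), c("gamma>0.2", 0.2, Inf)),
        function(sp) {
          i <- g > as.numeric(sp[2]) & g <= as.numeric(sp[3])
          if (sum(i) < 3) return(NULL)
          sm <- summary(stats::lm(y[i] ~ x[i]))
          data.frame(stratum = sp[1], n = sum(i),
                     slope = sm$coefficients[2, 1],
                     sigma2_e = sm$sigma^2, r2 = sm$r.squared,
                     stringsAsFactors = FALSE)
        }))
    }
    diag_regression(fit, model_tag, list(strata = strata))
  } else {
    if (is.null(g)) stopf("'ad_on_mi' requires gamma")
    if (length(y) < 5) stopf("fewer observations than parameters")
    fit <- stats::lm(y ~ x + g + x:g)
    out <- diag_regression(fit, model_tag)
    out$coefficients$term <- c("(Intercept)", "b1", "b2", "b3")
    out
  }
}

#' Average mutual information of a marker with the rest of the panel
#'
#' Mean of the pairwise mutual information (bits, pairwise-complete
#' observations) between marker `k` and every other marker; a proxy for
#' how much the panel knows about the marker, hence how imputable it is.
#'
#' @param X dosage matrix (>= 2 markers).
#' @param k marker index or name.
#' @param mi optional precomputed [mi_matrix()].
#' @return AMI in bits.
#' @export
average_mutual_information <- function(X, k, mi = NULL) {
  if (ncol(X) < 2) stopf("AMI needs at least 2 markers")
  if (is.character(k)) k <- match(k, marker_ids(X))
  scores <- if (is.null(mi)) {
    suppressWarnings(vapply(setdiff(seq_len(ncol(X)), k), function(j) {
      mutual_information(X[, k], X[, j])
    }, numeric(1)))
  } else mi[k, -k]
  if (all(is.na(scores))) stopf("all pairs undefined for marker %s", k)
  mean(scores, na.rm = TRUE)
}

#' Regress imputation uncertainty on its candidate drivers
#'
#' Ordinary least squares of `arcsin(gamma)` on the proportion of missing
#' values, the minor allele frequency, and the average mutual
#' information, with 10-fold cross-validated predictive r-squared and MSE
#' (folds seeded and stratified by PMV decile) against the intercept-only
#' null.
#'
#' @param gamma fraction of missing information per marker, in `[0, 1]`.
#' @param pmv,maf,ami aligned per-marker covariates.
#' @param folds number of CV folds (default 10).
#' @param seed fold-assignment seed.
#' @return a `diag_regression` with `cv_r2`, `cv_mse`, `cv_mse_null`, and
#'   `fold` (the fold assignment).
#' @export
gamma_factor_model <- function(gamma, pmv, maf, ami, folds = 10, seed = 1) {
  ok <- stats::complete.cases(gamma, pmv, maf, ami)
  gamma <- gamma[ok]; pmv <- pmv[ok]; maf <- maf[ok]; ami <- ami[ok]
  if (any(gamma < 0 | gamma > 1)) stopf("gamma must lie in [0, 1]")
  y <- asin(gamma)
  if (stats::sd(y) == 0) stopf("gamma is constant; factor model degenerate")
  df <- data.frame(y = y, pmv = pmv, maf = maf, ami = ami)
  fit <- stats::lm(y ~ pmv + maf + ami, data = df)
  # stratified fold assignment: spread PMV deciles across folds
  fold <- with_seed(seed, {
    dec <- cut(rank(pmv, ties.method = "first"), folds, labels = FALSE)
    f <- integer(length(pmv))
    for (d in unique(dec)) {
      i <- which(dec == d)
      f[i] <- sample(rep_len(seq_len(folds), length(i)))
    }
    f
  })
  pred <- numeric(nrow(df)); pred_null <- numeric(nrow(df))
  for (k in seq_len(folds)) {
    test <- fold == k
    fk <- stats::lm(y ~ pmv + maf + ami, data = df[!test, ])
    pred[test] <- stats::predict(fk, df[test, ])
    pred_null[test] <- mean(df$y[!test])
  }
  out <- diag_regression(fit, "gamma_factors",
                         list(cv_r2 = stats::cor(pred, y)^2,
                              cv_mse = mean((y - pred)^2),
                              cv_mse_null = mean((y - pred_null)^2),
                              fold = fold))
  out$coefficients$term <- c("(Intercept)", "b1_pmv", "b2_maf", "b3_ami")
  out
}

#' Pairwise squared correlation among markers on average dosages
#'
#' Pearson r-squared between the columns of the average-dosage matrix (a
#' linkage-disequilibrium proxy when no map is available), with the
#' standard two-sided correlation t-test per pair. Zero-variance columns
#' yield `NA` entries.
#'
#' @param Xbar average-dosage matrix.
#' @param markers marker ids or indices to compare (default all).
#' @return list with `r2` and `p` (symmetric matrices).
#' @export
pairwise_r2 <- function(Xbar, markers = NULL) {
  if (!is.null(markers)) Xbar <- Xbar[, markers, drop = FALSE]
  if (ncol(Xbar) < 2) stopf("need at least 2 markers")
  n <- nrow(Xbar)
  suppressWarnings(r <- stats::cor(Xbar))
  diag(r) <- 1
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), n - 2)
  diag(p) <- NA
  list(r2 = r^2, p = p)
}

#' Significance differential between two scans
#'
#' `Delta = -log10(p_mistar) + log10(p_cc)` per association: positive
#' values are gains in significance from the complete-case analysis to
#' the fully uncertainty-aware one. With `gamma`, summaries are reported
#' within the `gamma < 0.2` and `gamma >= 0.2` strata. Zero p-values are
#' clipped at the smallest representable double.
#'
#' @param p_cc,p_mistar aligned p-value vectors.
#' @param gamma optional per-association fraction of missing information.
#' @return list with `delta` and (if `gamma` given) `summary` (n, median,
#'   mean per stratum).
#' @export
delta_significance <- function(p_cc, p_mistar, gamma = NULL) {
  if (length(p_cc) != length(p_mistar)) stopf("p-value vectors must align")
  clip <- function(p) pmax(p, .Machine$double.xmin)
  delta <- -log10(clip(p_mistar)) + log10(clip(p_cc))
  out <- list(delta = delta)
  if (!is.null(gamma)) {
    strat <- ifelse(gamma < 0.2, "gamma<0.2", "gamma>=0.2")
    out$summary <- do.call(rbind, lapply(unique(strat[!is.na(strat)]),
      function(sname) {
        d <- delta[strat == sname & !is.na(delta)]
        data.frame(stratum = sname, n = length(d), median = stats::median(d),
                   mean = mean(d), stringsAsFactors = FALSE)
      }))
  }
  out
}
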