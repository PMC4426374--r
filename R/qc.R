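# Marker quality control: per-panel missingness, constant/collinear
# removal, and per-subset minor-allele-frequency filtering.

new_qc_report <- function(kept, dropped, thresholds, n_input) {
  stopifnot(is.data.frame(dropped))
  structure(list(kept = kept, dropped = dropped, thresholds = thresholds,
                 n_input = n_input),
            class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("Marker QC report: %d markers in, %d kept, %d dropped\n",
              x$n_input, length(x$kept), nrow(x$dropped)))
  if (nrow(x$dropped)) print(table(x$dropped$reason))
  invisible(x)
}

empty_dropped <- function() {
  data.frame(marker = character(0), reason = character(0),
             details = character(0), stringsAsFactors = FALSE)
}

#' Per-marker, per-group proportion of missing values
#'
#' @param X dosage matrix (individuals x markers, entries -1/0/1/NA).
#' @param groups factor-like of length `nrow(X)` partitioning individuals
#'   into panels; `NULL` treats the panel as one group.
#' @return a markers x groups matrix of PMV in `[0, 1]`.
#' @export
compute_pmv <- function(X, groups = NULL) {
  check_dosages(X)
  if (is.null(groups)) groups <- rep("all", nrow(X))
  if (length(groups) != nrow(X)) stopf("groups must have one entry per individual")
  groups <- as.factor(groups)
  if (any(table(groups) == 0)) stopf("empty group in 'groups'")
  miss <- is.na(X)
  out <- sapply(levels(groups), function(g) {
    rows <- groups == g
    colSums(miss[rows, , drop = FALSE]) / sum(rows)
  })
  out <- matrix(out, ncol = nlevels(groups),
                dimnames = list(marker_ids(X), levels(groups)))
  out
}

#' Filter markers on per-panel missingness
#'
#' A marker is kept iff its PMV is strictly below `threshold` in every
#' group (panel); a marker at or above the threshold in any one panel is
#' dropped.
#'
#' @inheritParams compute_pmv
#' @param threshold maximum tolerated PMV, in `(0, 1]`; default 0.90.
#' @return a `qc_report`.
#' @export
filter_pmv <- function(X, threshold = 0.90, groups = NULL) {
  if (!(threshold > 0 && threshold <= 1)) stopf("threshold must be in (0, 1]")
  pmv <- compute_pmv(X, groups)
  worst <- apply(pmv, 1L, max)
  ids <- marker_ids(X)
  drop <- worst >= threshold
  dropped <- if (any(drop)) {
    worst_grp <- colnames(pmv)[apply(pmv[drop, , drop = FALSE], 1L, which.max)]
    data.frame(marker = ids[drop], reason = "pmv",
               details = sprintf("pmv=%.3f in group %s", worst[drop], worst_grp),
               stringsAsFactors = FALSE)
  } else empty_dropped()
  new_qc_report(ids[!drop], dropped, list(pmv_max = threshold), ncol(X))
}

#' Filter constant and collinear markers
#'
#' Markers whose observed-value variance is at most `var_eps` (including
#' markers with fewer than two observed calls) are dropped as constant.
#' Among the remainder, for every pair correlated at `|r| >= r_threshold`
#' on pairwise-complete observations, the member with more missing values
#' is dropped. The scan is a greedy pass in ascending-missingness order
#' (ties broken by column index): a candidate is dropped as soon as it is
#' collinear with an already-kept, better-observed marker, so both members
#' of a flagged pair are never removed. Pairs with fewer than three
#' overlapping observations are not compared.
#'
#' @inheritParams compute_pmv
#' @param r_threshold absolute-correlation cutoff; default 0.999.
#' @param var_eps variance below which a marker counts as constant.
#' @return a `qc_report`.
#' @export
filter_constant_collinear <- function(X, r_threshold = 0.999, var_eps = 1e-12) {
  check_dosages(X)
  if (!(r_threshold > 0 && r_threshold <= 1)) stopf("r_threshold must be in (0, 1]")
  ids <- marker_ids(X)
  n_obs <- colSums(!is.na(X))
  v <- apply(X, 2L, stats::var, na.rm = TRUE)
  constant <- n_obs < 2 | (!is.na(v) & v <= var_eps)
  dropped <- if (any(constant)) {
    data.frame(marker = ids[constant], reason = "constant",
               details = sprintf("observed variance %.3g over %d calls",
                                 ifelse(is.na(v[constant]), 0, v[constant]),
                                 n_obs[constant]),
               stringsAsFactors = FALSE)
  } else empty_dropped()

  idx <- which(!constant)
  if (length(idx) >= 2) {
    Xs <- X[, idx, drop = FALSE]
    suppressWarnings(r <- stats::cor(Xs, use = "pairwise.complete.obs"))
    overlap <- crossprod(!is.na(Xs))
    r[overlap < 3] <- NA          # undefined pairs are not compared
    diag(r) <- NA
    ord <- order(colSums(is.na(Xs)), idx)    # ascending missingness, ties by index
    kept_local <- integer(0)
    for (j in ord) {
      rj <- abs(r[j, kept_local])
      hit <- which(!is.na(rj) & rj >= r_threshold)
      if (length(hit)) {
        partner <- ids[idx[kept_local[hit[1L]]]]
        dropped <- rbind(dropped, data.frame(
          marker = ids[idx[j]], reason = "collinear",
          details = sprintf("|r|=%.4f with better-observed %s",
                            rj[hit[1L]], partner),
          stringsAsFactors = FALSE))
      } else {
        kept_local <- c(kept_local, j)
      }
    }
  }
  kept <- setdiff(ids, dropped$marker)
  new_qc_report(kept, dropped,
                list(r_max = r_threshold, var_eps = var_eps), ncol(X))
}

#' Observed minor allele frequency per marker
#'
#' The alternate-allele frequency is estimated from observed calls as
#' `p = (2 * n(1) + n(0)) / (2 * n_obs)` and the MAF is `min(p, 1 - p)`.
#' Markers with no observed call in the subset get `NA`.
#'
#' @inheritParams compute_pmv
#' @param subset individuals (indices or names) on which to estimate;
#'   `NULL` uses all rows.
#' @return named numeric vector of MAF.
#' @export
compute_maf <- function(X, subset = NULL) {
  check_dosages(X)
  if (!is.null(subset)) X <- X[subset, , drop = FALSE]
  n_obs <- colSums(!is.na(X))
  p <- (2 * colSums(X == 1, na.rm = TRUE) + colSums(X == 0, na.rm = TRUE)) /
    (2 * n_obs)
  maf <- pmin(p, 1 - p)
  maf[n_obs == 0] <- NA
  names(maf) <- marker_ids(X)
  maf
}

#' Filter markers on observed minor allele frequency within a subset
#'
#' Markers with `MAF < threshold` (strict), or with no observed call in
#' the subset, are dropped.
#'
#' @inheritParams compute_maf
#' @param threshold minimum MAF; default 0.05.
#' @return a `qc_report`.
#' @export
filter_maf <- function(X, subset = NULL, threshold = 0.05) {
  maf <- compute_maf(X, subset)
  ids <- marker_ids(X)
  drop <- is.na(maf) | maf < threshold
  dropped <- if (any(drop)) {
    data.frame(marker = ids[drop], reason = "maf",
               details = ifelse(is.na(maf[drop]), "no observed calls in subset",
                                sprintf("maf=%.4f", maf[drop])),
               stringsAsFactors = FALSE)
  } else empty_dropped()
  new_qc_report(ids[!drop], dropped, list(maf_min = threshold), ncol(X))
}

#' Run the full marker QC sequence
#'
#' Applies, in order: per-panel PMV filter, constant/collinear filter,
#' and (optionally, for a designated analysis subset of individuals) the
#' MAF filter. Reasons are recorded in application order, and the combined
#' report partitions the input markers exactly.
#'
#' @inheritParams compute_pmv
#' @param pmv_max,r_max,var_eps,maf_min stage thresholds.
#' @param maf_subset individuals defining the association subset for the
#'   MAF filter; `NULL` skips the MAF stage.
#' @return list with `X` (filtered matrix) and `report` (`qc_report`).
#' @export
run_qc <- function(X, groups = NULL, pmv_max = 0.90, r_max = 0.999,
                   var_eps = 1e-12, maf_min = 0.05, maf_subset = NULL) {
  r1 <- filter_pmv(X, pmv_max, groups)
  X1 <- X[, r1$kept, drop = FALSE]
  r2 <- filter_constant_collinear(X1, r_max, var_eps)
  X2 <- X1[, r2$kept, drop = FALSE]
  dropped <- rbind(r1$dropped, r2$dropped)
  kept <- r2$kept
  if (!is.null(maf_subset)) {
    r3 <- filter_maf(X2, maf_subset, maf_min)
    dropped <- rbind(dropped, r3$dropped)
    kept <- r3$kept
    X2 <- X2[, kept, drop = FALSE]
  }
  report <- new_qc_report(kept, dropped,
                          list(pmv_max = pmv_max, r_max = r_max,
                               var_eps = var_eps,
                               maf_min = if (is.null(maf_subset)) NA else maf_min),
                          ncol(X))
  list(X = X2, report = report)
}
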