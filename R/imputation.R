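# Multiple imputation of dosage matrices by fully conditional
# specification (a pseudo-Gibbs sampler) with classification-tree donor
# pools: each missing call at a marker is filled by a draw from the
# observed dosages that share its terminal node in a CART fitted on the
# marker's best predictors.

DOSAGE_LEVELS <- c(-1, 0, 1)

#' Mutual information between two categorical dosage vectors
#'
#' Empirical mutual information (base 2) of the joint distribution over
#' dosage classes, computed on pairwise-complete observations. Symmetric
#' and non-negative; `NA` (with a warning) when there is no overlapping
#' observation, in which case predictor ranking treats the pair as
#' uninformative.
#'
#' @param x,y vectors with entries in \{-1, 0, 1, NA\}.
#' @return mutual information in bits.
#' @export
mutual_information <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  if (!any(ok)) {
    warning("no overlapping observations; mutual information undefined")
    return(NA_real_)
  }
  tab <- table(factor(x[ok], DOSAGE_LEVELS), factor(y[ok], DOSAGE_LEVELS))
  p <- tab / sum(tab)
  px <- rowSums(p); py <- colSums(p)
  e <- outer(px, py)
  terms <- p * log2(p / e)
  sum(terms[p > 0])
}

#' All pairwise mutual-information scores of a panel
#'
#' Vectorized computation of the q x q matrix of pairwise MI (bits) on
#' pairwise-complete observations, via per-class indicator cross-products.
#' Pairs with no overlap are `NA`.
#'
#' @param X dosage matrix.
#' @return q x q symmetric matrix, diagonal `NA`, with attribute
#'   `"overlap"` (pairwise-complete counts).
#' @export
mi_matrix <- function(X) {
  check_dosages(X)
  obs <- !is.na(X)
  storage.mode(obs) <- "double"
  O <- crossprod(obs)
  ind <- lapply(DOSAGE_LEVELS, function(v) {
    M <- (X == v) & !is.na(X)
    storage.mode(M) <- "double"
    M
  })
  N <- list()
  for (a in 1:3) for (b in 1:3) N[[paste(a, b)]] <- crossprod(ind[[a]], ind[[b]])
  # joint marginals per pair
  PX <- lapply(1:3, function(a) (N[[paste(a, 1)]] + N[[paste(a, 2)]] +
                                   N[[paste(a, 3)]]) / O)
  PY <- lapply(1:3, function(b) (N[[paste(1, b)]] + N[[paste(2, b)]] +
                                   N[[paste(3, b)]]) / O)
  MI <- matrix(0, ncol(X), ncol(X))
  for (a in 1:3) for (b in 1:3) {
    P <- N[[paste(a, b)]] / O
    E <- PX[[a]] * PY[[b]]
    term <- P * log2(P / E)
    term[P == 0 | !is.finite(term)] <- 0
    MI <- MI + term
  }
  MI[O == 0] <- NA
  diag(MI) <- NA
  dimnames(MI) <- list(marker_ids(X), marker_ids(X))
  attr(MI, "overlap") <- O
  MI
}

#' Select the best predictors of a marker by marginal mutual information
#'
#' Ranks all other markers by their MI with marker `k`, computed once
#' from the observed data (before any chain starts), and returns the top
#' `qsel`. Ties are broken by marker index; zero-overlap pairs rank last.
#'
#' @param X dosage matrix (post-QC).
#' @param k target marker (index or name).
#' @param qsel number of predictors to keep (default 500).
#' @param mi optional precomputed [mi_matrix()] to avoid rescoring.
#' @return list with `indices` (predictor column indices, best first) and
#'   `scores` (their MI in bits, `NA` for zero-overlap pairs).
#' @export
select_predictors <- function(X, k, qsel = 500, mi = NULL) {
  if (is.character(k)) k <- match(k, marker_ids(X))
  scores <- if (is.null(mi)) {
    suppressWarnings(vapply(seq_len(ncol(X)), function(j) {
      if (j == k) NA_real_ else mutual_information(X[, k], X[, j])
    }, numeric(1)))
  } else mi[k, ]
  cand <- setdiff(seq_len(ncol(X)), k)
  ranked <- cand[order(-replace(scores[cand], is.na(scores[cand]), -Inf), cand)]
  top <- ranked[seq_len(min(qsel, length(ranked)))]
  list(indices = top, scores = scores[top])
}

#' Fit a dosage classification tree with a donor floor per leaf
#'
#' Grows a CART over the dosage classes (Gini splits, via \pkg{rpart})
#' with at least `min_leaf` observed target values ("donors") per
#' terminal node and no cost-complexity pruning beyond that floor. A
#' constant target yields a single-leaf (marginal) tree.
#'
#' @param target observed dosages at the marker being imputed.
#' @param predictors matrix or data frame of current predictor values for
#'   the same rows.
#' @param min_leaf minimum donors per leaf (default 5).
#' @return object of class `dosage_tree`.
#' @export
cart_fit <- function(target, predictors, min_leaf = 5) {
  keep <- !is.na(target)
  target <- target[keep]
  if (!is.null(predictors)) predictors <- predictors[keep, , drop = FALSE]
  if (length(target) < min_leaf) {
    stopf("need at least min_leaf = %d observed target values", min_leaf)
  }
  y <- factor(target, DOSAGE_LEVELS)
  if (length(unique(target)) == 1L || is.null(predictors) ||
      NCOL(predictors) == 0) {
    return(structure(list(type = "marginal", donors = target),
                     class = "dosage_tree"))
  }
  df <- as.data.frame(predictors)
  df$.y <- droplevels(y)
  fit <- rpart::rpart(.y ~ ., data = df, method = "class",
                      control = rpart::rpart.control(
                        minsplit = 2L * min_leaf, minbucket = min_leaf,
                        cp = 0, xval = 0, maxcompete = 0,
                        maxsurrogate = 0, usesurrogate = 0))
  structure(list(type = "cart", fit = fit, donors = target),
            class = "dosage_tree")
}

#' Draw imputed dosages from a tree's donor pools
#'
#' Each row is routed down the tree to its terminal node and the imputed
#' dosage is drawn uniformly from that leaf's donors, independently across
#' rows. (Drawing a class with the leaf's class proportions is identical
#' in distribution to drawing a donor uniformly; the implementation uses
#' the leaf class proportions.) For a single-leaf tree this reduces to a
#' marginal draw from the observed values.
#'
#' @param tree a [cart_fit()] result.
#' @param newdata predictor values for the cells to impute (data frame or
#'   matrix with the columns the tree was fitted on); ignored for
#'   marginal trees except for its row count.
#' @param n for marginal trees without `newdata`, the number of draws.
#' @return numeric vector of imputed dosages in \{-1, 0, 1\}.
#' @export
cart_sample <- function(tree, newdata = NULL, n = NULL) {
  stopifnot(inherits(tree, "dosage_tree"))
  if (tree$type == "marginal") {
    n <- if (!is.null(newdata)) NROW(newdata) else n
    if (is.null(n)) stopf("number of draws unspecified for a marginal tree")
    return(sample(tree$donors, n, replace = TRUE))
  }
  prob <- stats::predict(tree$fit, as.data.frame(newdata), type = "prob")
  if (is.null(dim(prob))) prob <- matrix(prob, 1L, dimnames = list(NULL, names(prob)))
  lev <- as.numeric(colnames(prob))
  idx <- apply(prob, 1L, function(p) sample.int(length(lev), 1L, prob = p))
  lev[idx]
}

#' Multiply impute a dosage matrix by chained classification trees
#'
#' Runs `m` independent pseudo-Gibbs chains. Each chain initializes the
#' missing cells of every marker by marginal draws from that marker's
#' observed values, then performs `L` full sweeps; within a sweep, marker
#' `k` is re-imputed from a CART fitted on its `qsel` best predictors
#' (ranked once, from observed data, by marginal mutual information),
#' using the already-updated values of markers visited earlier in the
#' sweep and the previous sweep's values for the rest. The sweep visits
#' markers in ascending-missingness order (better-observed markers
#' stabilize first); complete markers are never re-imputed. Chains use
#' deterministic child seeds of `seed`, so the result is reproducible and
#' chains could run in parallel.
#'
#' @param X dosage matrix with missing values; every marker must have at
#'   least one observed call (run QC first).
#' @param m number of imputes (default 20).
#' @param L number of sweeps per chain (default 10).
#' @param qsel maximum predictors per marker (default 500).
#' @param min_leaf minimum donors per terminal node (default 5).
#' @param seed master seed.
#' @param visit `"missingness"` (default) or `"index"` sweep order.
#' @return an object of class `impute_set`: list with `imputes` (list of
#'   `m` complete matrices), `source` (the input), and `chain_params`.
#' @export
fcs_impute <- function(X, m = 20, L = 10, qsel = 500, min_leaf = 5,
                       seed = 1, visit = c("missingness", "index")) {
  check_dosages(X)
  visit <- match.arg(visit)
  q <- ncol(X); n <- nrow(X)
  n_mis <- colSums(is.na(X))
  if (any(n_mis == n)) {
    stopf("marker(s) with zero observed values (e.g. column %d); run QC first",
          which(n_mis == n)[1L])
  }
  mis_rows <- lapply(seq_len(q), function(j) which(is.na(X[, j])))
  obs_rows <- lapply(seq_len(q), function(j) which(!is.na(X[, j])))
  todo <- which(n_mis > 0)
  order_k <- if (visit == "missingness") todo[order(n_mis[todo], todo)] else todo

  pred_idx <- NULL
  if (length(todo) && q > 1) {
    mi <- mi_matrix(X)
    pred_idx <- lapply(seq_len(q), function(k) {
      if (n_mis[k] == 0) NULL else select_predictors(X, k, qsel, mi)$indices
    })
  }

  imputes <- vector("list", m)
  for (r in seq_len(m)) {
    imputes[[r]] <- with_seed(child_seed(seed, 100L + r), {
      cur <- X
      for (k in todo) {     # initialization: per-marker marginal draws
        cur[mis_rows[[k]], k] <- sample(X[obs_rows[[k]], k],
                                        n_mis[k], replace = TRUE)
      }
      if (length(todo) && q > 1) {
        for (l in seq_len(L)) {
          for (k in order_k) {
            pk <- pred_idx[[k]]
            tree <- cart_fit(X[obs_rows[[k]], k],
                             cur[obs_rows[[k]], pk, drop = FALSE], min_leaf)
            cur[mis_rows[[k]], k] <-
              cart_sample(tree, cur[mis_rows[[k]], pk, drop = FALSE])
          }
        }
      }
      cur
    })
  }
  structure(list(imputes = imputes, source = X,
                 chain_params = list(m = m, L = L, qsel = qsel,
                                     min_leaf = min_leaf, seed = seed,
                                     visit = visit)),
            class = "impute_set")
}

#' @export
print.impute_set <- function(x, ...) {
  p <- x$chain_params
  cat(sprintf("impute_set: m=%d imputes of a %d x %d matrix (L=%d, qsel=%d, min_leaf=%d, seed=%d)\n",
              p$m, nrow(x$source), ncol(x$source), p$L, p$qsel, p$min_leaf, p$seed))
  invisible(x)
}

#' Average-dosage matrix of an impute set
#'
#' Cell-wise mean of the `m` imputes; observed cells are unchanged and
#' imputed cells lie in `[-1, 1]`.
#'
#' @param S an [fcs_impute()] result.
#' @return numeric matrix.
#' @export
average_dosage <- function(S) {
  stopifnot(inherits(S, "impute_set"), length(S$imputes) >= 1)
  Reduce(`+`, S$imputes) / length(S$imputes)
}
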