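# Population structure (principal-component scores) and the realized
# genomic relationship matrix, plus cross-impute consistency.

#' Principal-component scores of a complete dosage matrix
#'
#' Column-centered PCA (no scaling). The sign of each component is fixed
#' by forcing its largest-magnitude loading positive, so scores are
#' comparable across imputes before taking absolute correlations.
#'
#' @param X complete dosage matrix (an average-dosage matrix or an
#'   impute); no missing entries.
#' @param t number of components to return; must be below the matrix
#'   rank.
#' @return list with `Q` (n x t score matrix), `explained_variance`
#'   (fractions for all components), and `rotation` (loadings for the
#'   first `t`).
#' @export
pca_scores <- function(X, t) {
  if (anyNA(X)) stopf("PCA input must be complete (impute or average-dosage matrix)")
  if (!is_count(t) || t < 1) stopf("t must be a count >= 1")
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  tol <- max(pc$sdev) * 1e-8
  rank <- sum(pc$sdev > tol)
  if (t > rank) stopf("t = %d exceeds the matrix rank (%d)", t, rank)
  flip <- vapply(seq_len(t), function(j) {
    l <- pc$rotation[, j]
    sign(l[which.max(abs(l))])
  }, numeric(1))
  Q <- sweep(pc$x[, seq_len(t), drop = FALSE], 2L, flip, `*`)
  rot <- sweep(pc$rotation[, seq_len(t), drop = FALSE], 2L, flip, `*`)
  colnames(Q) <- paste0("PC", seq_len(t))
  list(Q = Q, explained_variance = pc$sdev^2 / sum(pc$sdev^2), rotation = rot)
}

#' Realized genomic relationship matrix (VanRaden normalization)
#'
#' `K = W W' / c` with `W` the column-centered dosage matrix and
#' `c = sum_j 2 p_j (1 - p_j)`, where `p_j` is the alternate-allele
#' frequency of marker `j` estimated from the matrix at hand. Symmetric
#' and positive semidefinite by construction.
#'
#' @param X complete dosage matrix with at least 2 markers.
#' @param p optional vector of alternate-allele frequencies to use in the
#'   normalization constant (by default estimated from `X` itself, which
#'   assumes the -1/0/1 coding); supplying them makes `K` invariant to
#'   shifting a marker's dosages by a constant.
#' @return n x n relationship matrix.
#' @export
kinship <- function(X, p = NULL) {
  if (anyNA(X)) stopf("kinship input must be complete")
  if (ncol(X) < 2) stopf("kinship needs at least 2 markers")
  if (is.null(p)) p <- (colMeans(X) + 1) / 2
  c0 <- sum(2 * p * (1 - p))
  if (c0 <= 0) stopf("all markers monomorphic; relationship matrix undefined")
  W <- sweep(X, 2L, colMeans(X))
  K <- tcrossprod(W) / c0
  dimnames(K) <- list(rownames(X), rownames(X))
  K
}

#' Consistency of a structure variable across imputes
#'
#' The consistency of a per-impute quantity (a PC score vector, or a
#' relationship matrix) is the absolute Pearson correlation with the same
#' quantity computed from the average-dosage matrix, averaged over
#' imputes; the SD across imputes is reported alongside. Matrices are
#' compared on their vectorized lower triangle including the diagonal.
#'
#' @param per_impute list (length >= 2) of per-impute vectors or
#'   matrices.
#' @param reference the same quantity from the average-dosage matrix.
#' @return list with `mean` (average absolute correlation) and `sd`.
#' @export
consistency <- function(per_impute, reference) {
  if (length(per_impute) < 2) stopf("need at least 2 imputes")
  as_vec <- function(x) {
    if (is.matrix(x) && nrow(x) == ncol(x)) x[lower.tri(x, diag = TRUE)]
    else as.vector(x)
  }
  ref <- as_vec(reference)
  if (stats::sd(ref) == 0) stopf("reference has zero variance; correlation undefined")
  cors <- vapply(per_impute, function(x) {
    v <- as_vec(x)
    if (length(v) != length(ref)) stopf("impute and reference shapes differ")
    if (stats::sd(v) == 0) stopf("impute has zero variance; correlation undefined")
    abs(stats::cor(v, ref))
  }, numeric(1))
  list(mean = mean(cors), sd = stats::sd(cors))
}
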