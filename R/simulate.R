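# Synthetic GBS panel generator: population structure, LD blocks,
# calibrated per-marker missingness, and polygenic traits with known truth.

#' Per-marker missingness (PMV) distribution specifications
#'
#' A PMV distribution describes how the proportion of missing values is
#' drawn independently for each marker before MCAR masking. Three families
#' are provided:
#' \describe{
#'   \item{`pmv_dist_default()`}{A two-component scaled-beta mixture with
#'     mean exactly 0.78 and support `[0, 0.9)`: a small low-missingness
#'     component (weight 0.1, Beta(1.2, 2.4)) mimicking the minority of
#'     well-covered GBS tags, and a dominant high-missingness component
#'     (weight 0.9, Beta(12.5, 1)), both scaled by 0.9. This reproduces
#'     the ~78\% average missingness, with a wide right-skewed spread,
#'     typical of low-depth GBS after lenient per-panel filtering.}
#'   \item{`pmv_dist_beta(shape1, shape2, scale)`}{A single scaled beta.}
#'   \item{`pmv_dist_point(value)`}{A point mass (every marker gets the
#'     same PMV); `pmv_dist_point(0)` disables masking.}
#' }
#'
#' @param shape1,shape2 beta shape parameters (positive).
#' @param scale upper end of the support, in `(0, 1]`; values are drawn as
#'   `scale * Beta(shape1, shape2)` so the support is `[0, scale)`.
#' @param value PMV for every marker, in `[0, 1)`.
#' @return an object of class `pmv_dist`.
#' @seealso [pmv_mean()], [apply_mcar_mask()]
#' @export
pmv_dist_default <- function() {
  structure(list(family = "beta_mixture",
                 weights = c(0.1, 0.9),
                 shape1 = c(1.2, 12.5),
                 shape2 = c(2.4, 1.0),
                 scale = 0.9),
            class = "pmv_dist")
}

#' @rdname pmv_dist_default
#' @export
pmv_dist_beta <- function(shape1, shape2, scale = 1) {
  if (!(shape1 > 0 && shape2 > 0)) stopf("beta shapes must be positive")
  if (!(scale > 0 && scale <= 1)) stopf("PMV scale must be in (0, 1]")
  structure(list(family = "beta_mixture", weights = 1,
                 shape1 = shape1, shape2 = shape2, scale = scale),
            class = "pmv_dist")
}

#' @rdname pmv_dist_default
#' @export
pmv_dist_point <- function(value) {
  if (!is.numeric(value) || length(value) != 1L || is.na(value) ||
      value < 0 || value >= 1) {
    stopf("a point-mass PMV must lie in [0, 1)")
  }
  structure(list(family = "point", value = value), class = "pmv_dist")
}

#' Mean of a PMV distribution
#'
#' Closed-form mean of the per-marker missingness distribution; the
#' realized mean PMV of a masked panel converges to this value as the
#' number of markers grows.
#' @param dist a [pmv_dist_default()]-style object.
#' @return scalar in `[0, 1)`.
#' @export
pmv_mean <- function(dist) {
  stopifnot(inherits(dist, "pmv_dist"))
  switch(dist$family,
         point = dist$value,
         beta_mixture =
           dist$scale * sum(dist$weights * dist$shape1 /
                              (dist$shape1 + dist$shape2)),
         stopf("unknown PMV family '%s'", dist$family))
}

#' @noRd
pmv_draw <- function(dist, q) {
  stopifnot(inherits(dist, "pmv_dist"))
  switch(dist$family,
         point = rep(dist$value, q),
         beta_mixture = {
           comp <- sample.int(length(dist$weights), q, replace = TRUE,
                              prob = dist$weights)
           dist$scale * stats::rbeta(q, dist$shape1[comp], dist$shape2[comp])
         },
         stopf("unknown PMV family '%s'", dist$family))
}

#' Configuration for a synthetic GBS panel
#'
#' Defaults emulate the structure of a low-depth GBS diversity panel:
#' 500 individuals, 2000 biallelic markers in LD blocks of 5 with a
#' within-block target dosage correlation of 0.9, three subpopulations at
#' Fst 0.1 (a Balding-Nichols allele-frequency model), per-marker
#' missingness averaging 78\%, and a polygenic trait with unit polygenic
#' and residual variances.
#'
#' @param n_individuals,n_markers panel dimensions.
#' @param n_subpops number of subpopulations (>= 1).
#' @param fst differentiation among subpopulations, in `[0, 1)`; 0 means
#'   no structure.
#' @param ld_block_size markers per linkage-disequilibrium block; 1 means
#'   independent markers.
#' @param block_r target dosage correlation between a block's founder
#'   marker and the other markers of the block, in `[0, 1]`. May be a
#'   vector, recycled over blocks, to emulate heterogeneous LD.
#' @param pmv_dist per-marker missingness distribution
#'   (see [pmv_dist_default()]).
#' @param n_causal number of causal markers per trait.
#' @param effect_sizes per-allele effects of the causal markers (trait
#'   units); recycled to length `n_causal`.
#' @param mu trait intercept.
#' @param var_u polygenic variance (>= 0).
#' @param var_e residual variance (>= 0).
#' @param seed master seed; stages draw from deterministic child streams
#'   (1: allele frequencies and genotypes, 2: causal-marker selection,
#'   3: polygenic effects, 4: residuals, 5: MCAR mask).
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(n_individuals = 500, n_markers = 2000,
                       n_subpops = 3, fst = 0.1,
                       ld_block_size = 5, block_r = 0.9,
                       pmv_dist = pmv_dist_default(),
                       n_causal = 0, effect_sizes = numeric(0),
                       mu = 0, var_u = 1, var_e = 1, seed = 1) {
  if (!is_count(n_individuals) || n_individuals < 2) {
    stopf("n_individuals must be a count >= 2")
  }
  if (!is_count(n_markers) || n_markers < 1) stopf("n_markers must be a count >= 1")
  if (!is_count(n_subpops) || n_subpops < 1) stopf("n_subpops must be a count >= 1")
  if (!(fst >= 0 && fst < 1)) stopf("fst must lie in [0, 1)")
  if (!is_count(ld_block_size) || ld_block_size < 1) {
    stopf("ld_block_size must be a count >= 1")
  }
  if (any(block_r < 0 | block_r > 1)) stopf("block_r must lie in [0, 1]")
  if (!inherits(pmv_dist, "pmv_dist")) stopf("pmv_dist must be a 'pmv_dist' object")
  if (!is_count(n_causal) || n_causal > n_markers) {
    stopf("n_causal must be a count <= n_markers")
  }
  if (n_causal > 0 && length(effect_sizes) == 0) {
    stopf("effect_sizes required when n_causal > 0")
  }
  if (var_u < 0 || var_e < 0) stopf("variances must be >= 0")
  structure(list(n_individuals = as.integer(n_individuals),
                 n_markers = as.integer(n_markers),
                 n_subpops = as.integer(n_subpops), fst = fst,
                 ld_block_size = as.integer(ld_block_size), block_r = block_r,
                 pmv_dist = pmv_dist, n_causal = as.integer(n_causal),
                 effect_sizes = effect_sizes, mu = mu,
                 var_u = var_u, var_e = var_e, seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate complete genotypes with structure and LD blocks
#'
#' Subpopulation allele frequencies follow a Balding-Nichols scheme:
#' ancestral frequencies are uniform on (0.1, 0.9) (so the expected MAF is
#' 0.3) and subpopulation frequencies are Beta-distributed around them
#' with dispersion set by `fst`. Markers come in blocks: the first marker
#' of a block is the founder, drawn under Hardy-Weinberg at the
#' subpopulation frequency; every other marker of the block copies the
#' founder's dosage cell-wise and redraws each cell from the marginal with
#' probability `1 - block_r`, which makes the founder-copy dosage
#' correlation approximately `block_r`.
#'
#' @param config a [sim_config()].
#' @return a list with `genotypes` (complete n x q dosage matrix, entries
#'   in \{-1, 0, 1\}) and `truth` (class `sim_truth`: `causal_indices`,
#'   `causal_effects`, `true_var_u`, `true_var_e`, `subpop_labels`,
#'   `full_genotypes`, `block_id`).
#' @export
simulate_genotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_individuals
  q <- config$n_markers
  S <- config$n_subpops
  n_blocks <- ceiling(q / config$ld_block_size)
  block_id <- rep(seq_len(n_blocks), each = config$ld_block_size)[seq_len(q)]
  block_r <- rep_len(config$block_r, n_blocks)

  G <- with_seed(child_seed(config$seed, 1L), {
    subpop <- sort(rep_len(seq_len(S), n))
    p_anc <- stats::runif(n_blocks, 0.1, 0.9)   # one frequency per block founder
    freq <- matrix(NA_real_, S, n_blocks)
    for (s in seq_len(S)) {
      freq[s, ] <- if (config$fst == 0) p_anc else {
        a <- p_anc * (1 - config$fst) / config$fst
        b <- (1 - p_anc) * (1 - config$fst) / config$fst
        stats::rbeta(n_blocks, a, b)
      }
    }
    # founder dosage per block, Hardy-Weinberg within subpopulation
    p_ind <- freq[subpop, , drop = FALSE]             # n x n_blocks
    hwe_draw <- function(p) {
      u <- stats::runif(length(p))
      ifelse(u < (1 - p)^2, -1, ifelse(u < (1 - p)^2 + 2 * p * (1 - p), 0, 1))
    }
    founder <- matrix(hwe_draw(p_ind), n, n_blocks)
    X <- matrix(NA_real_, n, q)
    for (j in seq_len(q)) {
      b <- block_id[j]
      if (j == min(which(block_id == b))) {
        X[, j] <- founder[, b]
      } else {
        eps <- 1 - block_r[b]
        flip <- stats::runif(n) < eps
        col <- founder[, b]
        if (any(flip)) col[flip] <- hwe_draw(p_ind[flip, b])
        X[, j] <- col
      }
    }
    dimnames(X) <- list(paste0("ind", seq_len(n)), paste0("M", seq_len(q)))
    list(X = X, subpop = subpop)
  })

  causal <- with_seed(child_seed(config$seed, 2L), {
    if (config$n_causal > 0) sort(sample.int(q, config$n_causal)) else integer(0)
  })
  effects <- if (config$n_causal > 0) {
    rep_len(config$effect_sizes, config$n_causal)
  } else numeric(0)

  truth <- structure(list(causal_indices = causal, causal_effects = effects,
                          true_var_u = config$var_u, true_var_e = config$var_e,
                          subpop_labels = G$subpop, full_genotypes = G$X,
                          block_id = block_id),
                     class = "sim_truth")
  list(genotypes = G$X, truth = truth)
}

#' Mask genotype calls completely at random
#'
#' Draws a PMV for every marker from `pmv_dist`, then masks, per marker,
#' a uniformly random subset of cells of that size. Missingness depends on
#' nothing in the data (strict MCAR) and unmasked cells are untouched.
#'
#' @param G complete dosage matrix.
#' @param pmv_dist per-marker missingness distribution.
#' @param seed RNG seed for the masking stage.
#' @return the matrix with masked cells set to `NA`.
#' @export
apply_mcar_mask <- function(G, pmv_dist = pmv_dist_default(), seed = 1) {
  check_dosages(G)
  if (anyNA(G)) stopf("input to apply_mcar_mask must be complete")
  stopifnot(inherits(pmv_dist, "pmv_dist"))
  with_seed(seed, {
    n <- nrow(G)
    pmv <- pmv_draw(pmv_dist, ncol(G))
    for (j in seq_len(ncol(G))) {
      n_mis <- round(pmv[j] * n)
      if (n_mis > 0) G[sample.int(n, n_mis), j] <- NA
    }
    G
  })
}

#' Simulate a polygenic trait from a complete genotype matrix
#'
#' `g = mu + sum_j x_j beta_j + u + e` with `u ~ N(0, var_u * K)` where
#' `K` is the realized relationship matrix of the complete genotypes
#' (see [kinship()]), and `e` iid `N(0, var_e)`. If `K` is numerically
#' singular a jitter of `1e-8` is added to its diagonal before the
#' Cholesky factorization.
#'
#' @param truth a `sim_truth` from [simulate_genotypes()].
#' @param config the [sim_config()] (supplies `mu`, variances, seed).
#' @param seed optional override of the phenotype seed streams.
#' @return numeric trait vector of length `n_individuals`.
#' @export
simulate_phenotype <- function(truth, config, seed = config$seed) {
  stopifnot(inherits(truth, "sim_truth"), inherits(config, "sim_config"))
  X <- truth$full_genotypes
  n <- nrow(X)
  g <- rep(config$mu, n)
  if (length(truth$causal_indices)) {
    g <- g + as.vector(X[, truth$causal_indices, drop = FALSE] %*%
                         truth$causal_effects)
  }
  if (config$var_u > 0) {
    K <- kinship(X)
    R <- tryCatch(chol(config$var_u * K),
                  error = function(e) chol(config$var_u * K +
                                             diag(1e-8, n)))
    g <- g + with_seed(child_seed(seed, 3L),
                       as.vector(crossprod(R, stats::rnorm(n))))
  }
  if (config$var_e > 0) {
    g <- g + with_seed(child_seed(seed, 4L),
                       stats::rnorm(n, sd = sqrt(config$var_e)))
  }
  names(g) <- rownames(X)
  g
}

#' Simulate a full synthetic GBS study (genotypes, mask, traits)
#'
#' Convenience wrapper: complete genotypes, MCAR-masked observed matrix,
#' and `n_traits` polygenic traits, each with its own causal-marker draw
#' (causal sets are re-sampled per trait from independent child streams).
#'
#' @param config a [sim_config()].
#' @param n_traits number of traits to simulate.
#' @return list with `observed` (masked dosage matrix), `complete`,
#'   `traits` (n x n_traits matrix), `truth`, and `causal` (list of
#'   per-trait causal index vectors).
#' @export
simulate_panel <- function(config, n_traits = 1) {
  sim <- simulate_genotypes(config)
  observed <- apply_mcar_mask(sim$genotypes, config$pmv_dist,
                              seed = child_seed(config$seed, 5L))
  traits <- matrix(NA_real_, nrow(sim$genotypes), n_traits,
                   dimnames = list(rownames(sim$genotypes),
                                   paste0("trait", seq_len(n_traits))))
  causal <- vector("list", n_traits)
  for (tr in seq_len(n_traits)) {
    seed_tr <- child_seed(config$seed, 10L + tr)
    truth_tr <- sim$truth
    if (config$n_causal > 0) {
      truth_tr$causal_indices <- with_seed(child_seed(seed_tr, 2L),
        sort(sample.int(config$n_markers, config$n_causal)))
      truth_tr$causal_effects <- rep_len(config$effect_sizes, config$n_causal)
    }
    causal[[tr]] <- truth_tr$causal_indices
    traits[, tr] <- simulate_phenotype(truth_tr, config, seed = seed_tr)
  }
  list(observed = observed, complete = sim$genotypes, traits = traits,
       truth = sim$truth, causal = causal)
}
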