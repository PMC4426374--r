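# Internal helpers shared across modules.

#' Evaluate an expression under a fixed RNG seed
#'
#' Runs `expr` with the RNG seeded at `seed` and restores the caller's RNG
#' state afterwards, so seeded stages do not disturb the global stream.
#' @noRd
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Derive a child seed from a master seed
#'
#' One master seed spawns a deterministic child stream per pipeline stage
#' (and per imputation chain). Children are drawn by seeding the master
#' stream and taking the `index`-th draw, so streams are independent of
#' the order in which stages consume them. Kept below 2^31.
#' @noRd
child_seed <- function(seed, index) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, index)[index])
}

#' @noRd
stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

#' @noRd
is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0 && x == round(x)
}

#' Check that a dosage matrix has entries in {-1, 0, 1, NA}
#' @noRd
check_dosages <- function(X) {
  if (!is.matrix(X) || !is.numeric(X)) {
    stopf("dosage data must be a numeric matrix (individuals x markers)")
  }
  bad <- which(!(X %in% c(-1, 0, 1) | is.na(X)))
  if (length(bad)) {
    i <- arrayInd(bad[1L], dim(X))
    stopf("dosage value %s at row %d, column %d is not in {-1, 0, 1, NA}",
          format(X[bad[1L]]), i[1L], i[2L])
  }
  invisible(X)
}

#' @noRd
marker_ids <- function(X) {
  if (is.null(colnames(X))) paste0("M", seq_len(ncol(X))) else colnames(X)
}
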