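## Internal helpers shared across modules.

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores the global `.Random.seed`, so library code never
#' clobbers the caller's random stream.
#' @noRd
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (has_seed) old <- get(".Random.seed", envir = globalenv())
    on.exit({
      if (has_seed) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
  }
  force(code)
}

## single gate for count-valued arguments
check_count <- function(x, name, min = 1L) {
  if (length(x) != 1L || !is.finite(x) || x != as.integer(x) || x < min)
    stop(sprintf("`%s` must be a single integer >= %d", name, min),
         call. = FALSE)
  as.integer(x)
}

check_fraction <- function(x, name) {
  if (length(x) != 1L || !is.finite(x) || x < 0 || x > 1)
    stop(sprintf("`%s` must be a single value in [0, 1]", name), call. = FALSE)
  as.numeric(x)
}

check_nonneg <- function(x, name) {
  if (length(x) != 1L || !is.finite(x) || x < 0)
    stop(sprintf("`%s` must be a single non-negative number", name),
         call. = FALSE)
  as.numeric(x)
}

#' Column-standardize a matrix (zero mean, unit variance)
#'
#' Constant columns are dropped with a warning, matching the preprocessing
#' contract of the canonical-model fitters.
#' @param x numeric matrix.
#' @return standardized matrix, possibly with fewer columns.
#' @export
standardize_columns <- function(x) {
  x <- as.matrix(x)
  sds <- apply(x, 2L, stats::sd)
  keep <- is.finite(sds) & sds > 0
  if (!all(keep)) {
    warning(sprintf("dropping %d constant column(s): %s",
                    sum(!keep),
                    paste(utils::head(colnames(x)[!keep], 5L),
                          collapse = ", ")),
            call. = FALSE)
    x <- x[, keep, drop = FALSE]
    sds <- sds[keep]
  }
  scale(x, center = TRUE, scale = sds)[, , drop = FALSE]
}

l2norm <- function(x) sqrt(sum(x^2))
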