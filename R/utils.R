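#' dosestrat: dose-pattern stratification of radiotherapy patients
#'
#' Clusters patients on multi-organ DVH dose features, identifies the
#' high-dose cluster, distills it into threshold rules, and evaluates both
#' stratifications against clinical covariates and NTCP models.
#'
#' @importFrom graphics matplot axis legend
#' @keywords internal
"_PACKAGE"

# Run `expr` under a local RNG seeded with `seed`, restoring the caller's
# RNG state afterwards.  seed = NULL leaves the global stream untouched.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("`seed` must be a single finite number", call. = FALSE)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same items;
#' 1 for identical partitions (up to relabeling), ~0 for independent ones.
#' Used to compare recovered dose clusters with planted groups.
#'
#' @param a,b label vectors of equal length (any atomic type).
#' @return a number in (-1, 1].
#' @export
adjusted_rand <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) > 0L)
  tab <- table(a, b)
  n <- length(a)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  expected <- sum_a * sum_b / comb2(n)
  max_idx <- (sum_a + sum_b) / 2
  if (max_idx == expected) return(1)  # both partitions trivial
  (sum_ij - expected) / (max_idx - expected)
}

# deterministic argmin over rows of a list-of-keys ordering; keys is a list
# of atomic vectors compared in sequence (ascending).
order_by_keys <- function(keys) {
  do.call(order, keys)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
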