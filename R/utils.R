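`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(...) stop(sprintf(...), call. = FALSE)
warnf <- function(...) warning(sprintf(...), call. = FALSE)

#' Evaluate an expression under a temporary RNG seed
#'
#' Sets the RNG seed, evaluates `code`, and restores the previous RNG state,
#' so library code never clobbers the caller's random stream. A `NULL` seed
#' evaluates `code` with the current stream untouched.
#'
#' @param seed Integer seed or `NULL`.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else suppressWarnings(rm(".Random.seed", envir = globalenv()))
  }, add = TRUE)
  set.seed(seed)
  code
}

# Draw child seeds from a parent seed (kept < 2^31 so they remain valid
# R integer seeds); used for per-sample independent streams.
child_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

check_number <- function(x, name, min = -Inf, max = Inf,
                         allow_min = TRUE, allow_max = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x))
    stopf("'%s' must be a single number", name)
  lo_ok <- if (allow_min) x >= min else x > min
  hi_ok <- if (allow_max) x <= max else x < max
  if (!lo_ok || !hi_ok)
    stopf("'%s' = %g is outside its allowed range (%s%g, %g%s)",
          name, x, if (allow_min) "[" else "(", min, max,
          if (allow_max) "]" else ")")
  invisible(x)
}

check_count_vector <- function(x, name = "counts") {
  if (!is.numeric(x) || length(x) == 0L)
    stopf("'%s' must be a non-empty numeric vector", name)
  if (anyNA(x) || any(x < 0) || any(x != round(x)))
    stopf("'%s' must contain non-negative integers", name)
  if (sum(x) < 1)
    stopf("'%s' must contain at least one positive count", name)
  invisible(x)
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same items;
#' 1 for identical partitions, ~0 for independent ones. Used to score how
#' well a dendrogram cut recovers known sample blocks.
#'
#' @param a,b Vectors (factor, character or integer) of equal length giving
#'   the two partitions.
#' @return A single number in (-1, 1].
#' @export
#' @examples
#' adjusted_rand_index(c(1, 1, 2, 2), c("a", "a", "b", "b"))
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b)) stopf("partitions must have equal length")
  tab <- table(a, b)
  n <- length(a)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)
  (sum_ij - expected) / (max_index - expected)
}
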