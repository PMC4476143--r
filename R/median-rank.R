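#' Rank-abundance vector
#'
#' Canonical per-sample descending abundance profile: zeros are dropped,
#' the remaining abundances are sorted non-increasing (ties broken by
#' original position for determinism) and normalized to sum to 1. Accepts
#' raw counts or fractions; the result is identical either way (scale
#' invariance).
#'
#' @param x Non-negative numeric vector of abundances for one sample.
#' @param sample_id Optional label carried in the `sample_id` attribute.
#' @return Numeric vector of class `rank_abundance`.
#' @export
#' @examples
#' rank_abundance(c(1, 5, 0, 4))
rank_abundance <- function(x, sample_id = NULL) {
  if (!is.numeric(x) || length(x) == 0L)
    stopf("'x' must be a non-empty numeric vector")
  if (anyNA(x) || any(x < 0)) stopf("abundances must be non-negative")
  x <- x[x > 0]
  if (length(x) == 0L) stopf("all abundances are zero")
  ord <- order(x, seq_along(x), decreasing = c(TRUE, FALSE), method = "radix")
  f <- x[ord] / sum(x)
  structure(f, sample_id = sample_id, class = "rank_abundance")
}

#' Interpolated median rank
#'
#' The dominance statistic of this package: the rank at which the cumulative
#' normalized descending-abundance curve reaches 0.5. The cumulative curve
#' is piecewise linear through \eqn{(0, 0)} and \eqn{(k, \sum_{i \le k} f_i)}
#' for \eqn{k = 1..S}; the statistic is the unique `r` with `C(r) = 0.5`
#' (a tie landing exactly on a knot returns the knot rank). Anchoring at
#' `(0, 0)` is what permits values below 1: a community whose top OTU holds
#' more than half the sequences has median rank `0.5 / f1 < 1`. The value is
#' interpretable as the number of abundant OTUs — the OTUs making up the top
#' half of the community.
#'
#' @param x A [rank_abundance()] object, or any non-negative abundance
#'   vector (it will be canonicalized first).
#' @return A single positive number in `(0, S]` with attribute `n_otus`.
#' @export
#' @examples
#' interpolated_median_rank(c(0.4, 0.3, 0.2, 0.1))  # 1.3333
#' interpolated_median_rank(rep(0.25, 4))           # 2 (knot tie)
interpolated_median_rank <- function(x) {
  if (!inherits(x, "rank_abundance")) x <- rank_abundance(x)
  f <- as.numeric(x)
  cum <- cumsum(f)
  k <- which(cum >= 0.5 - 1e-12)[1]
  if (is.na(k)) k <- length(f)  # guard against rounding at the last knot
  r <- if (abs(cum[k] - 0.5) <= 1e-12) k
  else (k - 1) + (0.5 - if (k > 1) cum[k - 1] else 0) / f[k]
  structure(r, n_otus = length(f))
}

#' Median ranks for every sample of a table
#'
#' @param x An [otu_table()].
#' @return A `data.frame` with columns `sample_id`, `median_rank`, `n_otus`.
#' @export
median_rank_table <- function(x) {
  stopifnot(inherits(x, "otu_table"))
  res <- lapply(rownames(x$counts), function(id) {
    r <- interpolated_median_rank(x$counts[id, ])
    data.frame(sample_id = id, median_rank = as.numeric(r),
               n_otus = attr(r, "n_otus"), stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Classify median ranks into stable and outlier classes
#'
#' Samples inside the stable band (default ranks 1–4, inclusive) are
#' `stable`; below it `low_outlier` (one OTU holds more than half the
#' community); at or above the high band's lower edge (default 6)
#' `high_outlier`; in between `intermediate`. In the kill-the-winner
#' reading, low outliers are pre-crash dominated communities and high
#' outliers are freshly crashed ones with 6–7 competitors sharing the top
#' half.
#'
#' @param ranks Numeric vector of median ranks (or the data frame from
#'   [median_rank_table()]).
#' @param stable_range Length-2 inclusive stable band, default `c(1, 4)`.
#' @param high_range Length-2 high-outlier band; only its lower edge is
#'   used, default `c(6, 7)`.
#' @return A list with `class` (factor aligned with the input) and `counts`
#'   (named integer vector over the four classes).
#' @export
classify_median_ranks <- function(ranks, stable_range = c(1, 4),
                                  high_range = c(6, 7)) {
  if (is.data.frame(ranks)) ranks <- ranks$median_rank
  if (length(ranks) == 0L) stopf("no median ranks supplied")
  if (length(stable_range) != 2 || length(high_range) != 2 ||
      stable_range[1] >= stable_range[2] || high_range[1] >= high_range[2] ||
      stable_range[2] > high_range[1])
    stopf("malformed classification ranges")
  lev <- c("low_outlier", "stable", "intermediate", "high_outlier")
  cls <- ifelse(ranks < stable_range[1], "low_outlier",
         ifelse(ranks <= stable_range[2], "stable",
         ifelse(ranks >= high_range[1], "high_outlier", "intermediate")))
  cls <- factor(cls, levels = lev)
  counts <- table(cls)
  list(class = cls, counts = stats::setNames(as.integer(counts), lev))
}

#' Outlier dwell fraction
#'
#' Fraction of samples whose median rank falls outside the stable band —
#' under the assumption that snapshots are taken uniformly along
#' kill-the-winner cycles, this estimates the fraction of cycle time spent
#' in the transient (crash and recovery) stages. Every non-stable sample
#' counts as an outlier. An exact Clopper–Pearson binomial interval is
#' attached.
#'
#' @param classes Factor from [classify_median_ranks()], or a numeric vector
#'   of median ranks (classified with default bands), or the list returned
#'   by [classify_median_ranks()].
#' @param conf Confidence level, default 0.95.
#' @return A list with `fraction`, `n_outlier`, `n`, and `conf_int`.
#' @export
#' @examples
#' dwell_fraction(c(0.8, rep(2, 81), 6.5, 6.2, 6.8))  # 4 of 85
dwell_fraction <- function(classes, conf = 0.95) {
  if (is.list(classes) && !is.null(classes$class)) classes <- classes$class
  if (is.numeric(classes)) classes <- classify_median_ranks(classes)$class
  n <- length(classes)
  if (n == 0L) stopf("no classifications supplied")
  x <- sum(classes != "stable")
  alpha <- 1 - conf
  lower <- if (x == 0) 0 else stats::qbeta(alpha / 2, x, n - x + 1)
  upper <- if (x == n) 1 else stats::qbeta(1 - alpha / 2, x + 1, n - x)
  list(fraction = x / n, n_outlier = x, n = n, conf_int = c(lower, upper))
}
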