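#' Analytic rarefaction curve
#'
#' Expected OTU richness in a random subsample of `n` of the `N` sequences,
#' computed hypergeometrically:
#' \deqn{E[S_n] = \sum_i \left[1 - \binom{N - N_i}{n} / \binom{N}{n}\right]}
#' Evaluated at `n = step, 2*step, ..., N` (the full depth `N` is always
#' included). Binomial coefficients are computed in log space so deep
#' samples do not overflow. The curve is non-decreasing, concave, starts at
#' `E[S_1] = 1` and ends at the observed richness; a community of singletons
#' lies exactly on the 1:1 line.
#'
#' @param counts Non-negative integer vector of per-OTU counts for one
#'   sample (zeros are ignored).
#' @param step Evaluation spacing in sequences (default 1).
#' @return A `data.frame` with columns `n` and `expected_richness`, class
#'   `rarefaction_curve`.
#' @export
#' @examples
#' rarefaction_curve(c(2, 1))
rarefaction_curve <- function(counts, step = 1) {
  check_count_vector(counts)
  check_number(step, "step", min = 1)
  counts <- counts[counts > 0]
  n_total <- sum(counts)
  grid <- unique(c(seq(step, n_total, by = step), n_total))
  expected <- vapply(grid, function(n) {
    keep <- n_total - counts >= n
    miss <- numeric(length(counts))
    miss[keep] <- exp(lchoose(n_total - counts[keep], n) -
                        lchoose(n_total, n))
    sum(1 - miss)
  }, numeric(1))
  structure(data.frame(n = grid, expected_richness = expected),
            class = c("rarefaction_curve", "data.frame"))
}

#' Chao1 minimum-richness estimator
#'
#' Nonparametric lower bound on richness from singleton (F1) and doubleton
#' (F2) counts. The `"classic"` form is \eqn{S_{obs} + F_1^2 / (2 F_2)}; the
#' default `"bias_corrected"` form, \eqn{S_{obs} + F_1(F_1 - 1)/(2(F_2+1))},
#' is defined even when no doubletons exist, and the classic form falls back
#' to it (with a warning) when `F2 = 0`. Always at least `S_obs`.
#'
#' @param counts Non-negative integer vector of per-OTU counts.
#' @param variant `"bias_corrected"` (default) or `"classic"`.
#' @return Estimate (single number) with attribute `variant` recording the
#'   form actually used.
#' @export
#' @examples
#' chao1(c(rep(4, 4), rep(1, 4), rep(2, 2)))  # S=10, F1=4, F2=2 -> 12
chao1 <- function(counts, variant = c("bias_corrected", "classic")) {
  variant <- match.arg(variant)
  check_count_vector(counts)
  counts <- counts[counts > 0]
  s_obs <- length(counts)
  f1 <- sum(counts == 1)
  f2 <- sum(counts == 2)
  if (variant == "classic" && f2 == 0) {
    warnf("chao1: no doubletons; falling back to the bias-corrected form")
    variant <- "bias_corrected"
  }
  est <- if (variant == "classic") s_obs + f1^2 / (2 * f2)
  else s_obs + f1 * (f1 - 1) / (2 * (f2 + 1))
  structure(est, variant = variant)
}

#' Inverse Simpson diversity index
#'
#' Reciprocal of the probability that two randomly drawn sequences belong to
#' the same OTU. The `"plugin"` form is \eqn{1 / \sum p_i^2} on the observed
#' fractions; it ranges from 1 (a single OTU) to the number of OTUs
#' (perfectly even community). The default `"unbiased"` finite-sample form
#' (the mothur convention) is \eqn{N(N-1) / \sum n_i (n_i - 1)}; it is
#' infinite when every OTU is a singleton, which is reported as `Inf` with a
#' warning.
#'
#' @param counts Non-negative integer vector of per-OTU counts.
#' @param estimator `"unbiased"` (default) or `"plugin"`.
#' @return A single number.
#' @export
#' @examples
#' inverse_simpson(c(50, 30, 20), "plugin")    # 1/0.38
#' inverse_simpson(c(50, 30, 20))              # 9900/3700
inverse_simpson <- function(counts, estimator = c("unbiased", "plugin")) {
  estimator <- match.arg(estimator)
  check_count_vector(counts)
  counts <- counts[counts > 0]
  n_total <- sum(counts)
  if (estimator == "plugin") {
    p <- counts / n_total
    return(1 / sum(p^2))
  }
  if (n_total < 2)
    stopf("unbiased inverse Simpson requires at least 2 sequences")
  denom <- sum(counts * (counts - 1))
  if (denom == 0) {
    warnf("inverse_simpson: all OTUs are singletons; unbiased estimate is infinite")
    return(Inf)
  }
  n_total * (n_total - 1) / denom
}

#' Per-sample alpha-diversity table
#'
#' Tidy summary of observed richness, Chao1 (bias-corrected default) and
#' both inverse Simpson estimators for every sample of an OTU table.
#'
#' @param x An [otu_table()].
#' @param chao1_variant Passed to [chao1()].
#' @return A `data.frame` with columns `sample_id`, `metric`, `variant`,
#'   `value`.
#' @export
alpha_diversity <- function(x, chao1_variant = "bias_corrected") {
  stopifnot(inherits(x, "otu_table"))
  rows <- lapply(rownames(x$counts), function(id) {
    cts <- x$counts[id, ]
    ch <- chao1(cts, chao1_variant)
    data.frame(
      sample_id = id,
      metric = c("s_obs", "chao1", "inv_simpson", "inv_simpson"),
      variant = c("observed", attr(ch, "variant"), "plugin", "unbiased"),
      value = c(sum(cts > 0), as.numeric(ch),
                inverse_simpson(cts, "plugin"),
                inverse_simpson(cts, "unbiased")),
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
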