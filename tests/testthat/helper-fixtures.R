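# Fixtures are built in code; no data files ship with the tests.

tiny_counts <- function() {
  matrix(c(5, 0, 1,
           0, 2, 2,
           3, 3, 0), nrow = 3, byrow = TRUE,
         dimnames = list(c("S1", "S2", "S3"), c("Otu0001", "Otu0002", "Otu0003")))
}

tiny_table <- function() otu_table(tiny_counts())

random_table <- function(n_samples = 6, n_otus = 20, seed = 1,
                         depth = 500) {
  set.seed(seed)
  counts <- t(vapply(seq_len(n_samples), function(i) {
    p <- rgamma(n_otus, 0.3)
    as.numeric(rmultinom(1, depth, p / sum(p)))
  }, numeric(n_otus)))
  dimnames(counts) <- list(sprintf("S%02d", seq_len(n_samples)),
                           sprintf("Otu%04d", seq_len(n_otus)))
  otu_table(counts)
}

write_shared_fixture <- function(counts, path = tempfile(fileext = ".shared"),
                                 label = "0.03") {
  df <- data.frame(label = label, Group = rownames(counts),
                   numOtus = ncol(counts), counts, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

write_meta_fixture <- function(lines, path = tempfile(fileext = ".csv")) {
  writeLines(lines, path)
  path
}

# Brute-force oracle for the interpolated median rank: root of the
# piecewise-linear cumulative curve through (0,0),(k, cumsum)[k], found by
# bisection, independent of the production interpolation arithmetic.
median_rank_oracle <- function(fractions) {
  f <- sort(fractions[fractions > 0], decreasing = TRUE)
  f <- f / sum(f)
  cum_fun <- approxfun(c(0, seq_along(f)), c(0, cumsum(f)))
  uniroot(function(r) cum_fun(r) - 0.5, c(1e-12, length(f)),
          tol = 1e-13)$root
}

# Exhaustive rarefaction oracle: mean richness over all n-subsets of the N
# individuals (feasible for N <= 12).
rarefaction_oracle <- function(counts, n) {
  pool <- rep(seq_along(counts), counts)
  subsets <- combn(length(pool), n)
  mean(apply(subsets, 2, function(idx) length(unique(pool[idx]))))
}

# Exact PERMANOVA p by complete enumeration of distinct two-group label
# assignments (quotient of all label permutations).
permanova_exact_p <- function(d, groups) {
  d2 <- as.matrix(d)^2
  n <- nrow(d2)
  levs <- unique(groups)
  stopifnot(length(levs) == 2)
  n1 <- sum(groups == levs[1])
  f_of <- function(g) {
    ss_t <- sum(d2) / (2 * n)
    ss_w <- sum(vapply(unique(g), function(l) {
      idx <- which(g == l)
      sum(d2[idx, idx]) / (2 * length(idx))
    }, numeric(1)))
    ((ss_t - ss_w) / 1) / (ss_w / (n - 2))
  }
  f_obs <- f_of(groups)
  assignments <- combn(n, n1)
  fs <- apply(assignments, 2, function(idx) {
    g <- rep(levs[2], n)
    g[idx] <- levs[1]
    f_of(g)
  })
  mean(fs >= f_obs - 1e-12)
}
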