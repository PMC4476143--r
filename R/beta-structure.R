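#' Between-sample distance matrix
#'
#' Dissimilarities are computed on relative abundances by default (the
#' between-sample tests in this package operate on normalized profiles);
#' `normalize = FALSE` uses raw counts. Definitions for samples `x`, `y`
#' over OTUs `i`:
#' \describe{
#'   \item{bray_curtis}{\eqn{1 - 2\sum_i \min(x_i, y_i) / (\sum_i x_i +
#'     \sum_i y_i)}; bounded in \[0, 1\].}
#'   \item{euclidean}{\eqn{\sqrt{\sum_i (x_i - y_i)^2}}}
#'   \item{manhattan}{\eqn{\sum_i |x_i - y_i|}}
#'   \item{canberra}{\eqn{\sum_{i: x_i + y_i > 0} |x_i - y_i| / (x_i + y_i)}}
#' }
#'
#' @param x An [otu_table()] or a plain numeric matrix (samples in rows).
#' @param metric One of `"bray_curtis"`, `"euclidean"`, `"manhattan"`,
#'   `"canberra"`.
#' @param normalize Divide each row by its sum first (default `TRUE`).
#' @return An object of class `distance_matrix`: list with `ids`, symmetric
#'   numeric matrix `d` (zero diagonal), and `metric`.
#' @export
distance_matrix <- function(x, metric = c("bray_curtis", "euclidean",
                                          "manhattan", "canberra"),
                            normalize = TRUE) {
  metric <- match.arg(metric)
  m <- if (inherits(x, "otu_table")) {
    if (normalize) relative_abundance(x) else x$counts
  } else {
    m0 <- as.matrix(x)
    if (normalize) sweep(m0, 1, rowSums(m0), "/") else m0
  }
  n <- nrow(m)
  if (n < 2) stopf("need at least 2 samples for a distance matrix")
  ids <- rownames(m) %||% paste0("S", seq_len(n))
  d <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      a <- m[i, ]; b <- m[j, ]
      d[i, j] <- d[j, i] <- switch(metric,
        bray_curtis = 1 - 2 * sum(pmin(a, b)) / (sum(a) + sum(b)),
        euclidean = sqrt(sum((a - b)^2)),
        manhattan = sum(abs(a - b)),
        canberra = {
          s <- a + b
          keep <- s > 0
          sum(abs(a[keep] - b[keep]) / s[keep])
        })
    }
  }
  structure(list(ids = ids, d = d, metric = metric),
            class = "distance_matrix")
}

#' @export
as.dist.distance_matrix <- function(m, diag = FALSE, upper = FALSE)
  stats::as.dist(m$d, diag = diag, upper = upper)

#' @export
print.distance_matrix <- function(x, ...) {
  cat(sprintf("distance_matrix: %d samples, metric %s\n",
              length(x$ids), x$metric))
  invisible(x)
}

#' UPGMA (average-linkage) dendrogram
#'
#' Unweighted pair-group average-linkage hierarchical clustering of a
#' distance matrix, via [stats::hclust()] with `method = "average"`. Merge
#' heights are non-decreasing from leaves to root; identical samples merge
#' at height 0.
#'
#' @param dm A [distance_matrix()] (or `dist`).
#' @return Object of class `upgma_dendrogram`: list with the `hclust` fit,
#'   `ids`, and (after [jaccard_stability()]) per-internal-node `stability`.
#' @export
upgma <- function(dm) {
  d <- if (inherits(dm, "distance_matrix")) stats::as.dist(dm$d) else
    stats::as.dist(dm)
  hc <- stats::hclust(d, method = "average")
  structure(list(hclust = hc, ids = hc$labels, stability = NULL,
                 metric = if (inherits(dm, "distance_matrix")) dm$metric
                          else "user"),
            class = "upgma_dendrogram")
}

#' @export
print.upgma_dendrogram <- function(x, ...) {
  cat(sprintf("upgma_dendrogram: %d leaves (%s distances)%s\n",
              length(x$ids), x$metric,
              if (is.null(x$stability)) ""
              else sprintf("; Jaccard stability on %d nodes",
                           length(x$stability))))
  invisible(x)
}

# Leaf-label sets for each internal node (row of hclust's merge matrix).
node_leafsets <- function(hc) {
  n_nodes <- nrow(hc$merge)
  sets <- vector("list", n_nodes)
  for (i in seq_len(n_nodes)) {
    members <- unlist(lapply(hc$merge[i, ], function(m)
      if (m < 0) hc$labels[-m] else sets[[m]]))
    sets[[i]] <- members
  }
  sets
}

jaccard_sets <- function(a, b) {
  u <- length(union(a, b))
  if (u == 0) return(0)
  length(intersect(a, b)) / u
}

#' Bootstrap Jaccard stability of UPGMA clusters
#'
#' Assesses how reproducible each internal node of the reference UPGMA tree
#' is under resampling of samples. For each of `B` bootstrap resamples
#' (samples drawn with replacement), distances and the UPGMA tree are
#' recomputed on the unique samples present; each reference node's leaf set,
#' restricted to the samples present in the resample, is matched against all
#' clusters of the bootstrap tree (internal nodes and singleton leaves) and
#' scored by the best Jaccard similarity. The per-node mean over resamples
#' is reported on a 0–100 scale with a three-tier flag: `>75` (highly
#' stable), `60-75` (moderately stable), `<60` (unstable).
#'
#' @param x An [otu_table()] or numeric matrix.
#' @param metric,normalize Passed to [distance_matrix()].
#' @param B Number of bootstrap resamples (default 100).
#' @param seed RNG seed for reproducibility.
#' @return A `upgma_dendrogram` whose `stability` is a numeric vector (one
#'   entry per internal node, in `hclust` merge order) and `tier` the
#'   matching factor.
#' @export
jaccard_stability <- function(x, metric = "bray_curtis", normalize = TRUE,
                              B = 100, seed = NULL) {
  check_number(B, "B", min = 1)
  m <- if (inherits(x, "otu_table")) {
    if (normalize) relative_abundance(x) else x$counts
  } else as.matrix(x)
  dm <- distance_matrix(m, metric, normalize = FALSE)
  dend <- upgma(dm)
  ref_sets <- node_leafsets(dend$hclust)
  n <- nrow(m)
  contrib <- matrix(NA_real_, length(ref_sets), B)
  with_seed(seed, {
    for (b in seq_len(B)) {
      present <- character(0)
      while (length(present) < 3) {
        present <- sort(unique(sample(rownames(m), n, replace = TRUE)))
      }
      dm_b <- distance_matrix(m[present, , drop = FALSE], metric,
                              normalize = FALSE)
      hc_b <- upgma(dm_b)$hclust
      boot_sets <- c(node_leafsets(hc_b), as.list(present))
      for (k in seq_along(ref_sets)) {
        restricted <- intersect(ref_sets[[k]], present)
        if (length(restricted) == 0) next
        contrib[k, b] <- max(vapply(boot_sets, jaccard_sets, numeric(1),
                                    a = restricted))
      }
    }
  })
  stability <- 100 * rowMeans(contrib, na.rm = TRUE)
  dend$stability <- stability
  dend$tier <- cut(stability, c(-Inf, 60, 75, Inf),
                   labels = c("<60", "60-75", ">75"), right = FALSE)
  dend$B <- B
  dend
}

#' Export a dendrogram as Newick
#'
#' Writes an ultrametric Newick string in which leaf depths equal half the
#' merge heights and internal node labels carry the Jaccard stability means
#' (if present, rounded to one decimal).
#'
#' @param dend A `upgma_dendrogram`.
#' @param path Optional output path; when `NULL` the string is returned.
#' @return The Newick string (invisibly when written to a file).
#' @export
write_newick <- function(dend, path = NULL) {
  hc <- dend$hclust
  heights <- hc$height
  stab <- dend$stability
  build <- function(node, parent_h) {
    if (node < 0) {
      sprintf("%s:%g", hc$labels[-node], parent_h / 2)
    } else {
      h <- heights[node]
      lab <- if (!is.null(stab)) sprintf("%.1f", stab[node]) else ""
      sprintf("(%s,%s)%s:%g",
              build(hc$merge[node, 1], h), build(hc$merge[node, 2], h),
              lab, (parent_h - h) / 2)
    }
  }
  root <- nrow(hc$merge)
  nwk <- sprintf("(%s,%s)%s;",
                 build(hc$merge[root, 1], heights[root]),
                 build(hc$merge[root, 2], heights[root]),
                 if (!is.null(stab)) sprintf("%.1f", stab[root]) else "")
  if (is.null(path)) return(nwk)
  writeLines(nwk, path)
  invisible(nwk)
}

# Anderson-style pseudo-F from a squared distance matrix and a grouping.
# SS_T = (1/N) sum_{i<j} d2_ij ; SS_W = sum_g (1/n_g) sum_{i<j in g} d2_ij.
permanova_f <- function(d2, groups) {
  n <- nrow(d2)
  levs <- unique(groups)
  a <- length(levs)
  ss_t <- sum(d2) / (2 * n)
  ss_w <- 0
  for (g in levs) {
    idx <- which(groups == g)
    ss_w <- ss_w + sum(d2[idx, idx]) / (2 * length(idx))
  }
  ss_a <- ss_t - ss_w
  list(f = (ss_a / (a - 1)) / (ss_w / (n - a)),
       ss_t = ss_t, ss_w = ss_w, ss_a = ss_a,
       df_among = a - 1, df_within = n - a)
}

#' Permutational MANOVA on a distance matrix
#'
#' One-way PERMANOVA: the pseudo-F statistic
#' \deqn{F = \frac{SS_A / (a - 1)}{SS_W / (N - a)}}
#' with \eqn{SS_T = \frac1N \sum_{i<j} d_{ij}^2}, \eqn{SS_W = \sum_g
#' \frac1{n_g}\sum_{i<j \in g} d_{ij}^2} and \eqn{SS_A = SS_T - SS_W},
#' tested by whole-sample permutation of the group labels:
#' \eqn{p = (1 + \#\{F^* \ge F\}) / (1 + n_{perm})}, so the smallest
#' attainable p is \eqn{1/(n_{perm}+1)}.
#'
#' @param dm A [distance_matrix()] (or `dist`, or square matrix).
#' @param groups Factor/character grouping aligned with the samples of `dm`
#'   (or named by sample id). Every group needs at least 2 members.
#' @param n_permutations Number of label permutations (default 9999).
#' @param seed RNG seed.
#' @param factor_name Label stored in the result.
#' @return List of class `permanova`: `factor_name`, `f`, `p`, `df_among`,
#'   `df_within`, `n_permutations`, `n`. When all samples are identical the
#'   statistic is undefined and reported as `NA` with a warning.
#' @export
permanova <- function(dm, groups, n_permutations = 9999, seed = NULL,
                      factor_name = deparse(substitute(groups))) {
  d <- if (inherits(dm, "distance_matrix")) dm$d else as.matrix(dm)
  n <- nrow(d)
  ids <- rownames(d)
  groups <- align_groups(groups, ids, n)
  sizes <- table(groups)
  if (length(sizes) < 2) stopf("need at least 2 groups")
  if (any(sizes < 2))
    stopf("singleton group(s): %s",
          paste(names(sizes)[sizes < 2], collapse = ", "))
  d2 <- d^2
  obs <- permanova_f(d2, groups)
  if (obs$ss_w <= 0 || !is.finite(obs$f)) {
    warnf("permanova: within-group sum of squares is zero; pseudo-F undefined")
    return(structure(list(factor_name = factor_name, f = NA_real_,
                          p = NA_real_, df_among = obs$df_among,
                          df_within = obs$df_within,
                          n_permutations = n_permutations, n = n),
                     class = "permanova"))
  }
  exceed <- with_seed(seed, {
    sum(vapply(seq_len(n_permutations), function(b) {
      permanova_f(d2, groups[sample.int(n)])$f >= obs$f - 1e-12
    }, logical(1)))
  })
  structure(list(factor_name = factor_name, f = obs$f,
                 p = (1 + exceed) / (1 + n_permutations),
                 df_among = obs$df_among, df_within = obs$df_within,
                 n_permutations = n_permutations, n = n),
            class = "permanova")
}

align_groups <- function(groups, ids, n) {
  g <- as.character(groups)
  if (!is.null(names(groups)) && !is.null(ids)) {
    missing <- setdiff(ids, names(groups))
    if (length(missing) > 0)
      stopf("groups missing for sample(s): %s", paste(missing, collapse = ", "))
    g <- as.character(groups[ids])
  }
  if (length(g) != n)
    stopf("grouping length (%d) does not match sample count (%d)",
          length(g), n)
  g
}

#' @export
print.permanova <- function(x, ...) {
  cat(sprintf("PERMANOVA [%s]: F = %.4g (df %d, %d), p = %.4g (%d permutations, n = %d)\n",
              x$factor_name, x$f, x$df_among, x$df_within, x$p,
              x$n_permutations, x$n))
  invisible(x)
}

#' Pairwise PERMANOVA over all level pairs
#'
#' Runs [permanova()] on every unordered pair of group levels, restricted to
#' the samples of those two levels. Raw p-values are reported by default; a
#' Benjamini-Hochberg adjusted column can be added. Pairs in which a level
#' has fewer than 2 samples are skipped with a warning.
#'
#' @inheritParams permanova
#' @param adjust Add a `p_adj` (Benjamini-Hochberg) column (default FALSE).
#' @return A `data.frame` with one row per tested pair: `level1`, `level2`,
#'   `f`, `p`, (`p_adj`,) `df_among`, `df_within`, `n`.
#' @export
permanova_pairwise <- function(dm, groups, n_permutations = 9999,
                               seed = NULL, adjust = FALSE) {
  d <- if (inherits(dm, "distance_matrix")) dm$d else as.matrix(dm)
  ids <- rownames(d)
  groups <- align_groups(groups, ids, nrow(d))
  levs <- sort(unique(groups))
  pair_seeds <- child_seeds(seed %||% 1L, choose(length(levs), 2))
  rows <- list()
  k <- 0
  for (i in seq_len(length(levs) - 1)) {
    for (j in seq(i + 1, length(levs))) {
      k <- k + 1
      keep <- groups %in% c(levs[i], levs[j])
      sub_groups <- groups[keep]
      if (min(table(sub_groups)) < 2) {
        warnf("skipping pair %s vs %s: a level has fewer than 2 samples",
              levs[i], levs[j])
        next
      }
      res <- permanova(d[keep, keep, drop = FALSE], sub_groups,
                       n_permutations = n_permutations,
                       seed = if (is.null(seed)) NULL else pair_seeds[k],
                       factor_name = sprintf("%s vs %s", levs[i], levs[j]))
      rows[[length(rows) + 1]] <- data.frame(
        level1 = levs[i], level2 = levs[j], f = res$f, p = res$p,
        df_among = res$df_among, df_within = res$df_within, n = res$n,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) stopf("no testable level pairs")
  if (adjust) out$p_adj <- stats::p.adjust(out$p, method = "BH")
  out
}
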