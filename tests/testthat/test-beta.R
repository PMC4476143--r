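test_that("distance metrics match hand values and vegan/base oracles", {
  m <- matrix(c(10, 0, 5, 5, 5, 5), nrow = 2, byrow = TRUE,
              dimnames = list(c("x", "y"), c("a", "b", "c")))
  d <- distance_matrix(m, "bray_curtis", normalize = FALSE)
  expect_equal(d$d["x", "y"], 1 - 20 / 30, tolerance = 1e-12)
  ident <- distance_matrix(rbind(s1 = c(1, 2), s2 = c(1, 2)), "bray_curtis",
                           normalize = FALSE)
  expect_equal(ident$d["s1", "s2"], 0)
  disj <- distance_matrix(rbind(s1 = c(3, 0), s2 = c(0, 7)), "bray_curtis",
                          normalize = FALSE)
  expect_equal(disj$d["s1", "s2"], 1)

  set.seed(2)
  x <- matrix(rpois(60, 4) + 1, nrow = 5)
  rownames(x) <- paste0("S", 1:5)
  for (metric in c("bray_curtis", "euclidean", "manhattan", "canberra")) {
    mine <- distance_matrix(x, metric, normalize = FALSE)$d
    oracle <- as.matrix(switch(metric,
      bray_curtis = vegan::vegdist(x, "bray"),
      euclidean = dist(x, "euclidean"),
      manhattan = dist(x, "manhattan"),
      canberra = dist(x, "canberra")))
    expect_equal(unname(mine), unname(oracle), tolerance = 1e-10,
                 label = metric)
  }
})

test_that("distance matrices are symmetric, zero-diagonal, BC in [0,1]", {
  tab <- random_table(6, 25, seed = 4)
  d <- distance_matrix(tab, "bray_curtis")
  expect_equal(d$d, t(d$d), tolerance = 1e-12)
  expect_equal(unname(diag(d$d)), rep(0, 6))
  expect_true(all(d$d >= 0 & d$d <= 1 + 1e-12))
  expect_error(distance_matrix(tab, "chebyshev"), "arg")
})

test_that("UPGMA reproduces the hand-worked merge and heights", {
  d <- matrix(c(0, 1, 4, 1, 0, 4, 4, 4, 0), 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  dend <- upgma(structure(list(ids = rownames(d), d = d,
                               metric = "user"), class = "distance_matrix"))
  expect_equal(dend$hclust$height, c(1, 4))
  first <- rownames(d)[-dend$hclust$merge[1, ]]
  expect_setequal(first, c("A", "B"))
  # identical samples merge at height zero
  dup <- distance_matrix(rbind(a = c(2, 2), b = c(2, 2), c = c(9, 0)),
                         "bray_curtis", normalize = FALSE)
  expect_equal(min(upgma(dup)$hclust$height), 0)
})

test_that("UPGMA heights are self-consistent with cophenetic distances", {
  tab <- random_table(7, 30, seed = 6)
  dend <- upgma(distance_matrix(tab, "bray_curtis"))
  coph <- cophenetic(dend$hclust)
  redo <- hclust(coph, method = "average")
  expect_equal(sort(redo$height), sort(dend$hclust$height), tolerance = 1e-12)
})

test_that("UPGMA separates clean blocks (ARI = 1)", {
  bd <- block_dataset(blocks = 2, per_block = 5, seed = 3)
  dend <- upgma(distance_matrix(bd$table, "bray_curtis"))
  cut2 <- cutree(dend$hclust, k = 2)
  expect_equal(adjusted_rand_index(cut2, bd$blocks), 1)
})

test_that("pseudo-F matches the hand-computed two-group example exactly", {
  pts <- matrix(c(0, 1, 10, 11), 4, 1,
                dimnames = list(paste0("s", 1:4), "x"))
  d <- distance_matrix(pts, "euclidean", normalize = FALSE)
  res <- permanova(d, c("g1", "g1", "g2", "g2"), n_permutations = 99,
                   seed = 1)
  expect_equal(res$f, 200, tolerance = 1e-12)
  expect_equal(res$df_among, 1)
  expect_equal(res$df_within, 2)
  expect_gte(res$p, 1 / 100)
})

test_that("permanova agrees with the vegan::adonis2 pseudo-F", {
  tab <- random_table(10, 30, seed = 12)
  groups <- rep(c("a", "b"), each = 5)
  d <- distance_matrix(tab, "bray_curtis")
  mine <- permanova(d, groups, n_permutations = 99, seed = 1)
  ado <- vegan::adonis2(as.dist(d) ~ g,
                        data = data.frame(g = groups), permutations = 99)
  expect_equal(mine$f, ado$F[1], tolerance = 1e-9)
})

test_that("permanova is invariant to sample reordering", {
  tab <- random_table(9, 20, seed = 14)
  groups <- setNames(rep(c("a", "b", "c"), each = 3), sample_ids(tab))
  d1 <- distance_matrix(tab, "bray_curtis")
  perm <- sample(sample_ids(tab))
  d2 <- distance_matrix(subset(tab, samples = perm), "bray_curtis")
  r1 <- permanova(d1, groups, n_permutations = 199, seed = 5)
  r2 <- permanova(d2, groups, n_permutations = 199, seed = 5)
  expect_equal(r1$f, r2$f, tolerance = 1e-12)
})

test_that("Monte-Carlo p matches complete permutation enumeration (N = 8)", {
  set.seed(20)
  pts <- matrix(rnorm(16), 8, 2, dimnames = list(paste0("s", 1:8), NULL))
  pts[1:4, 1] <- pts[1:4, 1] + 1.5
  d <- distance_matrix(pts, "euclidean", normalize = FALSE)
  groups <- rep(c("a", "b"), each = 4)
  exact <- permanova_exact_p(as.dist(d), groups)
  mc <- permanova(d, groups, n_permutations = 4999, seed = 2)
  mc_err <- 3 * sqrt(exact * (1 - exact) / 4999) + 2 / 5000
  expect_lt(abs(mc$p - exact), mc_err + 0.01)
})

test_that("degenerate and malformed groupings are handled", {
  same <- matrix(5, 4, 3, dimnames = list(paste0("s", 1:4), NULL))
  d <- distance_matrix(same, "euclidean", normalize = FALSE)
  expect_warning(res <- permanova(d, rep(c("a", "b"), 2),
                                  n_permutations = 9), "undefined")
  expect_true(is.na(res$f))
  tab <- random_table(5, 10, seed = 1)
  dm <- distance_matrix(tab, "bray_curtis")
  expect_error(permanova(dm, c("a", "a", "a", "a", "b"), 9), "singleton")
  expect_error(permanova(dm, rep("a", 5), 9), "2 groups")
})

test_that("pairwise permanova tests each level pair, skipping singletons", {
  tab <- random_table(9, 20, seed = 23)
  groups <- rep(c("x", "y", "z"), each = 3)
  d <- distance_matrix(tab, "bray_curtis")
  pw <- permanova_pairwise(d, groups, n_permutations = 99, seed = 3)
  expect_equal(nrow(pw), 3)  # C(3,2)
  expect_setequal(paste(pw$level1, pw$level2),
                  c("x y", "x z", "y z"))
  pw_adj <- permanova_pairwise(d, groups, n_permutations = 99, seed = 3,
                               adjust = TRUE)
  expect_true(all(pw_adj$p_adj >= pw_adj$p - 1e-12))
  groups2 <- c("x", rep(c("y", "z"), each = 4))
  warnings <- testthat::capture_warnings(
    pw2 <- permanova_pairwise(d, groups2, 99, seed = 3))
  expect_length(warnings, 2)  # both pairs involving the singleton level
  expect_match(warnings, "fewer than 2", all = TRUE)
  expect_equal(nrow(pw2), 1)
})

test_that("jaccard stability is deterministic given a seed and in [0, 100]", {
  bd <- block_dataset(blocks = 2, per_block = 5, seed = 9)
  s1 <- jaccard_stability(bd$table, B = 25, seed = 7)
  s2 <- jaccard_stability(bd$table, B = 25, seed = 7)
  expect_identical(s1$stability, s2$stability)
  expect_true(all(s1$stability >= 0 & s1$stability <= 100))
  expect_length(s1$stability, nrow(bd$table$counts) - 1)
  # the two clean block nodes are highly stable
  sets <- rankbank:::node_leafsets(s1$hclust)
  block_nodes <- which(vapply(sets, function(s)
    setequal(s, sample_ids(bd$table)[bd$blocks == bd$blocks[1]]) ||
      setequal(s, sample_ids(bd$table)[bd$blocks != bd$blocks[1]]),
    logical(1)))
  expect_gt(min(s1$stability[block_nodes]), 75)
  expect_error(jaccard_stability(bd$table, B = 0), "B")
})

test_that("newick export is well-formed and re-parsable", {
  bd <- block_dataset(blocks = 2, per_block = 4, seed = 5)
  dend <- jaccard_stability(bd$table, B = 10, seed = 1)
  nwk <- write_newick(dend)
  expect_match(nwk, ";$")
  tree <- ape::read.tree(text = nwk)
  expect_setequal(tree$tip.label, sample_ids(bd$table))
  expect_equal(length(tree$node.label), nrow(bd$table$counts) - 1)
  path <- tempfile(fileext = ".nwk")
  write_newick(dend, path)
  expect_identical(readLines(path), nwk)
})
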