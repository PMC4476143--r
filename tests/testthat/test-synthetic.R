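test_that("bank_community: geometric abundant block and unit sum", {
  b <- bank_community(bank_model_params(n_abundant = 2, geometric_ratio = 0.5,
                                        abundant_mass = 0.6, s_bank = 50),
                      seed = 1)
  expect_equal(as.numeric(b[1:2]), c(0.4, 0.2), tolerance = 1e-12)
  for (seed in 1:10) {
    v <- bank_community(seed = seed)
    expect_equal(sum(v), 1, tolerance = 1e-9)
    expect_true(all(v > 0))
    expect_true(!is.unsorted(rev(as.numeric(v))))
  }
  expect_identical(as.numeric(bank_community(seed = 3)),
                   as.numeric(bank_community(seed = 3)))
})

test_that("bank model parameter contracts", {
  expect_error(bank_model_params(abundant_mass = 1.2), "abundant_mass")
  expect_error(bank_model_params(n_abundant = 1, abundant_mass = 0.6,
                                 s_bank = 0), "s_bank")
  expect_error(bank_model_params(geometric_ratio = 0), "geometric_ratio")
})

test_that("sample_counts is a reproducible multinomial at exact depth", {
  expect_identical(sample_counts(1, 100, seed = 1), 100L)
  expect_error(sample_counts(c(0.5, 0.5), 0), "depth")
  expect_error(sample_counts(c(0.7, 0.6), 10), "sum to 1")
  expect_identical(sample_counts(c(0.3, 0.7), 500, seed = 9),
                   sample_counts(c(0.3, 0.7), 500, seed = 9))
  cts <- sample_counts(c(0.5, 0.5), 1e6, seed = 4)
  expect_identical(sum(cts), 1000000L)
  sigma <- sqrt(1e6 * 0.25)
  expect_lt(abs(cts[1] - 5e5), 3 * sigma)
})

test_that("ktw snapshots hit the documented states", {
  p <- ktw_params(bank = bank_model_params(s_bank = 100))
  d1 <- p$phase_durations[1]
  # end of phase 1: dominance overshoot at f_max, median rank < 1
  pre_crash <- ktw_snapshot(p, d1 - 1e-9)
  expect_equal(as.numeric(pre_crash[1]), p$f_max, tolerance = 1e-6)
  expect_lt(as.numeric(interpolated_median_rank(pre_crash)), 1)
  # phase 2: crash community with median rank between 6 and 7
  crash_mr <- as.numeric(interpolated_median_rank(ktw_snapshot(p, d1 + 0.005)))
  expect_gte(crash_mr, 6)
  expect_lte(crash_mr, 7)
  # cycle continuity: t = 0 equals the phase-3 endpoint (the late snapshot
  # still carries vanishing scavenger fractions, dropped at exactly t = 0)
  start <- as.numeric(ktw_snapshot(p, 0))
  late <- as.numeric(ktw_snapshot(p, 1 - 1e-12))
  expect_equal(start, late[seq_along(start)], tolerance = 1e-6)
  expect_lt(sum(late[-seq_along(start)]), 1e-9)
  expect_error(ktw_snapshot(p, 1), "\\[0, 1\\)")
  expect_error(ktw_snapshot(p, -0.1), "\\[0, 1\\)")
  # fraction vectors sum to 1 across the whole cycle
  for (t in seq(0, 0.999, length.out = 25))
    expect_equal(sum(ktw_snapshot(p, t)), 1, tolerance = 1e-9)
})

test_that("ktw parameter contracts", {
  expect_error(ktw_params(phase_durations = c(0.5, 0.3, 0.2)), "d1 > d3 > d2")
  expect_error(ktw_params(phase_durations = c(0.9, 0.02, 0.04)), "sum to 1")
  expect_error(ktw_params(f_max = 0.4), "f_max")
  expect_error(ktw_params(f_start = 0.6), "f_start")
})

test_that("generate_dataset reproduces the 85-sample survey design", {
  ds <- generate_dataset(dataset_design(),
                         bank_model_params(s_bank = 150), seed = 2)
  tab <- ds$table
  meta <- ds$metadata
  expect_equal(nrow(tab$counts), 85)
  expect_identical(sample_ids(tab), meta$sample_id)
  expect_true(all(meta$depth_m >= 0))
  depths <- rowSums(tab$counts)
  expect_true(all(depths >= 288 & depths <= 12791))
  # seasonal-March OTUs never appear in September samples
  march_otus <- names(ds$otu_classes)[ds$otu_classes == "seasonal_march"]
  sept_rows <- tab$counts[meta$month == "September", march_otus]
  expect_true(all(sept_rows == 0))
  # the complement of September 2008 has 66 samples in this design
  sep08 <- meta$sample_id[meta$month == "September" & meta$year == 2008]
  expect_length(sep08, 19)
  rest <- subset(tab, samples = setdiff(meta$sample_id, sep08))
  expect_equal(nrow(rest$counts), 66)
})

test_that("generate_dataset is seed-deterministic and honors sporadic_prob = 0", {
  design <- dataset_design(cruises = data.frame(month = c("March", "September"),
                                                year = c(2010, 2010)),
                           depths = list(c(0, 100), c(0, 100)))
  bank <- bank_model_params(s_bank = 40)
  d1 <- generate_dataset(design, bank, seed = 5)
  d2 <- generate_dataset(design, bank, seed = 5)
  expect_identical(d1$table$counts, d2$table$counts)
  design0 <- dataset_design(cruises = design$cruises, depths = design$depths,
                            sporadic_prob = 0)
  d0 <- generate_dataset(design0, bank, seed = 5)
  sporadic <- names(d0$otu_classes)[d0$otu_classes == "sporadic"]
  expect_true(all(d0$table$counts[, sporadic] == 0))
})

test_that("block_dataset produces labeled, well-separated blocks", {
  bd <- block_dataset(blocks = 4, per_block = 3, seed = 11)
  expect_equal(nrow(bd$table$counts), 12)
  expect_equal(nlevels(bd$blocks), 4)
  d <- distance_matrix(bd$table, "bray_curtis")$d
  same <- outer(bd$blocks, bd$blocks, "==") & upper.tri(d)
  diff_blocks <- !outer(bd$blocks, bd$blocks, "==") & upper.tri(d)
  expect_gt(min(d[diff_blocks]), max(d[same]))
})
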