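#' Bank-model parameters
#'
#' Parameters of the synthetic "bank" community: a few abundant OTUs whose
#' fractions follow a normalized geometric series carrying `abundant_mass`
#' of the community, over a large reservoir of rare OTUs whose weights are
#' i.i.d. lognormal and carry the remaining mass.
#'
#' @param n_abundant Number of abundant OTUs (default 3).
#' @param abundant_mass Fraction of the community held by the abundant set,
#'   strictly in (0, 1) (default 0.6).
#' @param geometric_ratio Decay ratio of consecutive abundant fractions,
#'   in (0, 1] (default 0.6).
#' @param s_bank Number of rare ("bank") OTUs (default 500). Must be
#'   positive: with `abundant_mass < 1` some bank OTUs must carry the
#'   leftover mass.
#' @param bank_sigma Lognormal sdlog of the bank weights (default 1.5).
#' @param seed Integer seed making draws reproducible.
#' @return A validated list of class `bank_model_params`.
#' @export
bank_model_params <- function(n_abundant = 3, abundant_mass = 0.6,
                              geometric_ratio = 0.6, s_bank = 500,
                              bank_sigma = 1.5, seed = NULL) {
  check_number(n_abundant, "n_abundant", min = 1)
  check_number(abundant_mass, "abundant_mass", min = 0, max = 1,
               allow_min = FALSE, allow_max = FALSE)
  check_number(geometric_ratio, "geometric_ratio", min = 0, max = 1,
               allow_min = FALSE)
  check_number(s_bank, "s_bank", min = 0)
  check_number(bank_sigma, "bank_sigma", min = 0, allow_min = FALSE)
  if (s_bank == 0)
    stopf("s_bank = 0 is impossible: abundant_mass = %g < 1 leaves mass that only bank OTUs can carry",
          abundant_mass)
  structure(list(n_abundant = as.integer(n_abundant),
                 abundant_mass = abundant_mass,
                 geometric_ratio = geometric_ratio,
                 s_bank = as.integer(s_bank), bank_sigma = bank_sigma,
                 seed = seed),
            class = "bank_model_params")
}

# Geometric abundant fractions scaled to carry `mass`.
geometric_fractions <- function(n, ratio, mass) {
  g <- ratio^(seq_len(n) - 1)
  mass * g / sum(g)
}

#' Draw one bank-model community
#'
#' Abundant fractions are the deterministic geometric series of the
#' parameters; bank fractions are freshly drawn lognormal weights normalized
#' to `1 - abundant_mass`. The full vector sums to 1 and, with default
#' parameters, has interpolated median rank ~2.1 — inside the stable 1–4
#' band of persistent-dominant communities.
#'
#' @param params A [bank_model_params()].
#' @param seed Seed for the bank draw (defaults to `params$seed`).
#' @return A [rank_abundance()] vector of length `n_abundant + s_bank`.
#' @export
bank_community <- function(params = bank_model_params(),
                           seed = params$seed) {
  stopifnot(inherits(params, "bank_model_params"))
  ab <- geometric_fractions(params$n_abundant, params$geometric_ratio,
                            params$abundant_mass)
  w <- with_seed(seed, stats::rlnorm(params$s_bank, 0, params$bank_sigma))
  bank <- (1 - params$abundant_mass) * w / sum(w)
  rank_abundance(c(ab, bank))
}

#' Kill-the-winner cycle parameters
#'
#' Describes one deterministic kill-the-winner cycle in composition space,
#' traversed at very unequal speeds (canard-style): a long dominance drift,
#' a near-instant crash, and a fast-but-resolvable recovery.
#'
#' \itemize{
#'   \item Phase 1 (duration `d1`): the community drifts from the steady
#'     state (abundant group of `steady_group` OTUs, top fraction `f_start`)
#'     toward single-OTU dominance. The top fraction rises piecewise
#'     linearly in time: to 0.5 over most of the phase, then through a short
#'     terminal *overshoot* window (`overshoot`, a cycle fraction) to
#'     `f_max > 0.5`. Only inside the overshoot window does the median rank
#'     drop below 1.
#'   \item Phase 2 (`d2`, the fastest step): the winner is lysed; it falls
#'     to the level of `n_competitors` scavenger OTUs and its mass `f_max`
#'     is shared equally among all `n_competitors + 1` of them, producing a
#'     median rank between 6 and 7 with the defaults.
#'   \item Phase 3 (`d3`): linear relaxation of the composition back to the
#'     steady state, so the cycle is continuous at `t = 0`.
#' }
#'
#' @param phase_durations Fractions of one cycle `(d1, d2, d3)`, summing to
#'   1, with `d1 > d3 > d2` (default `c(0.95, 0.01, 0.04)`).
#' @param f_start Top-OTU fraction at the cycle start (default 0.30).
#' @param f_max Top-OTU fraction at the crash, > 0.5 (default 0.62).
#' @param n_competitors Scavenger OTUs enriched by the crash (default 7).
#' @param steady_group Abundant-group size at steady state (default 4).
#' @param overshoot Cycle fraction at the end of phase 1 during which the
#'   top fraction exceeds 0.5 (default 0.012, the observed frequency of
#'   dominance-overshoot snapshots: about 1 sample in 85).
#' @param bank A [bank_model_params()] block for the rare tail.
#' @param seed Seed fixing the bank profile (default 1), so a snapshot is
#'   deterministic given `(params, t)`.
#' @return A validated list of class `ktw_params`.
#' @export
ktw_params <- function(phase_durations = c(0.95, 0.01, 0.04),
                       f_start = 0.30, f_max = 0.62, n_competitors = 7,
                       steady_group = 4, overshoot = 0.012,
                       bank = bank_model_params(), seed = 1) {
  if (length(phase_durations) != 3 || any(phase_durations <= 0))
    stopf("phase_durations must be 3 positive fractions")
  if (abs(sum(phase_durations) - 1) > 1e-12)
    stopf("phase_durations must sum to 1")
  d <- phase_durations
  if (!(d[1] > d[3] && d[3] > d[2]))
    stopf("phase durations must satisfy d1 > d3 > d2 (slow drift, fast crash, intermediate recovery)")
  check_number(f_start, "f_start", min = 0, max = 0.5,
               allow_min = FALSE, allow_max = FALSE)
  check_number(f_max, "f_max", min = 0.5, max = 1,
               allow_min = FALSE, allow_max = FALSE)
  check_number(n_competitors, "n_competitors", min = 1)
  check_number(steady_group, "steady_group", min = 1)
  check_number(overshoot, "overshoot", min = 0, max = d[1],
               allow_min = FALSE, allow_max = FALSE)
  stopifnot(inherits(bank, "bank_model_params"))
  ab <- f_start * bank$geometric_ratio^(seq_len(steady_group) - 1)
  if (sum(ab) >= 1)
    stopf("steady-state abundant mass %.3f >= 1; lower f_start, steady_group or the geometric ratio",
          sum(ab))
  structure(list(phase_durations = d, f_start = f_start, f_max = f_max,
                 n_competitors = as.integer(n_competitors),
                 steady_group = as.integer(steady_group),
                 overshoot = overshoot, bank = bank, seed = seed),
            class = "ktw_params")
}

# Fixed OTU-slot layout for a cycle: winner, the other steady abundants,
# the scavengers (zero outside phases 2-3), and the bank tail.
ktw_states <- function(params) {
  g <- params$steady_group
  nc <- params$n_competitors
  ab <- params$f_start * params$bank$geometric_ratio^(seq_len(g) - 1)
  bank_w <- with_seed(params$seed,
                      stats::rlnorm(params$bank$s_bank, 0,
                                    params$bank$bank_sigma))
  bank_profile <- bank_w / sum(bank_w)
  rest0 <- c(ab[-1], (1 - sum(ab)) * bank_profile)  # non-winner mass layout
  dominated <- function(f) {
    scale <- (1 - f) / (1 - ab[1])
    c(f, rest0[seq_len(g - 1)] * scale, rep(0, nc),
      rest0[-seq_len(g - 1)] * scale)
  }
  s0 <- dominated(params$f_start)
  d_state <- dominated(params$f_max)
  level <- params$f_max / (nc + 1)
  crash <- d_state
  crash[1] <- level
  crash[g + seq_len(nc)] <- level  # scavenger slots
  list(s0 = s0, crash = crash, dominated = dominated)
}

#' Kill-the-winner cycle snapshot
#'
#' Deterministic community composition at cycle phase `t` in `[0, 1)`; see
#' [ktw_params()] for the trajectory. The output always sums to 1, and
#' `t = 0` reproduces the phase-3 endpoint (the cycle is continuous).
#'
#' @param params A [ktw_params()].
#' @param t Cycle phase in `[0, 1)`.
#' @return A [rank_abundance()] vector.
#' @export
#' @examples
#' p <- ktw_params(bank = bank_model_params(s_bank = 50))
#' interpolated_median_rank(ktw_snapshot(p, 0.955))  # crash: between 6 and 7
ktw_snapshot <- function(params, t) {
  stopifnot(inherits(params, "ktw_params"))
  if (!is.numeric(t) || length(t) != 1L || is.na(t) || t < 0 || t >= 1)
    stopf("t must lie in [0, 1)")
  d <- params$phase_durations
  st <- ktw_states(params)
  x <- if (t < d[1]) {
    t_mid <- d[1] - params$overshoot
    f <- if (t < t_mid)
      params$f_start + (0.5 - params$f_start) * t / t_mid
    else 0.5 + (params$f_max - 0.5) * (t - t_mid) / params$overshoot
    st$dominated(f)
  } else if (t < d[1] + d[2]) {
    st$crash
  } else {
    s <- (t - d[1] - d[2]) / d[3]
    (1 - s) * st$crash + s * st$s0
  }
  rank_abundance(x)
}

#' Multinomial read sampling
#'
#' Simulates sequencing a community of known composition to a fixed read
#' depth: one multinomial draw of `depth` reads over the OTU fractions.
#'
#' @param fractions Non-negative fractions summing to 1 (tolerance 1e-6).
#' @param depth Total reads, >= 1.
#' @param seed Seed for reproducibility.
#' @return Integer count vector summing to `depth`.
#' @export
sample_counts <- function(fractions, depth, seed = NULL) {
  fractions <- as.numeric(fractions)
  if (any(fractions < 0) || abs(sum(fractions) - 1) > 1e-6)
    stopf("fractions must be non-negative and sum to 1")
  check_number(depth, "depth", min = 1)
  with_seed(seed, as.integer(stats::rmultinom(1, depth, fractions)))
}

#' Survey design for the synthetic dataset generator
#'
#' Describes a month/year x depth sampling design plus the occupancy
#' structure of the OTU pool. The default reproduces a five-cruise
#' (September 2008; March and September of 2010 and 2011) oceanographic
#' depth-profile design with 85 samples: all cruises sample
#' 0–160 m every 20 m plus 200, 300 and 400 m; 180 m is sampled in 2008 and
#' 2011, 250 m in 2010 and 2011, and the deep profile (500–1000 m) in 2008
#' and 2011.
#'
#' Occupancy classes: `persistent` OTUs occur in every sample (and supply
#' the abundant group), `seasonal` OTUs occur only in their month,
#' `depth-restricted` OTUs only within their depth zone (alternately the
#' photic zone, <= 100 m, and the deep zone, >= 300 m), and `sporadic`
#' (bank) OTUs appear per sample with probability `sporadic_prob`.
#'
#' @param cruises Data frame with columns `month`, `year`.
#' @param depths List (one vector per cruise) of sampling depths in meters.
#' @param n_persistent,n_seasonal,n_depth_restricted Pool sizes (defaults
#'   5, 30 per season, 30).
#' @param sporadic_prob Per-sample appearance probability of a sporadic OTU
#'   (default 0.15).
#' @param read_depth Named vector `c(min=, median=, max=)` of reads per
#'   sample (default `c(288, 3028, 12791)`).
#' @return A validated list of class `dataset_design`.
#' @export
dataset_design <- function(cruises = NULL, depths = NULL,
                           n_persistent = 5, n_seasonal = 30,
                           n_depth_restricted = 30, sporadic_prob = 0.15,
                           read_depth = c(min = 288, median = 3028,
                                          max = 12791)) {
  if (is.null(cruises)) {
    cruises <- data.frame(
      month = c("September", "March", "September", "March", "September"),
      year = c(2008, 2010, 2010, 2011, 2011), stringsAsFactors = FALSE)
    shallow <- c(seq(0, 160, by = 20), 200, 300, 400)
    deep <- c(500, 600, 700, 800, 900, 1000)
    depths <- list(
      sort(c(shallow, 180, deep)),        # Sep 2008
      sort(c(shallow, 250)),              # Mar 2010
      sort(c(shallow, 250)),              # Sep 2010
      sort(c(shallow, 180, 250, deep)),   # Mar 2011
      sort(c(shallow, 180, 250, deep)))   # Sep 2011
  }
  # JSON round trips can deliver the per-cruise depth lists as a matrix or
  # a single vector; normalize to a list of vectors
  if (is.matrix(depths))
    depths <- lapply(seq_len(nrow(depths)), function(i) depths[i, ])
  if (is.atomic(depths) && !is.null(depths)) depths <- list(depths)
  if (length(depths) != nrow(cruises))
    stopf("need one depth vector per cruise")
  cruises$month <- normalize_month(cruises$month)
  if (any(unlist(depths) < 0)) stopf("depths must be non-negative")
  check_number(sporadic_prob, "sporadic_prob", min = 0, max = 1)
  if (!all(c("min", "median", "max") %in% names(read_depth)) ||
      any(read_depth < 1) || is.unsorted(read_depth[c("min", "median", "max")]))
    stopf("read_depth must be c(min=, median=, max=) with min <= median <= max")
  structure(list(cruises = cruises, depths = depths,
                 n_persistent = as.integer(n_persistent),
                 n_seasonal = as.integer(n_seasonal),
                 n_depth_restricted = as.integer(n_depth_restricted),
                 sporadic_prob = sporadic_prob, read_depth = read_depth),
            class = "dataset_design")
}

#' Generate a synthetic OTU table and metadata
#'
#' Builds one sample per (cruise, depth) of the design. Each sample draws a
#' bank-model composition whose abundant group (2–4 OTUs, abundant mass
#' 0.55–0.65, geometric ratio 0.45–0.75 — chosen so sample median ranks
#' spread over the stable 1–4 band) is taken from the persistent pool, with
#' the remaining mass spread lognormally over the OTUs present in that
#' sample (seasonal OTUs of the matching month, depth-restricted OTUs of
#' the matching zone, and sporadic OTUs appearing with the design
#' probability). Reads are a multinomial draw at a lognormal depth clipped
#' to the design's (min, max). One parent seed drives per-sample child
#' streams, so results are reproducible and samples independent.
#'
#' @param design A [dataset_design()].
#' @param bank A [bank_model_params()]; `s_bank` sets the sporadic pool
#'   size and `bank_sigma` the rare-tail spread.
#' @param seed Integer parent seed (default 1).
#' @return A list with `table` (an [otu_table()]), `metadata` (a
#'   `sample_metadata` data frame with a smooth temperature covariate), and
#'   `otu_classes` (named character vector of occupancy classes).
#' @export
generate_dataset <- function(design = dataset_design(),
                             bank = bank_model_params(), seed = 1) {
  stopifnot(inherits(design, "dataset_design"),
            inherits(bank, "bank_model_params"))
  cruise_idx <- rep(seq_len(nrow(design$cruises)),
                    lengths(design$depths))
  months <- design$cruises$month[cruise_idx]
  years <- design$cruises$year[cruise_idx]
  depth_m <- unlist(design$depths)
  n <- length(depth_m)
  ids <- sprintf("%s%d_%04dm", substr(months, 1, 3), years, depth_m)

  pools <- list(
    persistent = design$n_persistent,
    seasonal_march = design$n_seasonal,
    seasonal_september = design$n_seasonal,
    depth_restricted = design$n_depth_restricted,
    sporadic = bank$s_bank)
  classes <- rep(names(pools), unlist(pools))
  otu_names <- sprintf("Otu%04d", seq_along(classes))
  names(classes) <- otu_names
  # depth-restricted OTUs alternate photic (<= 100 m) and deep (>= 300 m)
  dr_idx <- which(classes == "depth_restricted")
  dr_zone <- rep(c("photic", "deep"), length.out = length(dr_idx))
  zone_ok <- function(zone, depth)
    if (zone == "photic") depth <= 100 else depth >= 300

  seeds <- child_seeds(seed, n)
  counts <- matrix(0L, n, length(classes), dimnames = list(ids, otu_names))
  meta_temp <- numeric(n)
  for (i in seq_len(n)) {
    row <- with_seed(seeds[i], {
      present <- classes == "persistent" |
        (classes == "seasonal_march" & months[i] == "March") |
        (classes == "seasonal_september" & months[i] == "September")
      present[dr_idx] <- vapply(dr_zone, zone_ok, logical(1),
                                depth = depth_m[i])
      sporadic <- which(classes == "sporadic")
      present[sporadic] <- stats::runif(length(sporadic)) <
        design$sporadic_prob
      n_ab <- sample(2:4, 1, prob = c(0.35, 0.4, 0.25))
      mass <- stats::runif(1, 0.55, 0.65)
      ratio <- stats::runif(1, 0.45, 0.75)
      ab_otus <- sample(which(classes == "persistent"), n_ab,
                        prob = 2^(design$n_persistent:1))
      fractions <- numeric(length(classes))
      fractions[ab_otus] <- geometric_fractions(n_ab, ratio, mass)
      rest <- which(present & fractions == 0)
      w <- stats::rlnorm(length(rest), 0, bank$bank_sigma)
      fractions[rest] <- (1 - mass) * w / sum(w)
      depth_reads <- round(min(max(
        stats::rlnorm(1, log(design$read_depth[["median"]]), 0.8),
        design$read_depth[["min"]]), design$read_depth[["max"]]))
      cts <- as.integer(stats::rmultinom(1, depth_reads, fractions))
      temp <- 4 + 18 * exp(-depth_m[i] / 120) +
        (months[i] == "September") * 4 * exp(-depth_m[i] / 80) +
        stats::rnorm(1, 0, 0.3)
      list(cts = cts, temp = temp)
    })
    counts[i, ] <- row$cts
    meta_temp[i] <- row$temp
  }
  metadata <- structure(
    data.frame(sample_id = ids, month = months, year = years,
               depth_m = depth_m, temperature_c = round(meta_temp, 2),
               stringsAsFactors = FALSE),
    class = c("sample_metadata", "data.frame"))
  list(table = otu_table(counts, label = "synthetic"),
       metadata = metadata, otu_classes = classes)
}

#' Block-structured synthetic dataset
#'
#' Clean test bed for cluster-recovery checks: `blocks` groups of samples,
#' each with its own disjoint trio of abundant OTUs (75% of the community,
#' geometric) over a bank shared by all samples. Samples are multinomial
#' draws from their block profile, so between-block dissimilarities dwarf
#' within-block ones.
#'
#' @param blocks Number of blocks (default 4, labeled like season x depth
#'   zone combinations).
#' @param per_block Samples per block (default 6).
#' @param s_noise Shared bank OTUs (default 100).
#' @param depth Reads per sample (default 5000).
#' @param seed Parent seed.
#' @return List with `table` (an [otu_table()]) and `blocks` (factor of
#'   block labels aligned with the samples).
#' @export
block_dataset <- function(blocks = 4, per_block = 6, s_noise = 100,
                          depth = 5000, seed = 1) {
  check_number(blocks, "blocks", min = 2)
  check_number(per_block, "per_block", min = 2)
  labels <- if (blocks == 4)
    c("March_photic", "March_deep", "September_photic", "September_deep")
  else paste0("B", seq_len(blocks))
  n_otus <- 3 * blocks + s_noise
  seeds <- child_seeds(seed, blocks * per_block + 1)
  bank_profile <- with_seed(seeds[1], stats::rlnorm(s_noise, 0, 1.5))
  bank_profile <- bank_profile / sum(bank_profile)
  counts <- matrix(0L, blocks * per_block, n_otus)
  block_f <- character(blocks * per_block)
  k <- 0
  for (b in seq_len(blocks)) {
    profile <- numeric(n_otus)
    profile[3 * (b - 1) + 1:3] <- geometric_fractions(3, 0.5, 0.75)
    profile[3 * blocks + seq_len(s_noise)] <- 0.25 * bank_profile
    for (s in seq_len(per_block)) {
      k <- k + 1
      counts[k, ] <- sample_counts(profile, depth, seed = seeds[k + 1])
      block_f[k] <- labels[b]
    }
  }
  rownames(counts) <- paste0(block_f, "_", rep(seq_len(per_block), blocks))
  colnames(counts) <- sprintf("Otu%04d", seq_len(n_otus))
  list(table = otu_table(counts, label = "synthetic-blocks"),
       blocks = factor(block_f, levels = labels))
}
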