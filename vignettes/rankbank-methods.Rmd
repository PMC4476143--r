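---
title: "Methods: median-rank dominance, RAD fits and bank-model simulation"
author: "rankbank maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: median-rank dominance, RAD fits and bank-model simulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rankbank)
```

# The problem

Marker-gene surveys of marine viral communities (and microbial communities
generally) produce OTU count tables with a characteristic shape: a handful
of large, common OTUs carry most of the sequences, while the great majority
of OTUs are small and rare — the *bank* structure, a small abundant subset
over a large reservoir of rare taxa. rankbank analyzes such tables along two
axes:

* **Within samples** — how concentrated is each community? (interpolated
  median rank, rank-abundance-distribution fits, rarefaction, Chao1,
  inverse Simpson.)
* **Between samples** — do communities group by season, depth or year?
  (Bray-Curtis distances, UPGMA clustering with bootstrap Jaccard
  stability, permutational MANOVA, dominance/occupancy/group summaries.)

A synthetic-data module generates OTU tables with exactly this structure,
including snapshots of kill-the-winner predator–prey cycles, so every
statistic in the package can be exercised and validated against communities
whose true parameters are known.

# The interpolated median rank

For one sample, sort the OTU fractions in descending order,
$f_1 \ge f_2 \ge \dots \ge f_S$, and let $C(k) = \sum_{i \le k} f_i$ be the
cumulative curve, extended piecewise-linearly through the knots
$(0, 0), (1, C(1)), \dots, (S, 1)$. The interpolated median rank is the
unique $r$ with $C(r) = 0.5$: the (fractional) number of OTUs needed to
cover half the community, i.e. the size of the abundant group.

Numerical conventions, stated explicitly because the statistic is defined
by interpolation:

* **Anchor at $(0, 0)$.** This makes ranks below 1 possible: a community
  whose top OTU holds $f_1 > 0.5$ gets $r = 0.5 / f_1 < 1$. A community
  dominated at 61.6% therefore scores $0.5/0.616 \approx 0.81$ — dominance
  so extreme that "half the community" is covered by less than one OTU.
  An alternative anchoring (e.g. at $(1, f_1)$) would clamp all such
  communities to $r = 1$ and lose the signal.
* **Knot ties return the knot.** Four equal OTUs give exactly $r = 2$.
* **Canonical ordering.** Zeros are dropped and ties in the descending sort
  are broken by input position; the statistic's value is unaffected by ties
  or by permutations of the input, and is invariant to rescaling (counts
  and fractions give the same value).

The statistic is monotone: moving mass onto the top OTU (taken
proportionally from all others) never increases the median rank. Tests
verify the closed-form examples, the invariances, and agreement to 1e-10
with an independent brute-force root finder on the cumulative curve.

## Outlier classes and dwell fractions

`classify_median_ranks()` buckets samples into `stable` (rank in the
inclusive band 1–4, where persistently dominated communities sit),
`low_outlier` (rank < 1, a single pre-crash winner), `high_outlier`
(rank ≥ 6, a freshly crashed community of 6–7 competitors) and
`intermediate`. `dwell_fraction()` reports the non-stable share with an
exact Clopper–Pearson interval: if snapshots sample a cyclic dynamic
uniformly in time, the share of outlying snapshots estimates the fraction
of cycle time spent in the transient stages.

# Rank-abundance distribution fits

`fit_rad()` fits three classical RAD shapes to each sample's descending
abundance profile by least squares **on the untransformed abundances**
(matching spreadsheet-solver practice on rank-abundance plots; log-space
fitting would change both the optima and the SSE-based model ranking):

* power law $f(r) = a\,r^{-b}$,
* exponential $f(r) = a\,e^{-kr}$,
* lognormal, default *quantile form*
  $f(r) = \exp\!\big(\mu + \sigma\,\Phi^{-1}(1 - (r - 0.5)/S)\big)$, the
  abundance at the standard-normal quantile of the rank's plotting
  position $(r - 0.5)/S$.

The exact lognormal parameterization used in rank-abundance work varies
between authors; the quantile form is the default here because it is the
direct expression of "abundances are lognormal, read off against rank
quantiles", and a `gaussian_logrank` alternative
($f(r) = a\,\exp(-(\ln r - \mu)^2 / 2\sigma^2)$) is provided. Only nonzero
abundances enter a fit; ranks are 1-based.

Optimization is multi-start: a log-linear regression seed (exactly solvable
for all three families) plus shape-perturbed restarts, each polished by
BFGS and Nelder–Mead with an SSE tolerance of 1e-12–1e-14. Shape parameters
are optimized as logarithms so they stay positive. The returned SSE never
exceeds any start's SSE; non-convergence is flagged, never silent.
`best_model()` takes the SSE argmin, breaking sub-1e-12 ties by the fixed
order power < exponential < lognormal, and is withheld (with a warning)
when any family failed to converge. `parameter_correlation()` reports the
Pearson correlation between the two decay parameters $b$ and $k$ across
samples — both measure steepness, so coherent sample sets correlate
strongly.

Parameter-recovery tests draw 200 communities per family, add multinomial
sampling noise at 5,000 reads, and require the median absolute relative
error of the recovered shape parameter to stay under 10%. The lognormal
recovery uses 60-rank communities: at 5,000 reads deeper tails start losing
ranks to sampling zeros, which shifts the observed plotting positions —
a real limitation of quantile-form fitting on shallow samples, not an
implementation artifact.

# Alpha diversity

* **Rarefaction** is analytic (hypergeometric expectation), computed with
  log-space binomial coefficients, and always includes the full depth $N$;
  a resampled check is unnecessary because for $N \le 12$ the tests compare
  against exhaustive enumeration of all subsets. The curve of an
  all-singleton community lies exactly on the 1:1 line, the upper bound for
  any community.
* **Chao1** defaults to the bias-corrected form
  $S_{obs} + F_1(F_1-1)/(2(F_2+1))$ (robust to $F_2 = 0$); the classic form
  $S_{obs} + F_1^2/(2F_2)$ is available and falls back with a warning when
  no doubletons exist. Both dominate $S_{obs}$.
* **Inverse Simpson** is reported in both the plug-in form $1/\sum p_i^2$
  (whose 1-to-$S$ range statements are exact) and the unbiased
  finite-sample form $N(N-1)/\sum n_i(n_i-1)$ (the convention of standard
  amplicon pipelines, default). All-singleton samples make the unbiased
  form infinite; this is reported as `Inf` with a warning.

# Beta structure

Distances are computed on relative abundances by default (raw-count mode is
retained for sensitivity analysis). Bray-Curtis is the primary metric;
Euclidean, Manhattan and Canberra are provided for the same
sanity-checking role they play in practice. UPGMA uses
`stats::hclust(method = "average")`.

**Jaccard stability.** Cluster-wise bootstrap stability: resample samples
with replacement, recluster the unique samples present, and score each
reference node's leaf set (restricted to the present samples) by its best
Jaccard match among the bootstrap tree's clusters; average over `B`
resamples, reported on a 0–100 scale with tiers >75 / 60–75 / <60. The
scheme is the standard resample-and-match bootstrap; stability is computed
per reference node (not per cut) because the dendrogram, not a fixed
partition, is the object of interest.

**PERMANOVA.** One-way, pseudo-F from squared distances:
$SS_T = \frac1N\sum_{i<j} d^2_{ij}$, $SS_W = \sum_g \frac1{n_g}
\sum_{i<j \in g} d^2_{ij}$, $F = \frac{(SS_T - SS_W)/(a-1)}{SS_W/(N-a)}$,
with $p = (1 + \#\{F^* \ge F\})/(1 + n_{perm})$ under whole-sample label
permutation (default 9,999 permutations, enough to resolve p = 1e-4).
Degenerate inputs (zero within-group variation) return `NA` with a warning
rather than an infinite F. Pairwise mode tests every level pair on its own
sample subset, reports raw p-values by default (Benjamini–Hochberg
adjustment available), and skips — not fails on — pairs with singleton
levels. Tests verify the hand-computed two-group example ($F = 200$
exactly), agreement with an exhaustive enumeration of label assignments at
$N = 8$, agreement of the F statistic with `vegan::adonis2`, and a type-I
error rate within [0.03, 0.07] at $\alpha = 0.05$ over 500 null
simulations.

# The synthetic community generator

The generator is first-class, tested code; it states a world and the
acceptance checks measure that world.

**Bank model** (`bank_community()`): the abundant group is a deterministic
geometric series — `n_abundant = 3` OTUs, ratio 0.6, carrying
`abundant_mass = 0.6` of the community — over `s_bank = 500` rare OTUs
with i.i.d. lognormal weights (sdlog 1.5) carrying the rest. Defaults give
a median rank of about 2.1, inside the stable 1–4 band; the geometric/
lognormal split was chosen because it reproduces "few large common OTUs,
majority small and rare" with two interpretable knobs, not because any
particular parametric form is claimed for real communities.

**Kill-the-winner cycle** (`ktw_snapshot()`): one deterministic cycle in
composition space, traversed at very unequal speeds (canard-style), with
phase durations (0.95, 0.01, 0.04):

1. *Dominance drift* (95% of the cycle): mass concentrates onto the
   winner; its fraction rises from 0.30 to 0.5 over most of the phase and
   only within a short terminal *overshoot* window (1.2% of the cycle) from
   0.5 to 0.62 — so median rank dips below 1 only briefly. The overshoot
   duration mirrors the empirical rate of dominated snapshots (about one
   sample in 85). A single linear ramp 0.30→0.62 across the whole phase
   would leave the community dominated (median rank < 1) for ~36% of the
   cycle, contradicting the ~5% transient share the model is meant to
   embody; the piecewise ramp is the package's resolution of that tension.
2. *Crash* (1%): the winner is lysed and falls to the level of the 7
   scavenger OTUs; its freed mass 0.62 is shared equally among all 8, which
   (with the retained second-ranked OTU) puts the median rank between
   6 and 7. Redistribution touches only the winner's mass; the other
   abundant OTUs keep their fractions, mirroring the lysis-release
   narrative.
3. *Recovery* (4%): linear mixing of the crash composition back to the
   steady state, so the cycle is continuous at $t = 0$.

The drift phases have no empirically measured trajectory; linear
interpolation (piecewise for phase 1) is an explicit assumption. Snapshot
times are sampled uniformly, reflecting the view of field samples as random
draws along such cycles. By construction, the fraction of cycle time with
median rank outside 1–4 is ≈ 0.046 (overshoot 0.012 + crash 0.01 + the
~60% of the recovery spent above rank 4), and the acceptance suite verifies
0.05 ± 0.01 over 10,000 uniform snapshots, with 85-snapshot outlier counts
consistent with Binomial(85, ~0.05) — mean ≈ 4.2, so observing four
outliers among 85 samples is a typical draw.

**Survey designs** (`generate_dataset()`): the default design is a
five-cruise (September 2008, March/September 2010 and 2011) depth-profile
survey totalling 85 samples (0–160 m every 20 m plus 200/300/400 m on all
cruises; 180 m in 2008/2011, 250 m in 2010/2011, 500–1,000 m in
2008/2011). OTUs carry occupancy classes: 5 persistent OTUs supply every
sample's abundant group (2–4 members, abundant mass U(0.55, 0.65),
geometric ratio U(0.45, 0.75) — ranges chosen a priori so per-sample median
ranks spread over the stable 1–4 band); 30 seasonal OTUs per month appear
only in their season; 30 depth-restricted OTUs alternate between the photic
(≤ 100 m) and deep (≥ 300 m) zones; the 500 sporadic bank OTUs appear per
sample with probability 0.15. Read depths are lognormal around a median of
3,028, clipped to [288, 12,791]. One parent seed spawns per-sample child
seeds, so runs are reproducible and samples independent.

**What a green test does and does not establish.** The generator reproduces
the *statistical shape* the analysis assumes — dominance structure,
occupancy classes, seasonal/depth blocks, realistic read depths — but none
of the things real amplicon data adds on top: PCR and amplification bias,
chimeras, sequencing error, compositional coupling between OTUs, or
phylogenetic structure. Green structure-recovery tests certify the
estimators on data satisfying their assumptions; they say nothing about
robustness to those artifacts.

`block_dataset()` is a deliberately clean variant — disjoint abundant trios
per block over a shared bank — used for cluster-recovery acceptance checks
(adjusted Rand ≥ 0.9 at the true block count, block nodes above the
75-point stability tier).

# Degenerate inputs and numerical choices

* Zero-sum samples are dropped (with a warning) at table construction;
  OTU subsetting can recreate them, and `relative_abundance()` then
  refuses to divide by zero.
* All-zero OTU columns are retained through subsetting and serialization
  (silent dimension changes are worse than carrying empty columns);
  per-sample statistics ignore them.
* Missing covariates parse to `NA` with the original token (e.g. "BDL",
  "n.d.") preserved as the missing reason — never to 0.
* Fraction-vector sums are checked to 1e-9; median-rank knot ties to
  1e-12; distance symmetry to 1e-12.
* PERMANOVA p-values use the +1 permutation correction, so p is never 0.
* RAD fits flag rather than hide non-convergence, and `best_model()`
  refuses to adjudicate between an unconverged field.

# Known limitations

* The lognormal RAD quantile form depends on the observed rank count $S$,
  so heavy sampling zeros (shallow depths, long tails) bias $\sigma$
  upward; the gaussian-in-logrank form is less exposed but has one more
  parameter.
* Jaccard stability resamples whole samples; it does not model read-level
  resampling uncertainty.
* PERMANOVA here is one-way only (no strata, no interactions, no
  dispersion test); pairwise mode inherits the usual caveat that pairwise
  pseudo-F values are not independent.
* The kill-the-winner generator is a kinematic description of a cycle in
  composition space, not a mechanistic phage–host dynamical model.
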