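Package: rankbank
Title: Rank-Abundance, Median-Rank and Bank-Model Analysis of Amplicon
    OTU Tables
Version: 0.1.0
Authors@R: person("rankbank", "maintainers", email = "rankbank@example.org",
    role = c("aut", "cre"))
Description: Community-ecology analysis of marker-gene OTU count tables from
    depth/time survey designs: the interpolated median-rank dominance
    statistic with outlier classification and dwell-fraction estimation,
    least-squares rank-abundance-distribution fits (power law, exponential,
    lognormal), analytic rarefaction, Chao1 and inverse Simpson diversity,
    Bray-Curtis (and other) distance matrices, UPGMA clustering with
    bootstrap Jaccard stability, permutational MANOVA (global and pairwise),
    and OTU dominance/occupancy/group composition summaries. Includes a
    synthetic community generator implementing a bank model (few abundant
    OTUs over a large rare tail) and kill-the-winner cycle snapshots, plus a
    reproducible pipeline runner and command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    ape,
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
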