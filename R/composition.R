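#' Global OTU dominance summary
#'
#' Ranks OTUs by total sequence count across all samples and reports each
#' OTU's share of the dataset, the cumulative share at every rank, and how
#' many OTUs exceed each of a set of global-share thresholds (default 1%,
#' 0.1%, 0.01%).
#'
#' @param x An [otu_table()].
#' @param thresholds Global-share thresholds (fractions) to count OTUs over.
#' @return A list with `otus` (data.frame: `otu_id`, `total`, `share`,
#'   `cum_share`, ordered by decreasing share) and `threshold_counts`
#'   (named integer vector).
#' @export
top_otu_summary <- function(x, thresholds = c(0.01, 0.001, 1e-4)) {
  stopifnot(inherits(x, "otu_table"))
  totals <- colSums(x$counts)
  ord <- order(totals, decreasing = TRUE)
  share <- totals[ord] / sum(totals)
  df <- data.frame(otu_id = colnames(x$counts)[ord],
                   total = unname(totals[ord]), share = unname(share),
                   cum_share = unname(cumsum(share)),
                   stringsAsFactors = FALSE)
  counts <- vapply(thresholds, function(t) sum(share >= t), integer(1))
  names(counts) <- paste0(">=", format(100 * thresholds, trim = TRUE,
                                       scientific = FALSE), "%")
  list(otus = df, threshold_counts = counts)
}

# Panel rule shared by the dot-plot style summaries: an OTU enters the panel
# if it holds >= global_threshold of all sequences, or >= sample_threshold
# of at least one individual sample. Always recomputed from the table.
selection_panel <- function(rel, totals_share, global_threshold,
                            sample_threshold) {
  global_in <- totals_share >= global_threshold
  sample_in <- apply(rel, 2, max) >= sample_threshold
  colnames(rel)[global_in | sample_in]
}

#' Per-sample contribution matrix for the dominant-OTU panel
#'
#' Builds the samples x OTUs matrix of per-sample fractions for the OTU
#' panel defined as the union of OTUs holding at least `global_threshold` of
#' all sequences and OTUs holding at least `sample_threshold` of any single
#' sample (the panel is recomputed from the table, never user-supplied).
#' Entries below `min_fraction` are masked as `NA` — explicitly masked, not
#' zero — mirroring dot-plot displays that omit sub-1% contributions. OTU
#' columns are ordered by decreasing largest single-sample contribution.
#'
#' @param x An [otu_table()].
#' @param min_fraction Mask entries below this per-sample fraction
#'   (default 0.01).
#' @param global_threshold Panel rule on the OTU's share of all sequences
#'   (default 0.001).
#' @param sample_threshold Panel rule on the OTU's share of any one sample
#'   (default 0.01).
#' @return Numeric matrix (samples x panel OTUs) with masked entries `NA`
#'   and attribute `panel` (the panel OTU ids).
#' @export
sample_contribution_matrix <- function(x, min_fraction = 0.01,
                                       global_threshold = 0.001,
                                       sample_threshold = 0.01) {
  stopifnot(inherits(x, "otu_table"))
  rel <- relative_abundance(x)
  totals_share <- colSums(x$counts) / sum(x$counts)
  panel <- selection_panel(rel, totals_share, global_threshold,
                           sample_threshold)
  if (length(panel) == 0) stopf("no OTUs pass the panel thresholds")
  sub <- rel[, panel, drop = FALSE]
  sub <- sub[, order(apply(sub, 2, max), decreasing = TRUE), drop = FALSE]
  sub[sub < min_fraction] <- NA_real_
  attr(sub, "panel") <- colnames(sub)
  sub
}

#' OTU occupancy and persistence classification
#'
#' Counts the samples in which each OTU is "present" and classifies OTUs as
#' `persistent` (present in at least `persistent_cutoff` of samples),
#' `sporadic` (at most `sporadic_cutoff`), or `intermediate`. Presence
#' defaults to holding at least `presence_fraction` of a sample's sequences
#' (single stray reads are noise-prone in amplicon data);
#' `mode = "reads"` restores presence = at least one read.
#'
#' @param x An [otu_table()].
#' @param presence_fraction Presence threshold on per-sample fraction
#'   (default 0.01; ignored when `mode = "reads"`).
#' @param mode `"fraction"` (default) or `"reads"`.
#' @param persistent_cutoff,sporadic_cutoff Occupancy-fraction cutoffs for
#'   the classification (defaults 0.9 and 0.25).
#' @return A `data.frame`: `otu_id`, `n_present`, `occupancy`, `class`.
#' @export
occupancy <- function(x, presence_fraction = 0.01,
                      mode = c("fraction", "reads"),
                      persistent_cutoff = 0.9, sporadic_cutoff = 0.25) {
  mode <- match.arg(mode)
  stopifnot(inherits(x, "otu_table"))
  present <- if (mode == "reads") x$counts >= 1
  else relative_abundance(x) >= presence_fraction
  n_present <- colSums(present)
  occ <- n_present / nrow(x$counts)
  cls <- ifelse(occ >= persistent_cutoff, "persistent",
         ifelse(occ <= sporadic_cutoff, "sporadic", "intermediate"))
  data.frame(otu_id = colnames(x$counts), n_present = unname(n_present),
             occupancy = unname(occ), class = unname(cls),
             stringsAsFactors = FALSE)
}

#' Group-level composition
#'
#' Aggregates per-sample OTU fractions by a user-supplied OTU-to-group map
#' (e.g. phylogenetic groups assigned to the dominant OTUs). OTUs absent
#' from the map fall into `"ungrouped"`, so each sample's group fractions
#' sum to 1. Map entries naming OTUs that do not occur in the table are
#' ignored with a warning.
#'
#' @param x An [otu_table()].
#' @param map Named character vector (`names` = otu ids, values = group
#'   labels) or a 2-column data frame (`otu_id`, `group`).
#' @return Numeric matrix samples x groups (including `"ungrouped"` when
#'   needed); rows sum to 1.
#' @export
group_composition <- function(x, map) {
  stopifnot(inherits(x, "otu_table"))
  if (is.data.frame(map)) {
    if (!all(c("otu_id", "group") %in% names(map)))
      stopf("map data frame needs columns 'otu_id' and 'group'")
    map <- stats::setNames(as.character(map$group), map$otu_id)
  }
  unknown <- setdiff(names(map), colnames(x$counts))
  if (length(unknown) > 0) {
    warnf("ignoring %d mapped OTU id(s) absent from the table: %s",
          length(unknown), paste(utils::head(unknown, 5), collapse = ", "))
    map <- map[setdiff(names(map), unknown)]
  }
  groups <- rep("ungrouped", ncol(x$counts))
  names(groups) <- colnames(x$counts)
  groups[names(map)] <- map
  rel <- relative_abundance(x)
  levs <- unique(c(sort(unique(unname(map))), if ("ungrouped" %in% groups)
    "ungrouped"))
  out <- vapply(levs, function(g)
    rowSums(rel[, groups == g, drop = FALSE]), numeric(nrow(rel)))
  if (nrow(rel) == 1L) out <- matrix(out, nrow = 1,
                                     dimnames = list(rownames(rel), levs))
  out
}

#' Read an OTU-to-group map
#'
#' @param path CSV with columns `otu_id` and `group`.
#' @return Named character vector suitable for [group_composition()].
#' @export
read_group_map <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("otu_id", "group") %in% names(df)))
    stopf("group map must have columns 'otu_id' and 'group'")
  stats::setNames(as.character(df$group), df$otu_id)
}
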