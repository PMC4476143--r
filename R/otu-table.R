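#' OTU count tables
#'
#' An `otu_table` holds a samples x OTUs matrix of non-negative integer
#' sequence counts, with unique ordered sample and OTU identifiers. Samples
#' are rows and OTUs are columns everywhere in this package (the orientation
#' of a mothur `.shared` file). OTU columns that are all zero are retained
#' (they matter when joining or subsetting tables); per-sample statistics
#' ignore them. Samples whose row sum is zero are dropped at construction
#' with a warning, since no downstream statistic is defined for them.
#'
#' @param counts Numeric matrix of non-negative integers, samples in rows.
#' @param sample_ids,otu_ids Optional identifier vectors; default to the
#'   matrix dimnames.
#' @param label Free-text label carried through serialization (e.g. the OTU
#'   definition, "0.03").
#' @return An object of class `otu_table`.
#' @export
#' @examples
#' m <- matrix(c(5, 0, 1, 0, 2, 2), nrow = 2, byrow = TRUE,
#'             dimnames = list(c("S1", "S2"), c("Otu1", "Otu2", "Otu3")))
#' otu_table(m)
otu_table <- function(counts, sample_ids = rownames(counts),
                      otu_ids = colnames(counts), label = "0.03") {
  if (!is.matrix(counts) || !is.numeric(counts))
    stopf("'counts' must be a numeric matrix (samples x OTUs)")
  if (is.null(sample_ids))
    sample_ids <- paste0("S", seq_len(nrow(counts)))
  if (is.null(otu_ids))
    otu_ids <- sprintf("Otu%04d", seq_len(ncol(counts)))
  sample_ids <- as.character(sample_ids)
  otu_ids <- as.character(otu_ids)
  if (length(sample_ids) != nrow(counts) || length(otu_ids) != ncol(counts))
    stopf("identifier lengths do not match the count matrix")
  if (anyDuplicated(sample_ids))
    stopf("duplicate sample ids: %s",
          paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  if (anyDuplicated(otu_ids))
    stopf("duplicate OTU ids: %s",
          paste(unique(otu_ids[duplicated(otu_ids)]), collapse = ", "))
  bad <- which(is.na(counts) | counts < 0 | counts != round(counts),
               arr.ind = TRUE)
  if (nrow(bad) > 0)
    stopf("invalid count at sample '%s', OTU '%s': %s (must be a non-negative integer)",
          sample_ids[bad[1, 1]], otu_ids[bad[1, 2]],
          format(counts[bad[1, , drop = FALSE]]))
  dimnames(counts) <- list(sample_ids, otu_ids)
  zero <- rowSums(counts) == 0
  if (any(zero)) {
    warnf("dropping %d zero-sum sample(s): %s", sum(zero),
          paste(sample_ids[zero], collapse = ", "))
    counts <- counts[!zero, , drop = FALSE]
  }
  if (nrow(counts) == 0) stopf("no samples left after dropping zero-sum rows")
  structure(list(counts = counts, label = as.character(label)[1]),
            class = "otu_table")
}

#' @export
print.otu_table <- function(x, ...) {
  cat(sprintf("otu_table: %d samples x %d OTUs (label '%s'), %s sequences\n",
              nrow(x$counts), ncol(x$counts), x$label,
              format(sum(x$counts), big.mark = ",")))
  invisible(x)
}

#' @export
dim.otu_table <- function(x) dim(x$counts)

#' Accessors for otu_table identifiers
#' @param x An `otu_table`.
#' @return Character vector of identifiers.
#' @export
sample_ids <- function(x) rownames(x$counts)

#' @rdname sample_ids
#' @export
otu_ids <- function(x) colnames(x$counts)

#' Read an OTU count table
#'
#' Two dialects are supported. `"shared"` is the mothur shared-file layout:
#' a header row `label group numOtus Otu0001 ...` followed by one row per
#' sample. `"matrix_tsv"` is a plain tab-separated matrix whose first column
#' holds sample ids and whose header names the OTUs. Zero-sum samples are
#' dropped with a warning; all-zero OTU columns are kept.
#'
#' @param path Path to the file.
#' @param dialect `"shared"` or `"matrix_tsv"`.
#' @return An [otu_table()].
#' @export
read_otu_table <- function(path, dialect = c("shared", "matrix_tsv")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stopf("file not found: %s", path)
  raw <- utils::read.table(path, sep = "\t", header = TRUE,
                           check.names = FALSE, stringsAsFactors = FALSE,
                           colClasses = "character", quote = "",
                           comment.char = "")
  if (dialect == "shared") {
    if (ncol(raw) < 4 ||
        !identical(tolower(names(raw)[1:3]), c("label", "group", "numotus")))
      stopf("malformed shared header (line 1): expected 'label\tGroup\tnumOtus\t<otu ids...>', got '%s'",
            paste(utils::head(names(raw), 4), collapse = "\t"))
    ids <- raw[[2]]
    label <- raw[[1]][1]
    body <- raw[, -(1:3), drop = FALSE]
  } else {
    if (ncol(raw) < 2)
      stopf("malformed matrix_tsv header (line 1): need a sample-id column plus at least one OTU column")
    ids <- raw[[1]]
    label <- "0.03"
    body <- raw[, -1, drop = FALSE]
  }
  counts <- parse_count_block(body, ids, path)
  otu_table(counts, sample_ids = ids, otu_ids = names(body), label = label)
}

parse_count_block <- function(body, ids, path) {
  counts <- suppressWarnings(
    vapply(body, as.numeric, numeric(nrow(body))))
  if (nrow(body) == 1L) counts <- matrix(counts, nrow = 1L,
                                         dimnames = list(NULL, names(body)))
  bad <- which(is.na(counts) | counts < 0 | counts != round(counts),
               arr.ind = TRUE)
  if (length(bad) > 0) {
    i <- bad[1, 1]; j <- bad[1, 2]
    stopf("%s: invalid count '%s' at row %d (sample '%s'), column '%s'",
          path, body[i, j], i, ids[i], names(body)[j])
  }
  rownames(counts) <- ids
  counts
}

#' Write an OTU count table
#'
#' Inverse of [read_otu_table()]; a write/read round trip reproduces counts
#' and identifier order exactly in either dialect.
#'
#' @param x An `otu_table`.
#' @param path Output path.
#' @param dialect `"shared"` or `"matrix_tsv"`.
#' @return `path`, invisibly.
#' @export
write_otu_table <- function(x, path, dialect = c("shared", "matrix_tsv")) {
  dialect <- match.arg(dialect)
  counts <- x$counts
  storage.mode(counts) <- "integer"
  if (dialect == "shared") {
    df <- data.frame(label = x$label, Group = rownames(counts),
                     numOtus = ncol(counts), counts, check.names = FALSE,
                     stringsAsFactors = FALSE)
  } else {
    df <- data.frame(sample_id = rownames(counts), counts,
                     check.names = FALSE, stringsAsFactors = FALSE)
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Relative abundances
#'
#' Converts counts to within-sample fractions; every row of the result sums
#' to 1 (to within 1e-9) and zero counts stay exactly zero.
#'
#' @param x An `otu_table`.
#' @return Numeric matrix of fractions with the same dimnames as the counts.
#' @export
relative_abundance <- function(x) {
  stopifnot(inherits(x, "otu_table"))
  rs <- rowSums(x$counts)
  if (any(rs == 0))
    stopf("zero-sum sample(s) present (%s); these should have been dropped at read time",
          paste(rownames(x$counts)[rs == 0], collapse = ", "))
  sweep(x$counts, 1, rs, "/")
}

#' Subset an OTU table by sample and/or OTU ids
#'
#' Retains the requested identifiers in the order given; counts are copied
#' unchanged (a sample whose retained OTUs are all zero is kept, and will be
#' rejected later by [relative_abundance()]).
#'
#' @param x An `otu_table`.
#' @param samples,otus Character vectors of ids to keep; `NULL` keeps all.
#' @param ... Unused.
#' @return An `otu_table`.
#' @export
subset.otu_table <- function(x, samples = NULL, otus = NULL, ...) {
  counts <- x$counts
  if (!is.null(samples)) {
    if (length(samples) == 0) stopf("empty sample id selection")
    missing <- setdiff(samples, rownames(counts))
    if (length(missing) > 0)
      stopf("unknown sample id(s): %s", paste(missing, collapse = ", "))
    counts <- counts[samples, , drop = FALSE]
  }
  if (!is.null(otus)) {
    if (length(otus) == 0) stopf("empty OTU id selection")
    missing <- setdiff(otus, colnames(counts))
    if (length(missing) > 0)
      stopf("unknown OTU id(s): %s", paste(missing, collapse = ", "))
    counts <- counts[, otus, drop = FALSE]
  }
  structure(list(counts = counts, label = x$label), class = "otu_table")
}
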