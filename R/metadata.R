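#' Read a sample metadata table
#'
#' Expects a CSV with required columns `sample_id`, `month`, `year`,
#' `depth_m`; any further columns are kept as numeric environmental
#' covariates. Covariate cells that are not numbers — below-detection-limit
#' codes ("BDL"), no-data codes ("n.d.", "nd"), or blanks — become `NA`,
#' never 0, and the original token is kept in the `missing_reason`
#' attribute (a character matrix parallel to the covariate columns).
#'
#' @param path Path to the CSV file.
#' @return A `data.frame` of class `sample_metadata` with normalized month
#'   names, plus attribute `missing_reason`.
#' @export
read_metadata <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  raw <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                         colClasses = "character")
  required <- c("sample_id", "month", "year", "depth_m")
  missing <- setdiff(required, names(raw))
  if (length(missing) > 0)
    stopf("metadata is missing required column(s): %s",
          paste(missing, collapse = ", "))
  if (anyDuplicated(raw$sample_id))
    stopf("duplicate sample_id in metadata: %s",
          paste(unique(raw$sample_id[duplicated(raw$sample_id)]),
                collapse = ", "))
  month <- normalize_month(raw$month)
  year <- as.integer(raw$year)
  if (anyNA(year)) stopf("non-integer 'year' value in metadata")
  depth <- suppressWarnings(as.numeric(raw$depth_m))
  if (anyNA(depth) || any(depth < 0))
    stopf("'depth_m' must be non-negative numbers")
  out <- data.frame(sample_id = raw$sample_id, month = month, year = year,
                    depth_m = depth, stringsAsFactors = FALSE)
  covars <- setdiff(names(raw), required)
  reasons <- NULL
  if (length(covars) > 0) {
    reasons <- matrix(NA_character_, nrow(raw), length(covars),
                      dimnames = list(raw$sample_id, covars))
    for (cv in covars) {
      txt <- trimws(raw[[cv]])
      val <- suppressWarnings(as.numeric(txt))
      flagged <- is.na(val) & !is.na(txt) & txt != "" &
        !toupper(txt) %in% "NA"
      reasons[flagged, cv] <- txt[flagged]
      out[[cv]] <- val
    }
  }
  structure(out, missing_reason = reasons,
            class = c("sample_metadata", "data.frame"))
}

normalize_month <- function(x) {
  idx <- match(tolower(trimws(x)), tolower(month.name))
  abbr <- match(tolower(substr(trimws(x), 1, 3)), tolower(month.abb))
  idx[is.na(idx)] <- abbr[is.na(idx)]
  if (anyNA(idx))
    stopf("invalid calendar month(s): %s",
          paste(unique(x[is.na(idx)]), collapse = ", "))
  month.name[idx]
}

#' Write a sample metadata table
#'
#' @param meta A `sample_metadata` data frame (or plain data frame with the
#'   required columns).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_metadata <- function(meta, path) {
  utils::write.csv(as.data.frame(meta), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
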