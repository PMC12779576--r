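#' Cohort metadata
#'
#' One row per scan session. Columns:
#' `subject_id`, `session_id`, `sex` ("female"/"male"), `birth_age_weeks`
#' (post-menstrual age at birth), `scan_age_days` (post-menstrual age at
#' scan), `pregnancy` ("singleton"/"multifetal"), `twin_pair` (pair id or
#' `NA`), `zygosity` ("MZ"/"DZ"/"unknown"). Longitudinal subjects repeat
#' `subject_id` across sessions. Twin pairs must have exactly two member
#' subjects.
#'
#' @param data Data frame with the columns above.
#' @return A validated tibble (class `cohort_metadata` prepended).
#' @export
cohort_metadata <- function(data) {
  data <- as_tibble(data)
  needed <- c("subject_id", "session_id", "sex", "birth_age_weeks",
              "scan_age_days", "pregnancy", "twin_pair", "zygosity")
  miss <- setdiff(needed, names(data))
  if (length(miss) > 0) {
    abort(sprintf("metadata is missing columns: %s",
                  paste(miss, collapse = ", ")))
  }
  if (any(data$birth_age_weeks <= 0, na.rm = TRUE)) {
    abort("birth_age_weeks must be positive.")
  }
  if (any(data$scan_age_days < 0, na.rm = TRUE)) {
    abort("scan_age_days must be non-negative.")
  }
  pairs <- data |>
    dplyr::filter(!is.na(.data$twin_pair)) |>
    dplyr::distinct(.data$twin_pair, .data$subject_id) |>
    dplyr::count(.data$twin_pair)
  bad <- pairs$twin_pair[pairs$n != 2L]
  if (length(bad) > 0) {
    abort(sprintf("twin pairs without exactly two members: %s",
                  paste(bad, collapse = ", ")))
  }
  class(data) <- c("cohort_metadata", class(data))
  data
}

#' Read cohort metadata from CSV
#'
#' @param path CSV with the [cohort_metadata()] column schema.
#' @return A validated `cohort_metadata` tibble.
#' @export
read_metadata_table <- function(path) {
  cohort_metadata(readr::read_csv(path, show_col_types = FALSE))
}

#' Feature tables
#'
#' A feature table is a tibble with a `scan_id` key column followed by one
#' numeric column per region, holding one morphological measure (FD or
#' volume) for every scan: the regional shape (or size) profile that all
#' downstream similarity, normative and prediction stages consume. Region
#' order is part of the object and fixed across rows.
#'
#' @param data Data frame: first column the scan key, remaining columns
#'   numeric regional values.
#' @param measure Measure name, e.g. `"fd"` or `"volume"`.
#' @return A tibble with class `feature_table` and attribute `measure`.
#' @export
feature_table <- function(data, measure = "fd") {
  data <- as_tibble(data)
  if (ncol(data) < 2L) abort("a feature table needs >= 1 region column.")
  if (names(data)[1] != "scan_id") names(data)[1] <- "scan_id"
  if (anyDuplicated(data$scan_id)) abort("duplicated scan_id keys.")
  for (j in seq(2L, ncol(data))) {
    if (!is.numeric(data[[j]])) {
      abort(sprintf("region column `%s` is not numeric.", names(data)[j]))
    }
  }
  attr(data, "measure") <- measure
  class(data) <- c("feature_table", class(data))
  data
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("<feature_table> measure '%s': %d scans x %d regions\n",
              attr(x, "measure"), nrow(x), ncol(x) - 1L))
  NextMethod()
}

region_names <- function(features) names(features)[-1L]

feature_matrix <- function(features) {
  m <- as.matrix(features[, -1L, drop = FALSE])
  rownames(m) <- features$scan_id
  m
}

#' Write / read a feature table as CSV
#'
#' Values are written as decimal text with enough digits to round-trip
#' doubles exactly; re-reading reproduces the table bit-identically.
#'
#' @param features A [feature_table()].
#' @param path Output CSV path.
#' @return `path` invisibly; `read_feature_table()` returns the table.
#' @export
write_feature_table <- function(features, path) {
  stopifnot(inherits(features, "feature_table"))
  if (ncol(features) < 2L) abort("empty region list.")
  readr::write_csv(as_tibble(features), path)
  invisible(path)
}

#' @rdname write_feature_table
#' @param measure Measure name to attach on read.
#' @export
read_feature_table <- function(path, measure = "fd") {
  feature_table(readr::read_csv(path, show_col_types = FALSE,
                                col_types = readr::cols(
                                  scan_id = readr::col_character(),
                                  .default = readr::col_double())),
                measure = measure)
}
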