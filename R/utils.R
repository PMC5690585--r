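# Shared internal helpers: age arithmetic, age bands, ICD-9 normalization.

# Completed years between `birth_date` and `ref_date` (both Date).
# floor() on fractional years is wrong across leap days; compare month/day.
age_at <- function(birth_date, ref_date) {
  by <- lubridate::year(birth_date)
  ry <- lubridate::year(ref_date)
  before_birthday <- (lubridate::month(ref_date) < lubridate::month(birth_date)) |
    (lubridate::month(ref_date) == lubridate::month(birth_date) &
       lubridate::day(ref_date) < lubridate::day(birth_date))
  as.integer(ry - by - before_birthday)
}

#' Age-band labels used throughout the index
#'
#' The five bands (65-69, 70-74, 75-79, 80-84, >=85) on which deficit
#' prevalence trends are assessed.
#'
#' @param age integer vector of completed years.
#' @return ordered factor with levels `"65-69" ... ">=85"`; ages outside
#'   65+ give `NA`.
#' @export
age_band <- function(age) {
  cut(age,
      breaks = c(65, 70, 75, 80, 85, Inf),
      labels = mfi_age_bands(),
      right = FALSE, ordered_result = TRUE)
}

# Canonical band labels, oldest last.
mfi_age_bands <- function() c("65-69", "70-74", "75-79", "80-84", ">=85")

# Strip dots and whitespace from ICD-9-CM codes ("428.0" -> "4280").
icd9_normalize <- function(codes) {
  gsub("[.[:space:]]", "", codes)
}

# Parse ISO dates strictly; NA for empty strings, error (with context) on
# malformed values.
parse_iso_date <- function(x, column, file = NULL) {
  x[!is.na(x) & x == ""] <- NA_character_
  out <- as.Date(rep(NA_real_, length(x)), origin = "1970-01-01")
  idx <- !is.na(x)
  parsed <- as.Date(x[idx], format = "%Y-%m-%d")
  if (anyNA(parsed)) {
    bad <- which(idx)[is.na(parsed)]
    abort(sprintf(
      "Malformed date in column '%s'%s at row(s) %s: %s",
      column,
      if (is.null(file)) "" else paste0(" of '", file, "'"),
      paste(head(bad, 5), collapse = ", "),
      paste(head(x[bad], 5), collapse = ", ")
    ), class = "mfi_schema_error")
  }
  out[idx] <- parsed
  out
}

# Stop unless `x` is a data frame containing all `cols`.
check_columns <- function(x, cols, what) {
  if (!is.data.frame(x)) {
    abort(sprintf("`%s` must be a data frame.", what), class = "mfi_type_error")
  }
  missing_cols <- setdiff(cols, names(x))
  if (length(missing_cols) > 0) {
    abort(sprintf("`%s` is missing column(s): %s", what,
                  paste(missing_cols, collapse = ", ")),
          class = "mfi_schema_error")
  }
  invisible(x)
}
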