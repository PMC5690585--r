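# Claims data model: reading/writing the delimited-text dialect and cohort
# screening.
#
# Dialect: UTF-8 CSV, one header row, ISO-8601 dates, ";" separating
# multiple diagnosis codes within one field, empty string for missing
# optional values. ICD-9-CM codes are accepted with or without the decimal
# point ("428.0" and "4280" are the same code).

#' Read a beneficiary registry table
#'
#' Expects columns `person_id, sex, birth_date, coverage_start,
#' coverage_end, death_date` (CSV, ISO dates, empty `death_date` for
#' persons alive at the end of data). Death is recorded as disenrollment:
#' when present, `death_date` must equal `coverage_end`.
#'
#' @param path file path to a beneficiaries CSV.
#' @return tibble with one row per beneficiary; dates parsed to `Date`,
#'   `sex` a factor with levels `male`, `female`.
#' @export
read_beneficiaries <- function(path) {
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  check_columns(raw, c("person_id", "sex", "birth_date", "coverage_start",
                       "coverage_end", "death_date"), "beneficiaries file")
  if (nrow(raw) == 0) {
    return(tibble(person_id = character(), sex = factor(levels = c("male", "female")),
                  birth_date = as.Date(character()), coverage_start = as.Date(character()),
                  coverage_end = as.Date(character()), death_date = as.Date(character())))
  }
  dup <- raw$person_id[duplicated(raw$person_id)]
  if (length(dup) > 0) {
    abort(sprintf("Duplicate person_id in '%s': %s", path,
                  paste(unique(head(dup, 5)), collapse = ", ")),
          class = "mfi_schema_error")
  }
  bad_sex <- which(!raw$sex %in% c("male", "female"))
  if (length(bad_sex) > 0) {
    abort(sprintf("Unknown sex code in column 'sex' of '%s' at row(s) %s: %s",
                  path, paste(head(bad_sex, 5), collapse = ", "),
                  paste(head(raw$sex[bad_sex], 5), collapse = ", ")),
          class = "mfi_schema_error")
  }
  out <- tibble(
    person_id = raw$person_id,
    sex = factor(raw$sex, levels = c("male", "female")),
    birth_date = parse_iso_date(raw$birth_date, "birth_date", path),
    coverage_start = parse_iso_date(raw$coverage_start, "coverage_start", path),
    coverage_end = parse_iso_date(raw$coverage_end, "coverage_end", path),
    death_date = parse_iso_date(raw$death_date, "death_date", path)
  )
  validate_beneficiaries(out)
  out
}

validate_beneficiaries <- function(x) {
  bad <- which(x$coverage_start > x$coverage_end)
  if (length(bad) > 0) {
    abort(sprintf("coverage_start after coverage_end at row(s) %s",
                  paste(head(bad, 5), collapse = ", ")),
          class = "mfi_schema_error")
  }
  has_death <- !is.na(x$death_date)
  bad <- which(has_death & x$death_date < x$birth_date)
  if (length(bad) > 0) {
    abort(sprintf("death_date before birth_date at row(s) %s",
                  paste(head(bad, 5), collapse = ", ")),
          class = "mfi_schema_error")
  }
  bad <- which(has_death & x$death_date != x$coverage_end)
  if (length(bad) > 0) {
    abort(sprintf(
      "death_date must equal coverage_end (death is disenrollment); row(s) %s",
      paste(head(bad, 5), collapse = ", ")), class = "mfi_schema_error")
  }
  invisible(x)
}

#' Write a beneficiary registry table
#'
#' Emits the same dialect [read_beneficiaries()] reads, bit-stable: fixed
#' column order, ISO dates, empty string for missing `death_date`.
#'
#' @param x beneficiaries tibble.
#' @param path output file path.
#' @return `x`, invisibly.
#' @export
write_beneficiaries <- function(x, path) {
  check_columns(x, c("person_id", "sex", "birth_date", "coverage_start",
                     "coverage_end", "death_date"), "beneficiaries")
  out <- x[, c("person_id", "sex", "birth_date", "coverage_start",
               "coverage_end", "death_date")]
  readr::write_csv(out, path, na = "", progress = FALSE)
  invisible(x)
}

#' Read a claims table
#'
#' Expects columns `person_id, setting, service_date, admission_date,
#' discharge_date, diagnosis_codes, ed_flag, icu_flag`. `setting` is
#' `outpatient` (requires `service_date`) or `inpatient` (requires
#' `admission_date <= discharge_date`). `diagnosis_codes` is a
#' ";"-separated list, split into a character-vector list-column with
#' whitespace trimmed and order preserved. `ed_flag`/`icu_flag` mark
#' admission via the emergency department and ICU service use; they are
#' only meaningful on inpatient claims (an outpatient claim with a flag set
#' is accepted with a warning and the flag is ignored downstream).
#'
#' @param path file path to a claims CSV.
#' @return tibble of claims with `diagnosis_codes` as a list-column.
#' @export
read_claims <- function(path) {
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  check_columns(raw, c("person_id", "setting", "service_date", "admission_date",
                       "discharge_date", "diagnosis_codes", "ed_flag", "icu_flag"),
                "claims file")
  if (nrow(raw) == 0) {
    return(tibble(person_id = character(),
                  setting = factor(levels = c("outpatient", "inpatient")),
                  service_date = as.Date(character()),
                  admission_date = as.Date(character()),
                  discharge_date = as.Date(character()),
                  diagnosis_codes = list(), ed_flag = logical(), icu_flag = logical()))
  }
  bad <- which(!raw$setting %in% c("outpatient", "inpatient"))
  if (length(bad) > 0) {
    abort(sprintf("Unknown setting in '%s' at row(s) %s: %s", path,
                  paste(head(bad, 5), collapse = ", "),
                  paste(head(raw$setting[bad], 5), collapse = ", ")),
          class = "mfi_schema_error")
  }
  out <- tibble(
    person_id = raw$person_id,
    setting = factor(raw$setting, levels = c("outpatient", "inpatient")),
    service_date = parse_iso_date(raw$service_date, "service_date", path),
    admission_date = parse_iso_date(raw$admission_date, "admission_date", path),
    discharge_date = parse_iso_date(raw$discharge_date, "discharge_date", path),
    diagnosis_codes = parse_code_field(raw$diagnosis_codes, path),
    ed_flag = parse_flag(raw$ed_flag, "ed_flag", path),
    icu_flag = parse_flag(raw$icu_flag, "icu_flag", path)
  )
  validate_claims(out)
  out
}

parse_code_field <- function(x, file = NULL) {
  empty <- which(is.na(x) | trimws(x) == "")
  if (length(empty) > 0) {
    abort(sprintf("Empty diagnosis_codes field%s at row(s) %s",
                  if (is.null(file)) "" else paste0(" in '", file, "'"),
                  paste(head(empty, 5), collapse = ", ")),
          class = "mfi_schema_error")
  }
  lapply(strsplit(x, ";", fixed = TRUE), trimws)
}

parse_flag <- function(x, column, file = NULL) {
  x <- tolower(trimws(x))
  x[is.na(x) | x == ""] <- "false"
  ok <- x %in% c("true", "false", "1", "0", "t", "f")
  if (!all(ok)) {
    abort(sprintf("Unparseable boolean in column '%s'%s at row(s) %s", column,
                  if (is.null(file)) "" else paste0(" of '", file, "'"),
                  paste(head(which(!ok), 5), collapse = ", ")),
          class = "mfi_schema_error")
  }
  x %in% c("true", "1", "t")
}

validate_claims <- function(x) {
  inpat <- x$setting == "inpatient"
  bad <- which(inpat & (is.na(x$admission_date) | is.na(x$discharge_date)))
  if (length(bad) > 0) {
    abort(sprintf("Inpatient claim missing admission/discharge date at row(s) %s",
                  paste(head(bad, 5), collapse = ", ")),
          class = "mfi_schema_error")
  }
  bad <- which(inpat & x$discharge_date < x$admission_date)
  if (length(bad) > 0) {
    abort(sprintf("Inpatient claim with discharge before admission at row(s) %s",
                  paste(head(bad, 5), collapse = ", ")),
          class = "mfi_schema_error")
  }
  bad <- which(!inpat & is.na(x$service_date))
  if (length(bad) > 0) {
    abort(sprintf("Outpatient claim missing service_date at row(s) %s",
                  paste(head(bad, 5), collapse = ", ")),
          class = "mfi_schema_error")
  }
  n_flagged <- sum(!inpat & (x$ed_flag | x$icu_flag))
  if (n_flagged > 0) {
    warn(sprintf(
      "%d outpatient claim(s) carry ed_flag/icu_flag; flags are ignored outside inpatient claims.",
      n_flagged))
  }
  invisible(x)
}

#' Write a claims table
#'
#' Inverse of [read_claims()]: stable column order, ";"-joined diagnosis
#' codes, lower-case `true`/`false` flags, empty strings for missing dates.
#'
#' @param x claims tibble (as returned by [read_claims()] or
#'   [simulate_cohort()]).
#' @param path output file path.
#' @return `x`, invisibly.
#' @export
write_claims <- function(x, path) {
  check_columns(x, c("person_id", "setting", "service_date", "admission_date",
                     "discharge_date", "diagnosis_codes", "ed_flag", "icu_flag"),
                "claims")
  out <- tibble(
    person_id = x$person_id,
    setting = as.character(x$setting),
    service_date = x$service_date,
    admission_date = x$admission_date,
    discharge_date = x$discharge_date,
    diagnosis_codes = vapply(x$diagnosis_codes, paste, character(1), collapse = ";"),
    ed_flag = ifelse(x$ed_flag, "true", "false"),
    icu_flag = ifelse(x$icu_flag, "true", "false")
  )
  readr::write_csv(out, path, na = "", progress = FALSE)
  invisible(x)
}

#' Screen the study cohort
#'
#' Keeps beneficiaries who (a) are within `age_range` in completed years at
#' the start of the baseline window, and (b) hold continuous coverage over
#' the whole baseline window (which excludes anyone dying during baseline,
#' since death ends coverage). Each excluded person is attributed to the
#' first failing criterion, checked in the order age, death-in-baseline,
#' coverage.
#'
#' @param beneficiaries tibble from [read_beneficiaries()].
#' @param baseline_window length-2 `Date` (or ISO string) vector, default
#'   2005-01-01 .. 2005-12-31.
#' @param age_range inclusive completed-years range, default `c(65, 100)`.
#' @return tibble with columns `person_id, sex, age_at_baseline, age_band`;
#'   attributes `baseline_window` and `exclusions` (tibble of
#'   `person_id, reason`).
#' @export
select_study_cohort <- function(beneficiaries,
                                baseline_window = c("2005-01-01", "2005-12-31"),
                                age_range = c(65, 100)) {
  check_columns(beneficiaries, c("person_id", "sex", "birth_date",
                                 "coverage_start", "coverage_end", "death_date"),
                "beneficiaries")
  baseline_window <- as.Date(baseline_window)
  if (length(baseline_window) != 2 || anyNA(baseline_window) ||
      baseline_window[1] > baseline_window[2]) {
    abort("`baseline_window` must be two ordered dates.", class = "mfi_config_error")
  }
  age <- age_at(beneficiaries$birth_date, baseline_window[1])
  age_ok <- age >= age_range[1] & age <= age_range[2]
  died_in_baseline <- !is.na(beneficiaries$death_date) &
    beneficiaries$death_date >= baseline_window[1] &
    beneficiaries$death_date <= baseline_window[2]
  coverage_ok <- beneficiaries$coverage_start <= baseline_window[1] &
    beneficiaries$coverage_end >= baseline_window[2]

  reason <- rep(NA_character_, nrow(beneficiaries))
  reason[!age_ok] <- "age"
  reason[is.na(reason) & died_in_baseline] <- "death"
  reason[is.na(reason) & !coverage_ok] <- "coverage"

  keep <- is.na(reason)
  cohort <- tibble(
    person_id = beneficiaries$person_id[keep],
    sex = beneficiaries$sex[keep],
    age_at_baseline = age[keep],
    age_band = age_band(age[keep])
  ) |>
    arrange(.data$person_id)

  exclusions <- tibble(person_id = beneficiaries$person_id[!keep],
                       reason = reason[!keep])
  if (nrow(cohort) == 0) warn("Study cohort is empty after screening.")
  if (nrow(exclusions) > 0) {
    tab <- table(exclusions$reason)
    inform(sprintf("Excluded %d of %d beneficiaries (%s).",
                   nrow(exclusions), nrow(beneficiaries),
                   paste(sprintf("%s: %d", names(tab), as.integer(tab)),
                         collapse = ", ")))
  }
  attr(cohort, "baseline_window") <- baseline_window
  attr(cohort, "exclusions") <- exclusions
  cohort
}
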