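# Tiny hand-built fixtures shared across test files.

fixture_beneficiaries <- function() {
  tibble::tibble(
    person_id = c("A1", "A2", "A3", "A4", "A5"),
    sex = factor(c("male", "female", "female", "male", "female"),
                 levels = c("male", "female")),
    birth_date = as.Date(c("1935-06-01", "1941-06-01", "1920-03-15",
                           "1930-01-01", "1938-10-20")),
    coverage_start = as.Date(rep("2000-01-01", 5)),
    coverage_end = as.Date(c("2013-12-31", "2013-12-31", "2005-07-01",
                             "2008-03-01", "2013-12-31")),
    death_date = as.Date(c(NA, NA, "2005-07-01", "2008-03-01", NA))
  )
}

make_claim <- function(person_id, setting, date, codes,
                       ed = FALSE, icu = FALSE, los = 3) {
  inpat <- setting == "inpatient"
  tibble::tibble(
    person_id = person_id,
    setting = factor(setting, levels = c("outpatient", "inpatient")),
    service_date = if (inpat) as.Date(NA) else as.Date(date),
    admission_date = if (inpat) as.Date(date) else as.Date(NA),
    discharge_date = if (inpat) as.Date(date) + los else as.Date(NA),
    diagnosis_codes = list(codes),
    ed_flag = ed, icu_flag = icu
  )
}

# survival records in the mfi_survival shape from bare vectors
fixture_records <- function(time, event, group = NULL, age = 75, sex = "female",
                            outcome = "death", horizon_years = 8,
                            horizon = max(time)) {
  n <- length(time)
  out <- tibble::tibble(
    person_id = sprintf("R%03d", seq_len(n)),
    time = time,
    event = event,
    status_reason = ifelse(event == 1, "event", "horizon"),
    age_at_baseline = rep_len(age, n),
    sex = factor(rep_len(sex, n), levels = c("male", "female")),
    frailty_category = if (is.null(group)) {
      factor(rep("fit", n), levels = c("fit", "mild", "moderate", "severe"))
    } else {
      factor(group)
    },
    mfi = 0
  )
  attr(out, "outcome") <- outcome
  attr(out, "horizon_years") <- horizon_years
  attr(out, "horizon_days") <- horizon
  class(out) <- c("mfi_survival", class(out))
  out
}
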