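# Outcome derivation: first events during follow-up and time-to-event
# datasets with administrative censoring at 1/5/8-year horizons.
#
# Time convention: `time` is the follow-up day number, i.e. an event on
# the first day of follow-up has time 1, so all times are > 0. Horizons
# are calendar-exact day counts from the follow-up start (365/1826/2922
# days for 1/5/8 years from 2006-01-01, leap days included).

#' Derive the death outcome
#'
#' Death is the disenrollment date recorded on the registry; an event
#' exists when it falls inside the follow-up window (deaths after the
#' window are administratively censored).
#'
#' @param beneficiaries registry tibble.
#' @param followup_window length-2 date vector, default
#'   2006-01-01 .. 2013-12-31.
#' @return tibble `person_id, event_date` for persons with an in-window
#'   death.
#' @export
derive_death <- function(beneficiaries,
                         followup_window = c("2006-01-01", "2013-12-31")) {
  check_columns(beneficiaries, c("person_id", "death_date"), "beneficiaries")
  fw <- as.Date(followup_window)
  beneficiaries |>
    filter(!is.na(.data$death_date),
           .data$death_date >= fw[1], .data$death_date <= fw[2]) |>
    mutate(event_date = .data$death_date) |>
    select("person_id", "event_date") |>
    as_tibble()
}

#' Derive the unplanned hospitalization outcome
#'
#' An unplanned hospitalization is a hospital admission that followed an
#' emergency-department visit: the first in-window inpatient claim with
#' `ed_flag` set. Non-ED admissions are ignored.
#'
#' @param claims claims tibble.
#' @param followup_window length-2 date vector.
#' @return tibble `person_id, event_date` (first qualifying admission).
#' @export
derive_unplanned_hospitalization <- function(claims,
                                             followup_window = c("2006-01-01", "2013-12-31")) {
  first_flagged_admission(claims, "ed_flag", followup_window)
}

#' Derive the ICU admission outcome
#'
#' First in-window hospital admission with ICU services recorded
#' (`icu_flag`).
#'
#' @inheritParams derive_unplanned_hospitalization
#' @return tibble `person_id, event_date`.
#' @export
derive_icu <- function(claims, followup_window = c("2006-01-01", "2013-12-31")) {
  first_flagged_admission(claims, "icu_flag", followup_window)
}

first_flagged_admission <- function(claims, flag, followup_window) {
  check_columns(claims, c("person_id", "setting", "admission_date", flag), "claims")
  fw <- as.Date(followup_window)
  hits <- claims |>
    filter(.data$setting == "inpatient", .data[[flag]],
           !is.na(.data$admission_date),
           .data$admission_date >= fw[1], .data$admission_date <= fw[2])
  if (nrow(hits) == 0) {
    return(tibble(person_id = character(), event_date = as.Date(character())))
  }
  hits |>
    group_by(.data$person_id) |>
    summarise(event_date = min(.data$admission_date), .groups = "drop") |>
    as_tibble()
}

#' Derive all three outcomes at once
#'
#' Convenience wrapper joining first-event dates for death, unplanned
#' hospitalization and ICU admission with the coverage end used for
#' non-death disenrollment censoring.
#'
#' @param beneficiaries registry tibble.
#' @param claims claims tibble.
#' @param followup_window length-2 date vector.
#' @return tibble `person_id, death_date, unplanned_hospitalization_date,
#'   icu_admission_date, coverage_end` (one row per beneficiary);
#'   attribute `followup_window`.
#' @export
derive_outcomes <- function(beneficiaries, claims,
                            followup_window = c("2006-01-01", "2013-12-31")) {
  fw <- as.Date(followup_window)
  deaths <- derive_death(beneficiaries, fw) |> rename(death_date = "event_date")
  hosp <- derive_unplanned_hospitalization(claims, fw) |>
    rename(unplanned_hospitalization_date = "event_date")
  icu <- derive_icu(claims, fw) |> rename(icu_admission_date = "event_date")
  out <- beneficiaries |>
    select("person_id", "coverage_end") |>
    left_join(deaths, by = "person_id") |>
    left_join(hosp, by = "person_id") |>
    left_join(icu, by = "person_id") |>
    select("person_id", "death_date", "unplanned_hospitalization_date",
           "icu_admission_date", "coverage_end") |>
    as_tibble()
  attr(out, "followup_window") <- fw
  out
}

#' Horizon length in days
#'
#' Calendar-exact day count covered by an `h`-year horizon starting at
#' `followup_start` (leap days included): 365, 1826 and 2922 days for 1, 5
#' and 8 years from 2006-01-01.
#'
#' @param horizon_years positive integer.
#' @param followup_start `Date`.
#' @return integer number of follow-up days.
#' @export
horizon_days <- function(horizon_years, followup_start = as.Date("2006-01-01")) {
  followup_start <- as.Date(followup_start)
  as.integer(lubridate::add_with_rollback(followup_start,
                                          lubridate::years(horizon_years)) -
               followup_start)
}

#' Assemble a time-to-event dataset for one outcome and horizon
#'
#' For each cohort member, follow-up time is the minimum of the outcome
#' event day, the death day (a censoring cause for non-fatal outcomes
#' only), the disenrollment (coverage-end) day, and the horizon; the event
#' indicator is 1 only when the outcome event attains that minimum. On a
#' same-day tie between an admission event and death, the admission counts
#' as the event. Follow-up also stops at the end of the follow-up window
#' regardless of horizon.
#'
#' @param cohort tibble from [select_study_cohort()].
#' @param scores categorized scores
#'   ([compute_mfi()] + [categorize_mfi()]); every cohort member must have
#'   one.
#' @param outcomes tibble from [derive_outcomes()].
#' @param outcome one of `"death"`, `"unplanned_hospitalization"`,
#'   `"icu_admission"`.
#' @param horizon_years horizon in years (1, 5 or 8 in the primary
#'   analysis; any positive integer accepted).
#' @param followup_window length-2 date vector; defaults to the window
#'   stored on `outcomes`.
#' @return tibble of class `mfi_survival` with columns `person_id, time,
#'   event, status_reason, age_at_baseline, sex, frailty_category, mfi`;
#'   `status_reason` is one of `event, death, coverage, horizon`.
#'   Attributes `outcome`, `horizon_years`, `horizon_days`.
#' @export
build_survival_dataset <- function(cohort, scores, outcomes,
                                   outcome = c("death", "unplanned_hospitalization",
                                               "icu_admission"),
                                   horizon_years = 8,
                                   followup_window = attr(outcomes, "followup_window")) {
  outcome <- match.arg(outcome)
  check_columns(cohort, c("person_id", "sex", "age_at_baseline"), "cohort")
  check_columns(scores, c("person_id", "mfi", "frailty_category"), "scores")
  check_columns(outcomes, c("person_id", "death_date", "coverage_end"), "outcomes")
  if (is.null(followup_window)) {
    abort("`followup_window` is required (none stored on `outcomes`).",
          class = "mfi_config_error")
  }
  fw <- as.Date(followup_window)
  missing_scores <- setdiff(cohort$person_id, scores$person_id)
  if (length(missing_scores) > 0) {
    abort(sprintf("%d cohort member(s) have no frailty score; run scoring first.",
                  length(missing_scores)), class = "mfi_data_error")
  }

  d <- cohort |>
    left_join(outcomes, by = "person_id") |>
    left_join(scores[, c("person_id", "mfi", "frailty_category")], by = "person_id")

  event_col <- switch(outcome,
                      death = "death_date",
                      unplanned_hospitalization = "unplanned_hospitalization_date",
                      icu_admission = "icu_admission_date")
  day_of <- function(dates) as.numeric(dates - fw[1]) + 1

  h_days <- min(horizon_days(horizon_years, fw[1]), day_of(fw[2]))
  t_event <- day_of(d[[event_col]])
  t_death <- if (outcome == "death") rep(Inf, nrow(d)) else day_of(d$death_date)
  t_cov <- pmin(day_of(d$coverage_end), day_of(fw[2]))
  t_death[is.na(t_death)] <- Inf
  t_event[is.na(t_event)] <- Inf
  t_cov[is.na(t_cov)] <- Inf

  time <- pmin(t_event, t_death, t_cov, h_days)
  # same-day ties: the outcome event wins over any censoring cause
  event <- as.integer(is.finite(t_event) & t_event <= time)
  reason <- dplyr::case_when(
    event == 1L ~ "event",
    time == h_days & h_days <= pmin(t_death, t_cov) ~ "horizon",
    t_death <= t_cov ~ "death",
    TRUE ~ "coverage"
  )
  if (any(time <= 0)) {
    abort("Derived non-positive follow-up time; check windows.",
          class = "mfi_data_error")
  }

  out <- tibble(
    person_id = d$person_id,
    time = time,
    event = event,
    status_reason = reason,
    age_at_baseline = d$age_at_baseline,
    sex = d$sex,
    frailty_category = d$frailty_category,
    mfi = d$mfi
  )
  attr(out, "outcome") <- outcome
  attr(out, "horizon_years") <- horizon_years
  attr(out, "horizon_days") <- h_days
  class(out) <- c("mfi_survival", class(out))
  out
}
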