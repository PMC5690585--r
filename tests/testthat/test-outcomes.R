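fw <- c("2006-01-01", "2013-12-31")

test_that("death events come from disenrollment within the window", {
  ben <- tibble::tibble(
    person_id = c("A", "B", "C"),
    death_date = as.Date(c("2008-03-01", NA, "2014-02-01")),
    coverage_end = as.Date(c("2008-03-01", "2013-12-31", "2014-02-01"))
  )
  ev <- derive_death(ben, fw)
  expect_equal(ev$person_id, "A")
  expect_equal(ev$event_date, as.Date("2008-03-01"))
})

test_that("unplanned hospitalization is the first in-window ED admission", {
  claims <- dplyr::bind_rows(
    make_claim("A", "inpatient", "2006-02-01", "428"),              # planned
    make_claim("A", "inpatient", "2006-05-01", "428", ed = TRUE),
    make_claim("A", "inpatient", "2007-01-01", "428", ed = TRUE),
    make_claim("B", "inpatient", "2005-06-01", "428", ed = TRUE),   # baseline year
    make_claim("C", "inpatient", "2007-03-01", "428")               # never ED
  )
  ev <- derive_unplanned_hospitalization(claims, fw)
  expect_equal(ev$person_id, "A")
  expect_equal(ev$event_date, as.Date("2006-05-01"))
})

test_that("ICU admission uses the icu flag, first occurrence", {
  claims <- dplyr::bind_rows(
    make_claim("A", "inpatient", "2006-03-01", "428"),
    make_claim("A", "inpatient", "2007-01-10", "428", icu = TRUE),
    make_claim("A", "inpatient", "2008-01-10", "428", icu = TRUE)
  )
  ev <- derive_icu(claims, fw)
  expect_equal(ev$event_date, as.Date("2007-01-10"))
})

test_that("horizons are calendar-exact day counts", {
  expect_equal(horizon_days(1, "2006-01-01"), 365L)
  expect_equal(horizon_days(5, "2006-01-01"), 1826L)
  expect_equal(horizon_days(8, "2006-01-01"), 2922L)
})

survival_fixture <- function() {
  ben <- tibble::tibble(
    person_id = c("A", "B", "C"),
    sex = factor(c("male", "female", "female"), levels = c("male", "female")),
    birth_date = as.Date(rep("1935-01-01", 3)),
    coverage_start = as.Date(rep("2000-01-01", 3)),
    coverage_end = as.Date(c("2006-04-10", "2006-04-10", "2013-12-31")),
    death_date = as.Date(c("2006-04-10", "2006-04-10", NA))
  )
  # A: dies day 100, never hospitalized. B: ED admission day 50, dies day
  # 100. C: no events.
  claims <- make_claim("B", "inpatient", "2006-02-19", "428", ed = TRUE)
  cohort <- tibble::tibble(
    person_id = c("A", "B", "C"),
    sex = ben$sex,
    age_at_baseline = c(70L, 70L, 70L),
    age_band = age_band(c(70, 70, 70))
  )
  scores <- categorize_mfi(tibble::tibble(person_id = c("A", "B", "C"),
                                          deficit_count = c(0L, 4L, 0L),
                                          total_items = 32L,
                                          mfi = c(0, 0.125, 0)))
  list(ben = ben, claims = claims, cohort = cohort, scores = scores,
       outcomes = derive_outcomes(ben, claims, fw))
}

test_that("survival datasets apply censoring and first-event rules", {
  fx <- survival_fixture()
  # 2006-04-10 is follow-up day 100; 2006-02-19 is day 50
  expect_equal(as.numeric(as.Date("2006-04-10") - as.Date("2006-01-01")) + 1, 100)

  hosp1 <- build_survival_dataset(fx$cohort, fx$scores, fx$outcomes,
                                  "unplanned_hospitalization", 1, fw)
  a <- hosp1[hosp1$person_id == "A", ]
  expect_equal(a$time, 100)       # censored at death
  expect_equal(a$event, 0L)
  expect_equal(a$status_reason, "death")
  b <- hosp1[hosp1$person_id == "B", ]
  expect_equal(b$time, 50)        # event before death
  expect_equal(b$event, 1L)
  c <- hosp1[hosp1$person_id == "C", ]
  expect_equal(c$time, 365)       # administratively censored at 1y
  expect_equal(c$event, 0L)
  expect_equal(c$status_reason, "horizon")

  hosp5 <- build_survival_dataset(fx$cohort, fx$scores, fx$outcomes,
                                  "unplanned_hospitalization", 5, fw)
  expect_equal(hosp5$time[hosp5$person_id == "C"], 1826)

  death5 <- build_survival_dataset(fx$cohort, fx$scores, fx$outcomes,
                                   "death", 5, fw)
  expect_equal(death5$event[death5$person_id == "A"], 1L)
  expect_equal(death5$time[death5$person_id == "A"], 100)

  # missing score aborts
  expect_error(build_survival_dataset(fx$cohort, fx$scores[-1, ], fx$outcomes,
                                      "death", 5, fw),
               "no frailty score", class = "mfi_data_error")
})

test_that("same-day death and admission counts as the admission event", {
  fx <- survival_fixture()
  claims <- make_claim("A", "inpatient", "2006-04-10", "428", ed = TRUE)
  outcomes <- derive_outcomes(fx$ben, claims, fw)
  hosp <- build_survival_dataset(fx$cohort, fx$scores, outcomes,
                                 "unplanned_hospitalization", 8, fw)
  a <- hosp[hosp$person_id == "A", ]
  expect_equal(a$time, 100)
  expect_equal(a$event, 1L)
})

test_that("times nest across horizons and events persist", {
  cfg <- default_sim_config(1500, seed = 21)
  sim <- simulate_cohort(cfg)
  suppressMessages(cohort <- select_study_cohort(sim$beneficiaries))
  suppressMessages(pm <- build_presence_matrix(cohort, sim$claims))
  sc <- categorize_mfi(compute_mfi(pm, select_deficits(pm, cohort)))
  outcomes <- derive_outcomes(sim$beneficiaries, sim$claims, fw)
  for (oc in c("death", "unplanned_hospitalization")) {
    d1 <- build_survival_dataset(cohort, sc, outcomes, oc, 1, fw)
    d5 <- build_survival_dataset(cohort, sc, outcomes, oc, 5, fw)
    d8 <- build_survival_dataset(cohort, sc, outcomes, oc, 8, fw)
    expect_true(all(d1$time <= d5$time & d5$time <= d8$time))
    expect_true(all(d1$time > 0))
    # an event by 1y is the same event at 5y and 8y
    e1 <- d1$person_id[d1$event == 1]
    expect_true(all(d5$event[d5$person_id %in% e1] == 1))
    expect_true(all(d5$time[d5$person_id %in% e1] ==
                      d1$time[d1$event == 1]))
    expect_true(all(d8$event[d8$person_id %in% e1] == 1))
  }
  # conservation: 8y death events equal registry deaths within the window
  d8 <- build_survival_dataset(cohort, sc, outcomes, "death", 8, fw)
  reg <- sim$beneficiaries
  in_cohort <- reg$person_id %in% cohort$person_id
  n_reg_deaths <- sum(!is.na(reg$death_date[in_cohort]) &
                        reg$death_date[in_cohort] <= as.Date(fw[2]))
  expect_equal(sum(d8$event), n_reg_deaths)
})
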