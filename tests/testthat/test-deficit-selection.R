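test_that("code truncation normalizes dots and keeps 3-character roots", {
  expect_equal(truncate_code("332.0"), "332")
  expect_equal(truncate_code("4280"), "428")
  expect_equal(truncate_code("428.0"), truncate_code("4280"))
  expect_equal(truncate_code("V72.1"), "V72")
  expect_equal(truncate_code(c("250", " 428.0 ")), c("250", "428"))
  expect_error(truncate_code("42"), "shorter", class = "mfi_parse_error")
})

test_that("the presence rule needs 3 outpatient or 1 inpatient claims", {
  out3 <- dplyr::bind_rows(
    make_claim("A1", "outpatient", "2005-01-10", "332.0"),
    make_claim("A1", "outpatient", "2005-03-10", "3320"),
    make_claim("A1", "outpatient", "2005-05-10", "332")
  )
  expect_equal(flag_presence(out3, "332"), 1L)
  expect_equal(flag_presence(out3[1:2, ], "332"), 0L)
  expect_equal(flag_presence(make_claim("A1", "inpatient", "2005-04-01", "332"), "332"), 1L)
  # a claim listing the same root twice counts once
  dup <- make_claim("A1", "outpatient", "2005-01-10", c("428.0", "4281"))
  pm_claims <- dplyr::bind_rows(dup, dup)
  expect_equal(flag_presence(pm_claims, "428"), 0L)
  expect_equal(flag_presence(dplyr::bind_rows(pm_claims, dup), "428"), 1L)
})

test_that("presence matrix covers all members and counts per claim line", {
  ben <- fixture_beneficiaries()
  suppressMessages(cohort <- select_study_cohort(ben))
  claims <- dplyr::bind_rows(
    make_claim("A1", "outpatient", "2005-01-10", "4280"),
    make_claim("A1", "outpatient", "2005-02-10", "428"),
    make_claim("A1", "outpatient", "2005-03-10", "428.1"),
    make_claim("A4", "inpatient", "2005-06-01", c("428", "332")),
    make_claim("A5", "outpatient", "2006-02-01", "428"),  # outside baseline
    make_claim("ZZ", "outpatient", "2005-02-01", "428")   # outside cohort
  )
  suppressMessages(pm <- build_presence_matrix(cohort, claims))
  expect_setequal(pm$person_id, c("A1", "A4", "A5"))
  expect_equal(sort(setdiff(names(pm), "person_id")), c("332", "428"))
  expect_equal(pm$`428`[pm$person_id == "A1"], 1L)
  # one inpatient claim listing two roots flags both
  expect_equal(pm$`428`[pm$person_id == "A4"], 1L)
  expect_equal(pm$`332`[pm$person_id == "A4"], 1L)
  # A5's only claim is post-baseline: all-zero row, still present
  expect_equal(pm$`428`[pm$person_id == "A5"], 0L)

  suppressMessages(pm0 <- build_presence_matrix(cohort, claims[0, ]))
  expect_equal(ncol(pm0), 1)
  expect_equal(nrow(pm0), 3)
})

test_that("age_trend is the closed-form 5-point OLS", {
  tr <- age_trend(c(0.02, 0.04, 0.06, 0.08, 0.10))
  expect_equal(tr$slope, 0.02)
  expect_equal(tr$r_squared, 1.0)
  # constant prevalences: slope 0, R^2 undefined
  tr <- age_trend(rep(0.1815, 5))
  expect_equal(tr$slope, 0)
  expect_true(is.na(tr$r_squared))
  # decreasing: negative slope
  expect_lt(age_trend(c(0.10, 0.08, 0.06, 0.04, 0.02))$slope, 0)
  # matches lm() on a noisy case
  y <- c(0.02, 0.05, 0.04, 0.09, 0.08)
  f <- stats::lm(y ~ x, data = data.frame(x = 0:4, y = y))
  tr <- age_trend(y)
  expect_equal(tr$slope, unname(coef(f)[2]))
  expect_equal(tr$r_squared, summary(f)$r.squared)
  expect_error(age_trend(c(0.1, 0.2)), "length 5", class = "mfi_type_error")
})

test_that("selection applies the three criteria strictly", {
  # synthetic presence with age bands balanced: 100 persons per band
  n <- 500
  band_age <- rep(c(66, 71, 76, 81, 90), each = 100)
  cohort <- tibble::tibble(
    person_id = sprintf("Q%03d", 1:n),
    sex = factor(rep("female", n), levels = c("male", "female")),
    age_at_baseline = band_age,
    age_band = age_band(band_age)
  )
  rising <- unlist(lapply(c(2, 4, 6, 8, 10), function(k) rep(c(1L, 0L), c(k, 100 - k))))
  flat <- rep(rep(c(1L, 0L), c(18, 82)), 5)
  saturated <- c(rep(1L, 100), rep(rep(c(1L, 0L), c(50, 50)), 4))
  rare_col <- rep(rep(c(1L, 0L), c(1, 99)), 5)
  pm <- tibble::tibble(person_id = cohort$person_id, `428` = rising,
                       `250` = flat, `V70` = saturated, `042` = rare_col)
  cat <- select_deficits(pm, cohort)
  expect_s3_class(cat, "mfi_catalog")
  row <- function(r) cat[cat$code_root == r, ]
  expect_true(row("428")$selected)    # 2..10% rising, R^2 = 1
  expect_false(row("250")$selected)   # exactly flat: fails trend
  expect_true(row("250")$passed_prevalence)
  expect_false(row("250")$passed_trend)
  expect_false(row("V70")$selected)   # 100% in band 65-69: saturation rule
  expect_false(row("V70")$passed_not_saturated)
  expect_false(row("042")$selected)   # 1% overall: below the 2% floor
  expect_false(row("042")$passed_prevalence)
  # strictness: a code at exactly 2% fails criterion i
  expect_equal(row("428")$overall_prevalence, 0.06)
  pm2 <- pm
  pm2$`428` <- unlist(lapply(c(0, 1, 2, 3, 4), function(k) rep(c(1L, 0L), c(k, 100 - k))))
  cat2 <- select_deficits(pm2, cohort)
  expect_equal(cat2$overall_prevalence[cat2$code_root == "428"], 0.02)
  expect_false(cat2$passed_prevalence[cat2$code_root == "428"])
})

test_that("selection agrees with the brute-force oracle on random panels", {
  for (seed in c(101, 102, 103)) {
    panel <- random_small_panel(seed, n = 120, n_roots = 8)
    suppressMessages(cohort <- select_study_cohort(panel$beneficiaries))
    suppressMessages(pm <- build_presence_matrix(cohort, panel$claims))
    cat <- select_deficits(pm, cohort)
    oracle <- oracle_select_deficits(panel$claims, cohort)
    merged <- merge(as.data.frame(cat)[, c("code_root", "selected", "overall_prevalence")],
                    oracle, by = "code_root", suffixes = c("", "_oracle"))
    expect_equal(nrow(merged), nrow(cat))
    expect_equal(merged$selected, merged$selected_oracle)
    expect_equal(merged$overall_prevalence, merged$overall_prevalence_oracle)
  }
})

test_that("raising the prevalence floor never adds a selected code", {
  panel <- random_small_panel(77, n = 200, n_roots = 10)
  suppressMessages(cohort <- select_study_cohort(panel$beneficiaries))
  suppressMessages(pm <- build_presence_matrix(cohort, panel$claims))
  sel <- lapply(c(0.0, 0.02, 0.05, 0.10),
                function(p) attr(select_deficits(pm, cohort, min_prevalence = p),
                                 "selected_roots"))
  for (i in 2:length(sel)) {
    expect_true(all(sel[[i]] %in% sel[[i - 1]]))
  }
})

test_that("V-code candidates can be excluded by switch", {
  panel <- random_small_panel(55, n = 80, n_roots = 5)
  panel$claims$diagnosis_codes[[1]] <- "V72.0"
  suppressMessages(cohort <- select_study_cohort(panel$beneficiaries))
  suppressMessages(pm <- build_presence_matrix(cohort, panel$claims))
  expect_true("V72" %in% select_deficits(pm, cohort)$code_root)
  expect_false("V72" %in% select_deficits(pm, cohort, numeric_only = TRUE)$code_root)
})
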