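# End-to-end orchestration: simulate or ingest claims, screen the cohort,
# select deficits, score, derive outcomes, run the statistical battery,
# and write every stage artifact plus a run manifest.

#' Pipeline configuration
#'
#' @param simulation `mfi_sim_config` for simulate-mode, or `NULL` when
#'   reading input files.
#' @param input_dir directory containing `beneficiaries.csv` and
#'   `claims.csv` (ignored in simulate-mode).
#' @param baseline_window,followup_window length-2 date vectors.
#' @param age_range inclusive completed-years range.
#' @param min_prevalence,min_r2 deficit-selection thresholds.
#' @param cut_points fixed mFI category cut points.
#' @param horizons integer vector of horizon years.
#' @param outcomes outcomes to analyze.
#' @param stratify_by_sex also fit sex-stratified adjusted models.
#' @param seed root seed (overrides the simulation config's seed).
#' @return list of class `mfi_pipeline_config`.
#' @export
pipeline_config <- function(simulation = NULL,
                            input_dir = NULL,
                            baseline_window = c("2005-01-01", "2005-12-31"),
                            followup_window = c("2006-01-01", "2013-12-31"),
                            age_range = c(65, 100),
                            min_prevalence = 0.02,
                            min_r2 = 0.30,
                            cut_points = c(0.0625, 0.125, 0.1875),
                            horizons = c(1, 5, 8),
                            outcomes = c("death", "unplanned_hospitalization",
                                         "icu_admission"),
                            stratify_by_sex = FALSE,
                            seed = NULL) {
  baseline_window <- as.Date(baseline_window)
  followup_window <- as.Date(followup_window)
  if (baseline_window[2] >= followup_window[1]) {
    abort("Baseline and follow-up windows must be ordered and non-overlapping.",
          class = "mfi_config_error")
  }
  if (any(horizons <= 0)) {
    abort("`horizons` must be positive.", class = "mfi_config_error")
  }
  outcomes <- match.arg(outcomes, several.ok = TRUE)
  if (is.null(simulation) && is.null(input_dir)) {
    abort("Provide either `simulation` or `input_dir`.", class = "mfi_config_error")
  }
  if (!is.null(simulation)) {
    stopifnot(inherits(simulation, "mfi_sim_config"))
    if (!is.null(seed)) simulation$seed <- as.integer(seed)
  }
  structure(
    list(simulation = simulation, input_dir = input_dir,
         baseline_window = baseline_window, followup_window = followup_window,
         age_range = age_range, min_prevalence = min_prevalence, min_r2 = min_r2,
         cut_points = cut_points, horizons = horizons, outcomes = outcomes,
         stratify_by_sex = stratify_by_sex,
         seed = seed %||% (if (!is.null(simulation)) simulation$seed else NA_integer_)),
    class = "mfi_pipeline_config"
  )
}

#' Run the full analysis pipeline
#'
#' Sequences every stage (simulate/ingest, cohort screening, presence
#' matrix, deficit selection, scoring, outcome derivation, survival
#' datasets, Kaplan-Meier + log-rank, Cox hazard-ratio table,
#' discrimination, cohort summary) and writes each stage's artifact to
#' `out_dir`. Identical config and seed give byte-identical CSV outputs.
#' The manifest (`manifest.json`, written last) records the config echo
#' and per-stage row counts.
#'
#' @param config `mfi_pipeline_config`.
#' @param out_dir output directory (created if needed).
#' @return the manifest, invisibly.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "mfi_pipeline_config"))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  t0 <- Sys.time()

  # stage: input
  if (!is.null(config$simulation)) {
    inform("Stage simulate: generating synthetic claims panel.")
    sim <- simulate_cohort(config$simulation)
    beneficiaries <- sim$beneficiaries
    claims <- sim$claims
    write_beneficiaries(beneficiaries, file.path(out_dir, "beneficiaries.csv"))
    write_claims(claims, file.path(out_dir, "claims.csv"))
    jsonlite::write_json(sim$ground_truth, file.path(out_dir, "ground_truth.json"),
                         dataframe = "columns", auto_unbox = TRUE, digits = NA,
                         na = "null")
  } else {
    inform(sprintf("Stage ingest: reading claims panel from %s.", config$input_dir))
    beneficiaries <- read_beneficiaries(file.path(config$input_dir, "beneficiaries.csv"))
    claims <- read_claims(file.path(config$input_dir, "claims.csv"))
  }

  # stage: cohort
  cohort <- select_study_cohort(beneficiaries, config$baseline_window,
                                config$age_range)
  exclusions <- attr(cohort, "exclusions")
  readr::write_csv(cohort, file.path(out_dir, "cohort.csv"), na = "", progress = FALSE)

  # stage: deficits
  inform("Stage deficits: presence matrix and selection criteria.")
  presence <- build_presence_matrix(cohort, claims, config$baseline_window)
  catalog <- select_deficits(presence, cohort,
                             min_prevalence = config$min_prevalence,
                             min_r2 = config$min_r2)
  write_deficit_catalog(catalog, file.path(out_dir, "deficit_catalog.csv"))

  # stage: scores
  scores <- compute_mfi(presence, catalog) |>
    categorize_mfi(cut_points = config$cut_points)
  write_frailty_scores(scores, file.path(out_dir, "frailty_scores.csv"))
  summary_tables <- summarize_cohort(scores, cohort)
  readr::write_csv(summary_tables$by_age_sex,
                   file.path(out_dir, "cohort_summary_by_age_sex.csv"),
                   na = "", progress = FALSE)
  readr::write_csv(bind_cols(summary_tables$distribution),
                   file.path(out_dir, "cohort_summary_distribution.csv"),
                   na = "", progress = FALSE)
  readr::write_csv(summary_tables$category_shares,
                   file.path(out_dir, "cohort_summary_categories.csv"),
                   na = "", progress = FALSE)

  # stage: outcomes
  inform("Stage outcomes: deriving events and survival datasets.")
  outcomes_tbl <- derive_outcomes(beneficiaries, claims, config$followup_window)
  datasets <- list()
  for (oc in config$outcomes) {
    for (h in config$horizons) {
      d <- build_survival_dataset(cohort, scores, outcomes_tbl, oc, h,
                                  config$followup_window)
      datasets[[sprintf("%s_%dy", oc, h)]] <- d
      readr::write_csv(as_tibble(d),
                       file.path(out_dir, sprintf("survival_%s_%dy.csv", oc, h)),
                       na = "", progress = FALSE)
    }
  }

  # stage: statistics
  inform("Stage statistics: KM, log-rank, Cox, discrimination.")
  hmax <- max(config$horizons)
  km_all <- purrr::map_dfr(config$outcomes, function(oc) {
    d <- datasets[[sprintf("%s_%dy", oc, hmax)]]
    as_tibble(km_estimate(d)) |> mutate(outcome = oc, horizon_years = hmax)
  })
  readr::write_csv(km_all, file.path(out_dir, "km_curves.csv"), na = "",
                   progress = FALSE)
  logrank_all <- purrr::map_dfr(config$outcomes, function(oc) {
    d <- datasets[[sprintf("%s_%dy", oc, hmax)]]
    logrank_test(d) |> mutate(outcome = oc, horizon_years = hmax, .before = 1)
  })
  readr::write_csv(logrank_all, file.path(out_dir, "logrank.csv"), na = "",
                   progress = FALSE)

  hr <- hr_table(datasets)
  readr::write_csv(hr, file.path(out_dir, "hr_table.csv"), na = "", progress = FALSE)

  hr_sex <- NULL
  if (isTRUE(config$stratify_by_sex)) {
    hr_sex <- purrr::map_dfr(c("male", "female"), function(s) {
      sub <- purrr::map(datasets, function(d) {
        keep <- d$sex == s
        out <- d[keep, , drop = FALSE]
        for (a in c("outcome", "horizon_years", "horizon_days")) {
          attr(out, a) <- attr(d, a)
        }
        out
      })
      purrr::map_dfr(sub, function(d) {
        fit <- cox_fit(d, covariates = c("frailty_category", "age_at_baseline"))
        tidy(fit) |>
          filter(stringr::str_starts(.data$term, "frailty_category")) |>
          mutate(term = sub("^frailty_category", "", .data$term),
                 outcome = attr(d, "outcome"), horizon_years = attr(d, "horizon_years"),
                 sex = s)
      })
    })
    readr::write_csv(hr_sex, file.path(out_dir, "hr_by_sex.csv"), na = "",
                     progress = FALSE)
  }

  disc <- purrr::map_dfr(datasets, function(d) as_tibble(discrimination(d)))
  readr::write_csv(disc, file.path(out_dir, "discrimination.csv"), na = "",
                   progress = FALSE)

  # stage: manifest (last)
  manifest <- list(
    package_version = as.character(packageVersion("mfindex")),
    seed = config$seed,
    timestamp = format(t0, "%Y-%m-%dT%H:%M:%S%z"),
    config = list(
      mode = if (is.null(config$simulation)) "ingest" else "simulate",
      n_subjects = if (is.null(config$simulation)) NA else config$simulation$n_subjects,
      baseline_window = as.character(config$baseline_window),
      followup_window = as.character(config$followup_window),
      age_range = config$age_range,
      min_prevalence = config$min_prevalence,
      min_r2 = config$min_r2,
      cut_points = config$cut_points,
      horizons = config$horizons,
      outcomes = config$outcomes,
      stratify_by_sex = config$stratify_by_sex
    ),
    counts = list(
      beneficiaries_in = nrow(beneficiaries),
      excluded = as.list(table(exclusions$reason)),
      cohort = nrow(cohort),
      candidate_codes = nrow(catalog),
      selected_deficits = attr(catalog, "total_items"),
      events = purrr::map(setNames(config$outcomes, config$outcomes), function(oc) {
        sum(datasets[[sprintf("%s_%dy", oc, hmax)]]$event)
      })
    )
  )
  stopifnot(manifest$counts$beneficiaries_in ==
              manifest$counts$cohort + nrow(exclusions))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  inform(sprintf("Pipeline complete: %d cohort members, %d deficits selected.",
                 nrow(cohort), attr(catalog, "total_items")))
  invisible(manifest)
}

#' Read a pipeline configuration from a YAML file
#'
#' Flat key-value document mirroring the [pipeline_config()] arguments;
#' simulate-mode is requested with `mode: simulate` plus optional
#' `n_subjects` and `seed` (the default study-like simulation
#' configuration is then used).
#'
#' @param path YAML file path.
#' @return `mfi_pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  sim <- NULL
  if (identical(y$mode, "simulate")) {
    sim <- default_sim_config(n_subjects = y$n_subjects %||% 20000,
                              seed = y$seed %||% 1L)
  }
  pipeline_config(
    simulation = sim,
    input_dir = y$input_dir,
    baseline_window = y$baseline_window %||% c("2005-01-01", "2005-12-31"),
    followup_window = y$followup_window %||% c("2006-01-01", "2013-12-31"),
    age_range = y$age_range %||% c(65, 100),
    min_prevalence = y$min_prevalence %||% 0.02,
    min_r2 = y$min_r2 %||% 0.30,
    cut_points = y$cut_points %||% c(0.0625, 0.125, 0.1875),
    horizons = y$horizons %||% c(1, 5, 8),
    outcomes = y$outcomes %||% c("death", "unplanned_hospitalization", "icu_admission"),
    stratify_by_sex = y$stratify_by_sex %||% FALSE,
    seed = y$seed
  )
}
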