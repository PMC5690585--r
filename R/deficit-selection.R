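# Deficit identification: 3-digit code roots, the claim-count presence
# rule, and the three selection criteria
#   (i)   prevalence of the (rule-qualified) deficit above 2%,
#   (ii)  prevalence rising across the five age bands with a positive OLS
#         slope and R^2 above 0.30,
#   (iii) not already saturated (below 100% prevalence) in the 65-69 band.

#' Truncate ICD-9-CM codes to their 3-character roots
#'
#' Codes are normalized by stripping the decimal point and whitespace, so
#' `"428.0"` and `"4280"` share the root `"428"`. V- and E-codes keep their
#' letter (`"V72.0"` -> `"V72"`).
#'
#' @param codes character vector of ICD-9-CM codes.
#' @return character vector of 3-character roots.
#' @export
truncate_code <- function(codes) {
  norm <- icd9_normalize(codes)
  short <- which(nchar(norm) < 3)
  if (length(short) > 0) {
    abort(sprintf("ICD-9 code(s) shorter than 3 characters after normalization: %s",
                  paste(unique(head(codes[short], 5)), collapse = ", ")),
          class = "mfi_parse_error")
  }
  substr(norm, 1, 3)
}

#' Presence of one deficit for one person
#'
#' A person carries the deficit `code_root` when their baseline claims
#' include at least `min_outpatient` outpatient claims or at least
#' `min_inpatient` inpatient claims whose truncated diagnosis codes contain
#' the root. Each claim line counts once per root, even if it lists two
#' codes sharing the root.
#'
#' @param claims claims tibble for a single person, already restricted to
#'   the baseline window.
#' @param code_root 3-character root.
#' @param min_outpatient,min_inpatient claim-count thresholds (defaults 3
#'   and 1).
#' @return integer 0/1.
#' @export
flag_presence <- function(claims, code_root, min_outpatient = 3, min_inpatient = 1) {
  if (nrow(claims) == 0) return(0L)
  has_root <- vapply(claims$diagnosis_codes,
                     function(codes) code_root %in% truncate_code(codes),
                     logical(1))
  n_out <- sum(has_root & claims$setting == "outpatient")
  n_in <- sum(has_root & claims$setting == "inpatient")
  as.integer(n_out >= min_outpatient | n_in >= min_inpatient)
}

#' Build the person-by-root deficit presence matrix
#'
#' Applies the claim-count presence rule to every cohort member and every
#' 3-digit root observed in the baseline claims. Claims outside the
#' baseline window, and claims of persons outside the cohort, are dropped
#' (the latter with an informational count).
#'
#' @param cohort tibble from [select_study_cohort()].
#' @param claims claims tibble.
#' @param baseline_window length-2 date vector; defaults to the window
#'   stored on `cohort`.
#' @param min_outpatient,min_inpatient presence-rule thresholds.
#' @return tibble with `person_id` (one row per cohort member, all-zero
#'   rows for members without qualifying claims) followed by one 0/1
#'   integer column per observed root, in lexicographic order.
#' @export
build_presence_matrix <- function(cohort, claims,
                                  baseline_window = attr(cohort, "baseline_window"),
                                  min_outpatient = 3, min_inpatient = 1) {
  check_columns(cohort, c("person_id"), "cohort")
  check_columns(claims, c("person_id", "setting", "service_date",
                          "admission_date", "diagnosis_codes"), "claims")
  if (is.null(baseline_window)) {
    abort("`baseline_window` is required (none stored on `cohort`).",
          class = "mfi_config_error")
  }
  baseline_window <- as.Date(baseline_window)

  n_foreign <- length(setdiff(unique(claims$person_id), cohort$person_id))
  if (n_foreign > 0) {
    inform(sprintf("Skipping claims of %d person(s) outside the cohort.", n_foreign))
  }
  anchor <- if_else(claims$setting == "inpatient",
                    claims$admission_date, claims$service_date)
  keep <- claims$person_id %in% cohort$person_id &
    !is.na(anchor) & anchor >= baseline_window[1] & anchor <= baseline_window[2]
  cl <- claims[keep, c("person_id", "setting", "diagnosis_codes")]

  base <- tibble(person_id = sort(cohort$person_id))
  if (nrow(cl) == 0) {
    out <- base
    attr(out, "code_roots") <- character()
    return(out)
  }

  # one row per claim line x distinct root on that line
  lens <- lengths(cl$diagnosis_codes)
  long <- tibble(
    person_id = rep(cl$person_id, lens),
    setting = rep(as.character(cl$setting), lens),
    root = truncate_code(unlist(cl$diagnosis_codes, use.names = FALSE)),
    line = rep(seq_len(nrow(cl)), lens)
  ) |>
    distinct(.data$line, .data$root, .keep_all = TRUE)

  counts <- long |>
    count(.data$person_id, .data$root, .data$setting) |>
    tidyr::pivot_wider(names_from = "setting", values_from = "n", values_fill = 0L)
  if (!"outpatient" %in% names(counts)) counts$outpatient <- 0L
  if (!"inpatient" %in% names(counts)) counts$inpatient <- 0L
  counts <- counts |>
    mutate(present = as.integer(.data$outpatient >= min_outpatient |
                                  .data$inpatient >= min_inpatient)) |>
    filter(.data$present == 1L)

  roots <- sort(unique(long$root))
  wide <- counts |>
    select("person_id", "root", "present") |>
    tidyr::pivot_wider(names_from = "root", values_from = "present", values_fill = 0L)
  out <- left_join(base, wide, by = "person_id")
  for (r in setdiff(roots, names(out))) out[[r]] <- 0L
  out <- out[, c("person_id", roots)]
  out[is.na(out)] <- 0L
  attr(out, "code_roots") <- roots
  out
}

#' Ordinary least squares age trend of band prevalences
#'
#' Regresses the five band prevalences on the band index 0..4 (equal
#' spacing; the open-ended oldest band has no midpoint, and slope sign and
#' R-squared are invariant to any affine recoding of an equally spaced
#' abscissa). Missing bands (`NA`) are dropped; at least 3 observed bands
#' are required for a trend, and R-squared is undefined when the observed
#' prevalences are constant (zero total sum of squares).
#'
#' @param band_prevalences numeric vector of length 5, values in
#'   `[0, 1]` or `NA` for empty bands.
#' @return list with `slope`, `r_squared` (both `NA` when undefined) and
#'   `n_bands`, the number of bands used.
#' @export
age_trend <- function(band_prevalences) {
  if (length(band_prevalences) != 5) {
    abort("`band_prevalences` must have length 5.", class = "mfi_type_error")
  }
  ok <- !is.na(band_prevalences)
  if (any(band_prevalences[ok] < 0 | band_prevalences[ok] > 1)) {
    abort("Band prevalences must lie in [0, 1].", class = "mfi_type_error")
  }
  if (sum(ok) < 3) {
    return(list(slope = NA_real_, r_squared = NA_real_, n_bands = sum(ok)))
  }
  x <- (0:4)[ok]
  y <- band_prevalences[ok]
  sxx <- sum((x - mean(x))^2)
  slope <- sum((x - mean(x)) * (y - mean(y))) / sxx
  tss <- sum((y - mean(y))^2)
  r2 <- if (tss == 0) NA_real_ else slope^2 * sxx / tss
  list(slope = slope, r_squared = r2, n_bands = sum(ok))
}

#' Select deficit items from the presence matrix
#'
#' Evaluates, for every candidate root, the three criteria:
#' overall prevalence strictly above `min_prevalence`; positive age-band
#' OLS slope with R-squared strictly above `min_r2`; and 65-69-band
#' prevalence strictly below 1. All three are computed on rule-qualified
#' presence. A root is selected iff all three pass. Full diagnostics are
#' returned for every candidate.
#'
#' @param presence tibble from [build_presence_matrix()].
#' @param cohort tibble from [select_study_cohort()] (supplies age bands).
#' @param min_prevalence,min_r2 strict thresholds (defaults 0.02 and 0.30).
#' @param numeric_only if `TRUE`, restrict candidates to numeric roots
#'   001-999 (drop V-/E-codes).
#' @return a deficit catalog: tibble of class `mfi_catalog` with one row
#'   per candidate (`code_root, overall_prevalence, prev_65_69 ...
#'   prev_85plus, slope, r_squared, passed_prevalence, passed_trend,
#'   passed_not_saturated, selected, note`), lexicographically ordered;
#'   attributes `selected_roots`, `total_items`, `thresholds`.
#' @export
select_deficits <- function(presence, cohort,
                            min_prevalence = 0.02, min_r2 = 0.30,
                            numeric_only = FALSE) {
  check_columns(presence, "person_id", "presence")
  check_columns(cohort, c("person_id", "age_band"), "cohort")
  roots <- setdiff(names(presence), "person_id")
  if (numeric_only) roots <- roots[grepl("^[0-9]{3}$", roots)]
  roots <- sort(roots)

  band <- cohort$age_band[match(presence$person_id, cohort$person_id)]
  if (anyNA(band)) {
    abort("Every presence row must match a cohort member with an age band.",
          class = "mfi_data_error")
  }
  band_n <- table(factor(band, levels = mfi_age_bands()))

  diag_one <- function(root) {
    x <- presence[[root]]
    overall <- mean(x)
    bp <- vapply(mfi_age_bands(), function(b) {
      nb <- band_n[[b]]
      if (nb == 0) NA_real_ else sum(x[band == b]) / nb
    }, numeric(1))
    tr <- age_trend(unname(bp))
    note <- if (tr$n_bands < 3) "insufficient bands"
      else if (!is.na(tr$slope) && is.na(tr$r_squared)) "constant prevalence"
      else NA_character_
    tibble(
      code_root = root,
      overall_prevalence = overall,
      prev_65_69 = bp[[1]], prev_70_74 = bp[[2]], prev_75_79 = bp[[3]],
      prev_80_84 = bp[[4]], prev_85plus = bp[[5]],
      slope = tr$slope, r_squared = tr$r_squared,
      passed_prevalence = overall > min_prevalence,
      passed_trend = !is.na(tr$slope) && !is.na(tr$r_squared) &&
        tr$slope > 0 && tr$r_squared > min_r2,
      passed_not_saturated = is.na(bp[[1]]) || bp[[1]] < 1,
      note = note
    )
  }

  catalog <- purrr::map_dfr(roots, diag_one) |>
    mutate(selected = .data$passed_prevalence & .data$passed_trend &
             .data$passed_not_saturated) |>
    arrange(.data$code_root)

  selected_roots <- catalog$code_root[catalog$selected]
  attr(catalog, "selected_roots") <- selected_roots
  attr(catalog, "total_items") <- length(selected_roots)
  attr(catalog, "thresholds") <- list(min_prevalence = min_prevalence, min_r2 = min_r2)
  class(catalog) <- c("mfi_catalog", class(catalog))
  catalog
}

#' Write a deficit catalog table
#'
#' Emits the per-candidate diagnostics (prevalences, slope, R-squared,
#' pass flags, selection) as CSV.
#'
#' @param catalog object from [select_deficits()].
#' @param path output file path.
#' @return `catalog`, invisibly.
#' @export
write_deficit_catalog <- function(catalog, path) {
  readr::write_csv(as_tibble(catalog), path, na = "", progress = FALSE)
  invisible(catalog)
}
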