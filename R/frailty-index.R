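# The index itself: non-weighted deficit proportion and its
# categorization, either by the fixed published cut points (primary) or by
# empirical quantiles (sensitivity analysis).

#' Compute the multimorbidity frailty index
#'
#' For each person, the mFI is the number of catalog deficits present
#' divided by the catalog size (non-weighted): a number in \[0, 1\], larger
#' meaning frailer. Presence columns outside the catalog are ignored.
#'
#' @param presence tibble from [build_presence_matrix()].
#' @param catalog deficit catalog from [select_deficits()], or a character
#'   vector of selected code roots.
#' @return tibble `person_id, deficit_count, total_items, mfi`.
#' @export
compute_mfi <- function(presence, catalog) {
  check_columns(presence, "person_id", "presence")
  roots <- if (is.character(catalog)) catalog else attr(catalog, "selected_roots")
  if (is.null(roots)) {
    abort("`catalog` must be an mfi_catalog or a character vector of roots.",
          class = "mfi_type_error")
  }
  if (length(roots) == 0) {
    abort("Empty deficit catalog: the index is undefined (division by zero).",
          class = "mfi_data_error")
  }
  missing_roots <- setdiff(roots, names(presence))
  if (length(missing_roots) > 0) {
    abort(sprintf("Presence matrix lacks catalog root(s): %s",
                  paste(head(missing_roots, 5), collapse = ", ")),
          class = "mfi_data_error")
  }
  count <- as.integer(rowSums(presence[, roots, drop = FALSE]))
  tibble(
    person_id = presence$person_id,
    deficit_count = count,
    total_items = length(roots),
    mfi = count / length(roots)
  )
}

#' Categorize mFI scores by fixed cut points
#'
#' Assigns the four frailty categories using right-closed intervals:
#' fit `[0, c1]`, mild `(c1, c2]`, moderate `(c2, c3]`, severe `(c3, 1]`.
#' The defaults `c(0.0625, 0.125, 0.1875)` are multiples of 2/32, so with a
#' 32-item catalog the category is a function of the deficit count alone
#' (fit <= 2, mild 3-4, moderate 5-6, severe >= 7) and "severe" means
#' strictly more than 0.1875. Cut points themselves belong to the lower
#' category.
#'
#' @param scores tibble from [compute_mfi()] (or any tibble with an `mfi`
#'   column).
#' @param cut_points strictly increasing proportions in (0, 1), length 3
#'   for the four named categories.
#' @return `scores` with an added ordered factor column
#'   `frailty_category` with levels `fit < mild < moderate < severe`.
#' @export
categorize_mfi <- function(scores, cut_points = c(0.0625, 0.125, 0.1875)) {
  check_columns(scores, "mfi", "scores")
  if (length(cut_points) != 3 || is.unsorted(cut_points, strictly = TRUE) ||
      any(cut_points <= 0) || any(cut_points >= 1)) {
    abort("`cut_points` must be 3 strictly increasing values in (0, 1).",
          class = "mfi_config_error")
  }
  scores$frailty_category <- cut(
    scores$mfi,
    breaks = c(-Inf, cut_points, Inf),
    labels = c("fit", "mild", "moderate", "severe"),
    right = TRUE, ordered_result = TRUE
  )
  scores
}

#' Categorize mFI scores by empirical quantiles
#'
#' Sensitivity-analysis alternative: cut the cohort's score distribution
#' at tertiles, quartiles or quintiles. Cut points are the empirical
#' quantiles of `mfi`; intervals are right-closed, so ties at a cut point
#' all fall in the lower group. With heavy ties (many zero scores) groups
#' can be very unbalanced; duplicate cut points are collapsed with a
#' warning, so fewer than `n_groups` groups may result.
#'
#' @param scores tibble with an `mfi` column.
#' @param n_groups 3, 4 or 5.
#' @return `scores` with an added ordered factor column `quantile_group`
#'   (levels `"1" < "2" < ...`, 1 = least frail); attribute `cut_points`
#'   holds the quantiles used.
#' @export
categorize_quantile <- function(scores, n_groups = 4) {
  check_columns(scores, "mfi", "scores")
  if (nrow(scores) == 0) abort("`scores` is empty.", class = "mfi_data_error")
  if (!n_groups %in% 3:5) {
    abort("`n_groups` must be 3, 4 or 5.", class = "mfi_config_error")
  }
  qs <- unname(quantile(scores$mfi, probs = seq_len(n_groups - 1) / n_groups,
                        type = 7))
  breaks <- c(-Inf, qs, Inf)
  dup <- duplicated(breaks)
  if (any(dup)) {
    warn(sprintf("Collapsing %d duplicated quantile cut point(s); fewer than %d groups.",
                 sum(dup), n_groups))
    breaks <- breaks[!dup]
  }
  grp <- cut(scores$mfi, breaks = breaks, labels = FALSE, right = TRUE)
  scores$quantile_group <- factor(grp, levels = seq_len(length(breaks) - 1),
                                  ordered = TRUE)
  sizes <- table(scores$quantile_group)
  inform(sprintf("Quantile group sizes: %s",
                 paste(sprintf("%s=%d", names(sizes), as.integer(sizes)),
                       collapse = ", ")))
  attr(scores, "cut_points") <- qs
  scores
}

#' Summarize the cohort's frailty distribution
#'
#' Builds the descriptive tables reported for the index: mean (SD) of the
#' mFI by age band and sex (five bands plus a total row, with overall /
#' male / female columns), the overall distribution summary (mean, SD,
#' median, 99th percentile), and category shares.
#'
#' @param scores tibble from [compute_mfi()] + [categorize_mfi()].
#' @param cohort tibble from [select_study_cohort()].
#' @return list of three tibbles: `by_age_sex` (6 rows), `distribution`
#'   (1 row), `category_shares` (one row per category).
#' @export
summarize_cohort <- function(scores, cohort) {
  check_columns(scores, c("person_id", "mfi"), "scores")
  check_columns(cohort, c("person_id", "sex", "age_band"), "cohort")
  d <- inner_join(scores, cohort, by = "person_id")

  cell <- function(x) c(mean = mean(x), sd = if (length(x) > 1) sd(x) else 0, n = length(x))
  one_row <- function(rows, label) {
    o <- cell(rows$mfi)
    m <- cell(rows$mfi[rows$sex == "male"])
    f <- cell(rows$mfi[rows$sex == "female"])
    tibble(age_band = label,
           n = as.integer(o[["n"]]),
           overall_mean = o[["mean"]], overall_sd = o[["sd"]],
           male_mean = m[["mean"]], male_sd = m[["sd"]],
           female_mean = f[["mean"]], female_sd = f[["sd"]])
  }
  by_age_sex <- bind_rows(
    purrr::map_dfr(mfi_age_bands(), function(b) one_row(d[d$age_band == b, ], b)),
    one_row(d, "total")
  )

  distribution <- tibble(
    n = nrow(d),
    mean = mean(d$mfi),
    sd = sd(d$mfi),
    median = median(d$mfi),
    p99 = unname(quantile(d$mfi, 0.99, type = 7))
  )

  category_shares <- if ("frailty_category" %in% names(d)) {
    d |>
      count(.data$frailty_category, name = "n_persons") |>
      mutate(share = .data$n_persons / sum(.data$n_persons))
  } else {
    tibble(frailty_category = factor(), n_persons = integer(), share = numeric())
  }

  list(by_age_sex = by_age_sex, distribution = distribution,
       category_shares = category_shares)
}

#' Write per-person frailty scores
#'
#' @param scores tibble from [compute_mfi()] (optionally categorized).
#' @param path output file path.
#' @return `scores`, invisibly.
#' @export
write_frailty_scores <- function(scores, path) {
  readr::write_csv(scores, path, na = "", progress = FALSE)
  invisible(scores)
}
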