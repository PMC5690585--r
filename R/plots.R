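# ggplot2 displays for the main result types.

#' Plot Kaplan-Meier curves
#'
#' Step-function survival curves per frailty category.
#'
#' @param object `mfi_km` tibble from [km_estimate()].
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.mfi_km <- function(object, ...) {
  d <- as_tibble(object)
  # prepend S(0) = 1 so every curve starts at the origin
  origin <- d |> distinct(.data$group) |>
    mutate(time = 0, survival = 1)
  ggplot2::ggplot(bind_rows(origin, d),
                  ggplot2::aes(x = .data$time, y = .data$survival,
                               colour = .data$group)) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Follow-up day", y = "Survival probability",
                  colour = "Frailty category") +
    ggplot2::theme_minimal()
}

#' Plot the mFI distribution
#'
#' Histogram of per-person scores; claims-based frailty indices are
#' typically right-skewed with a spike at zero.
#'
#' @param scores tibble from [compute_mfi()].
#' @param binwidth histogram bin width, default one deficit (1/total
#'   items).
#' @return a ggplot.
#' @export
plot_mfi_distribution <- function(scores, binwidth = NULL) {
  check_columns(scores, "mfi", "scores")
  binwidth <- binwidth %||% (1 / max(scores$total_items))
  ggplot2::ggplot(scores, ggplot2::aes(x = .data$mfi)) +
    ggplot2::geom_histogram(binwidth = binwidth, boundary = 0,
                            fill = "grey30", colour = "white") +
    ggplot2::labs(x = "Multimorbidity frailty index", y = "Persons") +
    ggplot2::theme_minimal()
}

#' Plot deficit prevalence age trends
#'
#' Band prevalences against age band for each candidate root, faceted by
#' selection outcome; the visual counterpart of the slope/R-squared
#' criterion.
#'
#' @param catalog `mfi_catalog` from [select_deficits()].
#' @param max_codes cap on number of codes drawn (largest-prevalence
#'   first), default 40.
#' @return a ggplot.
#' @export
plot_age_trends <- function(catalog, max_codes = 40) {
  d <- as_tibble(catalog) |>
    arrange(dplyr::desc(.data$overall_prevalence)) |>
    head(max_codes) |>
    tidyr::pivot_longer(dplyr::starts_with("prev_"), names_to = "band",
                        values_to = "prevalence") |>
    mutate(band = factor(.data$band,
                         levels = paste0("prev_", c("65_69", "70_74", "75_79",
                                                    "80_84", "85plus")),
                         labels = mfi_age_bands()))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$band, y = .data$prevalence,
                                  group = .data$code_root,
                                  colour = .data$selected)) +
    ggplot2::geom_line(alpha = 0.6) +
    ggplot2::labs(x = "Age band", y = "Prevalence", colour = "Selected") +
    ggplot2::theme_minimal()
}
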