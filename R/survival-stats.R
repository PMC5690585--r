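# Evaluation battery: Kaplan-Meier product-limit curves, k-group log-rank
# test, Cox proportional hazards fits (Breslow ties by default), and
# horizon-wise logistic discrimination (C-statistic, pseudo-R^2).
# The survival machinery is delegated to the survival package; tidy
# tibble surfaces and the frailty-specific conventions (reference
# category, Wald CIs, censoring handling at a horizon) live here.

#' Kaplan-Meier curves by frailty category
#'
#' Product-limit estimate of survival per group. Censored times do not
#' step the curve.
#'
#' @param records `mfi_survival` tibble (or any tibble with `time`,
#'   `event` and the grouping column).
#' @param group grouping column name, default `"frailty_category"`; use
#'   `NULL` for a single pooled curve.
#' @return tibble of class `mfi_km`: `group, time, n_risk, n_event,
#'   n_censor, survival`, one row per distinct observed time per group,
#'   with `survival` the probability just after `time`.
#' @export
km_estimate <- function(records, group = "frailty_category") {
  check_columns(records, c("time", "event"), "records")
  if (nrow(records) == 0) abort("`records` is empty.", class = "mfi_data_error")
  if (is.null(group)) {
    records$.group <- factor("all")
    group <- ".group"
  }
  grp <- factor(records[[group]])
  empty <- setdiff(levels(grp), unique(as.character(grp[!is.na(grp)])))
  if (length(empty) > 0) {
    warn(sprintf("Empty group(s) produce no curve: %s", paste(empty, collapse = ", ")))
  }
  fit <- survival::survfit(survival::Surv(time, event) ~ g,
                           data = data.frame(time = records$time,
                                             event = records$event,
                                             g = grp))
  s <- summary(fit, censored = TRUE)
  group_label <- if (is.null(s$strata)) {
    rep(levels(droplevels(grp))[1], length(s$time))
  } else {
    sub("^g=", "", as.character(s$strata))
  }
  out <- tibble(
    group = group_label,
    time = s$time,
    n_risk = s$n.risk,
    n_event = s$n.event,
    n_censor = s$n.censor,
    survival = s$surv
  )
  class(out) <- c("mfi_km", class(out))
  attr(out, "group_var") <- group
  out
}

#' K-group log-rank test
#'
#' Standard log-rank chi-square comparing survival across groups,
#' `df = k - 1`.
#'
#' @inheritParams km_estimate
#' @return one-row tibble `chi_square, df, p_value`.
#' @export
logrank_test <- function(records, group = "frailty_category") {
  check_columns(records, c("time", "event"), "records")
  grp <- droplevels(factor(records[[group]]))
  if (nlevels(grp) < 2) {
    abort("log-rank test needs at least 2 non-empty groups.",
          class = "mfi_data_error")
  }
  fit <- survival::survdiff(survival::Surv(time, event) ~ g,
                            data = data.frame(time = records$time,
                                              event = records$event,
                                              g = grp))
  df <- nlevels(grp) - 1
  tibble(chi_square = unname(fit$chisq), df = df,
         p_value = pchisq(unname(fit$chisq), df, lower.tail = FALSE))
}

#' Cox proportional hazards fit
#'
#' Fits the partial likelihood by Newton-Raphson (via
#' `survival::coxph`, Breslow tie handling by default, Efron available).
#' The frailty category enters as indicator terms with `fit` as the
#' reference; the adjusted model adds age (continuous, years) and sex.
#' Wald 95% CIs are computed on the log-hazard scale with
#' `z = qnorm(0.975)`.
#'
#' @param records `mfi_survival` tibble.
#' @param covariates model terms, a subset of
#'   `c("frailty_category", "age_at_baseline", "sex")` (or any columns of
#'   `records`); default the unadjusted category-only model.
#' @param adjusted shorthand: if `TRUE`, use
#'   `frailty_category + age_at_baseline + sex`.
#' @param ties `"breslow"` (default) or `"efron"`.
#' @return object of class `mfi_cox`; see [tidy.mfi_cox()] and
#'   [glance.mfi_cox()].
#' @export
cox_fit <- function(records, covariates = "frailty_category",
                    adjusted = FALSE, ties = c("breslow", "efron")) {
  ties <- match.arg(ties)
  if (adjusted) covariates <- c("frailty_category", "age_at_baseline", "sex")
  check_columns(records, c("time", "event", covariates), "records")
  if (sum(records$event) == 0) {
    abort("No events in `records`; the Cox model is undefined.",
          class = "mfi_data_error")
  }
  dat <- as.data.frame(records[, c("time", "event", covariates)])
  if ("frailty_category" %in% covariates) {
    dat$frailty_category <- factor(as.character(dat$frailty_category),
                                   levels = c("fit", "mild", "moderate", "severe"))
    dat$frailty_category <- droplevels(dat$frailty_category)
  }
  fml <- stats::as.formula(paste("survival::Surv(time, event) ~",
                                 paste(covariates, collapse = " + ")))
  fit <- survival::coxph(fml, data = dat, ties = ties,
                         control = survival::coxph.control(eps = 1e-10, iter.max = 50))
  converged <- fit$iter < 50 && !anyNA(coef(fit)) &&
    all(is.finite(sqrt(diag(vcov(fit)))))
  se <- sqrt(diag(vcov(fit)))
  # monotone partial likelihood (complete separation) inflates coefficients
  # and their SEs without a convergence failure; flag it
  if (any(abs(coef(fit)) > 15 | se > 50)) converged <- FALSE
  structure(
    list(fit = fit, covariates = covariates, ties = ties,
         converged = converged, n = fit$n, n_event = fit$nevent),
    class = "mfi_cox"
  )
}

#' @export
print.mfi_cox <- function(x, ...) {
  cat(sprintf("Cox PH fit (%s ties): n = %d, events = %d, %s\n",
              x$ties, x$n, x$n_event,
              if (x$converged) "converged" else "NOT converged"))
  print(tidy(x))
  invisible(x)
}

#' Tidy a Cox fit
#'
#' @param x `mfi_cox` object.
#' @param ... unused.
#' @return tibble `term, estimate, std_error, hazard_ratio, conf_low,
#'   conf_high, p_value`; `estimate` is the log hazard ratio, CIs are Wald
#'   95% intervals `exp(estimate +/- qnorm(0.975) * std_error)`.
#' @export
tidy.mfi_cox <- function(x, ...) {
  z <- qnorm(0.975)
  b <- coef(x$fit)
  se <- unname(sqrt(diag(vcov(x$fit))))
  tibble(
    term = names(b),
    estimate = unname(b),
    std_error = unname(se),
    hazard_ratio = exp(unname(b)),
    conf_low = exp(unname(b) - z * se),
    conf_high = exp(unname(b) + z * se),
    p_value = 2 * pnorm(-abs(unname(b) / se))
  )
}

#' One-line summary of a Cox fit
#'
#' @param x `mfi_cox` object.
#' @param ... unused.
#' @return one-row tibble with sample counts, log partial likelihood,
#'   likelihood-ratio / score / Wald statistics, concordance, iterations
#'   and convergence flag.
#' @export
glance.mfi_cox <- function(x, ...) {
  s <- summary(x$fit)
  tibble(
    n = x$n,
    n_event = x$n_event,
    log_partial_likelihood = x$fit$loglik[2],
    lr_statistic = unname(s$logtest["test"]),
    score_statistic = unname(s$sctest["test"]),
    wald_statistic = unname(s$waldtest["test"]),
    concordance = unname(s$concordance["C"]),
    iterations = x$fit$iter,
    converged = x$converged,
    ties = x$ties
  )
}

#' Horizon discrimination of the frailty categories
#'
#' Converts the time-to-event records into a binary outcome at the horizon
#' (event by the horizon vs. not), fits a logistic model of the outcome on
#' the frailty-category indicators, and reports the C-statistic (area
#' under the ROC curve, computed as the Mann-Whitney concordance of the
#' fitted probabilities) together with Cox-Snell and Nagelkerke pseudo-R^2.
#'
#' Persons censored before the horizon for reasons other than death carry
#' no horizon outcome and are excluded (count reported); persons dying
#' before the horizon without the event are controls for the non-fatal
#' outcomes, and survivors to the horizon are controls for death.
#'
#' @param records `mfi_survival` tibble built at the horizon of interest.
#' @param predictor predictor column, default `"frailty_category"`.
#' @return one-row tibble of class `mfi_discrimination`: `outcome,
#'   horizon_years, c_statistic, pseudo_r2_cox_snell,
#'   pseudo_r2_nagelkerke, n, n_events, n_excluded`.
#' @export
discrimination <- function(records, predictor = "frailty_category") {
  check_columns(records, c("time", "event", "status_reason", predictor), "records")
  h <- attr(records, "horizon_days")
  if (is.null(h)) h <- max(records$time)
  drop <- records$event == 0 & records$time < h & records$status_reason == "coverage"
  d <- records[!drop, , drop = FALSE]
  y <- d$event
  out_tbl <- function(c_stat, cs, nag) {
    res <- tibble(
      outcome = attr(records, "outcome") %||% NA_character_,
      horizon_years = attr(records, "horizon_years") %||% NA_integer_,
      c_statistic = c_stat, pseudo_r2_cox_snell = cs, pseudo_r2_nagelkerke = nag,
      n = nrow(d), n_events = sum(y), n_excluded = sum(drop)
    )
    class(res) <- c("mfi_discrimination", class(res))
    res
  }
  if (length(unique(y)) < 2) {
    warn("All horizon outcomes identical; discrimination undefined.")
    return(out_tbl(NA_real_, NA_real_, NA_real_))
  }
  x <- droplevels(factor(d[[predictor]]))
  m1 <- glm(y ~ x, family = binomial())
  m0 <- glm(y ~ 1, family = binomial())
  ll1 <- as.numeric(logLik(m1))
  ll0 <- as.numeric(logLik(m0))
  nn <- length(y)
  cs <- 1 - exp(-2 * (ll1 - ll0) / nn)
  nag <- cs / (1 - exp(2 * ll0 / nn))
  out_tbl(concordance_probability(stats::fitted(m1), y), cs, nag)
}

# Mann-Whitney concordance of predictions `p` for binary labels `y`:
# P(p_case > p_control) + 0.5 P(tie), via midranks.
concordance_probability <- function(p, y) {
  n1 <- sum(y == 1)
  n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(p, ties.method = "average")
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Hazard-ratio table across outcomes, horizons and categories
#'
#' Fits unadjusted (category only) and adjusted (plus age and sex) Cox
#' models for each supplied survival dataset and stacks the category
#' hazard ratios into a long table.
#'
#' @param datasets list of `mfi_survival` tibbles (any outcomes/horizons).
#' @param ties tie method passed to [cox_fit()].
#' @return tibble `outcome, horizon_years, model, term, hazard_ratio,
#'   conf_low, conf_high, estimate, std_error, p_value`, `model` being
#'   `"unadjusted"` or `"adjusted"`.
#' @export
hr_table <- function(datasets, ties = "breslow") {
  purrr::map_dfr(datasets, function(d) {
    purrr::map_dfr(c(unadjusted = FALSE, adjusted = TRUE), function(adj) {
      fit <- cox_fit(d, adjusted = adj, ties = ties)
      tidy(fit) |>
        filter(stringr::str_starts(.data$term, "frailty_category")) |>
        mutate(term = sub("^frailty_category", "", .data$term))
    }, .id = "model") |>
      mutate(outcome = attr(d, "outcome"),
             horizon_years = attr(d, "horizon_years"))
  }) |>
    select("outcome", "horizon_years", "model", "term", "hazard_ratio",
           "conf_low", "conf_high", "estimate", "std_error", "p_value")
}
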