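# Independent oracles, deliberately written in plain base R with naive
# loops and closed-form formulas, so they share no code path with the
# package implementation they check.

# Brute-force deficit selection: recount claims per person and root,
# apply the presence rule, compute band prevalences by looping, and refit
# the 5-point regression with the closed-form OLS formulas.
oracle_select_deficits <- function(claims, cohort, min_prevalence = 0.02,
                                   min_r2 = 0.30, baseline = as.Date(c("2005-01-01", "2005-12-31"))) {
  norm <- function(code) gsub("[.[:space:]]", "", code)
  root_of <- function(code) substr(norm(code), 1, 3)

  anchor <- ifelse(claims$setting == "inpatient",
                   as.character(claims$admission_date),
                   as.character(claims$service_date))
  anchor <- as.Date(anchor)
  in_window <- !is.na(anchor) & anchor >= baseline[1] & anchor <= baseline[2]
  cl <- claims[in_window & claims$person_id %in% cohort$person_id, ]

  all_roots <- sort(unique(unlist(lapply(cl$diagnosis_codes, root_of))))
  bands <- c("65-69", "70-74", "75-79", "80-84", ">=85")

  res <- data.frame(code_root = all_roots, selected = FALSE,
                    overall_prevalence = NA_real_, slope = NA_real_,
                    r_squared = NA_real_)
  for (ri in seq_along(all_roots)) {
    root <- all_roots[ri]
    present <- logical(nrow(cohort))
    for (pi in seq_len(nrow(cohort))) {
      pid <- cohort$person_id[pi]
      rows <- which(cl$person_id == pid)
      n_out <- 0; n_in <- 0
      for (j in rows) {
        if (root %in% root_of(cl$diagnosis_codes[[j]])) {
          if (cl$setting[j] == "outpatient") n_out <- n_out + 1 else n_in <- n_in + 1
        }
      }
      present[pi] <- (n_out >= 3) || (n_in >= 1)
    }
    overall <- mean(present)
    bp <- rep(NA_real_, 5)
    for (b in seq_along(bands)) {
      idx <- as.character(cohort$age_band) == bands[b]
      if (sum(idx) > 0) bp[b] <- mean(present[idx])
    }
    ok <- !is.na(bp)
    slope <- NA_real_; r2 <- NA_real_
    if (sum(ok) >= 3) {
      x <- (0:4)[ok]; y <- bp[ok]
      slope <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
      tss <- sum((y - mean(y))^2)
      if (tss > 0) r2 <- (sum((x - mean(x)) * (y - mean(y)))^2 /
                            sum((x - mean(x))^2)) / tss
    }
    pass_i <- overall > min_prevalence
    pass_ii <- !is.na(slope) && !is.na(r2) && slope > 0 && r2 > min_r2
    pass_iii <- is.na(bp[1]) || bp[1] < 1
    res$selected[ri] <- pass_i && pass_ii && pass_iii
    res$overall_prevalence[ri] <- overall
    res$slope[ri] <- slope
    res$r_squared[ri] <- r2
  }
  res
}

# Hand product-limit estimator: S(t) after each distinct event time.
oracle_km <- function(time, event) {
  ord <- order(time)
  time <- time[ord]; event <- event[ord]
  ts <- sort(unique(time[event == 1]))
  s <- 1
  out <- data.frame(time = ts, survival = NA_real_)
  for (i in seq_along(ts)) {
    n_risk <- sum(time >= ts[i])
    d <- sum(time == ts[i] & event == 1)
    s <- s * (1 - d / n_risk)
    out$survival[i] <- s
  }
  out
}

# Two-group log-rank chi-square from the classical O-E / hypergeometric
# variance table.
oracle_logrank2 <- function(time, event, group) {
  g <- as.integer(factor(group))
  stopifnot(length(unique(g)) == 2)
  ts <- sort(unique(time[event == 1]))
  O1 <- 0; E1 <- 0; V <- 0
  for (t in ts) {
    n <- sum(time >= t)
    n1 <- sum(time >= t & g == 1)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & g == 1)
    O1 <- O1 + d1
    E1 <- E1 + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  (O1 - E1)^2 / V
}

# Breslow log partial likelihood for a single covariate, maximized by
# golden-section search: the written-out formula, no model machinery.
oracle_cox_binary <- function(time, event, x, interval = c(-8, 8)) {
  neg_logpl <- function(beta) {
    ll <- 0
    for (t in sort(unique(time[event == 1]))) {
      at_risk <- time >= t
      dead <- time == t & event == 1
      ll <- ll + beta * sum(x[dead]) -
        sum(dead) * log(sum(exp(beta * x[at_risk])))
    }
    -ll
  }
  optimize(neg_logpl, interval = interval, tol = 1e-10)$minimum
}

# Concordance by explicit enumeration of all case-control pairs.
oracle_concordance <- function(pred, y) {
  cases <- pred[y == 1]; controls <- pred[y == 0]
  tot <- 0
  for (a in cases) for (b in controls) {
    tot <- tot + (a > b) + 0.5 * (a == b)
  }
  tot / (length(cases) * length(controls))
}

# Small random claims panel (base-R RNG only) for oracle-equivalence
# checks: `n` persons, `n_roots` candidate roots, claims with dotted /
# dot-free code variants.
random_small_panel <- function(seed, n = 500, n_roots = 20) {
  set.seed(seed)
  roots <- sprintf("%03d", sample(100:899, n_roots))
  person_id <- sprintf("S%04d", seq_len(n))
  age <- sample(65:100, n, replace = TRUE, prob = 0.93^(0:35))
  birth <- as.Date(sprintf("%d-01-01", 2005 - age)) - sample(0:364, n, replace = TRUE)
  beneficiaries <- tibble::tibble(
    person_id = person_id,
    sex = factor(sample(c("male", "female"), n, replace = TRUE),
                 levels = c("male", "female")),
    birth_date = birth,
    coverage_start = as.Date("2000-01-01"),
    coverage_end = as.Date("2013-12-31"),
    death_date = as.Date(NA)
  )
  n_claims <- rpois(n, 6)
  pid <- rep(person_id, n_claims)
  m <- length(pid)
  root <- sample(roots, m, replace = TRUE, prob = runif(n_roots, 0.2, 1))
  form <- sample(1:3, m, replace = TRUE)
  digit <- sample(0:9, m, replace = TRUE)
  code <- ifelse(form == 1, root,
                 ifelse(form == 2, paste0(root, digit), paste0(root, ".", digit)))
  inpat <- runif(m) < 0.15
  date <- as.Date("2005-01-01") + sample(0:364, m, replace = TRUE)
  claims <- tibble::tibble(
    person_id = pid,
    setting = factor(ifelse(inpat, "inpatient", "outpatient"),
                     levels = c("outpatient", "inpatient")),
    service_date = as.Date(ifelse(inpat, NA, date), origin = "1970-01-01"),
    admission_date = as.Date(ifelse(inpat, date, NA), origin = "1970-01-01"),
    discharge_date = as.Date(ifelse(inpat, date + 3, NA), origin = "1970-01-01"),
    diagnosis_codes = as.list(code),
    ed_flag = FALSE, icu_flag = FALSE
  )
  list(beneficiaries = beneficiaries, claims = claims)
}
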