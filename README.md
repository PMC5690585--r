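# mfindex

Builds a **multimorbidity frailty index (mFI)** from administrative
health-insurance claims and quantifies how well it predicts death and
hospitalization in older adults.

Frailty instruments based on examinations or surveys are expensive and
cover small samples. A claims database already records diagnoses for a
whole population, so frailty can instead be operationalized with the
**cumulative-deficit model**: pick a catalog of $K$ deficit items, and
score each person as the fraction they carry,

$$\mathrm{mFI} = \frac{\text{number of deficits present}}{K} \in [0, 1].$$

This package implements the full pipeline on claims tables:

1. **Cohort screening** — beneficiaries aged 65–100 with continuous
   coverage through a one-year baseline window
   (`select_study_cohort()`).
2. **Deficit selection** — candidate items are 3-digit ICD-9-CM code
   roots; a person carries one only with ≥3 outpatient or ≥1 inpatient
   baseline claims naming it; a root enters the catalog only if its
   rule-qualified prevalence exceeds 2%, rises across the five age bands
   65–69…≥85 (OLS slope > 0, R² > 0.30), and is below 100% in the
   youngest band (`build_presence_matrix()`, `select_deficits()`).
3. **Scoring and categories** — exact deficit proportion, categorized as
   fit / mild / moderate / severe at cut points 0.0625 / 0.125 / 0.1875
   (right-closed), or by quantiles as a sensitivity analysis
   (`compute_mfi()`, `categorize_mfi()`, `categorize_quantile()`).
4. **Outcomes** — all-cause death (disenrollment), unplanned
   hospitalization (admission after an ED visit) and ICU admission, as
   time-to-event data at 1/5/8-year horizons with death censoring for
   non-fatal outcomes (`derive_outcomes()`, `build_survival_dataset()`).
5. **Statistics** — Kaplan–Meier + log-rank, unadjusted and age/sex-
   adjusted Cox models (Breslow ties, Wald 95% CIs), and logistic
   discrimination (C-statistic, Cox–Snell/Nagelkerke pseudo-R²)
   (`km_estimate()`, `logrank_test()`, `cox_fit()`, `discrimination()`).

A **synthetic claims generator** (`simulate_cohort()`,
`default_sim_config()`) emits beneficiary/claims tables with known ground
truth — which codes are genuine age-trending deficits, each person's
latent burden, and the true outcome log-hazards — so every stage is
testable end to end. `run_pipeline()` orchestrates everything and writes
per-stage CSV artifacts plus a run manifest; a thin CLI lives at
`inst/cli/mfi.R`.

All user-facing functions take and return tibbles and chain with the
pipe; fitted objects have `tidy()`/`glance()` methods and results have
`autoplot()`/`plot_*()` displays.

## Worked example

```r
library(mfindex)
library(dplyr)

sim      <- simulate_cohort(default_sim_config(n_subjects = 20000, seed = 1))
cohort   <- select_study_cohort(sim$beneficiaries)
#> Excluded 193 of 20000 beneficiaries (coverage: 193).
presence <- build_presence_matrix(cohort, sim$claims)
catalog  <- select_deficits(presence, cohort)
attr(catalog, "total_items")
#> [1] 32
```

The catalog carries full diagnostics for every candidate. The planted
decoys fail for the right reasons — `250` (the diabetes-like code, 15%
prevalence but flat in age) fails the trend criterion, `042` (rare) the
prevalence floor:

```r
head(as_tibble(catalog)[, c("code_root", "overall_prevalence", "slope",
                            "r_squared", "selected")], 4)
#>   code_root overall_prevalence     slope r_squared selected
#> 1 042                  0.00353  0.000732    0.633  FALSE
#> 2 250                  0.151   -0.000884    0.0607 FALSE
#> 3 285                  0.0335   0.00935     0.987  TRUE
#> 4 290                  0.0342   0.00865     0.964  TRUE
```

Scores are right-skewed with a mean near 0.05 and three quarters of the
cohort in the fit category:

```r
scores <- compute_mfi(presence, catalog) |> categorize_mfi()
summarize_cohort(scores, cohort)$distribution
#>       n   mean     sd median   p99
#> 1 19807 0.0514 0.0542 0.0312 0.219
```

Adjusted 1-year mortality hazard ratios show the expected frailty
gradient (the generator plants category log-hazards ln 2 / ln 3 / ln 5,
an age effect of 0.08/year and a male effect of 0.3):

```r
outcomes <- derive_outcomes(sim$beneficiaries, sim$claims)
d1 <- build_survival_dataset(cohort, scores, outcomes, "death", 1)
tidy(cox_fit(d1, adjusted = TRUE))
#>   term                     estimate std_error hazard_ratio conf_low conf_high
#> 1 frailty_categorymild        0.690     0.069        1.99     1.74      2.28
#> 2 frailty_categorymoderate    1.15      0.087        3.17     2.67      3.76
#> 3 frailty_categorysevere      1.46      0.109        4.32     3.49      5.35
#> 4 age_at_baseline             0.083     0.004        1.09     1.08      1.10
#> 5 sexfemale                  -0.360     0.058        0.698    0.623     0.781
```

Each hazard ratio compares a frailty category against the fit reference:
severely frail subjects die at about 4.3 times the rate of fit subjects
of the same age and sex within one year. `discrimination(d1)` reports a
C-statistic of 0.654 for the same horizon — the categories alone order
1-year deaths moderately well.

The whole analysis, with every stage artifact written to disk:

```r
cfg <- pipeline_config(simulation = default_sim_config(20000, seed = 1))
run_pipeline(cfg, "mfi_output")
```

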