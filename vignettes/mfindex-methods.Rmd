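---
title: "Methods: a claims-based multimorbidity frailty index"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a claims-based multimorbidity frailty index}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mfindex)
library(dplyr)
```

## The model

The cumulative-deficit model operationalizes frailty as the fraction of a
fixed catalog of health deficits an individual exhibits. Given a catalog of
$K$ deficit items and a person carrying $d$ of them,

$$\mathrm{mFI} = \frac{d}{K} \in [0, 1],$$

with larger values meaning a frailer state. All deficits are equally
weighted: the signal comes from accumulation, not from any single
diagnosis. This package constructs such an index — a *multimorbidity
frailty index* (mFI) — from administrative claims alone, which trades the
richer clinical detail of survey-based frailty instruments for population
scale and routine availability.

### Deficit items from diagnosis codes

Candidate items are 3-digit ICD-9-CM code roots: all codes sharing their
first three characters (after stripping the decimal point, so `428.0` and
`4280` agree) count as one candidate. A person is considered to *carry*
a deficit in the one-year baseline window only with at least **3
outpatient claims or 1 inpatient claim** naming the root — a specificity
filter against one-off rule-out diagnoses. Each claim line counts once per
root even if it lists the root twice.

A candidate root enters the catalog only if, computed on rule-qualified
presence in the study cohort:

1. overall prevalence is strictly above 2%;
2. prevalence across the five age bands 65–69, 70–74, 75–79, 80–84, ≥85,
   regressed on band index 0–4 by ordinary least squares, has a strictly
   positive slope with $R^2$ strictly above 0.30 (deficits should
   accumulate with age);
3. prevalence in the 65–69 band is strictly below 100% (a code everyone
   already has by 65 carries no discriminating information).

The band index, not an age midpoint, is the regression abscissa: the
open-ended oldest band has no midpoint, and slope sign and $R^2$ are
invariant to any affine recoding of an equally spaced abscissa, so the
choice only changes the slope's units. When band prevalences are exactly
constant the total sum of squares is zero, $R^2$ is undefined, and the
code fails criterion 2 (its slope is zero anyway). With fewer than three
non-empty bands no trend is computed and the code fails with an
"insufficient bands" diagnostic.

A statistical caveat worth knowing: criterion 2 applied to a code whose
*true* prevalence is exactly constant still passes with roughly 20%
probability at any cohort size, because the five estimated prevalences are
then pure sampling noise and $R^2$ is scale-free (its null distribution is
approximately Beta(1/2, 3/2), giving $P(R^2 > 0.3) \approx 0.66$, halved
by the sign constraint). The five-point screen is a filter on trend
*shape*, not a calibrated hypothesis test; genuinely flat codes are
rejected only most of the time. Codes with truly rising prevalence and
slopes of realistic size are selected essentially always at cohort sizes
in the tens of thousands.

### Categories

The four frailty categories use fixed cut points 0.0625, 0.125 and 0.1875
— multiples of 2/32, so with a 32-item catalog they are pure deficit-count
boundaries (fit ≤ 2, mild 3–4, moderate 5–6, severe ≥ 7). Intervals are
right-closed: a score exactly at a cut point belongs to the lower
category, the convention forced by "severe" being defined strictly above
the top cut point; the printed ranges in the source material overlap at
the boundaries, so this convention is declared rather than inferred.
Tertile/quintile categorization on empirical quantiles is available as a
sensitivity analysis (`categorize_quantile()`); with heavy ties at zero —
typical for right-skewed deficit counts — the lowest group absorbs all
tied scores and groups are deliberately left unbalanced.

### Outcomes and censoring

Three outcomes are derived per person: all-cause death (the disenrollment
date on the registry), unplanned hospitalization (first inpatient
admission that followed an emergency-department visit), and ICU admission
(first admission with ICU services). Follow-up runs from the day after the
baseline year to the end of the study window; events are evaluated at 1-,
5- and 8-year horizons measured in calendar-exact days (365/1826/2922 days
from 2006-01-01). For the non-fatal outcomes, death censors follow-up; on
a same-day tie the admission counts as the event. Disenrollment for
reasons other than death is right-censoring at coverage end; baseline-year
admissions are never outcome events because follow-up starts after the
baseline window. Time is the follow-up *day number* (an event on the first
follow-up day has time 1), keeping all times positive.

### Statistics

Kaplan–Meier curves with the $k$-group log-rank test describe the
category-outcome association; Cox proportional-hazards models (Breslow
tie handling by default, Efron by switch; `survival::coxph` with
`eps = 1e-10`, `iter.max = 50`) estimate hazard ratios with Wald 95%
intervals on the log scale ($z = 1.959964$). The unadjusted model uses
category indicators only (fit as reference); the adjusted model adds age
as a continuous covariate in years and sex. Monotone likelihoods
(complete separation) are flagged as non-converged rather than reported.
Discrimination at a horizon uses a logistic fit of the binary
event-by-horizon outcome on the category indicators: the C-statistic is
the Mann–Whitney concordance of the fitted probabilities (identical to
the area under the ROC curve), with Cox–Snell and Nagelkerke pseudo-$R^2$
from the log-likelihoods. Because a logistic model cannot represent
censoring, persons censored before the horizon for non-death reasons are
excluded (with a reported count); persons dying event-free before the
horizon are controls for the non-fatal outcomes, and survivors to the
horizon are controls for death. The categories enter as indicators rather
than an ordinal score; an ordinal alternative would constrain the fit but
not change the concordance ordering of the categories.

## The synthetic cohort generator

Real national claims databases are not redistributable, so the package
ships a generator (`simulate_cohort()`) whose output has *recoverable
ground truth* at every pipeline stage: which roots are genuine
age-trending deficits, each person's latent deficit count and true
category, and the true log-hazards behind every outcome.

* **Presence.** Each code's presence is Bernoulli with a per-age-band
  probability. An optional mean-one Gamma person factor
  (`frailty_dispersion`, the Gamma variance) multiplies all of a person's
  presence probabilities, inducing positive deficit correlation and
  over-dispersed counts; 0 disables it. Codes specified at exactly 100%
  prevalence stay at 100% — a saturated code has no person-level
  variation for the factor to modulate.
* **Claims.** Present codes emit `claim_min + Poisson(claim_lambda)`
  outpatient claims and an inpatient claim with a per-code probability,
  so a predictable fraction of latent presences fail the
  3-outpatient/1-inpatient rule — a distinct truth state reported in
  `ground_truth$code_truth`. Codes surface in varied forms (`428`,
  `4280`, `428.0`) to exercise normalization; irrelevant noise claims
  draw from a pool of transient-condition roots. Claim dates are uniform
  within the year, which is immaterial to the index.
* **Outcomes.** Event times are exponential with hazard
  $\lambda_o \exp(\beta_{\text{cat}} + \beta_{\text{age}}(a - 75) +
  \beta_{\text{male}} m)$, the category being the person's *true* one
  (latent count over the 32 genuine roots, fixed cut points). Constant
  hazards with log-linear covariates are the simplest generator exactly
  consistent with proportional hazards, so a correct Cox implementation
  recovers the planted coefficients without approximation bias. Non-fatal
  events occurring before death and inside the window materialize as
  flagged inpatient claims; unflagged "planned" admissions are also
  emitted so the ED filter does real work. ED and ICU flags are kept
  disjoint on generated event claims so each outcome's hazard is exactly
  the planted one.

### Default configuration

`default_sim_config()` encodes the study conditions the package is tested
under, calibrated to the published cohort the index was developed on:

* 20,000 subjects; age-band weights 0.331/0.275/0.218/0.115/0.061 and a
  49.8% male share, giving a mean age near 73.9; within-band ages are
  uniform (geometrically damped above 85).
* 32 genuine age-rising roots with 65–69-band latent prevalences spread
  over 2.5–5.5% and per-band rises of 1.2–2.2 percentage points. With the
  claim-count distribution (1 + Poisson(3) outpatient, 15% inpatient),
  about 83% of latent presences rule-qualify, which puts the mean mFI
  near 0.05, the median at 0.031, and roughly 75% of the cohort in the
  fit category — matching the published distribution.
* Decoys exercising every criterion: one exactly flat code at 18.15%
  prevalence in every band (the diabetes-mellitus case: common but not
  age-trending), two rare codes below the 2% floor, and one saturated
  code at 100% in all bands whose claim distribution guarantees
  qualification, so the saturation rule rejects it deterministically.
* `frailty_dispersion = 0.4`: the published index is clearly
  over-dispersed relative to independent deficits (SD above the mean,
  99th percentile near 0.25), and a Gamma variance of 0.4 reproduces that
  right tail while leaving per-code band prevalences unbiased.
* Category log-hazards for death of $\ln 2 / \ln 3 / \ln 5$ with an age
  effect of 0.08 per year and a male effect of 0.3 (similar gradients,
  smaller age effects, for the two admission outcomes) — close to the
  adjusted 1-year gradients reported for the real index.

What the generator does *not* emulate: real Taiwanese epidemiology or any
code-to-disease ontology (roots are plausible labels, nothing more),
diagnosis-code misclassification, care-seeking behavior that correlates
claim counts with frailty itself, competing-risk structure beyond
death-censoring, or non-proportional hazards. Passing the recovery tests
therefore demonstrates that the *pipeline arithmetic* is right — not that
the index would show these exact properties on any particular real
database.

## Numerical and design choices

* **Age** is completed years at the baseline window start (the reference
  date is otherwise ambiguous), both for eligibility and band assignment.
* **Selection thresholds are strict inequalities** ("more than 2%",
  "more than 0.30"), and the saturation rule is "strictly below 1" in the
  65–69 band.
* **Criterion order**: the presence rule is applied before prevalence is
  computed, so all three criteria see rule-qualified presence; a switch
  for raw-occurrence prevalence is deliberately absent because the two
  interleave incoherently. V- and E-codes are candidates by default
  (`numeric_only = FALSE` drops them by switch).
* **Cohort screening** attributes each exclusion to the first failing
  criterion in the order age → death-in-baseline → coverage, making the
  exclusion ledger single-counted.
* **Cox convergence** uses `survival`'s Newton–Raphson with a tightened
  tolerance (`eps = 1e-10`); coefficients above 15 in absolute value or
  standard errors above 50 are treated as monotone-likelihood
  divergence and flagged.
* **Determinism**: all randomness flows from the single configured seed;
  rerunning a pipeline with the same configuration reproduces every CSV
  byte-for-byte (the manifest differs only in its timestamp).

## Problem sizes in the test suite

The bundled checks run the oracle-equivalence comparison on 100 random
panels of 500 persons with 20 candidate roots; deficit recovery on twenty
20,000-subject replicates; Wald-interval coverage on 200 replicates of
n = 5,000 with a true hazard ratio of 3; and gradient recovery on one
20,000-subject cohort — sizes at which every binomial or Wald tolerance
used in the assertions has comfortable slack while the whole suite stays
desk-scale.

## Known limitations

* The index is cross-sectional at baseline; no time-varying mFI.
* First events only; no recurrent-event or competing-risk
  (subdistribution hazard) modelling.
* The ED-linkage of an admission is collapsed into a single flag on the
  inpatient claim; real claims systems require a visit-level linkage the
  generator does not model.
* No ICD-10 support and no clinical grouping of related roots; each
  3-digit root is its own item even when clinically overlapping.
* The flat-code caveat above: the age-trend screen has a known,
  irreducible false-pass rate on exactly-flat codes.
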