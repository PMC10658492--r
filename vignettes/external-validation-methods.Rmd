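---
title: "Validating the canine Cushing's prediction tool: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating the canine Cushing's prediction tool: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cushval)
```

## The prediction tool

Spontaneous Cushing's syndrome (hypercortisolism) in dogs is usually
suspected from a typical picture — polydipsia/polyuria, a potbellied
appearance with hepatomegaly, dermatological changes, raised serum alkaline
phosphatase (ALP) — and confirmed with adrenal function tests that are
slow, costly, and imperfect. A points-based prediction tool was developed
in UK primary-care practice to quantify the pre-test likelihood from ten
routinely available predictors: neuter status, age, breed, five presenting
signs (polydipsia, vomiting, potbelly/hepatomegaly, alopecia, pruritus),
urine specific gravity (USG) category, and serum ALP category.

`cushval` embeds this tool in two forms:

* **the integer points score** (`cushing_points_grid()`, applied by
  `score_cohort()`): one category per predictor, summed; the achievable
  total spans −13 to 10 (`score_range()` confirms this by exhaustive
  enumeration of all 13,824 category combinations);
* **the full logistic model** (`cushing_coefficients("development")`,
  applied by `linear_predictor()` and `predict_probability()`): log-odds
  coefficients with a finer age banding (<7, 7–<11, ≥11 years) and a
  ten-category breed factor whose baseline is *crossbreed*.

The two encodings deliberately differ in their breed and age handling, so a
cohort record carries raw age in years and a free-text breed label, and
each consumer derives its own banding and breed category
(`normalise_breed()` matches case-insensitively after stripping
punctuation; anything unrecognised becomes "other"). Band edges are closed
on the left: a dog of exactly 7.0 years falls in "≥7" and "7–<11".

Two scoring conventions come from the source data being medical records: a
clinical sign not mentioned is treated as **absent**, whereas missing
laboratory values map to their explicit **"not recorded"** categories
(which carry their own points and coefficients), never to a default level.

The original publication maps each total score to a predicted likelihood
(0% at −13 up to 96% at 10), but the intermediate values are not restated
with the grid. `score_to_probability()` therefore takes a user-supplied
lookup table, and the full-model probability is the default predicted
probability throughout the validation pipeline. Probabilities are clipped
into [0.001, 0.999] before any logit transform so that the published 0%
endpoint cannot produce an infinite logit; the floor and ceiling are
arguments of `clip_probability()`.

## Case adjudication

`interpret_uccr_hddst()` encodes the urine corticoid-to-creatinine ratio
(UCCR) protocol with oral high-dose dexamethasone suppression: disease is
suspected when the mean of the first two UCCRs is at or above a screening
cut-off (default 10 × 10⁻⁶, a laboratory-specific parameter), and a third
UCCR below 50% of that mean is suggestive of pituitary-dependent disease.
Boundaries follow the rules as written — a mean exactly at the cut-off
qualifies ("≥"), a third UCCR exactly at 50% does not suppress ("<"). The
protocol description in the source material restates the suppression
direction in an internally contradictory way; this implementation follows
the self-consistent form (suppression *below* 50% is PDH-suggestive) and
says so in its documentation. `alive_compliant()` implements the
three-criterion consensus checklist; imaging and morphology findings enter
as pre-adjudicated flags, since no imaging logic belongs in a scoring
package.

## The validation pipeline

`run_validation()` follows the two-step logic of external validation.

**Step 1 — transportability.** Whether the validation cohort differs from
the development cohort in case mix: `baseline_table()` summarises each
variable by outcome with Fisher's exact test (categorical) or Wilcoxon's
rank-sum test (numeric); `cohort_compare()` compares two cohorts from
summary counts or percentages (percentages are converted back to counts by
rounding and flagged as reconstructed); `fit_logistic()` refits the model
structure and `compare_coefficients()` sets development and refitted
coefficients side by side. Heterogeneity between paired coefficients is
quantified by a labelled supplementary statistic
$z = (r_{val} - r_{dev}) / \sqrt{SE_{dev}^2 + SE_{val}^2}$ — an addition
for convenience that never alters the published-style columns.

**Step 2 — performance.**

* *Calibration.* `recalibrate()` fits
  $\mathrm{logit}(y) = a + b \cdot \mathrm{logit}(\hat y)$ by maximum
  likelihood. $a$ is calibration-in-the-large (ideal 0; negative means the
  model overestimates), $b$ the calibration slope (ideal 1). Both are
  fitted jointly by default; `fix_slope = TRUE` gives the intercept-only
  update. Because the natural null for the slope is ambiguous (0 tests
  informativeness, 1 tests ideality), both Wald tests are returned,
  labelled. `hosmer_lemeshow()` groups records by deciles of predictions
  (ties stay together, so bins can be unequal; bins with zero expected
  counts are merged with a neighbour under a warning) and uses
  `groups − 2` degrees of freedom. `calibration_table()` emits the decile
  table behind a calibration plot.
* *Discrimination.* `c_statistic()` computes the probability that a random
  case outranks a random non-case (ties count half), identical to the area
  under the ROC curve; `roc_curve()` returns the empirical staircase whose
  trapezoidal area equals the c-statistic to machine precision (this
  identity is asserted in the test suite at 10⁻¹²). The 95% CI uses the
  DeLong variance by default; a seeded bootstrap (2,000 resamples) is the
  alternative, since the CI method behind published intervals is often
  unstated. Interpretation bands: below 0.7 poor, 0.7–0.8 acceptable,
  0.8–0.9 excellent, above 0.9 outstanding, with 0.8 and 0.9 both read as
  excellent.
* *Thresholds.* `threshold_diagnostics()` dichotomises at a score
  threshold (≥ threshold predicts a case, the convention used for the
  published thresholds 2 and 0, which are the defaults reported by
  `run_validation()`) and returns the confusion counts with sensitivity,
  specificity, PPV and NPV; a zero denominator yields `NA` with a warning
  rather than a silent 0.

## Exact contingency-table tests

Fisher's exact test is implemented by enumeration because its two-sided
convention and tie handling are exactly what case-mix comparisons depend
on. The two-sided p-value sums the probabilities of all tables with the
observed margins that are *at most as probable* as the observed table —
the convention of mainstream statistical software — with a relative
tolerance of 10⁻⁷ on probability ties to keep enumeration platform-stable.
The r×c generalisation (Freeman–Halton) enumerates recursively and is
guarded at a table total of 500; beyond that a seeded Monte Carlo estimate
over `r2dtable()` draws is offered instead. The test suite checks the 2×2
implementation against an independent log-factorial enumeration for every
table with total ≤ 60, and against `stats::fisher.test()` on random r×c
tables.

Comorbidity 2×2 tests exclude the "not recorded" category, following the
recorded-only denominators used in the source analyses; USG and ALP keep
"not recorded" as a real category because the tool itself scores it. Two
of the published comorbidity p-values (diabetes mellitus, gall-bladder
content) and the lymphopenia value do not reproduce exactly under any
standard two-sided Fisher convention we examined; the package reports the
computed values rather than the printed ones.

## The synthetic cohort generator

No dog-level data are distributed, so `generate_cohort()` simulates
cohorts with the statistical structure the pipeline assumes: predictors
drawn independently from configurable marginals, and the outcome drawn
Bernoulli with probability $\mathrm{expit}(\delta + \gamma \cdot lp)$,
where $lp$ is the linear predictor of a true coefficient set, $\delta$ an
injected calibration-in-the-large offset and $\gamma$ a slope multiplier.
With $\delta = 0, \gamma = 1$ the generator is perfectly calibrated for
the model, so `recalibrate()` must recover $(a, b) = (0, 1)$; with an
injected offset it must recover $a \approx \delta$ — these recovery
properties are the backbone of the test suite.

`validation_casemix_spec()` packages the marginals of the external-validation
case mix (polydipsia 86.5%, potbelly/hepatomegaly 52.6%, alopecia 30.9%,
USG not recorded 49.6%, ALP not elevated 31.7%, and so on; marginals
printed to one decimal are renormalised to sum to 1) with the development
coefficients as truth. Ages are drawn uniformly within the sampled band,
between 2 and 16 years — the age range seen in referral practice.

Its deliberate limitation: real predictors are correlated (a dog with
hypercortisolism tends to show several signs together), but only marginal
frequencies are published, so the generator draws predictors
independently. Independence compresses the spread of the linear predictor,
which lowers the achievable discrimination: the generating model scores a
c-statistic of roughly 0.77 on such cohorts, below the 0.83 observed on
real dogs. Passing tests therefore demonstrate correctness of the
*machinery* (calibration recovery, slope tracking, estimator equivalences)
— not that the tool attains any particular performance in a real
population. For the same reason cohort-level published statistics
(c = 0.83, a = −1.10, b = 1.35, the threshold sensitivities) are not used
as test expectations; they derive from confidential records.

## Numerical choices

* Logistic fits (recalibration and refit) use iteratively reweighted least
  squares with a relative convergence tolerance of 10⁻¹⁰ and at most 100
  iterations, from zero start values — fully deterministic.
* Complete or quasi-complete separation (e.g. a breed category with no
  cases) is reported as-is — the diverged estimate and inflated standard
  error, flagged with a warning — because that is how such rows are
  conventionally displayed; penalised (Firth-type) fitting is out of
  scope. An estimate is flagged when |estimate| > 10 or SE > 100. The
  remaining coefficients are unaffected: perturbing the separated
  coefficient's start value moves them by less than 10⁻⁴.
* An intercept-only design returns the logit of the observed prevalence to
  within 10⁻⁶, which the test suite asserts.
* P-values are formatted to three decimals with "<.001" below that;
  percentages print to one decimal.

## Problem sizes in the tests

The simulation-based tests use cohorts of 2,000–5,000 dogs (recalibration
recovery, slope tracking, coefficient recovery over 20 replicates),
100,000 for marginal-convergence checks, 200 replicates for type-I-error
checks of the Hosmer–Lemeshow and rank-sum tests, and exhaustive
enumeration for the scoring grid (13,824 combinations) and the 2×2 exact
test (all 628,055 tables with total ≤ 60). These sizes give Monte Carlo
error comfortably below the asserted tolerances while keeping the full
suite fast.

## Known limitations

* Predictor independence in the generator, as discussed above.
* The score-to-likelihood lookup must be supplied by the user; only its
  endpoints are embedded.
* Exact r×c enumeration grows combinatorially; the guard and the Monte
  Carlo fallback are blunt instruments for very large sparse tables.
* `fit_logistic()` refits only the published model structure; variable
  selection, shrinkage, intercept updating and the construction of new
  models are intentionally out of scope.
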