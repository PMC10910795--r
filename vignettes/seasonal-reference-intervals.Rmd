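---
title: "Seasonally adjusted reference intervals: model, pipeline and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Seasonally adjusted reference intervals: model, pipeline and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Clinical laboratories flag a test result as abnormal when it falls outside a
standard reference interval (RI) — the central 95% band of a healthy
reference population, published per test, sex and age group. Many analytes
(CRP and other inflammation markers, haemoglobin, vitamin D, TSH) drift with
the seasons, so a fixed year-round interval systematically over-flags in one
half of the year and under-flags in the other. When abnormality flags are
fed to disease-classification models as features, that seasonal
misclassification is pure noise from the model's point of view.

`seasonri` implements a pipeline that (i) quantifies per-stratum seasonality
in laboratory values with a bounded single-harmonic cosinor, (ii) translates
each standard RI week by week to follow the fitted seasonal wave, (iii)
re-encodes abnormality flags under both the standard interval ("version 1")
and the adjusted interval ("version 2"), and (iv) asks whether classifiers
trained on version-2 features beat their version-1 twins, using a paired
bootstrap with bias-corrected accelerated (BCa) intervals, plus
permutation-sampled Shapley attributions for interpretation.

Because the registry data this design targets is person-sensitive and not
redistributable, the package ships a synthetic EHR generator
(`simulate_cohort()`) whose statistical structure matches what the analysis
assumes. All claims the test suite makes are claims about that synthetic
structure, not about any real cohort.

## The seasonal model

For each stratum — a unique combination of test name, specimen, unit,
laboratory ID, sex, and 10-year age group — values are z-scored and their
weekly means $y_w$ are fit to the single-harmonic cosinor

$$ y = \beta_0 + \beta_1 \cos\!\left(2\pi\,\frac{week - \theta}{52}\right), $$

with $\beta_0,\beta_1 \in [-1, 1]$ (normalized units) and $\theta \in
[0, 52]$ (weeks), using `nls()` with the `"port"` algorithm so the bounds
are honoured. A single harmonic captures one peak and one trough per year,
which is the empirically dominant pattern for seasonal analytes.

Choices that the model statement leaves open, and what this package does:

* **Normalization.** "Normalize to zero" could mean centring or z-scoring;
  we z-score, because bounding $\beta_1$ to $[-1, 1]$ is only meaningful on
  a unit-variance scale shared across tests. A consequence worth knowing:
  the z-score divisor includes the seasonal variance itself, so fitted
  amplitudes are attenuated by $1/\sqrt{1 + \beta_1^2/2}$ relative to
  amplitudes expressed in noise-SD units (about 4% at $\beta_1 = 0.5$).
* **Fit target.** The fit is to the 52 count-weighted weekly means pooled
  across years, not to raw records: the model is week-indexed, weekly means
  keep the NLS well-conditioned at any cohort size, and the weights recover
  the raw-record least-squares solution up to within-week variation.
  Fitting needs at least 26 observed weeks (identifiability of three
  parameters across the season) and at least 20 records per stratum.
* **Multi-start.** The cosine's phase creates local minima; the fit is
  restarted from $\theta_0 \in \{1, 13, 26, 39\}$ and the converged start
  with the lowest weighted RSS is kept. Fits are canonicalized to
  $\beta_1 \ge 0$ (a negative amplitude is the same wave shifted 26 weeks),
  so $\theta$ is always the week of the peak.
* **Inference.** P-values are Wald tests of each parameter against zero
  from the asymptotic NLS covariance — exactly what `summary.nls()`
  reports. Benjamini–Hochberg FDR is applied separately within each
  parameter family (all $\beta_0$ p-values together, all $\beta_1$, all
  $\theta$) across strata.

### The significance rule

The strictest reading — all three q-values below $\alpha = 0.05$ — is the
`fdr_correct()` default. It is, however, vacuous under z-scoring: the
normalization forces $\hat\beta_0 \approx 0$, so its Wald test essentially
never rejects, and no stratum could ever be adjusted. The pipeline
configurations therefore use the `"amplitude_phase"` rule (only $\beta_1$
and $\theta$), which tests what actually matters: is there a wave, and is
its phase resolved? Note that a Wald test of $\theta$ against zero has no
power when the true peak sits near the week-0/52 seam; strata with
mid-winter peaks at week 1 are genuinely hard to declare significant under
either rule. The synthetic defaults place phases away from the seam for
this reason; real mid-winter analytes would need a reparameterized test
(out of scope here).

### From fit to adjusted interval

For a significant stratum the standard interval $(L, U)$ becomes, at week
$w$,

$$ (L, U) + s \cdot \left[\beta_0 + \beta_1 \cos\!\left(2\pi\,\frac{w - \theta}{52}\right)\right], $$

where $s$ is the stratum standard deviation used in the normalization: both
bounds translate by the de-normalized seasonal deviation. Translation
preserves the interval's width, reduces to the standard interval when
$\beta_1 = 0$, and keeps the adjustment a pure recalibration of *location* —
we deliberately do not rescale the width, since the cosinor models the
seasonal drift of the mean, not of the dispersion. Non-significant strata
keep their authority-defined intervals untouched.

## Cohort construction rules

All thresholds sit in `pipeline_config()`:

* Hospital encounters of one patient merge into an admission while the gap
  to the chain's running end is *strictly* under 24 h (a tie at exactly
  24 h starts a new admission); codes are unioned.
* Laboratory records attach to the earliest admission whose closed,
  one-sided window `[start, start + 24 h]` contains them.
* Among repeats of a test in one window, the record kept is the abnormal
  one with the largest deviation beyond the nearer bound, *normalized by
  the interval width* so that a −1 and a +1 are comparable across tests; if
  every repeat is normal, the last by timestamp is kept. Selection is
  re-run per encoding version, because the flag itself defines "most
  abnormal".
* Filters apply in a fixed order: age ≥ 20 → ICD codes truncated to level 3
  → tests kept at ≥ 20% admission coverage → outcomes kept at ≥ 1,000
  unique patients (desk-scale configs lower this) → a *fitting mask*
  excluding draws from patients who died within 28 days of the admission.
  Coverage and prevalence are computed on the age-eligible cohort; the
  survivor rule masks records from fitting only, never from the cohort.
* A record's stratum uses age *at draw*: patients crossing a decade
  boundary legitimately contribute to both strata over time.

## Feature encoding and the model comparison

Each admission becomes a row with one column per included test — flag −1,
0, +1 at the record's week under the version's bounds, 0 when unmeasured —
plus sex (0 = female, 1 = male). Values exactly on a bound are normal.
Columns are standardized with means and scales fitted on the development
split only; zero-variance columns pass through unscaled with a warning.

The split is at patient level (70/30), so no patient straddles it. Each
family (AdaBoost over weighted rpart trees, rpart decision tree, nnet
neural net, ranger random forest) is tuned by random search (≤ 40
configurations by default) under patient-grouped k-fold cross-validation;
training folds are balanced by oversampling the minority class with
replacement; selection is by mean F1 at a fixed 0.5 threshold, ties going
to the earliest sampled configuration.

The version comparison is paired end to end:

* the *same* tuning seed drives both versions' searches, so identical
  feature matrices yield identical models — without this, stochastic
  training alone (e.g. neural-net initialization) can manufacture a
  "significant" difference under the null;
* the *same* bootstrap resamples of the test admissions are used for both
  versions (1,000 boots by default; resamples missing a class are redrawn,
  keeping the count fixed);
* the BCa interval (10,000 outer boots) is computed on the **mean** of the
  paired difference distribution — the mean is the BCa-regular functional —
  while the **median** difference is reported as the effect size. A
  difference is significant when the BCa interval excludes zero.

Per-family net gain sums the median AUROC differences over outcomes with
non-significant entries zeroed first.

## Shapley attributions

`permutation_shap()` approximates Shapley values of the model score by
sampling (permutation, background row) pairs and crediting each feature the
marginal score change when its value is switched in along the permutation.
With exhaustive orderings and the full background this is exactly the
Shapley value and attributions sum to `f(x) − base_value` per row; the test
suite verifies this against brute-force enumeration. The background is a
seeded draw of up to 100 development rows — small enough for desk-scale
runtime, and the quantity of interest (mean |SHAP| rankings and level-wise
contrasts) is insensitive to the background size well before 100. Per
feature, attributions are compared across the *pre-standardization* input
levels (−1/0/+1) by one-way ANOVA with Bonferroni correction over the
features actually tested; features without two levels represented twice are
reported untested rather than dropped.

## What the generator emulates — and what it does not

`simulate_cohort()` reproduces the structure the pipeline relies on:
per-stratum cosinor signal plus Gaussian noise (the fitter's residual
assumption), admissions in uniformly drawn ISO weeks with uniform
within-week timing, transfer splits with <24 h gaps, repeated measurements,
per-test missingness, deaths within 28 days of an admission, and outcomes
drawn from a logistic model on abnormality flags — computed against the
*seasonally-true* interval when `uses_seasonal_truth` is set, which is
precisely the regime where the version-2 encoding carries real signal.
Separate admissions are spaced ≥ 72 h so only deliberate transfer splits
merge downstream.

It does **not** emulate: non-Gaussian or heteroscedastic lab noise,
between-year trends, correlated test panels, informative missingness,
diagnosis-code hierarchies beyond synthetic level-3 strings, or realistic
demography. Passing tests therefore demonstrate that the pipeline recovers
what it assumes, not that any particular real analyte behaves this way.

## Study conditions and problem sizes

`synthetic_study_config()` freezes the conditions used by the end-to-end
experiments: 3 tests with amplitudes 0.5–0.8 and phases at weeks 8, 20 and
30; baseline scales placed so the standard intervals sit roughly 1–1.5 SD
from the mean (a realistic abnormal rate of 15–25%, and enough flag
movement — over 15% of nonzero flags change between versions — for the
comparison to have something to detect); 4 years; one outcome at ~15%
prevalence with log-odds weights about ±1.3 per abnormality unit and 0.4
for sex. Evaluation uses a small neural-net grid (3 of 4 configurations
sampled, 3 patient-grouped folds), 200 paired boots and 2,000 BCa boots;
experiments run at 1,000–2,000 patients. These sizes keep a single
replicate under half a minute while leaving the expected version-2
advantage (~0.02–0.05 AUROC) several bootstrap standard errors from zero.

## Numerical corners

* Degenerate strata (constant values, < 2 records, < 26 observed weeks, or
  all-start NLS failure) are marked unfittable/unconverged and can never be
  significant.
* A perfectly flat weekly target makes the cosine unidentifiable in
  $\theta$; whichever way `nls` resolves it, the amplitude is ~0 and the
  stratum non-significant.
* Week 53 of ISO calendars folds into week 52.
* BCa on an all-equal difference sample returns a zero-width interval at
  that value (verdict: no difference). The bias-correction proportion is
  clamped away from 0/1 so $z_0$ stays finite.
* All randomness flows from one master seed through counter-derived
  sub-seeds per stage, per bootstrap index and per CV fit, so reruns and
  resumed runs are bitwise reproducible and bootstrap resamples are
  indexed, not order-dependent.

## Known limitations

* The adjustment translates intervals; seasonal variance changes (wider
  winter spread, say) are not modelled.
* Wald-on-$\theta$ significance is weak near the calendar seam (above).
* Single-harmonic only: analytes with two seasonal peaks need a richer
  basis, which is out of scope.
* At desk scale the outcome-prevalence threshold must be lowered from the
  1,000-patient default; the filter logic is identical.
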