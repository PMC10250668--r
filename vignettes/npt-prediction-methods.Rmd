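---
title: "Predicting nasal provocation test outcome: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting nasal provocation test outcome: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nptpredict)
library(dplyr)
```

## The clinical problem

In poly-sensitized children with seasonal allergic rhinitis, serum IgE
positivity to several pollens does not say which allergen actually drives
nasal symptoms. The nasal provocation test (NPT) — a controlled intranasal
allergen challenge — is the reference standard, but it is time-consuming
and poorly suited to routine use. This package implements a
diagnostic-accuracy workflow for predicting the grass-pollen NPT outcome
from quantities that are cheap to obtain at the clinic:

* **IgE-specific activity**: allergen-specific IgE expressed as a
  percentage of total IgE, $100 \cdot \mathrm{sIgE}/\mathrm{tIgE}$. For a
  set of molecules (e.g. the major timothy allergen Phl p 5 and the major
  Bermuda-grass allergen Cyn d 1) the *combined* activity divides the
  summed specific IgE by total IgE, and therefore equals the sum of the
  component activities.
* **Retrospective severity VAS** (0–10) for the past pollen season, and
  prospective e-diary scores (RTSS 0–18, CSMS 0–6, daily VAS 0–10)
  summarized over days with high airborne grass pollen.

Predictors are compared by empirical ROC curves; the decision algorithm of
interest calls the NPT positive when the combined Phl p 5 + Cyn d 1
activity is at least 7.25 % **or** the retrospective severity VAS is at
least 7 (both comparisons inclusive).

## Pollen-season windowing

Daily grass-pollen concentrations (grains/m³) are classified as *low*
(< 10), *medium* (10–30, both ends inclusive) and *high* (> 30, strict
inequality, matching the convention used for "high days" throughout).
Season windows come from a run rule: the season starts on the first day of
the first run of `run_length` (default 3) consecutive days at or above the
threshold and ends on the last day of the last such run — 10 grains/m³ for
the whole season, 30 for the peak season. Threshold-based season criteria
are always adapted to the local aerobiology, so both thresholds and the
run length are configurable, and `detect_season()` also accepts verbatim
window overrides for reproducing externally published season dates. Diary
summaries (`summarize_diaries()`) restrict each patient's records to the
high days inside the peak window and report the maximum and the
coefficient of variation, $CV = 100 \cdot SD/\bar{x}$, per score.

Numerical conventions worth stating:

* CV uses the **sample** SD (n − 1); with diary runs of a handful of days
  the denominator choice is visible, and the sample SD is the standard
  small-sample estimator. An all-zero score vector returns CV = 0 (the
  0/0 case is read as "no dispersion").
* A CV needs at least 2 observed high days; otherwise the summary is
  missing and the patient drops out of CV-based comparisons. Missing
  diary days are dropped, never imputed as zero: app non-entry is not
  evidence of absent symptoms.

## ROC analysis and cutoff selection

`roc_auc()` computes the probability that a random positive outscores a
random negative (ties 0.5), identical to the trapezoidal area under the
empirical ROC curve; inference uses the Hanley–McNeil standard error with
a two-sided normal test against AUC = 0.5. Candidate cutoffs are the
midpoints between consecutive distinct observed values plus two sentinels
(below the minimum, above the maximum) so both trivial corners of the ROC
curve are reachable. The reported cutoff maximizes Youden's
$J = \text{sens} + \text{spec} - 1$ under the rule "positive if score ≥
cutoff"; ties are broken toward higher specificity, then the lower cutoff.
The selection criterion is a genuine design choice — published ROC tables
rarely state one — so the accuracy-maximizing cutoff is reported alongside.
Percentages are rounded half-up to one decimal, the convention of the
tables this layout mirrors; `round_half_up()` is exported because R's
`round()` is banker's rounding and silently disagrees on exact halves.

`confusion_from_rates()` inverts a published ROC-table row: with the class
sizes and sensitivity/specificity in percent it reconstructs the integer
confusion matrix (half-up rounding, the unique convention consistent with
the predictive values printed in the tables this package reproduces), from
which PPV and NPV follow.

## Logistic model

`fit_logistic()` is a self-contained Newton–Raphson maximizer of the
binomial log-likelihood ("enter" method: all predictors at once).
Convergence requires the maximum absolute score below 1e-8 or a parameter
step below 1e-10 within 25 iterations; standard errors come from the
inverse observed information, Wald statistics are $(B/SE)^2$ with 1 df,
and odds-ratio intervals are $\exp(B \pm 1.96\,SE)$ — Wald intervals, the
convention of the statistical software whose output layout the
coefficient table mirrors. Non-convergence or any $|B| > 15$ raises a
typed separation error rather than returning a divergent fit; with 11
negatives a separating predictor is a realistic hazard. Model-level
summaries are the likelihood-ratio $\chi^2$ against the intercept-only
model, Nagelkerke's $R^2$ (Cox–Snell rescaled by its attainable maximum),
and classification accuracy at the 0.5 probability threshold.
`box_tidwell()` checks linearity in the logit by augmenting the model
with $x\ln x$ terms and reporting their Wald p-values; zero-containing
predictors are shifted by 0.5 (half of the smallest increment of the
integer-valued scores used here) before the log transform. VAS enters the
model as a continuous covariate — a deliberate reading of its single
printed coefficient.

In tests, `stats::glm`, `wilcox.test`, `fisher.test` and `chisq.test`
serve purely as independent cross-checks of the self-implemented
routines; the package never delegates to them.

Two-group comparisons use a self-implemented Mann–Whitney U (exact
p-value by full enumeration of the U null distribution for tie-free
samples up to combined size 12, otherwise a tie-corrected,
continuity-corrected normal approximation) and, for 2×2 frequency tables,
either Fisher's exact test (probability-mass two-sided definition) or the
Yates-corrected $\chi^2$. "χ² with Fisher's correction" is an ambiguous
label in applied reports; `compare_2x2()` follows the common convention of
the exact test whenever an expected cell is below 5.

## The synthetic cohort generator

The study data this workflow targets are patient-level and not publicly
deposited, so the package ships a generator whose defaults emulate the
published cohort structure; every downstream stage is exercised against
it. The defaults are fixed study conditions, not tuning knobs:

* 72 patients, NPT-positive prevalence 0.847.
* Total IgE lognormal with median 421 kU/L and $\sigma_{\log} = 0.97$
  (chosen so the IQR spans roughly 199–737 kU/L).
* Per-analyte sensitization rates and level medians split by NPT group
  (`default_analyte_panel()`). Phl p 5 carries the key separation: 64 %
  sensitized among NPT-positives vs 18.2 % among negatives. Phl p 1 and
  Phl p 4 are near-ubiquitous in both groups (hence uninformative),
  Phl p 7 and Phl p 12 rare in both. Rates and medians for the extracts
  and Cyn d 1 were set once to plausible values consistent with the
  group medians of the emulated cohort and not revisited.
* Semi-quantitative specific IgE: non-sensitized analytes are coded
  exactly at the 0.1 kU/L assay floor; sensitized levels are lognormal,
  clipped (not resampled) into [0.36, 100] kU/L — the lower edge keeps a
  sensitized draw above the 0.35 kU/L positivity threshold, the upper
  edge reproduces the saturation of multiplex immunoblot assays.
* Physical consistency: each patient's summed specific IgE is rescaled,
  when necessary, to at most 90 % of total IgE, so every combined
  activity stays below 100 %. This is a joint constraint the per-analyte
  clipping alone cannot give.
* Retrospective severity VAS: rounded truncated normal on 0–10 with
  group medians 7 (positive) vs 5 (negative), SD 2 (only medians are
  published; the discretized normal is the simplest shape with the right
  centre).
* Diaries: per-patient latent severity (normal, group means separated by
  1.6 VAS units) plus an exposure term proportional to
  $\log(1 + \text{pollen})$ and day-level noise; RTSS and CSMS are
  range-proportional rescalings. All scores are clipped to their ranges.
* Pollen: a Gaussian seasonal hump with multiplicative lognormal noise,
  rounded and capped at 199 grains/m³.

A single seed drives named RNG substreams per stage, so cohort, pollen
and diary can be regenerated independently and byte-identically.

What the generator does **not** emulate: medication effects on symptom
scores, SPT–IgE discordance mechanisms (SPT wheals and IgE are correlated
only through the NPT group), multi-pollen co-exposure, and within-day
resolution. Passing tests on synthetic cohorts therefore demonstrate the
correctness and internal consistency of the statistical machinery under
the assumed data-generating process, not the clinical transportability of
any cutoff.

## Problem sizes used by the test-suite

Calibration checks run at 10 000 patients (binomial 3-SE bands), the
generator-monotonicity property at 5 000 patients over 10 seeds,
logistic parameter recovery at n = 2000 over 200 replicates, and the
exhaustive oracle comparisons cover all 2×2 tables up to n = 40 and all
Mann–Whitney layouts up to combined size 10. These sizes make the
Monte-Carlo bands tight enough to be meaningful while keeping the whole
suite quick to run.

## Worked example

```{r example}
cfg <- pipeline_config(
  cohort = cohort_config(n_patients = 72, seed = 7),
  pollen_args = list(n_days = 120),
  seed = 7
)
report <- run_pipeline(cfg)
report

report$roc |>
  filter(predictor %in% c("activity_phl_p_5_cyn_d_1",
                          "vas_severity_retro")) |>
  select(predictor, auc, auc_p, cutoff, sens, spec)

if (inherits(report$logistic, "npt_logit")) {
  tidy(report$logistic)
  glance(report$logistic)
}
```

```{r roc-plot, fig.width = 4.5, fig.height = 4.5}
d <- left_join(report$cohort, report$activity, by = "patient_id")
autoplot(roc_curve_points(d$activity_phl_p_5_cyn_d_1, d$npt_positive))
```

## Known limitations

* The "overall quality of the model" column that some ROC tables print
  has no stated formula and is not reproduced.
* The Hanley–McNeil AUC test is asymptotic; with 11 negatives it is
  indicative rather than exact.
* Bootstrap confidence intervals for cutoffs and DeLong comparisons of
  correlated ROC curves are out of scope.
* Cutoffs selected by Youden's J on 72 patients are highly variable;
  the simulated-cohort cutoff distribution makes this visible.
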