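---
title: "Methods: sway and drift biomarkers, reliability, and disability models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sway and drift biomarkers, reliability, and disability models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(swaymetrics)
```

This vignette is the package's account of its methods: what each stage
computes, which choices were genuinely open and how they were settled,
and what the synthetic cohort does and does not establish about real
data.

## Signal model of the synthetic cohort

Each subject carries a latent disability scalar `D >= 0`: zero disease
severity for healthy volunteers plus a small age term
(`0.02 * (age - 18)` by default), and a gamma-distributed severity for
disease groups whose means are ordered by diagnosis (progressive MS
highest). Severity is split into cerebellar, proprioceptive and motoric
subsystem components that drive the exam panel scores, the MRI grades
and — for the cerebellar component — pronator-drift tremor.

A sway trial's horizontal acceleration is a band-limited stochastic
process (2–4 damped sinusoids with random frequencies below ~3 Hz and
phases, plus AR(1) noise), matching the frequency range postural-sway
analyses operate in while giving analytic control over spectral moments.
Its standard deviation scales multiplicatively with:

* a stance difficulty factor, ordered EO-FA (1.0) < EO-FT (1.45) <
  EC-FT (2.3) — removing vision and narrowing the base increase sway;
* an age factor, `1 + 0.012 * (age - 20)` per year;
* `exp(0.25 * D)` in latent disability;
* a per-subject lognormal factor (SD 0.30 on the log scale) that is
  stable across trials, and a per-trial lognormal factor (SD 0.25)
  modelling between-day variability.

The ratio of those last two variances is the generator's test-retest
knob: amplitude biomarkers inherit an ICC near
`sigma_b^2 / (sigma_b^2 + sigma_w^2)` before estimation noise, and the
spectral biomarkers come out less reliable simply because a 450-sample
periodogram is a noisy estimator — the same hierarchy reliability
filtering is meant to exploit. Trial timing is not modelled; the
between-day knob (`trial_sd_log`) stands in for whatever the true
inter-trial spacing contributes.

Drift trials add a narrowband 4–8 Hz tremor whose amplitude scales with
the cerebellar component, with a configurable dominant/non-dominant
asymmetry (default ±15%). Gravity (9.81 m/s²) plus a fixed per-subject
mounting tilt (uniform within 15° of vertical) embeds the horizontal
process in the device frame, and white sensor noise (SD 0.01 m/s²) is
added — so the calibration stage has real work to do.

Clinical scales are wide logistic transforms of `D` (near-linear over
the observed range, saturating at the scale bounds) plus Gaussian noise
whose SD is derived from the realized signal SD so that each scale's
Pearson correlation with `D` hits a configured target (0.85 by
default); the EDSS is then rounded to 0.5 steps and clamped to [0, 10].
This reproduces the bounded, mutually correlated scale structure without
claiming clinical realism.

What passing tests on this cohort do **not** show: robustness to
non-stationary artifacts (steps, coughs, phone handling), to missing or
truncated trials, to orientation changes mid-trial, or to the much
weaker and colinear effect structure of real clinical scales.

## Calibration

The referenced device-calibration protocols differ in detail; we adopt
the standard tilt-correction convention for trunk-worn accelerometers:
trim to the **first** 9 s (the only deterministic reading of "trimmed to
9 seconds"), estimate gravity as the trial-mean vector, rotate it onto
the vertical via the minimal (Rodrigues) rotation, and demean the two
horizontal components per trial. Per-trial demeaning, rather than
high-pass filtering, is the default because it is exactly invertible
and leaves spectral content above 1/9 Hz untouched; it is the one place
a DC-blocking filter would be a defensible alternative. Rotation
preserves per-sample vector magnitude to machine precision, and the
radial series definition makes `RMS_Net^2 = RMS_ML^2 + RMS_AP^2` an
algebraic identity — both are enforced as tests.

For hand-held drift trials the phone's orientation is uncontrolled, so
ML/AP labels are meaningless there; only orientation-invariant Net
measurements enter the drift biomarker set.

## Measurements and the biomarker grammar

`rms()` is the plain quadratic mean. `jerk()` differentiates with
central differences (one-sided at the ends) and integrates the squared
derivative with the trapezoid rule — both second-order accurate, and
exact on the linear-ramp oracle. `power_spectrum()` is a single-taper
periodogram of the mean-removed series, normalized so the full-band
integral equals the series variance; 450 samples are too few for Welch
averaging without destroying the 0.11 Hz frequency resolution the sway
band needs. Band edges default to 0.15–10 Hz for sway and 0.15–15 Hz
for drift (covering the tremor band); the lower edge excludes DC
leakage. Spectral spread is reported as the second central moment μ₂
(Hz²), as defined, not its square root.

Feature names follow `<measurement>_<direction>_<condition>`. Condition
ratios (Romberg = EC-FT:EO-FT, Stance = EO-FT:EO-FA) are computed on raw
values and then logged, which by the log identity equals the difference
of logged stance features — forming them before or after the transform
is mathematically equivalent, so the raw-ratio-then-log order was
chosen and the identity is tested. The across-hand difference
(Dom − Ndom) is sign-indefinite, so a blanket log10 is impossible for
it; it uses the signed, order-preserving transform
`sgn(x) * log10(1 + |x|/1e-3)` instead, recorded as such in the feature
dictionary. All other raw values are floored at 1e-12 before log10.

## Reliability and outliers

`icc_2_1()` implements the single-measure absolute-agreement intraclass
correlation from the two-way crossed ANOVA decomposition,
`(MSR - MSE) / (MSR + (k-1) MSE + (k/n)(MSC - MSE))` with k = 2 trials
treated as raters. The literature sometimes labels this form
"two-way mixed-effects"; canonically ICC(2,1) is two-way *random*, and
the absolute-agreement formula above is what both conventions compute
for this design — the tests pin it against an independent `aov()`
mean-squares oracle. Zero-variance input returns a flagged `NA` rather
than propagating NaN. Retention uses the published ICC > 0.5 guideline.

Outliers are masked by Tukey fences (1.5×IQR beyond the quartiles,
type-7 linear-interpolation quantiles — the most common convention,
pinned for reproducibility). The **value** is masked, not the subject:
masking preserves cohort size, and downstream correlation uses
pairwise-complete deletion. Reliability is computed before masking
(matching the order the analysis stages are described in); both the
order and the fence multiplier are configurable.

## Association analyses

Correlation screens are Pearson over pairwise-complete cells, with
Benjamini–Hochberg adjustment applied once per screen (one family per
figure-equivalent table). Binary sex enters as 0/1 Pearson coding
(numerically the point-biserial correlation). Constant columns yield
flagged degenerate rows, not errors.

The normative age analysis fits OLS of a biomarker on age over healthy
volunteers and forms the standard two-sided 95% prediction interval for
a new observation. Flagging is **one-sided** — only values above the
upper bound count as abnormal, since disability elevates sway — so the
in-distribution flag rate is 2.5%, and a +3-residual-SD shift is
flagged at the normal-tail rate `pnorm(3 - qnorm(0.975)) ≈ 0.85`. An
epsilon guard keeps a zero-residual (exact line) fit from flagging on
floating-point jitter. Pairwise diagnosis-group comparisons use the
two-sided Wilcoxon rank-sum test on age-adjusted residuals with BH
adjustment across all pairs.

## Modeling protocol

The subject-level 80/20 split is stratified by diagnosis and drawn once
from the configured seed; it is an explicit input to the pipeline, so a
replay without the validation subjects reproduces every training-side
artifact bit for bit (asserted as a test). Features enter models only if
reliable (ICC > 0.5 on training) **and** BH-significant against at least
one relevant outcome on training; the default relevant sets are the
test-specific exam subpanels plus the three global disability scales and
the summed infratentorial MRI score.

Six candidates per outcome: ridge (α = 0), lasso (α = 1) and elastic
net (α searched over 0.1/0.5/0.9) on standardized raw features and on
PCA scores (components to 95% explained variance, minimum 2).
Regularization strength is chosen by 5-fold cross-validation with folds
shared across candidates; the conservative `lambda.1se` rule is the
default (configurable to `lambda.min`). The winner is the candidate
with the highest **cross-validated** R² — in-sample R² would trivially
favor near-unpenalized ridge — and is then refit on the full training
cohort. Standardization and PCA statistics come from training only.
Validation reports Pearson r, R² = 1 − SS_res/SS_tot, and Lin's CCC
(population-moment form), side by side with a univariate OLS on the best
single training predictor; residual missing cells in the model matrix
(left by outlier masking) are imputed with training medians.

## Problem sizes and numerical tolerances

The analysis drivers use 150 synthetic subjects with 2 trial sets; the
test suite exercises the same stages at 30–200 subjects, 50-replicate
simulation blocks for the model-selection properties, and n = 1000–2000
Monte-Carlo blocks for the ICC and prediction-interval calibrations.
Algebraic identities are asserted to 1e-10 relative, analytic signal
oracles at their discretization error (1% for the jerk ramp, one
frequency bin for the centroid), and stochastic recoveries at their
Monte-Carlo standard error.

## Known limitations

* The generator's inverted-pendulum biomechanics are not faithful; only
  the statistical structure (effect ordering, spectra, reliability
  hierarchy) is emulated, and its healthy-volunteer age effect is
  deliberately mild.
* Directional (ML/AP) drift biomarkers are out of scope by design, as
  hand-held orientation cannot support them.
* ICC confidence intervals and ICC(3,k) variants are not implemented;
  the threshold is a point decision.
* With small validation arms (20% of 100–150 subjects) validation R²
  is itself noisy; comparisons between models at a single seed should
  be read accordingly.
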