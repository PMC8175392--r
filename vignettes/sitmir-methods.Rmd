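---
title: "Methods: from sitting patterns to extracellular-vesicle microRNA screening"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from sitting patterns to extracellular-vesicle microRNA screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sitmir)
```

## The scientific problem

Prolonged, uninterrupted sitting is associated with endothelial dysfunction
and cardiovascular-disease (CVD) risk, particularly in postmenopausal
overweight/obese women, but the molecular intermediates are largely unknown.
One candidate readout is the microRNA (miR) cargo of endothelial-cell-derived
extracellular vesicles (EC-EVs) circulating in plasma: EC miR expression
tracks endothelial state, and EV cargo is stable enough to serve as a
biomarker. `sitmir` implements an observational screening design that links
device-measured sitting *patterns* — not just total sitting time, but how
sitting accumulates into bouts — to differential expression of a CVD-focused
qPCR miR panel, with confounding handled by covariate-balancing propensity
weights.

The pipeline has two stages. A **screening** stage phenotypes a cohort into
extreme sitting-pattern groups, pools RNA across participants (3 per pool),
profiles a panel of 84 CVD-related miRs, and ranks them by a bootstrapped
standardized weighted effect. A **validation** stage re-measures the selected
candidates in individual samples from ethnicity-augmented groups and tests
them with bootstrap confidence intervals.

## Behavioral metrics

Minute-epoch accelerometer records (activity counts plus a posture label in
sit/stand/move/walk) are reduced per participant:

* **Non-wear** is detected with the Choi rule: any span of at least 90
  consecutive zero-count minutes is non-wear, where nonzero spikes of at most
  2 minutes are absorbed if flanked by at least 30 zeros on both sides. The
  90/2/30 parameters are exposed because the literature varies; these are the
  common defaults.
* A **sitting bout** is a maximal run of sit-labelled wear minutes — no
  minimum duration and no tolerance, and bouts never bridge non-wear gaps or
  midnight.
* **MVPA** is the count of wear minutes at or above 1952 counts per minute
  (inclusive threshold).
* A day is **adherent** with at least 10 h (600 min) of wear; a participant
  with at least 4 adherent days. Daily metrics are averaged over adherent
  days.

One genuinely open choice: the mean sitting bout duration could be the mean
of all bouts pooled across days, or a mean of daily means. We default to the
pooled mean — it is the literal arithmetic mean of bout durations — and
expose `bout_mean = "daily"` for the other reading; on synthetic data the two
differ by a few percent.

## Phenotyping and pooling

Quartiles of mean sitting bout duration and of MVPA are computed cohort-wide
(type-7 linear interpolation; ties go to the lower quartile, so a fully
degenerate variable lands everyone in quartile 1). *Interrupted Sitters* (IS)
are bout-Q1 and MVPA-Q1; *Super Sitters* (SS) are bout-Q4 and MVPA-Q1. For
validation, the groups are augmented with Hispanic participants from MVPA
quartile 2 in the respective extreme bout quartile (IS+/SS+), enlarging the
groups and the ethnic diversity available to an interaction analysis.

RNA pools hold 3 members each, drawn from distinct parent studies where
possible and at random otherwise. A group of size 2 mod 3 yields one pool of
2; size 1 mod 3 is not covered by the source design, and we default to one
pool of 4 (a single distorted pool) with two pools of 2 available by flag.

## Expression

qPCR cycle-threshold (Ct) values convert to relative expression by
`2^(-dCt)`, with dCt measured against the mean of the stage's control assays:
an array-control panel at screening, SNORD61 plus the cel-miR-39 spike-in at
validation. Pooling is simulated on the linear abundance scale — equal RNA
mass per member means the pooled abundance is the arithmetic mean of member
abundances, so pooled Ct is `-log2(mean(2^-Ct))`. Not-detected reactions are
treated as missing rather than imputed to a ceiling cycle; relative
expression is arbitrary-but-consistent in scale within a stage.

## Weighting

Confounding is addressed with inverse-probability-of-treatment weights from a
**just-identified covariate-balancing propensity score** (CBPS). The logistic
propensity coefficients solve the ATE balance moment conditions

$$\frac{1}{n}\sum_i \left[\frac{T_i}{\pi_\beta(x_i)} -
  \frac{1-T_i}{1-\pi_\beta(x_i)}\right] x_i = 0,$$

whose defining property is *exact* equality of weighted covariate means
between arms. We chose the just-identified variant (balance moments only,
rather than a GMM compromise with the likelihood score) because exact balance
is a crisp, testable property; the test suite asserts first-moment balance
below 1e-6 on every converged fit. The seven confounders are physical
functioning, MVPA, device wear days, device wear time, waist circumference,
BMI and age. Weights are stabilized by the marginal treated fraction and
Hajek-normalized to mean 1 within each arm (a pure rescaling that changes no
weighted mean). Balance is reported — not enforced — for squares and pairwise
interactions, plus a weighted Kolmogorov-Smirnov statistic per covariate.

Numerical details: covariates are standardized internally; the moment system
is solved by damped Newton iteration (step halving, max 200 iterations,
tolerance 1e-8 on the standardized moment residual) initialized at the
logistic MLE, with a gradient-based minimizer of the squared moment norm as a
polish step. In *small resamples* the exact-balance root need not exist at
all — with p covariates and few samples per arm, the arms' covariate hulls
may fail to intersect. Bootstrap refits therefore fall back to the
best-achievable balance (the moment-norm minimizer, the same estimand the
over-identified CBPS family targets) and are counted in `n_boot_inexact`;
only outright fit errors cause a resample to be redrawn, capped at 10% of
draws. The same hull problem affects the *point* fit at pool level (about a
dozen pools per arm against seven covariates), so the screening stage runs
`ate_bootstrap(..., balance = "best")` and reports the achieved moment
residual; the individual-level validation stage and the user-facing `cbps()`
always require the exact root.

Missing covariates (waist, physical functioning in practice) are completed by
single imputation with chained equations using predictive mean matching
(5 donors, 10 sweeps, seeded) — every imputed value is an observed value of
its variable. Pool-level covariates are the arithmetic means of member
covariates (median by flag); the source design does not state how pool
covariates were formed.

## Effect estimation and selection

Per miR, the ATE is the stabilized-weight difference of mean relative
expression, SS-side minus IS-side. Its SD comes from `B` stratified bootstrap
resamples (arm sizes preserved) with the **propensity model re-fit inside
every resample**, so design-estimation variability propagates into the SD.
The default CI is the normal approximation `ATE ± 1.96·SD`, which reproduces
the published validation bounds at printed precision for three of five
candidates; a percentile CI is available by flag (the remaining row is
consistent with percentile construction or unrounded inputs, and we do not
guess). Significance means zero strictly outside the 95% CI.

Screening selection is two-step: rank the panel by absolute standardized ATE
(ATE divided by its bootstrap SD), keep the top 10, then keep the 5 of those
with the largest *unweighted* SD. The second step removes candidates whose
standardized effect is inflated by an unusually small dispersion rather than
driven by a large effect. Ties (not expected with continuous data) break by
absolute ATE, then name, so the ranking is a total order.

Validation adds Pearson correlations among validated miRs (combined and per
group) and a weighted linear regression of expression on group, ethnicity and
their product with HC0 sandwich standard errors.

Enrichment of validated miR target genes against user-supplied GMT pathway
files uses the one-sided Fisher's exact test (hypergeometric upper tail) over
a user-supplied gene universe; the package bundles no pathway content because
published enrichment p-values depend on external database versions.

## The synthetic cohort generator

All real data for this design are unavailable, so the package carries a
first-class generator that emulates the study's data structure with known
ground truth:

* **Covariates** — age (truncated normal, minimum 55, population mean 65.9,
  SD 6.6), BMI (truncated at 25, mean 32.8, SD 5.0), waist circumference
  correlated with BMI, physical functioning in [0, 100], a Hispanic indicator
  (34%), three parent studies, and MCAR missingness on waist and physical
  functioning (3% default).
* **Latent sitting propensity** `z` — standard normal, partially driven by an
  age/BMI covariate score with path coefficient `confounding_strength`
  (default 0.2, sized so the extreme-quartile groups differ by roughly
  0.3-0.4 pooled SD on age and BMI, matching the contrast the design
  produces). Physical functioning declines with `z` with a coupling sized to
  an extreme-quartile gap of about 18 points (0.7 pooled SD).
* **Behavior** — each participant's mean sitting bout duration is
  `exp(log(39) + 0.45 z)` minutes, a lognormal centered near 39 min whose
  extreme quartiles average roughly 25 and 64 min; days are alternating
  renewal processes of sitting and non-sitting bouts inside a 14-16 h wear
  window (within-person bout spread is a lognormal `sdlog` of 0.75, an
  exposed knob because day-to-day variance is not pinned down by the design).
  Roughly 12% of days have short (< 10 h) wear so device wear days vary.
  Counts per posture class: sitting/standing 0-99 cpm, daily movement
  100-759, walking 760-1951, MVPA 1952-5000; per-person MVPA is lognormal
  with median 15.5 min/day so the lowest quartile sits below 7 min/day.
* **Expression** — per-miR log2 expression is a baseline plus
  `effect · z / 2.54` plus `confounding_strength ·` covariate score plus
  noise (SD 0.5 default). The divisor 2.54 is the expected gap
  `E[z | top quartile] − E[z | bottom quartile]` for a standard normal, so a
  configured effect of 1.0 equals the expected log2 expression difference
  between the extreme sitting-pattern groups. Ct values are a control
  baseline minus log2 expression; control assays have SD 0.15.

What the generator does **not** emulate: wet-lab EV isolation variability
beyond lognormal noise, amplification-efficiency differences, raw 30 Hz
accelerometry (labels are taken as given), posture misclassification, and
non-MCAR missingness. Passing tests on this generator show the *pipeline
arithmetic and its statistical calibration* are right under the stated data
structure — they cannot show that the posture classifier, the qPCR chemistry
or the confounder set of a real study behave as modelled.

A separate compact generator, `simulate_treatment_cohort()`, produces
covariates, a confounded binary exposure and an outcome with an exactly known
treatment effect; it is the calibration surface for bias-reduction and
CI-coverage checks, where the full cohort generator's group contrast is only
implicitly defined.

## Problem sizes used by the test suite

The packaged checks run screening on synthetic cohorts of 600 participants
and 5-7 device days (about 24 pools of 3, mirroring the source design's 24),
with B = 100-200 bootstrap resamples; planted-signal recovery uses 50
replicate cohorts with five miRs at +3 log2 units against noise SD 0.4, null
calibration 25 replicate cohorts, and weighting calibration 100 cohorts of
n = 120 with B = 200. These sizes were chosen to keep Monte-Carlo error well
inside the asserted bands.

## Known limitations

* The just-identified CBPS can fail on severely separated small samples; the
  error message suggests covariate reduction rather than silently trimming
  weights (weight trimming is deliberately not offered).
* The bootstrap SD treats pools as independent units; correlation induced by
  shared parent-study membership is ignored, as in the source design.
* Rank-based selection applies no multiple-testing correction across the
  panel; the validation stage is the error control.
* With heavy not-detected rates the pooled Ct and the ATE silently lose
  precision; the package reports inestimable records rather than imputing a
  detection ceiling.
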