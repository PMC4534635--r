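---
title: "Crowdsourced IHC scoring: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Crowdsourced IHC scoring: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crowdihc)
```

This vignette is the package's own account of the methods it
implements: what each model assumes, which parameters matter and why
their defaults are what they are, and where the design was genuinely
open and a choice had to be made.

## 1. The scoring model

Each tumor core is photographed, transformed (negation, HSL
saturation/hue modulate, 4×4 tiling with corners removed — see
`prepare_core_image()`) and shown to volunteers as 12 sub-image tiles.
A volunteer answers up to four questions per tile: cancer cells
present (yes/no); if yes, a cell-count bin (1–4), a proportion-staining
bin (0–5: 0%, <1%, 1–9%, 10–33%, 34–66%, 67–100%) and an intensity bin
(0–3: none, weak, moderate, strong). The per-reading **pseudo-Allred
score** is the proportion bin plus the intensity bin (0–8), mirroring
the clinical Allred system; a core with a score above 2 is called
ER-positive.

A reading that answers "no cancer" contributes **zero** (not a missing
value) to every ordinal question. This is deliberate: the interface
routes "no" answers away from the later questions, and treating the
absence as 0 is the only convention under which an all-negative
sub-image has a defined score at all.

## 2. User performance scores

Reliability weighting uses only the binary cancer-present question.
The algorithm (`iterate_to_convergence()`):

1. every volunteer starts at UPS 0.5; experts are fixed at 1;
2. a volunteer who scored expert-referenced sub-images moves to 0.7
   if they agreed with the expert, else stays at 0.5;
3. for every sub-image *without* an expert answer, the *modal
   classification* is the UPS-weighted mean of the binary answers
   (yes = 1), read as a pseudo-likelihood of cancer;
4. each volunteer is re-scored per sub-image — the modal value `m` if
   they said yes and `m > 0.5`; `1 − m` if they said no and
   `m < 0.5`; 0 on disagreement — and their UPS becomes the mean of
   these per-sub-image scores (expert sub-images enter with `m` fixed
   at the expert answer);
5. steps 3–4 repeat until the absolute change in the mean UPS is below
   `tol = 3e-4` (cap: 100 iterations, flagged if reached).

Open points the enumerated scheme leaves undefined, and the choices
made:

* **Several expert overlaps.** Promotion to 0.7 requires a *strict
  majority* of agreements — the simplest rule that is monotone in
  agreement and stays within the binary 0.5/0.7 scheme. Ties stay at
  0.5.
* **`m` exactly 0.5.** Neither step-4 branch applies; the per-image
  score is 0.5 regardless of the answer. An uninformative consensus
  should neither reward nor punish.
* **All weights zero on a sub-image.** The modal value falls back to
  the unweighted mean rather than 0/0.
* **Convergence metric.** "Change in average UPS" is read as
  `|mean(new) − mean(old)|`.
* **Preliminary agreement is frozen** after initialization; iteration
  only updates steps 3–4, as the enumerated order implies.

Every UPS stays in [0, 1] by construction. A consequence worth knowing:
a volunteer who scores one or two sub-images and happens to disagree
with a confident consensus ends at UPS 0 — in live deployments a
non-trivial share of casual scorers land there, and the test suite
reproduces this behavior.

## 3. Aggregation

All medians are **lower medians** (the ⌈n/2⌉-th order statistic), so
every aggregate remains an attained value on its original integer
scale; `weighted_median()` generalises this as the smallest value whose
cumulative weight reaches half the total, and reduces exactly to the
lower median under equal weights (property-tested).

Sub-image consensus comes in three variants: plain medians,
UPS-weighted medians, and plain medians after excluding volunteers with
fewer than five scored sub-images (falling back to the plain median
when no reading survives the filter — dropping the sub-image would
silently shrink cores). The per-core **cell-count score** is the sum of
the sub-image median count bins (0–48 for 12 tiles, up to 64 for 16);
the per-core **pseudo-Allred** is the weighted median of the sub-image
median pseudo-Allred scores with the median cell counts as weights, so
tiles with no visible tumor carry no weight. If every tile has median
count 0 the core is scored 0 / ER-negative. The cancer-present call
uses a cell-count threshold of 10 by default (the maximum-accuracy
operating point; 1 is the most sensitive setting and is exercised in
the tests).

## 4. Accuracy evaluation

`roc_auc()` computes the Mann–Whitney AUC from mid-ranks (ties count
1/2) and a curve evaluated at midpoints between distinct scores, so
trapezoidal integration of the curve equals the rank AUC to machine
precision (asserted at 1e−12). Intervals use DeLong's placement
variance by default with a seeded stratified bootstrap as an option —
the reference method is unstated in this literature, and DeLong is the
field default. Spearman correlation is mid-rank Pearson via
`stats::cor`; rates are kept at full precision internally and rounded
only for reporting.

## 5. Survival validation

The prognostic check treats the ER call as a covariate whose log
hazard ratio varies with follow-up time:

$$h_i(t) = h_{0s}(t)\,\exp\{x_i'\gamma + \mathrm{er}_i(\beta_1 + \beta_2 t)\},$$

stratified by study (`s`), with age and indicator contrasts for stage
(II–IV vs I) and grade (2–3 vs 1). `HR(t) = exp(β₁ + β₂ t)` crosses 1
at `t* = −β₁/β₂` when β₁ < 0 < β₂; `crossing_time()` gives a
delta-method CI on the ratio by default (Fieller as option, useful when
β₂ is imprecise).

A note on the time scale: descriptions of this model family sometimes
say "linear in log time" while printing `exp(β₁ + β₂ t)` and crossing
times equal to −β₁/β₂ — which are only mutually consistent when the
effect is linear in *t*. The package defaults to linear-in-t, which
reproduces that arithmetic, and offers `time_transform = "log"` as an
explicit option.

Numerical choices in `cox_tvc_fit()`:

* **Breslow ties.** Event times are continuous in the generator, so
  ties are rare; Breslow is the simplest consistent choice.
* **Newton–Raphson from a zero start with step halving**; convergence
  on the relative log-likelihood change (1e−9, the convention of
  standard Cox implementations) with a coarse gradient guard.
  Continuous covariates are centered for conditioning; coefficients
  are invariant to this.
* **Risk-set sums by group.** Because the time-dependent column is
  `er·t`, risk-set sums factor into ER / non-ER running sums times
  `exp(β₁ + β₂ t)` terms; each Newton iteration is O(n·p²) without any
  per-risk-set rescan. The fitter matches `survival::coxph` exactly
  (tolerance 1e−6) both at β₂ = 0 against a standard fit and with the
  time-varying term against a `tt()` fit — `coxph` serves only as the
  independent oracle in tests, never as the implementation.
* **Degenerate inputs** (no events, a single distinct event time,
  missing covariates, separation/monotone likelihood) raise immediate,
  descriptive errors rather than returning unstable estimates.

Missing stage and grade are imputed by chained equations
(`impute_stage_grade()`): ordinal-logistic draws for each variable
given age, ER, study, the event indicator and the Nelson–Aalen
cumulative-hazard transform of follow-up time — the standard
survival-imputation convention, which avoids conditioning on raw time.
Parameter draws from the approximate posterior N(θ̂, V̂) make the
imputations proper; sparse resamples fall back to multinomial logistic
and finally to hot-deck draws. Default `m = 20` imputations; pooling
(`rubin_pool()`) uses the mean estimate, total variance
`W̄ + (1 + 1/m)B`, and Barnard–Rubin degrees of freedom (collapsing to
the single-fit result when all imputations agree).

## 6. What the generator emulates — and what it does not

`simulate_crowd()` / `simulate_cores()` / `simulate_classifications()`
encode the study conditions the analysis assumes:

* **Scores per user**: a discretized log-normal (`meanlog = log 6`,
  `sdlog = 1.251`), fitted so the median is 6 with 5th/95th
  percentiles near 1 and 47 — a long tail of casual scorers plus a few
  heavy contributors, without inventing further structure.
* **Scores per sub-image**: bimodal 5/20 mixture (60/40) under the
  default `by_subimage` assignment, matching the characteristic
  two-humped workload seen on live platforms. Because an exact
  per-user count and an exact per-sub-image mixture cannot both hold,
  the `by_user` mode (exactly `n_scores` sub-images per scorer, with a
  coverage top-up) is provided and is the mode under which the
  per-user count contract is tested.
* **Reliability**: `p_detect ~ Beta(7, 3)` (mean 0.7) for the binary
  question; ordinal answers are truth plus rounded Gaussian noise
  (sd ~ Gamma(2, 0.35)), clipped to each scale — a single-parameter
  corruption, monotone in reliability.
* **Cores**: 69% contain cancer; 76% of those are ER-positive; within
  a cancer-bearing core 25% of tiles are cancer-free (tumor cells are
  unevenly distributed), and staining truth is shared across a core's
  cancer-bearing tiles.
* **Survival**: exponential baseline (0.004/year, giving
  breast-cancer-like 15-year mortality once stage/grade multipliers
  are applied), stage/grade log hazard ratios of cohort-typical size,
  ER effect `β₁ = −1.41`, `β₂ = 0.21` by default; times drawn by
  inverse transform on the numerically integrated cumulative hazard;
  censoring is uniform loss to follow-up truncated at the 15-year
  administrative horizon. Missingness (7.8% stage, 9.3% grade) is
  masked *after* outcome generation, i.e. MCAR.

What it deliberately does **not** emulate: pixel-level image content
(image preparation is tested on synthetic rasters); scorer behavior
that drifts over time or responds to media-driven participation
spikes; correlated errors between volunteers (e.g. shared confusion on
particular stain patterns); per-image totals beyond the 5/20 mixture;
and real-cohort survival curves. Passing tests therefore demonstrate
that the *algorithms* are correct and that the pipeline recovers known
truth under realistic noise — not that a live crowd would achieve any
particular accuracy; real-data AUCs are not reproducible without the
original study images and records.

## 7. Problem sizes used by the tests and acceptance script

The property-based checks run at sizes chosen to give stable Monte
Carlo behavior on a single CPU: the UPS-discrimination check uses
1,000 scorers on ~2,000 sub-images; oracle cross-checks use 10,000
random weighted-median fixtures; parameter recovery refits 50
simulated cohorts of n = 5,000 (no missingness) and 50 cohorts of
n = 1,200 with 10% MCAR grade under m = 5 imputations. The acceptance
script simulates a 400-core / 800-scorer study and one 4,947-patient
cohort with m = 20 imputations. At these sizes the full suite runs in
a few minutes.

## 8. Known limitations

* The UPS model scores reliability on the binary question only; a
  volunteer could be reliable at detection yet biased on intensity, and
  that would go unmeasured (confusion-matrix models such as
  Dawid–Skene are out of scope by design).
* The weighted median is attained-value by construction; with very few
  readings it is a coarse estimator, and sub-images scored by a single
  volunteer simply echo that volunteer.
* The imputation model assumes missingness ignorable given the
  predictors; the generator's MCAR masking satisfies this trivially,
  so the bias checks validate the machinery, not robustness to MNAR.
* The exact ImageMagick call sequence behind the color transform used
  on live platforms is not standardised; `saturate_hue()` implements
  documented modulate semantics and exposes both percentages as
  parameters rather than asserting bit-exactness against any one tool.
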