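---
title: "Methods: two-device step-count agreement in free-living wear"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-device step-count agreement in free-living wear}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Research-grade accelerometers worn on the hip record activity counts and
steps in short fixed epochs (here 30 s); consumer wrist devices report hourly
step totals, transmitted opportunistically. When the same people wear both in
daily life, the two streams disagree for many reasons at once: the devices
are worn at different times of day, the wrist device is removed nightly to
charge, its step records can drop out while heart-rate sampling continues
(connectivity interruptions), and the step-detection hardware itself differs.
`stepconcord` separates those sources. It harmonizes wear time, builds two
analysis samples — same-date person-days (sample 1), in which wear-time
differences are *part of* the disagreement, and trimmed overlap-block
person-hours (sample 2), in which they are largely removed — and computes a
method-comparison suite over each.

## Wear-time harmonization

**Hip device.** 30 s epochs are reintegrated to one minute and nonwear is
detected with the Choi rule: a minute is nonwear when it lies in a run of at
least `window_min = 90` minutes of zero activity counts, where nonzero
"spikes" of up to `spike_tolerance_min = 2` consecutive minutes are tolerated
inside the run provided each is flanked by at least `flank_min = 30` zero
minutes on both sides. The source protocol cites the rule without parameters;
we use the published 90/2/30 defaults and expose all three. Processing then
removes a nightly block, leaving an 18 h daily possible-wear window; we take
the removed block as 00:00–06:00 (configurable), matching the stated
nightly-removal protocol without reproducing the original SAS code. Hip daily
wear time is worn minutes / 60 (fractional) inside the window — the standard
accelerometry convention — and steps in Choi-nonwear minutes are excluded
from totals (the alternative, counting them, is not what a nonwear filter is
for; this is a documented choice where the source is silent).

**Wrist device.** Two wear rules are printed by the protocol and they are
*not* identical; we implement both literally rather than harmonize. The
daily-accumulation rule counts an hour as worn with at least 2 heart-rate
samples **or at least 30** steps; the block-overlap rule requires **more than
30** steps, or 0–30 steps with at least 2 heart-rate samples. Hours with
missing step counts never enter overlap blocks but can count as daily wear
via heart rate. Missing is never conflated with zero anywhere in the
pipeline.

**Validity.** A valid day has ≥ 10 h wear; participants need ≥ 3 valid days
per device. Both thresholds are config keys.

## The two samples

Sample 1 inner-joins person-days on (participant, date) where both devices
were valid. Sample 2, within each midnight-to-midnight day of sample 1,
takes maximal runs of consecutive hours in which both devices satisfy their
block rules, discards runs shorter than 3 h, trims the first and last hour of
each surviving run (possibly partial hours), and treats each interior hour as
a unit. Participants with no interior hours at all are excluded (<3 h
overlap), as are participants outside Eastern time (the wrist device
re-stamps clock time when its wearer travels; the hip device does not, so
cross-timezone hours would be misaligned). The protocol also removed one
extreme person-hour without stating a criterion; we refuse to delete data
silently: hours with |difference| above a configurable threshold (default
10 000 steps) are *flagged*, and removed only when `outlier_remove = TRUE`.
Every removal at every stage lands in an exclusion ledger whose counts
reconcile exactly.

The scatter-section classifier partitions paired days by thresholds of 1000
and 30 000 steps/day on each axis. The source figure defines the six regions
only through counts; our reading is a disjoint partition with precedence:
both-outside-same-side (E), hip above 30 000 (A), wrist above 30 000 (D),
wrist below 1000 (B), hip below 1000 (F), closed central box (C). Values
exactly at a threshold fall in C. This geometry is an interpretation and is
configurable in one place.

## Agreement statistics

Let \(w_{ij}, h_{ij}\) be wrist and hip steps for unit \(j\) (day or hour) of
participant \(i\), \(d_{ij} = w_{ij} - h_{ij}\), and
\[
p_{ij} = 100\,\frac{w_{ij}-h_{ij}}{(w_{ij}+h_{ij})/2},
\]
the symmetric percent difference (defined 0 at \(w=h=0\); ±200 when exactly
one count is zero — the formula forces it, and we keep it).

* **ICC.** The protocol says only "random-effects model". We bracket the
  ambiguity: the default is one-way random effects, single measures,
  ICC(1,1), computed from ANOVA mean squares with the paired unit as the
  random subject and the two devices as ratings; the two-way random
  absolute-agreement form ICC(A,1) is computed alongside and both are
  reported. CIs use the F distribution (exact for one-way; McGraw–Wong
  Satterthwaite form for A,1). Which random effect the original analysis
  used (unit vs participant) is unstated; we document the unit convention.
* **Lin's CCC**, \( \rho_c = 2s_{wh} / (s_w^2 + s_h^2 + (\bar w - \bar
  h)^2)\) with \(n\)-divisor moments, pooled over all units — the
  "accounting for repeated observations" usage, justified by the source's
  own observation that it matched the ICC throughout. Fisher-z CI with
  Lin's variance.
* **Repeated-measures Bland–Altman.** Differences (and percent differences)
  are decomposed by one-way random-effects ANOVA into between-participant
  \(\sigma_b^2\) and within-participant \(\sigma_w^2\); limits of agreement
  are \(\bar d \pm 1.96\sqrt{\sigma_b^2+\sigma_w^2}\) on both scales. With
  one unit per participant this reduces *exactly* to the classical limits
  (asserted in tests); negative between-variance estimates are truncated at
  zero.
* **Tolerance bands.** Share of units with \(|p_{ij}| \le 15\) (lenient) and
  \(\le 5\) (strict).
* **Threshold concordance.** Participants' average daily steps per device
  are cross-classified at 3000/6000/8000/10 000 steps/day; percent
  concordance and Cohen's kappa with the Fleiss–Cohen–Everitt asymptotic CI.
  Degenerate margins leave kappa undefined (signalled) while concordance is
  still reported. A per-person-day variant is also emitted.
* **Adjusted regression and interactions.** Wrist steps on hip steps plus
  age, sex, cohort, BMI, height (and the wear-time difference in sample 1),
  with CR1 cluster-robust errors by participant and t reference with
  (clusters − 1) degrees of freedom; whether the original models used robust
  errors is unstated, so clustering is a flag. Interaction tests regress
  steps on device × moderator in a two-row-per-unit layout with the same
  error structure.

## The synthetic cohort

Because the motivating cohort's data are not public, every stage is
exercised on a generator with known ground truth. Per participant a personal
activity level \(p_i\) is log-normal (mean 1, log-SD 0.5); true steps in
hour \(h\) are negative-binomial with mean \(p_i \lambda_h\) and size 8.
Each device observes truth through independent multiplicative log-normal
noise with mean 1 (hip CV 0.30, wrist CV 0.45) and the wrist applies a step
ratio (default 0.95). Wear mechanics: hip off during sleep (22:00–06:00) and
in hour-aligned daytime removal bouts (Poisson 1.5/day, geometric whole-hour
durations, mean 90 min); wrist off nightly for charging (22:00–06:00) plus a
Poisson number of extra morning off-wrist hours (mean 1, giving realistic
day-to-day wear variation); wrist step counts go missing in geometric-length
interruption runs (marginal rate 0.08/h, mean run 3 h) while heart-rate
counts (always ≥ 2 when worn) persist.

Defaults were set once, against the published cohort descriptives: a flat
waking rate of 450 steps/h over 06:00–22:00 gives ≈ 7200 steps/day (the
cohort median was ≈ 7060), hip wear ≈ 14 h under the 18 h window with bouts
(reported 14.4) and wrist wear ≈ 15–16 h (reported 15.6). The daily-scale
mean difference (hip higher) and hourly-scale difference (near zero)
reported for the cohort imply inconsistent marginal ratios because wear
patterns differ; 0.95 is a documented middle-ground hourly ratio, and no
interruption frequency is published, so 0.08/3 h is an artifact choice
exposed in config.

Two generator choices are deliberate simplifications, made so the recovery
oracles are exact rather than approximate:

* **Flat waking profile.** Under the model, the percent difference
  \(200(r e_w - e_h)/(r e_w + e_h)\) does not involve true steps at all, and
  the absolute difference moments depend only on the first two moments of
  true steps. A flat profile makes those moments invariant to *which* waking
  hours survive block construction and trimming, so `expected_agreement()`
  is exact. Diurnal shape influences none of the agreement statistics under
  this noise model, so nothing scientific is lost.
* **Hour-aligned hip bouts.** Minute-level removal bouts would truncate hip
  totals in partially-worn hours, which still pass the steps>0 block rule
  and would contaminate matched hours by an analytically intractable amount.
  Hour-aligned bouts preserve everything the analysis cares about — wear-time
  differences, block splitting, Choi-detectable long gaps — while keeping
  matched interior hours clean.

`expected_agreement()` integrates the percent-difference moments over the
two log-normal noise terms on a deterministic Gaussian quantile grid
(a delta-method expansion is accurate only to second order and visibly
biased at CV 0.3, so quadrature replaces it; the second-order expansion
remains as a cross-check in tests), and returns the exact absolute-difference
moments \(E[D] = E[T](r-1)\),
\(\mathrm{Var}[D] = E[T^2](r^2c_w^2 + c_h^2 + (r-1)^2) - E[T]^2(r-1)^2\).

**What a green test does and does not establish.** The generator reproduces
the *structure* of free-living paired streams (wear asymmetry, charging
gaps, interruption runs, heavy-tailed counts) but not participant-specific
device bias (gait-driven), intra-hour wrist granularity, seasonal or
day-of-week behavior, or delayed step transmission. Pipeline correctness and
statistical calibration are established; the cohort's numerical results are
not reproducible from synthetic data and are not targeted.

## Numerical and degenerate-input conventions

Zero-variance inputs: ICC and CCC are undefined and signalled (warning +
`NA`), not silently 1; identical-pairs input gives exactly 1 with a
collapsed CI. Bland–Altman with identical differences collapses the limits
onto the mean. Kappa with a degenerate margin is `NA` with concordance still
reported. Percent difference at (0, 0) is 0 by convention. Section-boundary
ties go to the central box. Rank-deficient regression designs error naming
the collinear columns; inside `run_pipeline()` (where degenerate simulated
worlds can produce constant covariates legitimately) the regression
statistics are skipped with the reason recorded in the report details.
Negative variance-component estimates truncate at zero. All randomness flows
from a single integer seed; fixed seed implies byte-identical outputs.

## Known limitations

* The wrist 30-step boundary inconsistency (≥ 30 daily vs > 30 block) is
  reproduced, not resolved.
* ICC beyond the two ANOVA forms (e.g. mixed-effects with covariates) is out
  of scope, as are imputation of missing wrist hours and sleep/wake
  detection.
* The kappa CI is asymptotic; a participant-resampling bootstrap is the
  obvious extension and the asymptotic form's calibration at n = 100 is
  verified by simulation rather than assumed.
* Cross-midnight overlap blocks are intentionally not formed (blocks are
  within calendar days, as the design prescribes).
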