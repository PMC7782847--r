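---
title: "Simulating and analysing multi-item targeted memory reactivation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and analysing multi-item targeted memory reactivation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The scientific question

Targeted memory reactivation (TMR) presents learning-associated sounds during
non-REM sleep to bias which memories are consolidated. When one sound is
linked to several items (e.g., one "meow" for six cat images at six screen
locations), the per-item benefit of cueing discriminates between hypotheses
about reactivation capacity:

* **Parallel reactivation (PRH)** — every item linked to the cue is
  reactivated simultaneously; each item receives the full benefit
  $\Delta$ regardless of set size $k$.
* **Limited capacity, divided (LCH-divided)** — a fixed benefit budget is
  split evenly; each item receives $\Delta/k$.
* **Limited capacity, random subset** — each cue presentation reactivates one
  item sampled uniformly from the set. The probability that a given item is
  reactivated at least once over $n$ repetitions is $1-((k-1)/k)^n$, so the
  model predicts a positive correlation between cue repetitions and the set's
  mean benefit.
* **Limited capacity, biased subset** — one fixed item per set monopolises
  the benefit, predicting lower within-set agreement (ICC) of item benefits
  for cued than non-cued sets.
* **null** — cueing does nothing; all items drift by the forgetting rate.

`napcue` implements the complete workflow as testable code: the constrained
experimental design, a generative behavioural model for each hypothesis, the
swap-aware scoring, the statistical battery, and a synthetic single-channel
EEG arm with the cue-locked spindle and spectral analyses.

## The experimental design

The design (`build_design()`) follows the published structure: 24 multi-item
sets randomly partitioned per participant into 18 two-item and 6 six-item
sets, 18 usable one-item sets, 3 practice one-item sets, and one novel sound
never paired with items — 90 scored items and 43 distinct sounds (42 scored
+ novel). Items live on a disc of radius 540 px; every set receives six
candidate locations at least 400 px apart, of which 6, 2, or 1 become real
item locations; the rest are *phantoms* used only by the swap classifier.

Placement constraints are enforced by rejection sampling
(`sample_set_locations()`): at least 50 px from centre and border, within-set
candidates pairwise at least 400 px apart, and at least 41 px from the true
item locations of other sets. We enforce the 41-px rule against **true item
locations only**, not against other sets' phantom candidates: the within-set
rule pushes roughly five of each set's six candidates into the outer annulus
(radii about 340–490 px), and 270 mutually spaced points there would require
about 84% of hexagonal packing density — geometrically unreachable by any
sampler. The 90 true locations pose no such problem.

Learning blocks (`schedule_blocks()`) split the 90 items into six blocks of
15 with no two same-set items in one block; each six-item set spans all six
blocks and each two-item set occupies consecutive blocks. Cueing assignment
(`balance_cuing()`) picks half of the sets per size class by exhaustively
enumerating all half-splits and minimising the difference in pre-sleep
incorrect placements, with ties broken by swap counts, then absolute error,
then at random. The sleep cue sequence (`build_cue_sequence()`) is a
randomized-blocks schedule: each pass is a fresh permutation of the 21 cued
sounds plus the novel sound (cue duration 600 ms, inter-cue interval drawn
from 4.5/5/5.5 s), so repetition counts never differ by more than one at any
truncation point.

## The generative behavioural model

The hypotheses are published as qualitative predictions, not a generative
model, so the package fixes one (`reactivation_model_params()`):

* A placement is the true location plus isotropic Gaussian noise
  (`sigma_pre_px` = 45 px), except that
* with probability `p_guess` (0.1) the item was never consolidated and the
  placement is uniform on the disc, and
* with probability `p_confuse_per_alt` (0.07) **per other real item in the
  set** the participant retrieves a same-set neighbour's location instead (a
  within-set confusion). Confusions are what make swap rates grow with set
  size — uniform guesses cannot, because the six-candidate swap rule treats
  all set sizes identically by construction.
* Over sleep, the radial error of each item changes by its model-specific
  benefit, floored at zero, and the placement direction is re-randomised.
  Non-benefiting items drift outward by `forget_px` (5 px); the cueing
  benefit is `delta_px` (8 px).

Guessing is an **item property, not a trial property**: an item guessed
before sleep is guessed again after sleep with probability `p_guess_keep`
(0.8), and a known item is newly forgotten with probability `p_guess_new`
(default `0.3 * p_guess`), keeping the marginal guess rate roughly constant
across tests. Phase-independent guessing would create physically implausible
item histories (location known before sleep, random after, known again) whose
rare swap-surviving benefits of several hundred pixels would dominate the
benefit variance. With these defaults, simulated pre-sleep swap rates are
approximately 0.40 (six-item), 0.15 (two-item) and 0.08 (one-item) per item,
close to the reported means of 0.385, 0.175 and 0.1 — they are configuration,
not truth.

What the generator deliberately does **not** emulate: trial-by-trial learning
dynamics, set-size-dependent pre-sleep accuracy differences among unswapped
placements (confusions and guesses carry the entire size effect), distance
dependence of confusion probability, and any N2-versus-N3 timing effects.
Passing tests therefore show that the *analysis logic* discriminates the
hypotheses under a faithful noise model, not that real data would behave this
cleanly.

Cue repetitions vary per participant (rounded Gaussian, mean 11, SD 5.5,
clamped to 2–24 passes, final pass truncated at a random point), matching the
reported 11 ± 1 (SEM) repetitions per sound with range 1–24.

## Scoring

`score_dataset()` implements the two-error decomposition. A placement is a
**swap error** if it lies strictly closer to one of the set's other five
candidate locations than to the item's own location; exact ties are not
swaps (ties have measure zero for continuous coordinates). Because every set
carries six candidates, a pure guess is flagged at the same rate (~5/6)
whatever the real set size — removing the bias that would otherwise inflate
accuracy errors for small sets. **Accuracy error** is the Euclidean distance
in pixels, reported only for unswapped placements; the **lenient criterion**
counts placements strictly under 100 px (27.7 mm) as correct. The **sleep
benefit** is pre-error minus post-error (positive = improvement), computed
only for items unswapped in both phases so pre/post comparisons use the same
items.

## Statistics

* `rm_anova()` — one- or two-factor fully within-subject ANOVA by classical
  sums-of-squares partitioning, each effect tested against its own
  participant-interaction error term, partial $\eta^2$ as effect size, no
  sphericity correction (the study reports uncorrected integer degrees of
  freedom). Effects with numerically zero sums of squares report $F=0$,
  $p=1$. The test suite cross-checks it against `stats::aov()` error strata.
  Participants who lose every item of a cell to swap exclusion (rare,
  probability about $5\times10^{-5}$ per six-item cell) are dropped from
  that ANOVA with a warning.
* `tukey_hsd()` — studentized-range follow-ups fed by the ANOVA error term.
* `bic_bayes_factor()` — $BF_{01} = \exp((BIC_{alt}-BIC_{null})/2)$ with
  equal prior odds; the pipeline applies it to the nested cell-mean models
  with and without the cuing-by-size interaction.
* `regress_out_presleep()` — OLS of forgetting on pre-sleep error; adjusted
  score = residual + grand mean.
* `subsample_robustness()` — repeatedly keeps 50% of items per participant
  and set size, retains datasets whose pre-sleep set-size effect has
  $p \ge 0.5$, and re-runs the benefit ANOVA on each; reports significance
  rates, mean/median p, and bias-corrected Fisher–Pearson skewness of both
  p-value distributions. Within one cohort the subsample p-values are
  strongly dependent (they share the cohort's realised noise), so type-I
  calibration is only meaningful pooled across cohorts.
* `icc_with_permutation()` — one-way random-effects single-measure ICC
  (ICC(1,1)), compared between cued and non-cued sets against a permutation
  null that shuffles item-to-set assignment separately within each
  condition, with the add-one correction so $p > 0$ always. Because swap
  exclusion leaves sets incomplete, the unbalanced-ANOVA estimator (the
  $n_0$ group-size coefficient) is used and sets with fewer than two
  surviving benefits are dropped; the estimator variant is configurable in
  principle because the reliability literature admits several.
* `max_abs_z_outlier()` — within-set z-scores of benefits, the maximum
  absolute value per six-item set as an outlier statistic, cued versus
  non-cued compared by unpaired t-test.
* `repetition_benefit_correlation()` — Pearson correlation of
  per-participant mean benefit with mean cue repetitions, optionally after
  transforming repetitions through $1-((k-1)/k)^n$.
* `familiarity_covariate_analysis()` — set-level benefit on cuing, size, and
  their interaction with the training familiarity index (3 sound plays per
  positioning trial + 2 per exposure trial, summed over items) as covariate;
  Type II F-tests by model comparison.

The permutation default is $10^6$ shuffles to match the study's procedure;
`run_config()` uses $10^4$ by default so a full run stays interactive — the
seed contract is identical and the p-value changes only by Monte-Carlo
noise.

## The EEG arm

`synthesize_background()` produces a $1/f^{1.5}$ Gaussian noise bed (15 µV
RMS) plus a continuous 0.8 Hz slow oscillation (20 µV). Each cue evokes a
Hann-enveloped 2–6 Hz delta-theta burst whose amplitude grows linearly with
set size ($30 + 4k$ µV — K-complex-scale responses), and with probability
$0.2 + 0.05k$ a Hann-enveloped spindle (uniform 11–16 Hz, duration uniform
0.9–1.8 s, 25 µV). The duration range sits in the central part of reported
spindle durations and away from the detector's 0.5-s minimum, because a
Hann-ramped event's suprathreshold core is only ~60–70% of its nominal
extent.

The analysis (`analyze_eeg_cohort()` and the underlying operations) follows
the published recipe: epochs from −0.5 to +4 s around cue onset (the printed
epoch text contradicts the pre-cue baseline, so the window is interpreted to
start 500 ms *before* onset), mean-subtracted, short-time Fourier
spectrograms on a 0.25–25 Hz grid in 0.25 Hz steps (500-ms Hamming window,
87.5% overlap), percent power change against the 300-ms baseline starting
500 ms before onset. Power is averaged over trials per participant **before**
the percent-change conversion: a single-trial baseline is so noisy a
denominator that the ratio acquires a systematic positive bias (Jensen's
inequality), which at one point in development produced spurious
low-frequency clusters. Trial-level modulation is referenced to the
participant-mean baseline for the same reason. One-sample t-tests across
participants with Bonferroni correction at $p<0.001$ over the whole grid,
8-connected components as clusters. The pipeline then selects the largest
post-onset positive cluster below ~12 Hz (delta-theta) and the largest one
reaching above 11 Hz (sigma); small spurious clusters can survive the
correction — partly a residual of the deterministic slow oscillation whose
phase at cue onset lives on the 0.1-s ITI lattice — and are ignored by this
selection.

`detect_spindles()` filters to 11–16 Hz with a zero-phase FIR (order sized
from a transition width of `min(2, lo/2)` Hz so the passband is genuinely
flat — a short kernel attenuates band-edge spindles), computes a centred
200-ms moving RMS (shrinking windows at the edges), and thresholds at the
mean plus 1.5 SD of the artifact-free RMS trace; runs of 0.5–3 s become
events, with peak amplitude the larger of the highest peak and the absolute
lowest trough of the filtered trace. A bare 1.5·SD of the RMS trace (without
the mean) would sit *below* the trace mean and flag everything, so the
mean-referenced threshold is the operative reading; thresholding on the SD
of the filtered signal instead is available via `sd_basis = "signal"` and is
numerically almost identical.

Set-size modulation is estimated with
`Modulation ~ 1 + SetSize + (1 + SetSize | participant) + (1 | sound)`
(maximum likelihood, set size coded numerically with the novel sound as 0);
singular fits are simplified stepwise (drop the random slope, then the sound
intercept, then OLS) with the path recorded. The memory–physiology link uses
`Benefit ~ Modulation × SetSize + (Modulation | participant)`. Spindle
probability is the fraction of trials with a detected spindle ongoing at
each time point, baseline-subtracted; the per-trial binary response uses the
sigma cluster's timeframe, falling back to a canonical 0.9–1.45 s window
when no sigma cluster survives correction.

## Problem sizes and reproducibility

Orchestration (`run_experiment()`, `compare_hypotheses()`) derives all
per-stage seeds from one master seed through a counter-based scheme, so
identical configurations give identical outputs and any stage can be rerun
in isolation. The package's own validation suite uses these problem sizes,
chosen to make each check statistically decisive at desk scale: behavioural
hypothesis discrimination over 100 cohorts of 31 participants per model
(cohorts share a pool of four designs; behaviour is regenerated each time);
subsample type-I calibration pooled over 50 null cohorts (500 screened
datasets); ICC permutation uniformity over 500 replications in fast
permutation mode; EEG sign recovery over 10 cohorts of 16 participants with
3 cue passes at 256 Hz; detector precision/recall over ~140 injected
spindles in six 10-minute recordings; mixed-model CI coverage over 200
response-level simulations.

## Known limitations

* The generative model is deliberately minimal: benefits are radial-error
  decrements with re-randomised direction, so per-item benefit noise comes
  from guessing, confusion, and the floor at zero rather than from graded
  encoding-strength variation.
* Pre-sleep accuracy among unswapped items does not differ by set size in
  the generator, so the pre-sleep set-size accuracy effect reported for the
  human data is not reproduced — only the machinery that corrects for it is.
* The EEG bed is stationary and single-channel; sleep staging, artifacts,
  K-complex morphology and topography are out of scope, and the
  percent-change scale of the synthetic evoked responses is much larger
  than that of real recordings (the low-frequency noise floor is the
  denominator).
* Absolute ICC values under the generator are near zero (there is no
  set-level random effect); only the cued/non-cued *difference* carries
  signal, which is exactly what the permutation test targets.
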