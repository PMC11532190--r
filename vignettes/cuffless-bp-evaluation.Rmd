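---
title: "Evaluating cuffless blood-pressure tracking with ISO 81060-3-style statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating cuffless blood-pressure tracking with ISO 81060-3-style statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cufflessbp)
```

## The problem

Cuffless blood-pressure (BP) devices estimate pressure from surrogate
signals — most often pulse-wave analysis of a photoplethysmographic (PPG)
signal — and are calibrated once against a cuff reading. They therefore track
*changes* relative to the calibration value. Under resting conditions BP
barely moves, so almost any calibrated device looks accurate; the meaningful
question is whether the device follows genuine, physiologically induced BP
swings. The ISO 81060-3:2022 standard frames this with three statistical
requirements for continuous cuffless devices:

* **Accuracy** — pooled mean (SD) of paired device-minus-reference
  differences with |mean| ≤ 6 mmHg and SD ≤ 10 mmHg;
* **Stability** — the same statistic over a later wearing period (here a
  second-day session), with the original one-point calibration still in
  force;
* **Change** — over within-activity intervals with a minimum reference
  change (15 mmHg SBP, 10 mmHg DBP, 12 mmHg MAP), the error rate
  |Δdev − Δref| / |Δref| × 100 must satisfy 50th percentile ≤ 25% and
  85th percentile ≤ 50%.

`cufflessbp` implements the full evaluation pipeline around these statistics
for a three-activity laboratory protocol — isometric handgrip, mental
arithmetic stress, and cold pressor — together with a synthetic
protocol-cohort generator, so the entire pipeline is exercisable and testable
without access to any human recordings.

## Pipeline at a glance

```{r overview, eval = FALSE}
cohort <- simulate_cohort(n_subjects = 38, seed = 1)   # ~35 s
result <- run_pipeline(cohort, run_config(seed = 1))
print(result$report)
report_write(result, "audit")                          # traceable CSV/JSON
```

The stages are: artifact filtering and beat extraction from the reference
pressure waveform; 15-second segment aggregation; per-activity brachial
recalibration of the reference; subject-wise 3-fold cross-validated ridge
regression from PPG-style features to BP; a single one-point offset
calibration of the device estimates; and the agreement statistics.

## The synthetic cohort

### What it emulates

The generator reproduces the *study conditions* of a three-activity
laboratory protocol on healthy adults:

* **Protocol timeline.** Each activity session is one continuous recording:
  4-min rest, then the activity (handgrip 2 min × 3 with 2-min pauses;
  serial-subtraction stress 5 min; cold pressor 2 min), then 1-min recovery.
  A configurable subset of subjects (11 of 38 by default) repeats the
  handgrip session on a second day.
* **Baselines.** Supine baselines are drawn as SBP ~ N(119.3, 9.4) and
  DBP ~ N(72.6, 7.1) mmHg, matching the cohort summary the protocol is
  modelled on; baseline heart rate is N(65, 8) beats/min (not reported
  there; a typical resting value for healthy adults).
* **Activity responses.** Each activity adds a response ramp (linear 20-s
  onset/offset; the underlying kinetics are not reported, and 20 s is a
  typical pressor-response time scale) scaled by per-subject amplitudes.
  Handgrip raises SBP and DBP together (isometric exercise), mental stress
  predominantly SBP and HR, and the cold pressor produces the largest, fast
  SBP rise. The amplitude distributions are normal, truncated at zero, with
  IQRs taken from the protocol's within-subject change summaries and centres
  calibrated (once, by Monte-Carlo) so the cohort medians of within-subject
  segment change land at ~25.5 / 22.6 / 35.1 mmHg SBP for
  handgrip / mental stress / cold pressor (~41.3 mmHg over the whole day),
  with the matching DBP and HR summaries. Only these summary statistics are
  available, so the distributions are calibrated to them and to nothing
  else.
* **Beat-level noise.** Stationary AR(1) with coefficient 0.7 and marginal
  SD 3 mmHg for SBP (0.6 × that for DBP, 2 beats/min for HR). White noise
  would understate the run-to-run variability of real beat series;
  physiological BP variability is strongly autocorrelated.
* **Pulse waveform.** Each cycle is a parametric template: raised-cosine
  systolic upstroke over the first 30% of the cycle, exponential decay
  (rate constant 3) back to exactly the diastolic value. Waveform morphology
  is not part of the evaluated claims, so a simple documented template is
  used; its time-weighted mean sits at DBP + 0.347 × pulse pressure, close
  to the physiological one-third rule. Within each cycle the samples nearest
  the extrema are set to the exact true SBP/DBP, so sampled extrema equal
  the truth at any rate.
* **Brachial triplets.** Three (SBP, DBP) readings 1 min apart during each
  pre-activity rest, each the 30-s windowed mean of the true series plus
  reading noise (SD 2 mmHg, a typical oscillometric repeatability).
* **Device error model.** The device's BP sensing is corrupted by a fixed
  bias (0.3 / 0.04 / 0.8 mmHg for SBP/DBP/MAP), a per-subject random effect
  (SD 6 / 4.5 / 5.5 mmHg), per-segment white noise (SD 6 / 4.8 / 5.7 mmHg),
  an optional linear drift, and a +2 mmHg day-2 offset that exercises the
  Stability statistic. The SBP defaults pool to ≈ 8.7 mmHg, echoing the
  pooled accuracy SD the protocol is modelled on; they are defaults, not
  constants, and the one-point calibration removes the bias and most of the
  subject effect, so the pipeline's measured SD is smaller. PPG features are
  affine functions (rank 4, documented in `default_feature_map()`) of the
  corrupted segment state plus small feature noise, so a linear regressor
  can in principle recover BP.

### What it does not emulate

No optical PPG physics or volume-clamp servo behaviour, no arrhythmia or
peripheral-artery pathology, no proprietary device filtering, no posture or
motion effects, and no genuinely nonlinear BP-feature relationships. Passing
tests therefore demonstrate that the *statistical pipeline* is correct and
well-calibrated — they say nothing about how any physical device performs on
real signals. In particular, the linear feature model makes the regression
stage's recovery properties provable, but real PPG-BP relationships are
harder, so real-device error statistics will be worse than the synthetic
ones at matched noise levels.

## Beat processing

Cardiac cycles are half-open windows `[R_i, R_{i+1})` between consecutive
ECG R-peak times (boundary handling is a package choice; the trailing
partial cycle is dropped). Per cycle, SBP is the sample maximum, DBP the
minimum, and MAP the trapezoidal time-weighted mean — stable to < 0.1 mmHg
under doubling of the sampling rate. Heart rate is 60/RR.

Artifact masking has three rules with configurable defaults: flat-line runs
(|Δsample| < 10⁻³ mmHg for ≥ 0.5 s — finger-cuff self-calibration gaps),
physiologically impossible samples (outside 20–300 mmHg), and 1-s windows
whose high-frequency content (> 20 Hz, moving-average high-pass) exceeds 30%
of the window's variance. The named artifact classes come from the modelled
protocol; the thresholds are package defaults. Beats overlapping masked
samples fail quality.

Accepted beats are averaged over non-overlapping 15-s windows aligned to
session start. A window is missing when it has no accepted beat **or** fewer
than half its beats are accepted — a segment mean computed from a small
minority of cycles is not credible. A subject is excluded when strictly more
than 50% of their reference segments are missing; the removal unit (samples,
beats or segments) is not specified in the modelled protocol, and segments
are chosen because they are the analysis unit.

## Calibration

The reference waveform is recalibrated before each activity: the calibration
value is the mean of the last two of the three brachial readings, and the
offset `calibration value − mean accepted cycle maxima in the rest window`
is added to every sample. Only the systolic brachial value drives the shift;
DBP and MAP move by the same constant, which is the unavoidable consequence
of shifting the whole waveform.

The device is calibrated exactly once per subject: per parameter, the offset
`reference − device` over an anchor window, applied to all of that subject's
segments across sessions and days, and never recomputed (a second call is
rejected). The anchor is the last 60 s of the initial rest before the
handgrip session — the protocol says only "during the initial rest period",
and the last minute is the most settled part of it; the window is
configurable.

## The regression ensemble

Seven documented per-segment features (pulse amplitude, width at half
amplitude, rise time, decay time, maximum upstroke slope, a
reflection-index surrogate, and segment heart rate) feed one
ridge-regularized linear regression per fold and BP parameter. Subjects are
dealt into three folds (seeded shuffle, sizes differing by at most one);
member *m* trains on the two folds excluding fold *m*; targets are the
calibrated reference segment values. Ridge (per-observation penalty 10⁻³ on
a standardized design, intercept unpenalized) handles the deliberate
rank-deficiency of the feature map; the penalty is small enough that
noiseless linear cohorts are recovered to well under 0.5 mmHg held-out.

Two evaluation modes exist because the modelled procedure is ambiguous about
whether reported metrics use the final averaged ensemble (in-sample with
respect to folds) or held-out predictions:

* `"strict"` (default): each subject is predicted by the one member that
  never saw that subject — no test-time leakage;
* `"paper"`: the arithmetic mean of all three members predicts for
  everyone, reproducing the averaged-ensemble reading.

Strict is the default because averaged-ensemble evaluation is optimistic;
both are one flag apart and neither is asserted to be the original choice.

## Agreement statistics

* **Pair selection:** 22 valid pairs per subject (Accuracy; 38 × 22 = 836)
  and 44 per day-2 subject pooled over both days (Stability;
  11 × 44 = 484), drawn uniformly without replacement (whether repeats were
  allowed is unstated; without replacement is the conservative reading).
* **Accuracy/Stability:** pooled mean and sample SD (n−1 denominator
  throughout) of device − reference; bounds ≤ 6 (10) mmHg, inclusive.
* **Change:** candidate pairs are all ordered (start < end) window pairs
  within one activity session meeting the parameter's minimum reference
  change; a per-subject cap (default 200, seeded subsample) bounds the
  combinatorics since the original candidate rule is not recoverable. The
  error-rate formula |Δdev − Δref| / |Δref| × 100 follows the standard's
  change-requirement definition. Percentiles use linear interpolation
  between order statistics (R type 7); no method is stated in the standard.
* **Bland-Altman:** bias ± 1.96 SD limits of agreement over all valid day-1
  pairs; for plotting, differences beyond ±30 mmHg are drawn at the bound
  while statistics always use unclamped values.
* **ICC:** one-way random-effects ICC(1,1) on paired differences grouped by
  subject, via ANOVA variance components with the unbalanced-design average
  group size; negative estimates are reported as-is. The standard's
  ICC-to-sample-size table is not reproduced (the standard's text is not
  part of this package); pair counts are configuration inputs with the
  defaults above.

`criteria_report()` assembles the three statistics per parameter with
inclusive ≤ verdicts against the bounds.

## Numerical choices and problem sizes

* Default cohort sampling rate is 250 Hz (1000 Hz supported). The pulse
  template has no content near the Nyquist limit at 250 Hz: per-beat
  extrema are exact by construction and MAP agrees with dense sampling to
  < 0.1 mmHg, while a 38-subject cohort simulates in well under a minute.
* All timestamps are seconds from session start; windows are 0-based and
  half-open; the final partial window of a session is dropped.
* Every stochastic step (parameter draws, noise, pair selection, fold
  split, capping) is seeded from a single master seed; identical
  configuration and seed reproduce results bit-for-bit, with the RNG state
  restored afterwards.
* The test suite exercises the full 38-subject default cohort once and
  otherwise uses short two-activity protocols (4-min rests retained so
  calibration semantics are unchanged) at 125 Hz with 1–6 subjects; the
  kernel statistics (mean/SD, percentiles, ICC, per-beat MAP) are checked
  against independent brute-force oracles on 100 randomized instances each.

## Known limitations

* The feature-BP relationship is affine by construction; the pipeline's
  recovery guarantees do not transfer to nonlinear real-world devices.
* Day-2 stability is modelled as a single extra session with an additive
  offset, not a genuine 24-h ambulatory wear.
* The change-pair candidate set (and hence pair counts) is a package
  convention; published change-pair totals cannot be reproduced because the
  original candidate rule is unrecoverable.
* Manual artifact review is replaced by the automatic mask plus an optional
  caller-supplied mask override.
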