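---
title: "Methods: synthetic gait cohorts, feature validation and gait classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: synthetic gait cohorts, feature validation and gait classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## Scope

`imugait` implements an analysis pipeline for discriminating the gait of
patients shortly after total hip arthroplasty (THA) from healthy gait using
wearable-sensor joint kinematics: gait-cycle segmentation, extraction of a
spatio-temporal feature set (Set 1: stride length, stride time, cadence,
speed) and a joint-kinematic feature set (Set 2: left-minus-right symmetry
of sagittal hip ROM and of the flexion/extension peaks, plus three-plane
pelvis ROM), validation of these features against a paired reference
measurement (RMSE, MAE, Pearson r and r², range-of-motion error, coefficient
of multiple correlation, group t-tests), RBF-kernel SVM classification with
stratified cross-validation (accuracy, sensitivity, specificity, AUC), and
minimum-redundancy-maximum-relevance (MRMR) feature ranking. Because no
patient data ship with the package, a seeded synthetic cohort generator
provides ground-truth-known inputs for every stage.

## The synthetic cohort generator

The generator is first-class, tested code; its defaults define the study
conditions used throughout the test suite and the acceptance script.

**Waveform model.** Each sagittal hip angle is built per stride from a fixed
two-harmonic template `u(phi) = cos(2*pi*phi) + 0.3*cos(4*pi*phi + 0.8)`,
rescaled to `[0, 1]` and mapped affinely so that each stride's extension
peak (the waveform minimum; extension is negative by clinical convention)
and range of motion (ROM) take prescribed values. A harmonic template keeps
the waveform smooth and periodic while the per-stride extrema remain
directly controllable; it does not attempt to reproduce the detailed shape
of a physiological hip trajectory (double-bump stance profiles, swing-phase
asymmetries), which none of the downstream features depend on. Pelvis tilt
and obliquity oscillate at two cycles per stride, pelvis rotation and hip
ab-/adduction and axial rotation at one cycle per stride.

**Variability.** Two levels of Gaussian variability act on the amplitudes:
a subject-level random effect (`inter_subject_sd`, default 2 deg, drawn
independently per side and channel) and stride-to-stride jitter
(`intra_subject_sd`, default 1 deg). Independent per-side subject effects
matter: they give healthy subjects non-zero, subject-specific symmetry
values (SD about `sqrt(2) * inter_subject_sd`), without which the symmetry
features would separate the groups trivially. Stride time and stride length
likewise have a between-subject SD (defaults 0.07 s, 0.10 m — typical
between-subject spreads for adult overground walking) and a within-subject
stride-to-stride jitter (defaults 0.02 s, 0.02 m).

**Group effects.** Healthy subjects use a 40 deg sagittal hip ROM with a
-10 deg extension peak. For patients, the operated side (drawn uniformly
left/right, as side prevalence is not better known) loses
`delta_rom_operated` (default 8 deg) of ROM and `delta_extension_operated`
(default 5 deg) of its extension peak; stride length drops by 0.15 m and
stride time rises by 0.1 s; pelvis ROM changes per plane (defaults: tilt
3 to 4, obliquity 4 to 5, rotation 8 to 6 deg). Only the directions of these
deficits are established in the post-THA literature; the magnitudes are
package defaults, all configurable, chosen as mid-range clinically reported
early-rehabilitation deficits.

**Trajectories and events.** Foot and pelvis positions are constructed so
that coordinate-based event detection is exact by design: the
heel-minus-pelvis (toe-minus-pelvis) forward coordinate follows a
piecewise-cosine easing whose maxima fall exactly on the initial contacts
(minima on the terminal contacts, at 62% of the stride). The pelvis
advances with piecewise-constant velocity, covering exactly one drawn
stride length per left stride, so left stride lengths are recovered
near-exactly from heel positions at the detected contacts; right stride
lengths are implied by the shared pelvis trajectory and recorded in the
ground truth. Sampling is 60 Hz by default; trials last 30 s (about 25
retained cycles per subject, the same order as the per-subject cycle counts
a few minutes of overground walking yield).

**Paired reference channel.** A second "measurement system" per trial is
emulated as truth + static offset + white noise (defaults: offsets uniform
in ±12.5 deg, noise SD 0.3 deg). Offsets are drawn once *per angle
definition* and shared across the left/right channel pair
(`bilateral = TRUE`): static calibration offsets enter through the joint
angle definition, and this structure is exactly what makes left-minus-right
symmetry features robust to them. With independent per-channel offsets
(`bilateral = FALSE`, provided for sensitivity analyses) the extrema
symmetry features would inherit the full left-right offset difference —
they shift by exactly `offset_left - offset_right`, an identity the test
suite asserts — and no sub-degree validation regime could exist. ROM-based
features are invariant under either model.

**Static IMU records.** The boxed-sensor calibration procedure is simulated
directly: gyroscope samples are bias + noise; accelerometer samples are the
rotated gravity vector (9.81 m/s²) + bias + noise, i.e. they lie on a
sphere centred at the bias. Only static records are simulated; dynamic raw
IMU signals during walking (and hence orientation tracking) are out of
scope.

## Preprocessing choices

**Accelerometer bias** is the centre of a sphere fitted to the static
samples: an algebraic (Kåsa) linear least-squares fit with the radius
estimated jointly, followed by one Gauss-Newton step on the geometric
distance. Joint radius estimation lets the fitted radius act as a sanity
check against local gravity (`radius_minus_gravity` is reported). Sample
clouds that do not span at least four non-coplanar orientations make the
centre unidentifiable and are rejected (singular-value threshold `1e-8`
relative to the largest).

**Joint angles** come from the relative rotation (parent-inverse times
child) decomposed with an intrinsic Z–X–Y sequence
(flexion–abduction–rotation), the common lower-limb convention; Z–Y–X is
available. Inputs are scalar-first unit quaternions (tolerance `1e-6` on
the norm) or rotation matrices. Samples whose middle angle comes within
1 deg of ±90 deg are flagged as gimbal-proximal rather than silently
returned.

**Angle-channel smoothing.** Feature extraction applies a zero-lag
second-order Butterworth low-pass (two-pass filtering, reflective padding,
default cutoff 6 Hz — the standard choice for gait kinematics, more than
three times the highest harmonic the generator produces) before per-cycle
extrema are taken. Extrema are order statistics: with white measurement
noise of SD 0.3 deg at 60 Hz, the raw per-cycle maximum of a low-amplitude
pelvis channel is biased upward by most of a degree, while after the filter
the residual noise is small and smooth. Signal attenuation at stride
frequencies (about 0.9–1.8 Hz) is negligible. Set `smooth_cutoff_hz = NULL`
to disable.

## Segmentation and outlier rule

Initial contacts are local maxima of the heel-minus-pelvis forward
coordinate, terminal contacts local minima of the toe-minus-pelvis forward
coordinate, with a minimum peak separation of half the median inter-peak
interval (taller peak wins). This coordinate-based detector is
parameter-light and exact on the generated trajectories; it assumes
straight overground walking.

Cycles run from each initial contact to the next ipsilateral one and are
linearly resampled to 101 points (0–100% in 1% steps, endpoints preserved).
All channels are segmented on the *left* foot's contacts so that the left
and right hip cycles of one row are time-aligned to the same stride — a
prerequisite for the symmetry features. Set 1 values attach from the left
stride containing the cycle; cadence uses the step beginning at that
cycle's initial contact, and cycles without a contralateral contact are
dropped.

Cycles whose duration falls outside mean ± 2 SD of all cycle durations are
removed. The rule is read as two-sided (standard practice, even where a
one-sided wording might suggest otherwise); `rule = "upper"` gives the
one-sided variant. The bounds are computed once on the input — reapplying
the rule recomputes them on the survivors, so idempotence is not
guaranteed, and the tests document this.

## Validation statistics

RMSE and MAE are computed per subject over that subject's cycles and
aggregated across subjects as mean ± SD with a t-based 95% CI of the mean
(`mean ± t(0.975, n-1) * SD / sqrt(n)`). A t-based CI is a deliberate,
stated choice: published gait-validation tables rarely say how their CIs
were built, and reverse-engineering them is not attempted. Pearson r and r²
are pooled over all cycles.

The range-of-motion error (ROME) is the absolute ROM difference of a paired
cycle, offset-invariant by construction. Waveform agreement uses the
Kadaba-form within-condition coefficient of multiple correlation for P
waveforms of T points:

sqrt(1 − [Σₜ Σₚ (Yₚₜ − Ȳₜ)² / (T(P−1))] / [Σₜ Σₚ (Yₚₜ − Ȳ)² / (PT−1)])

Of the several CMC variants in the literature this is the within-condition
form appropriate for comparing two simultaneous measurements of one
movement. When the between-waveform scatter exceeds the overall scatter the
radicand is negative; the CMC is then reported as missing with a reason
code (`imaginary`), never clamped to zero, and all-constant input yields a
`zero_denominator` code. Note that a static offset between the two systems
*does* depress the CMC — unlike the ROM features — which is why pelvis
channels with small ROM can show low CMC under large offsets while their
ROME stays small.

Group differences use a two-sample t-test, pooled-variance by default
(Welch optional). Normality is checked with a chi-square goodness-of-fit
test against a fitted normal: Sturges bins over the sample range, tails
extended to ±∞, adjacent bins merged until every expected count is ≥ 5,
and df = bins − 3 for the two estimated parameters; fewer than 8
observations or zero variance yield a flagged non-result.

## Classification

The SVM uses a Gaussian RBF kernel with box constraint C = 1.7,
standardization, and 12-fold stratified cross-validation. Three points are
resolved by explicit design decisions:

- *Kernel scale "auto"* is defined as the median pairwise Euclidean
  distance between standardized training samples of the fold (the kernel
  is `exp(-||u-v||²/s²)`); a fixed scalar can be supplied instead, and the
  per-fold resolved scales are reported.
- *Standardization leakage*: means and SDs come from the training fold
  only and are applied to the validation fold.
- *Positive class* for sensitivity/specificity is `patient` (clinically
  conventional) and configurable; which class a published confusion matrix
  treats as positive is often ambiguous, so both views are obtainable.

Folds are per gait cycle by default — each cycle an independent case,
matching how per-cycle classifiers are commonly evaluated. This leaks
subject identity across folds (cycles of one subject appear on both sides
of a split), so a subject-grouped stratified mode
(`group_by_subject = TRUE`) is provided; per-cycle accuracies should be
read as within-population, not subject-generalization, estimates.

Validation predictions are pooled over folds into one confusion matrix;
accuracy, sensitivity and specificity follow the standard percent
definitions, with empty margins flagged undefined rather than forced to a
number. The AUC uses the Mann-Whitney rank statistic with average ranks for
ties, equivalent to trapezoidal ROC integration.

**MRMR** is the greedy mutual-information difference variant: select the
feature maximizing `I(f; label) − mean I(f; selected)`. Continuous features
are discretized by equal-frequency binning (10 bins) before plug-in MI
estimation; an F-statistic relevance variant would be an alternative, but
binned MI makes no linearity assumption, which matters here because the
patient symmetry features are bimodal (operated side left *or* right).
Zero-relevance features (constants collapse to a single bin) take the
trailing ranks deterministically in column order. Because a ROM deficit
necessarily moves the flexion peak too, the symmetry features are mutually
correlated and the greedy redundancy term spreads them down the ranking —
the same interplay published rankings show.

## Problem sizes and determinism

The test suite and the acceptance script run cohorts of 24 healthy + 20
patient subjects, 30 s trials at 60 Hz (about 1100 retained cycles per
cohort — the same order as published per-cycle case counts), 10 seeded
cohort replicates for the stochastic direction checks, and 100 Monte-Carlo
repetitions for calibration recovery; these sizes were chosen so the whole
suite completes in a few minutes on one CPU. Every stochastic stage is
seeded: a cohort is a pure function of (configuration, seed), subject seeds
derive from the master seed, and `run_pipeline()` writes byte-identical
CSV/JSON artifacts on reruns, with a manifest recording the configuration
hash and seed.

## What passing tests do and do not show

The generator emulates the statistical structure the analysis assumes —
periodic smooth kinematics, two variability levels, static inter-system
offsets, exact event geometry — not real post-THA gait. Passing tests
therefore demonstrate correctness of the computations and the offset
robustness of the feature design, and qualitative reproduction of effect
*directions* (the joint-kinematic set outclassifies spatio-temporal
features; hip ROM symmetry ranks highly when its deficit dominates). They
do not certify classifier accuracy on real patients: real data add
soft-tissue artefact, orientation-filter drift, turning strides, footwear
and walkway differences, and group confounds (age, BMI) that the synthetic
cohorts deliberately omit. Published accuracies from clinical cohorts are
likewise specific to those datasets and are not asserted by this package.

## Known limitations

- Straight steady-state walking only; no turning-stride exclusion logic.
- No raw dynamic IMU simulation or orientation tracking; joint-angle
  extraction is tested on synthetic orientation series instead.
- The reference-system emulation pairs channels intrinsically; pairing two
  systems with different cycle counts is not addressed.
- Per-cycle cross-validation leaks subject identity (see above).
- The chi-square normality check loses power below a few dozen samples and
  abstains below eight.
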