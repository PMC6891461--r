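# imugait

Wearable-sensor gait analysis for rehabilitation after total hip
arthroplasty (THA): can features computed from IMU-based hip and pelvis
kinematics separate post-THA gait from healthy gait?

Patients shortly after THA walk with a reduced sagittal hip range of motion
and a diminished extension peak on the operated side, shorter and slower
strides, and altered pelvis motion. `imugait` implements the full analysis
chain around that question:

- **Synthetic cohort generator** — seeded healthy and post-THA cohorts with
  configurable deficits, exact ground-truth gait events, paired
  "reference-system" channels (static offsets + noise, emulating a second
  measurement system such as optical motion capture), and static IMU
  calibration records. Every downstream stage is testable against known
  truth.
- **Sensor calibration** — gyroscope bias as sample means; accelerometer
  bias as the centre of a least-squares sphere (Kåsa fit + Gauss–Newton
  refinement) through static samples.
- **Joint kinematics** — Euler-angle decomposition (intrinsic Z–X–Y:
  flexion, abduction, rotation) of relative segment orientations given as
  quaternions or rotation matrices.
- **Segmentation** — coordinate-based initial/terminal contact detection
  (heel/toe-minus-pelvis forward extrema), stride parameters, 101-point
  gait-cycle normalization, and removal of cycles whose duration leaves
  mean ± 2 SD.
- **Features** — Set 1 (spatio-temporal): stride length, stride time,
  cadence = 60 / (time to the next contralateral contact), speed =
  stride length / stride time. Set 2 (joint-kinematic, per gait cycle):
  left-minus-right symmetry of sagittal hip ROM and of the flexion and
  extension peaks, and pelvis ROM in all three planes.
- **Validation statistics** — per-subject RMSE/MAE with t-based 95% CIs,
  pooled r and r², range-of-motion error, Kadaba-form coefficient of
  multiple correlation, pooled-variance t-tests with a chi-square
  normality check.
- **Classification** — Gaussian-RBF SVM (box constraint C = 1.7, automatic
  kernel scale, per-fold standardization) under 12-fold stratified
  cross-validation, pooled into

  ACC = (TP + TN) / (TP + TN + FP + FN) · 100%,
  SEN = TP / (TP + FN) · 100%,
  SPEC = TN / (TN + FP) · 100%,

  plus the rank-statistic AUC, and greedy minimum-redundancy-
  maximum-relevance (MRMR) feature ranking on binned mutual information.

A key design property, asserted exhaustively in the tests: all ROM-based
features are invariant to static per-channel calibration offsets, and the
extrema-symmetry features are invariant to offsets shared across the
left/right pair — which is why such features survive imperfect
sensor-to-segment calibration.

See the methods vignette (`vignettes/imugait-methods.Rmd`) for the models,
defaults and design decisions.

## Worked example

```r
library(imugait)

# a cohort of 24 healthy and 20 post-THA subjects at 60 Hz
cfg <- cohort_config(seed = 42)
cohort <- generate_cohort(cfg)
cohort[[30]]
#> <trial_recording> S30_patient (patient, operated right), 60 Hz, 30.0 s,
#>   9 angle channels, paired reference

# per-cycle features from the trials' own channels and from the paired
# offset-corrupted reference system
features <- build_feature_table(cohort, "truth")
features_ref <- build_feature_table(cohort, "reference")
nrow(features)
#> [1] 1077

# how well do the measured Set 2 features agree with the reference?
val <- validate_features(features, features_ref,
                         features = feature_set_columns("set2"))
round(as.data.frame(val)[, c("rmse_mean", "mae_mean", "r")], 3)
#>   rmse_mean mae_mean     r
#> 1     0.236    0.191 0.999
#> 2     0.168    0.134 0.999
#> 3     0.170    0.138 0.999
#> 4     0.204    0.173 0.995
#> 5     0.199    0.167 0.994
#> 6     0.176    0.143 0.990

# cross-validated RBF-SVM on each feature set
report1 <- train_and_crossvalidate(features, "set1", classifier_config(seed = 42))
report2 <- train_and_crossvalidate(features, "set2", classifier_config(seed = 42))
report1
#> <classifier_report> 1077 cycles, positive class 'patient'
#>   ACC 92.7%  SEN 89.9%  SPEC 94.8%  AUC 0.967
#>   confusion: TP 417  TN 581  FP 32  FN 47
report2
#> <classifier_report> 1077 cycles, positive class 'patient'
#>   ACC 99.9%  SEN 99.8%  SPEC 100.0%  AUC 1.000
#>   confusion: TP 463  TN 613  FP 0  FN 1

# which features drive the separation?
head(rank_features_mrmr(features), 4)
#>   rank              feature         score relevance
#> 1    1   hip_maxext_sym_deg  0.4569819352 0.4569819
#> 2    2      stride_length_m  0.0389171942 0.4097943
#> 3    3   pelvis_sag_rom_deg -0.0341405059 0.2247838
#> 4    4 pelvis_trans_rom_deg  0.0003314429 0.2207937
```

Reading the output: all six Set 2 features agree with the reference system
to well under a degree despite static offsets up to 12.5° — the offsets
cancel in ROM and symmetry features, leaving only the noise floor. The
joint-kinematic set separates the groups more cleanly (99.9%) than the
spatio-temporal set (92.7%), because symmetry features expose the
operated-side deficit directly, regardless of which side was operated,
while stride parameters overlap between slow healthy walkers and patients.
The MRMR ranking puts a hip symmetry feature first, followed by a
spatio-temporal and pelvis features — correlated runner-up symmetry
features are pushed down by the redundancy term.

`run_pipeline(cfg, classifier_config(), "out/")` executes the whole chain
(simulation → features for both channel sources → validation →
correlations → four classifier reports → MRMR ranking) and writes
CSV/JSON artifacts plus a manifest; reruns with the same configuration and
seed are byte-identical.

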