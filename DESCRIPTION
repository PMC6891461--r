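Package: imugait
Title: Simulation, Validation and Classification of Inertial-Sensor Gait
    Kinematics After Total Hip Arthroplasty
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: An end-to-end pipeline for wearable-sensor gait analysis in
    rehabilitation after total hip arthroplasty (THA): a seeded synthetic
    generator for healthy and post-THA gait cohorts (joint-angle waveforms,
    foot and pelvis trajectories, paired offset-corrupted reference channels
    and static IMU calibration records); gyroscope and accelerometer bias
    estimation (sample means and least-squares sphere fitting); Euler-angle
    joint kinematics from segment orientations; coordinate-based gait event
    detection, stride-parameter computation and gait-cycle normalization with
    duration-based outlier removal; spatio-temporal (Set 1) and
    joint-kinematic (Set 2) feature extraction; waveform and feature
    validation statistics against a paired reference system (RMSE, MAE,
    Pearson r, range-of-motion error, coefficient of multiple correlation,
    group t-tests with a chi-square normality check); RBF-kernel
    support-vector classification of impaired versus non-impaired gait with
    stratified cross-validation (accuracy, sensitivity, specificity, AUC);
    and minimum-redundancy-maximum-relevance feature ranking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    e1071,
    jsonlite,
    signal,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
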