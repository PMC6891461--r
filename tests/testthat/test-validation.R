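test_that("paired error statistics follow the defining formulas", {
  # identity: zero errors, perfect correlation
  a <- c(1, 2, 3, 4)
  st <- paired_error_stats(a, a, subject = c("s1", "s1", "s2", "s2"))
  expect_equal(st$rmse_mean, 0)
  expect_equal(st$mae_mean, 0)
  expect_equal(st$r_squared, 1)

  # direct formula on one subject: a = (0,0), b = (3,4)
  st2 <- paired_error_stats(c(0, 0), c(3, 4), subject = c("s1", "s1"))
  expect_equal(st2$rmse_mean, sqrt(12.5), tolerance = 1e-12)
  expect_equal(st2$mae_mean, 3.5, tolerance = 1e-12)
  expect_false(st2$ci_defined)
  expect_true(all(is.na(st2$rmse_ci)))
})

test_that("paired error statistics match a per-subject loop oracle", {
  set.seed(55)
  subj <- rep(sprintf("s%02d", 1:8), each = 12)
  a <- stats::rnorm(96, 10, 3)
  b <- a + stats::rnorm(96, 0.5, 1)
  st <- paired_error_stats(a, b, subj)
  rmse_o <- mae_o <- numeric(8)
  for (i in 1:8) {
    ix <- which(subj == sprintf("s%02d", i))
    rmse_o[i] <- oracle_rmse(a[ix], b[ix])
    mae_o[i] <- oracle_mae(a[ix], b[ix])
  }
  expect_equal(sort(st$per_subject$rmse), sort(rmse_o), tolerance = 1e-12)
  expect_equal(st$rmse_mean, mean(rmse_o), tolerance = 1e-12)
  expect_equal(st$rmse_sd, stats::sd(rmse_o), tolerance = 1e-12)
  half <- stats::qt(0.975, 7) * stats::sd(rmse_o) / sqrt(8)
  expect_equal(st$rmse_ci, mean(rmse_o) + c(-half, half), tolerance = 1e-12)
  expect_equal(st$mae_mean, mean(mae_o), tolerance = 1e-12)
  expect_equal(st$r, oracle_pearson(a, b), tolerance = 1e-12)
  expect_equal(st$r_squared, st$r^2, tolerance = 1e-12)
  # RMSE >= MAE >= 0 per subject
  expect_true(all(st$per_subject$rmse >= st$per_subject$mae))
  expect_true(all(st$per_subject$mae >= 0))
})

test_that("range-of-motion error follows offset and scaling algebra", {
  phi <- seq(0, 1, length.out = 101)
  a <- -10 + 40 * (1 + cos(2 * pi * phi)) / 2
  expect_equal(rome(a, a), 0)
  expect_equal(rome(a, a + 7), 0, tolerance = 1e-12)
  expect_equal(rome(a, 1.1 * a), 4, tolerance = 1e-12)   # ROM 40 vs 44
  expect_error(rome(a, a[1:50]), "101")
})

test_that("CMC matches the direct Kadaba formula and flags undefined cases", {
  y1 <- c(0, 1, 2)
  y2 <- y1 + 0.1
  Y <- rbind(y1, y2)
  expect_equal(as.numeric(cmc(Y)), oracle_cmc(Y), tolerance = 1e-12)

  phi <- seq(0, 1, length.out = 101)
  w <- sin(2 * pi * phi)
  expect_equal(as.numeric(cmc(rbind(w, w))), 1, tolerance = 1e-12)

  flat <- cmc(rbind(rep(2, 10), rep(2, 10)))
  expect_true(is.na(flat))
  expect_identical(attr(flat, "reason"), "zero_denominator")

  # independent white noise: undefined or near zero over repeated draws
  set.seed(77)
  vals <- replicate(50, {
    v <- cmc(rbind(stats::rnorm(101), stats::rnorm(101)))
    if (is.na(v)) NA_real_ else as.numeric(v)
  })
  expect_true(mean(is.na(vals)) > 0.3)
  expect_lt(stats::median(vals, na.rm = TRUE), 0.6)

  # random waveform sets match the loop oracle
  for (i in 1:20) {
    Yr <- matrix(stats::rnorm(5 * 31, sd = 2), 5, 31) +
      matrix(rep(sin(seq(0, 2 * pi, length.out = 31)) * 10, each = 5), 5, 31)
    expect_equal(as.numeric(cmc(Yr)), oracle_cmc(Yr), tolerance = 1e-12)
  }
})

test_that("CMC is invariant to a common constant but penalized by a one-waveform shift", {
  phi <- seq(0, 1, length.out = 101)
  a <- sin(2 * pi * phi) * 10
  b <- a + stats::rnorm(101, 0, 0.5)
  base <- as.numeric(cmc(rbind(a, b)))
  common <- as.numeric(cmc(rbind(a + 25, b + 25)))
  expect_equal(common, base, tolerance = 1e-9)
  shifted <- cmc(rbind(a, b + 5))
  expect_true(is.na(shifted) || as.numeric(shifted) < base)
})

test_that("group comparison reproduces the pooled t-test and handles degenerate input", {
  x <- c(1.2, 3.4, 2.2, 5.1, 0.7, 2.9)
  y <- c(2.0, 4.1, 3.3, 6.0, 1.9)
  gt <- compare_groups(x, y)
  expect_equal(gt$t, oracle_t_pooled(x, y), tolerance = 1e-12)
  expect_equal(gt$p_value, stats::t.test(x, y, var.equal = TRUE)$p.value,
               tolerance = 1e-12)

  same <- compare_groups(rep(2, 5), rep(2, 4))
  expect_equal(same$t, 0)
  expect_equal(same$p_value, 1)

  w <- compare_groups(x, y, var_equal = FALSE)
  expect_equal(w$p_value, stats::t.test(x, y)$p.value, tolerance = 1e-12)
})

test_that("t-test rejection rate matches its theoretical power", {
  # effect = 0.5 SD, n = 50 per group
  pw <- stats::power.t.test(n = 50, delta = 0.5, sd = 1, sig.level = 0.05)$power
  set.seed(101)
  rej <- mean(replicate(400, {
    compare_groups(stats::rnorm(50), stats::rnorm(50, 0.5))$p_value < 0.05
  }))
  expect_equal(rej, pw, tolerance = 0.12)
})

test_that("chi-square normality check separates normal from bimodal samples", {
  set.seed(9)
  hits_norm <- mean(replicate(30, {
    imugait:::chisq_normality(stats::rnorm(300))$normal
  }))
  expect_gt(hits_norm, 0.7)   # ~1 - alpha acceptance for true normals
  bimodal <- c(stats::rnorm(200, -3, 0.5), stats::rnorm(200, 3, 0.5))
  expect_false(imugait:::chisq_normality(bimodal)$normal)
})

test_that("error statistics vanish continuously as reference corruption goes to zero", {
  cfg0 <- noiseless_config()
  tr <- generate_subject(cfg0, "healthy", subject_seed = 3)
  rmse_at <- vapply(c(0.5, 0.1, 0), function(ns) {
    co <- list(add_reference_channel(tr, offset_range = 5, noise_sd = ns, seed = 2))
    tab_t <- build_feature_table(co, "truth")
    tab_r <- build_feature_table(co, "reference")
    validate_features(tab_t, tab_r)$rmse_mean |> max()
  }, numeric(1))
  expect_true(all(diff(rmse_at) <= 1e-9))
  expect_equal(rmse_at[3], 0, tolerance = 1e-9)
})

test_that("waveform validation: small ROME throughout; static offsets depress CMC", {
  chans <- c("hip_flexion_l", "pelvis_rotation")
  cfg0 <- cohort_config(n_healthy = 2, n_patient = 2, trial_duration = 15,
                        ref_offset_range = 0, ref_noise_sd = 0.2, seed = 3)
  wf0 <- validate_waveforms(generate_cohort(cfg0), channels = chans)
  expect_identical(nrow(wf0), 2L)
  expect_true(all(wf0$rome_mean < 1))
  expect_true(all(wf0$cmc_mean > 0.98))  # offset-free pairs are near-identical

  cfg1 <- cohort_config(n_healthy = 2, n_patient = 2, trial_duration = 15,
                        ref_offset_range = 8, ref_noise_sd = 0.2, seed = 3)
  wf1 <- validate_waveforms(generate_cohort(cfg1), channels = chans)
  # ROM is offset-invariant, so ROME stays small even under 8 deg offsets
  expect_true(all(wf1$rome_mean < 1))
  # a static offset on one waveform of the pair strictly lowers the CMC
  expect_true(all(wf1$cmc_mean < wf0$cmc_mean | is.na(wf1$cmc_mean)))
})
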