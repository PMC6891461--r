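test_that("events are recovered within one sample on noiseless trials", {
  cfg <- cohort_config(n_healthy = 1, n_patient = 1, trial_duration = 20, seed = 4)
  co <- generate_cohort(cfg, reference_channels = FALSE)
  for (tr in co) {
    ev <- detect_gait_events(tr)
    tol <- 1 / tr$fs + 1e-9
    for (pair in list(c("ic_left", "ic_left"), c("ic_right", "ic_right"),
                      c("tc_left", "tc_left"), c("tc_right", "tc_right"))) {
      det <- ev[[pair[1]]]
      tru <- tr$truth[[pair[2]]]
      expect_true(all(vapply(det, function(x) min(abs(x - tru)), numeric(1)) <= tol))
      interior <- tru[tru > 0.3 & tru < cfg$trial_duration - 0.3]
      expect_true(all(vapply(interior, function(x) min(abs(x - det)), numeric(1)) <= tol))
    }
  }
})

test_that("constant trajectories yield no events", {
  flat <- cbind(rep(1, 200), 0, 0)
  pel <- cbind(rep(0, 200), 0, 0)
  expect_warning(ic <- detect_initial_contacts(flat, pel, 60), "fewer than 2")
  expect_length(ic, 0L)
  expect_warning(tc <- detect_terminal_contacts(flat, pel, 60), "fewer than 2")
  expect_length(tc, 0L)
})

test_that("event counts and ordering are consistent on full trials", {
  tr <- generate_subject(cohort_config(trial_duration = 25, seed = 9), "healthy", 17)
  ev <- detect_gait_events(tr)
  expect_true(length(ev$tc_left) %in% (length(ev$ic_left) + c(-1L, 0L, 1L)))
  # alternating IC/TC per foot
  merged <- sort(c(ev$ic_left, ev$tc_left))
  kinds <- c(rep("ic", length(ev$ic_left)), rep("tc", length(ev$tc_left)))
  kinds <- kinds[order(c(ev$ic_left, ev$tc_left))]
  expect_true(all(kinds[-1] != kinds[-length(kinds)]))
})

test_that("time-shifting the trajectories shifts the events equally", {
  tr <- generate_subject(cohort_config(trial_duration = 20, seed = 2), "healthy", 3)
  shift <- 120L  # 2 s at 60 Hz
  ev1 <- detect_initial_contacts(tr$positions$heel_l, tr$positions$pelvis, tr$fs)
  ev2 <- detect_initial_contacts(tr$positions$heel_l[-(1:shift), ],
                                 tr$positions$pelvis[-(1:shift), ], tr$fs)
  shifted <- ev1[ev1 > shift / tr$fs + 0.3] - shift / tr$fs
  matched <- vapply(shifted, function(x) min(abs(x - ev2)), numeric(1))
  expect_true(all(matched < 1e-9))
})

test_that("stride parameters follow their defining formulas", {
  # worked example: ICs 0.0 and 1.2 s, heels 1.32 m apart, contralateral IC 0.6 s
  fs <- 10
  tt <- seq(0, 1.2, by = 1 / fs)
  heel_l <- cbind(seq(0, 1.32, length.out = length(tt)), 0, 0)
  heel_r <- cbind(seq(0.5, 1.5, length.out = length(tt)), 0, 0)
  ev <- gait_events(ic_left = c(0, 1.2), ic_right = c(0.6, 1.15))
  stp <- compute_stride_parameters(ev, heel_l, heel_r, fs)
  left <- stp[stp$side == "left", ]
  expect_equal(left$stride_length, 1.32, tolerance = 1e-12)
  expect_equal(left$stride_time, 1.2, tolerance = 1e-12)
  expect_equal(left$speed, 1.1, tolerance = 1e-12)
  expect_equal(left$cadence, 100, tolerance = 1e-12)

  # zero displacement is flagged implausible
  ev2 <- gait_events(ic_left = c(0, 1.0), ic_right = c(0.5, 0.9))
  still <- cbind(rep(1, length(tt)), 0, 0)
  stp2 <- compute_stride_parameters(ev2, still, still, fs)
  expect_identical(stp2$flag[stp2$side == "left"], "implausible_length")
  expect_equal(stp2$stride_length[stp2$side == "left"], 0)

  expect_error(compute_stride_parameters(gait_events(ic_left = 0.5, ic_right = 1),
                                         heel_l, heel_r, fs),
               "at least 2")
})

test_that("speed equals stride length over stride time for every stride", {
  tr <- generate_subject(cohort_config(trial_duration = 20, seed = 6), "patient", 8)
  ev <- detect_gait_events(tr)
  stp <- compute_stride_parameters(ev, tr$positions$heel_l, tr$positions$heel_r, tr$fs)
  expect_equal(stp$speed, stp$stride_length / stp$stride_time, tolerance = 1e-12)
})

test_that("noiseless cohort recovers the configured stride parameters near-exactly", {
  cfg <- noiseless_config()
  co <- generate_cohort(cfg, reference_channels = FALSE)
  for (tr in co) {
    ev <- detect_gait_events(tr)
    stp <- compute_stride_parameters(ev, tr$positions$heel_l, tr$positions$heel_r, tr$fs)
    left <- stp[stp$side == "left", ]
    g <- tr$group
    expect_equal(mean(left$stride_time), cfg$stride_time_mean[[g]], tolerance = 1e-6)
    expect_equal(mean(left$stride_length), cfg$stride_length_mean[[g]], tolerance = 1e-6)
    expect_equal(mean(left$speed),
                 cfg$stride_length_mean[[g]] / cfg$stride_time_mean[[g]],
                 tolerance = 1e-6)
  }
})

test_that("cycles are resampled to 101 points with endpoint-preserving interpolation", {
  fs <- 60
  x <- stats::rnorm(601)
  ic <- (seq(0, 600, by = 60))[1:6] / fs
  cyc <- segment_gait_cycles(x, ic, fs)
  expect_length(cyc, 5L)
  expect_true(all(vapply(cyc, function(c) length(c$values), integer(1)) == 101L))
  expect_equal(vapply(cyc, function(c) c$duration, numeric(1)), rep(1, 5))

  ramp <- seq(0, 10, length.out = 601)
  rcyc <- segment_gait_cycles(ramp, c(0, 5), fs)[[1]]
  expect_equal(rcyc$values, seq(ramp[1], ramp[301], length.out = 101), tolerance = 1e-12)

  tt <- (0:600) / fs
  sine <- sin(2 * pi * tt / 1.2)
  scyc <- segment_gait_cycles(sine, seq(0, 8.4, by = 1.2), fs)
  for (c2 in scyc[-1]) expect_equal(c2$values, scyc[[1]]$values, tolerance = 1e-9)

  expect_error(segment_gait_cycles(x, c(0, 20), fs), "outside")
  expect_error(segment_gait_cycles(x, 1, fs), "at least 2")
})

test_that("cycle count equals IC count minus one before outlier removal", {
  tr <- generate_subject(cohort_config(trial_duration = 18, seed = 12), "healthy", 2)
  ev <- detect_gait_events(tr)
  cyc <- segment_gait_cycles(tr$channels$hip_flexion_l, ev$ic_left, tr$fs)
  expect_length(cyc, length(ev$ic_left) - 1L)
})

test_that("duration outlier rule removes cycles outside mean +/- 2 SD", {
  # arithmetic oracle: durations 1.0 x 9 and 2.0 -> mean 1.1, sd 0.3162,
  # upper bound 1.732, so exactly the 2.0 s cycle is removed
  cyc <- fake_cycles(c(rep(1, 9), 2))
  kept <- remove_outlier_cycles(cyc)
  expect_length(kept, 9L)
  expect_identical(attr(kept, "removed"), 10L)
  expect_equal(attr(kept, "bounds")[["upper"]], 1.1 + 2 * stats::sd(c(rep(1, 9), 2)))

  same <- remove_outlier_cycles(fake_cycles(rep(1.1, 8)))
  expect_length(same, 8L)

  # one-sided variant keeps short cycles
  mixed <- fake_cycles(c(0.2, rep(1, 9)))
  expect_length(remove_outlier_cycles(mixed, rule = "upper"), 10L)
  expect_length(remove_outlier_cycles(mixed, rule = "two-sided"), 9L)
})

test_that("about 4.6 percent of Gaussian durations fall outside the 2 SD band", {
  set.seed(31)
  frac <- mean(replicate(40, {
    cyc <- fake_cycles(stats::rnorm(1000, 1.1, 0.05))
    1 - length(remove_outlier_cycles(cyc)) / 1000
  }))
  expect_equal(frac, 0.046, tolerance = 0.2)
})
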