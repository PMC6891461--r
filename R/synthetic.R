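# Synthetic gait-cohort generator: healthy and post-THA recordings with
# controllable group effects, plus paired "reference-system" channels and
# static IMU calibration records.

# Canonical sagittal-hip shape: two cosine harmonics, rescaled to [0, 1] so
# that per-stride extension/flexion peaks can be imposed exactly.
.hip_shape <- local({
  u <- function(phi) cos(2 * pi * phi) + 0.3 * cos(4 * pi * phi + 0.8)
  grid <- u(seq(0, 1, length.out = 4001L))
  lo <- min(grid)
  hi <- max(grid)
  function(phi) (u(phi) - lo) / (hi - lo)
})

.angle_channels <- c(
  "hip_flexion_l", "hip_abduction_l", "hip_rotation_l",
  "hip_flexion_r", "hip_abduction_r", "hip_rotation_r",
  "pelvis_tilt", "pelvis_obliquity", "pelvis_rotation"
)

#' Configuration for a synthetic gait cohort
#'
#' Bundles every parameter of the synthetic cohort generator: cohort sizes,
#' sampling, stride timing and length (between-subject spread and
#' stride-to-stride jitter), the healthy sagittal hip template, the operated-
#' side deficits that characterise post-THA gait (reduced sagittal hip range
#' of motion, loss of the extension peak), per-plane pelvis ROM for each
#' group, amplitude variability, and the corruption applied to the paired
#' reference channel (static per-channel offsets and white noise).
#'
#' Per-group parameters are length-2 vectors named `healthy`/`patient`;
#' scalars are recycled to both groups.
#'
#' @param n_healthy,n_patient Number of subjects per group.
#' @param fs Sampling rate in Hz.
#' @param trial_duration Length of each walking trial in seconds.
#' @param stride_time_mean,stride_time_sd Per-group mean and between-subject
#'   SD of stride time (s).
#' @param stride_length_mean,stride_length_sd Per-group mean and
#'   between-subject SD of stride length (m).
#' @param stride_time_jitter,stride_length_jitter Within-subject
#'   stride-to-stride SD of stride time (s) and length (m).
#' @param hip_rom_healthy Healthy sagittal hip range of motion (deg).
#' @param hip_extension_peak Healthy extension peak (deg; negative =
#'   extension, so the flexion peak is `hip_extension_peak + hip_rom_healthy`).
#' @param delta_rom_operated Reduction of the operated-side sagittal hip ROM
#'   (deg) in the patient group.
#' @param delta_extension_operated Loss of the operated-side extension peak
#'   (deg; the minimum is raised by this amount).
#' @param pelvis_rom Named list with elements `healthy` and `patient`, each a
#'   length-3 vector of pelvis ROM (deg) in the order tilt, obliquity,
#'   rotation.
#' @param intra_subject_sd Stride-to-stride amplitude jitter SD (deg).
#' @param inter_subject_sd Subject-level amplitude random-effect SD (deg),
#'   drawn independently per side and channel.
#' @param ref_offset_range Static per-channel offset magnitude for the paired
#'   reference channel (deg); offsets are drawn uniformly from
#'   `[-ref_offset_range, ref_offset_range]`.
#' @param ref_noise_sd White-noise SD added to the reference channel (deg).
#' @param seed Master seed; identical configuration and seed give a
#'   byte-identical cohort.
#'
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_healthy = 24L,
                          n_patient = 20L,
                          fs = 60,
                          trial_duration = 30,
                          stride_time_mean = c(healthy = 1.1, patient = 1.2),
                          stride_time_sd = c(healthy = 0.07, patient = 0.07),
                          stride_length_mean = c(healthy = 1.3, patient = 1.15),
                          stride_length_sd = c(healthy = 0.10, patient = 0.10),
                          stride_time_jitter = 0.02,
                          stride_length_jitter = 0.02,
                          hip_rom_healthy = 40,
                          hip_extension_peak = -10,
                          delta_rom_operated = 8,
                          delta_extension_operated = 5,
                          pelvis_rom = list(healthy = c(tilt = 3, obliquity = 4, rotation = 8),
                                            patient = c(tilt = 4, obliquity = 5, rotation = 6)),
                          intra_subject_sd = 1,
                          inter_subject_sd = 2,
                          ref_offset_range = 12.5,
                          ref_noise_sd = 0.3,
                          seed = 1L) {
  per_group <- function(x, nm) {
    if (length(x) == 1L) x <- c(healthy = unname(x), patient = unname(x))
    if (is.null(names(x))) names(x) <- c("healthy", "patient")
    if (!all(c("healthy", "patient") %in% names(x))) {
      stop(sprintf("'%s' must be named with groups 'healthy' and 'patient'", nm))
    }
    x[c("healthy", "patient")]
  }
  cfg <- list(
    n_healthy = as.integer(n_healthy),
    n_patient = as.integer(n_patient),
    fs = fs,
    trial_duration = trial_duration,
    stride_time_mean = per_group(stride_time_mean, "stride_time_mean"),
    stride_time_sd = per_group(stride_time_sd, "stride_time_sd"),
    stride_length_mean = per_group(stride_length_mean, "stride_length_mean"),
    stride_length_sd = per_group(stride_length_sd, "stride_length_sd"),
    stride_time_jitter = stride_time_jitter,
    stride_length_jitter = stride_length_jitter,
    hip_rom_healthy = hip_rom_healthy,
    hip_extension_peak = hip_extension_peak,
    delta_rom_operated = delta_rom_operated,
    delta_extension_operated = delta_extension_operated,
    pelvis_rom = pelvis_rom,
    intra_subject_sd = intra_subject_sd,
    inter_subject_sd = inter_subject_sd,
    ref_offset_range = ref_offset_range,
    ref_noise_sd = ref_noise_sd,
    seed = as.integer(seed)
  )
  validate_cohort_config(cfg)
  structure(cfg, class = "cohort_config")
}

validate_cohort_config <- function(cfg) {
  stopifnot(
    cfg$n_healthy >= 0L, cfg$n_patient >= 0L,
    cfg$n_healthy + cfg$n_patient > 0L,
    cfg$fs > 0, cfg$trial_duration > 0,
    all(cfg$stride_time_mean > 0), all(cfg$stride_time_sd >= 0),
    all(cfg$stride_length_mean > 0), all(cfg$stride_length_sd >= 0),
    cfg$stride_time_jitter >= 0, cfg$stride_length_jitter >= 0,
    cfg$hip_rom_healthy > 0,
    cfg$intra_subject_sd >= 0, cfg$inter_subject_sd >= 0,
    cfg$ref_offset_range >= 0, cfg$ref_noise_sd >= 0
  )
  if (cfg$delta_rom_operated >= cfg$hip_rom_healthy) {
    stop("delta_rom_operated must be smaller than hip_rom_healthy")
  }
  invisible(cfg)
}

# Draw a per-side stride schedule (IC times and per-stride durations)
# covering [-margin, duration + margin] so that every sample of the trial
# falls inside a defined stride.
.stride_schedule <- function(t0, duration, mean_time, jitter, margin = 2) {
  n_back <- ceiling((t0 + margin) / mean_time) + 1L
  n_total <- n_back + ceiling((duration + 2 * margin) / mean_time) + 2L
  durs <- stats::rnorm(n_total, mean_time, jitter)
  durs <- pmax(durs, 0.4 * mean_time)
  start <- t0 - sum(durs[seq_len(n_back)])
  ic <- start + cumsum(c(0, durs))
  list(ic = ic, dur = durs) # length(ic) == n_total + 1; dur[k] spans ic[k]..ic[k+1]
}

# Piecewise evaluation over a stride schedule: for each time return the
# stride index and within-stride phase in [0, 1).
.stride_phase <- function(t, sched) {
  k <- findInterval(t, sched$ic, rightmost.closed = FALSE)
  k <- pmin(pmax(k, 1L), length(sched$dur))
  phi <- (t - sched$ic[k]) / sched$dur[k]
  list(k = k, phi = pmin(pmax(phi, 0), 1 - 1e-12))
}

# Relative (segment-minus-pelvis) forward coordinate with extrema exactly at
# the gait events: maximum `a` at each initial contact, minimum `-b` at each
# terminal contact (cosine easing, zero slope at the events).
.relative_forward <- function(t, sched, stance_frac, a, b) {
  sp <- .stride_phase(t, sched)
  phi <- sp$phi
  stance <- phi < stance_frac
  r <- numeric(length(t))
  s1 <- phi[stance] / stance_frac
  r[stance] <- -b + (a + b) * (1 + cos(pi * s1)) / 2
  s2 <- (phi[!stance] - stance_frac) / (1 - stance_frac)
  r[!stance] <- -b + (a + b) * (1 - cos(pi * s2)) / 2
  r
}

#' Generate one synthetic walking trial
#'
#' Builds a single subject's recording: bilateral hip and global pelvis angle
#' channels from a harmonic per-stride template with subject- and
#' stride-level amplitude variability, plus heel/toe/pelvis trajectories
#' constructed so that coordinate-based event detection recovers the exact
#' ground-truth initial/terminal contacts. For `group = "patient"` the
#' operated side's sagittal hip ROM is reduced by `delta_rom_operated` and
#' its extension peak raised by `delta_extension_operated`.
#'
#' @param config A [cohort_config()].
#' @param group `"healthy"` or `"patient"`.
#' @param subject_seed Integer seed for this subject's random draws.
#' @param subject_id Identifier stored in the recording.
#'
#' @return An object of class `trial_recording`: a list with `subject_id`,
#'   `group`, `operated_side`, `fs`, `time`, `channels` (named list of angle
#'   series in degrees), `positions` (named list of n-by-3 matrices in
#'   meters, columns x/y/z with z vertical), `reference_channels` (NULL until
#'   [add_reference_channel()] is applied) and `truth` (exact event times and
#'   per-stride parameters).
#' @export
generate_subject <- function(config, group = c("healthy", "patient"),
                             subject_seed = config$seed,
                             subject_id = sprintf("%s_%06d", group, subject_seed %% 1000000L)) {
  validate_cohort_config(config)
  group <- match.arg(group)
  fs <- config$fs
  dur <- config$trial_duration
  if (dur < 2 * config$stride_time_mean[[group]]) {
    stop("trial_duration shorter than two strides: no full gait cycle can be generated")
  }
  with_seed(subject_seed, {
    operated <- if (group == "patient") sample(c("left", "right"), 1L) else "none"

    st_mean <- max(stats::rnorm(1, config$stride_time_mean[[group]],
                                config$stride_time_sd[[group]]),
                   0.5 * config$stride_time_mean[[group]])
    sl_mean <- max(stats::rnorm(1, config$stride_length_mean[[group]],
                                config$stride_length_sd[[group]]),
                   0.4 * config$stride_length_mean[[group]])

    sched_l <- .stride_schedule(0.25, dur, st_mean, config$stride_time_jitter)
    sched_r <- .stride_schedule(0.25 + st_mean / 2, dur, st_mean,
                                config$stride_time_jitter)

    n_l <- length(sched_l$dur)
    n_r <- length(sched_r$dur)
    stride_len_l <- pmax(sl_mean + stats::rnorm(n_l, 0, config$stride_length_jitter),
                         0.2 * sl_mean)

    # Subject-level amplitude effects, independent per side/channel.
    inter <- config$inter_subject_sd
    intra <- config$intra_subject_sd
    flex_peak0 <- config$hip_extension_peak + config$hip_rom_healthy
    hip <- list()
    for (side in c("l", "r")) {
      rom0 <- config$hip_rom_healthy + stats::rnorm(1, 0, inter)
      ext0 <- config$hip_extension_peak + stats::rnorm(1, 0, inter / 2)
      if (group == "patient" &&
          ((side == "l" && operated == "left") || (side == "r" && operated == "right"))) {
        rom0 <- rom0 - config$delta_rom_operated
        ext0 <- ext0 + config$delta_extension_operated
      }
      rom0 <- max(rom0, 5)
      nk <- if (side == "l") n_l else n_r
      rom_k <- pmax(rom0 + stats::rnorm(nk, 0, intra), 2)
      ext_k <- ext0 + stats::rnorm(nk, 0, intra / 2)
      hip[[side]] <- list(rom = rom_k, ext = ext_k,
                          abd_amp = pmax(5 + stats::rnorm(1, 0, inter / 2) +
                                           stats::rnorm(nk, 0, intra / 2), 1),
                          rot_amp = pmax(4 + stats::rnorm(1, 0, inter / 2) +
                                           stats::rnorm(nk, 0, intra / 2), 1))
    }

    prom0 <- config$pelvis_rom[[group]]
    pel_sub <- pmax(prom0 + stats::rnorm(3, 0, inter / 2), 0.5)
    pel_rom <- sapply(1:3, function(j) pmax(pel_sub[j] + stats::rnorm(n_l, 0, intra / 2), 0.3))

    t <- seq(0, dur, by = 1 / fs)

    hip_channels <- function(side) {
      sched <- if (side == "l") sched_l else sched_r
      p <- hip[[side]]
      sp <- .stride_phase(t, sched)
      flex <- p$ext[sp$k] + p$rom[sp$k] * .hip_shape(sp$phi)
      abd <- p$abd_amp[sp$k] / 2 * sin(2 * pi * sp$phi + 0.5)
      rot <- p$rot_amp[sp$k] / 2 * sin(2 * pi * sp$phi + 2.1)
      list(flexion = flex, abduction = abd, rotation = rot)
    }
    hl <- hip_channels("l")
    hr <- hip_channels("r")

    spl <- .stride_phase(t, sched_l)
    pelvis_tilt <- 5 + pel_rom[spl$k, 1] / 2 * cos(4 * pi * spl$phi + 0.3)
    pelvis_obl <- pel_rom[spl$k, 2] / 2 * sin(4 * pi * spl$phi + 1.2)
    pelvis_rot <- pel_rom[spl$k, 3] / 2 * sin(2 * pi * spl$phi + 0.7)

    # Pelvis advances by the left stride length over each left stride
    # (piecewise-constant velocity), so left stride lengths are exact.
    pel_x_ic <- cumsum(c(0, stride_len_l))
    v_k <- stride_len_l / sched_l$dur
    pelvis_x <- pel_x_ic[spl$k] + v_k[spl$k] * (t - sched_l$ic[spl$k])

    stance_frac <- 0.62
    r_heel_l <- .relative_forward(t, sched_l, stance_frac, 0.35, 0.20)
    r_heel_r <- .relative_forward(t, sched_r, stance_frac, 0.35, 0.20)

    spr <- .stride_phase(t, sched_r)
    swing_z <- function(sp) {
      z <- numeric(length(t))
      sw <- sp$phi >= stance_frac
      z[sw] <- 0.06 * sin(pi * (sp$phi[sw] - stance_frac) / (1 - stance_frac))
      z
    }
    z_l <- swing_z(spl)
    z_r <- swing_z(spr)

    pos <- list(
      heel_l = cbind(x = pelvis_x + r_heel_l, y = rep(0.1, length(t)), z = z_l),
      heel_r = cbind(x = pelvis_x + r_heel_r, y = rep(-0.1, length(t)), z = z_r),
      toe_l = cbind(x = pelvis_x + r_heel_l - 0.15, y = rep(0.1, length(t)), z = z_l),
      toe_r = cbind(x = pelvis_x + r_heel_r - 0.15, y = rep(-0.1, length(t)), z = z_r),
      pelvis = cbind(x = pelvis_x, y = rep(0, length(t)), z = rep(0.95, length(t)))
    )

    in_trial <- function(x) x[x >= 0 & x <= dur]
    tc_l <- sched_l$ic[-length(sched_l$ic)] + stance_frac * sched_l$dur
    tc_r <- sched_r$ic[-length(sched_r$ic)] + stance_frac * sched_r$dur

    # Right stride lengths are implied by the shared pelvis trajectory.
    pel_at <- stats::approx(t, pelvis_x, xout = pmin(pmax(sched_r$ic, 0), dur))$y
    stride_len_r <- diff(pel_at)

    keep_l <- which(sched_l$ic >= 0 & sched_l$ic <= dur)
    keep_r <- which(sched_r$ic >= 0 & sched_r$ic <= dur)
    stride_l_idx <- keep_l[-length(keep_l)]
    stride_r_idx <- keep_r[-length(keep_r)]

    truth <- list(
      ic_left = in_trial(sched_l$ic), ic_right = in_trial(sched_r$ic),
      tc_left = in_trial(tc_l), tc_right = in_trial(tc_r),
      stride_time_left = sched_l$dur[stride_l_idx],
      stride_time_right = sched_r$dur[stride_r_idx],
      stride_length_left = stride_len_l[stride_l_idx],
      stride_length_right = stride_len_r[stride_r_idx],
      hip_rom_left = hip$l$rom[stride_l_idx],
      hip_rom_right = hip$r$rom[stride_r_idx],
      hip_ext_left = hip$l$ext[stride_l_idx],
      hip_ext_right = hip$r$ext[stride_r_idx],
      stride_time_mean = st_mean,
      stride_length_mean = sl_mean,
      operated_side = operated
    )

    if (length(truth$ic_left) < 3L || length(truth$ic_right) < 3L) {
      stop("trial_duration shorter than two strides: no full gait cycle recorded")
    }

    channels <- list(
      hip_flexion_l = hl$flexion, hip_abduction_l = hl$abduction,
      hip_rotation_l = hl$rotation,
      hip_flexion_r = hr$flexion, hip_abduction_r = hr$abduction,
      hip_rotation_r = hr$rotation,
      pelvis_tilt = pelvis_tilt, pelvis_obliquity = pelvis_obl,
      pelvis_rotation = pelvis_rot
    )

    structure(list(
      subject_id = subject_id, group = group, operated_side = operated,
      fs = fs, time = t, channels = channels, positions = pos,
      reference_channels = NULL, truth = truth
    ), class = "trial_recording")
  })
}

#' @export
print.trial_recording <- function(x, ...) {
  cat(sprintf("<trial_recording> %s (%s%s), %.0f Hz, %.1f s, %d angle channels%s\n",
              x$subject_id, x$group,
              if (x$operated_side != "none") paste0(", operated ", x$operated_side) else "",
              x$fs, max(x$time), length(x$channels),
              if (!is.null(x$reference_channels)) ", paired reference" else ""))
  invisible(x)
}

#' Generate a full synthetic cohort
#'
#' Generates `n_healthy + n_patient` trials with subject seeds derived
#' reproducibly from the master seed, optionally attaching the paired
#' offset-corrupted reference channel to each trial.
#'
#' @param config A [cohort_config()].
#' @param reference_channels If `TRUE` (default), call
#'   [add_reference_channel()] on every trial using the configured
#'   `ref_offset_range` and `ref_noise_sd`.
#'
#' @return A list of [trial_recording][generate_subject] objects (healthy
#'   subjects first).
#' @export
generate_cohort <- function(config, reference_channels = TRUE) {
  validate_cohort_config(config)
  n <- config$n_healthy + config$n_patient
  seeds <- with_seed(config$seed, sample.int(.Machine$integer.max - 1L, 2L * n))
  groups <- rep(c("healthy", "patient"), c(config$n_healthy, config$n_patient))
  lapply(seq_len(n), function(i) {
    trial <- generate_subject(config, groups[i], subject_seed = seeds[i],
                              subject_id = sprintf("S%02d_%s", i, groups[i]))
    if (reference_channels) {
      trial <- add_reference_channel(trial, config$ref_offset_range,
                                     config$ref_noise_sd, seed = seeds[n + i])
    }
    trial
  })
}

#' Attach a paired offset-corrupted reference channel
#'
#' Emulates a second measurement system (e.g. optical motion capture) whose
#' joint-angle output differs from the truth by a static offset — the
#' signature of imperfect sensor-to-segment calibration — plus white noise.
#' By default (`bilateral = TRUE`) one offset is drawn per angle definition
#' and applied to both sides of a bilateral channel pair (left and right hip
#' flexion share one offset, and so on): calibration offsets enter through
#' the joint-angle definition, and this structure is what makes left-minus-
#' right symmetry features robust to static offsets. `bilateral = FALSE`
#' draws an independent offset per channel instead. Offsets are drawn from
#' `[-offset_range, offset_range]` and stored for introspection.
#'
#' @param trial A [trial_recording][generate_subject].
#' @param offset_range Maximum static offset magnitude (deg).
#' @param noise_sd White-noise SD (deg); must be non-negative.
#' @param seed Seed for the offset and noise draws.
#' @param bilateral Share one offset across each left/right channel pair
#'   (default `TRUE`).
#'
#' @return The trial with `reference_channels` set (same names as
#'   `channels`); the per-channel offsets actually applied are in
#'   `attr(trial$reference_channels, "offsets")` and
#'   `trial$truth$ref_offsets`.
#' @export
add_reference_channel <- function(trial, offset_range = 12.5, noise_sd = 0.3,
                                  seed = 1L, bilateral = TRUE) {
  stopifnot(inherits(trial, "trial_recording"))
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  if (offset_range < 0) stop("offset_range must be non-negative")
  with_seed(seed, {
    nms <- names(trial$channels)
    if (bilateral) {
      defs <- sub("_[lr]$", "", nms)
      draw <- stats::runif(length(unique(defs)), -offset_range, offset_range)
      names(draw) <- unique(defs)
      offsets <- draw[defs]
    } else {
      offsets <- stats::runif(length(nms), -offset_range, offset_range)
    }
    names(offsets) <- nms
    ref <- lapply(nms, function(nm) {
      trial$channels[[nm]] + offsets[[nm]] +
        if (noise_sd > 0) stats::rnorm(length(trial$channels[[nm]]), 0, noise_sd) else 0
    })
    names(ref) <- nms
    attr(ref, "offsets") <- offsets
    trial$reference_channels <- ref
    trial$truth$ref_offsets <- offsets
    trial
  })
}

#' Simulate a static IMU calibration record
#'
#' Emulates the boxed-IMU bias-calibration procedure: the sensor rests in a
#' number of orientations; gyroscope samples are the gyroscope bias plus
#' noise, accelerometer samples are the rotated gravity vector (magnitude
#' `gravity`) plus the accelerometer bias plus noise, so the noiseless
#' accelerometer samples lie on a sphere of radius `gravity` centred at the
#' bias.
#'
#' @param bias_gyro Gyroscope bias, rad/s 3-vector.
#' @param bias_accel Accelerometer bias, m/s^2 3-vector.
#' @param orientations List of 3x3 rotation matrices (world-to-sensor
#'   attitudes); defaults to the six axis-aligned box faces.
#' @param n_per_orientation Samples recorded per orientation.
#' @param noise_sd Additive white-noise SD on both sensors (rad/s, m/s^2).
#' @param gravity Gravity magnitude in m/s^2.
#' @param seed Seed for the noise draws.
#'
#' @return A list with matrices `gyro` and `accel` (n-by-3), the
#'   `orientation` index per sample, and the simulated `bias_gyro`,
#'   `bias_accel` and `gravity`.
#' @export
simulate_static_imu <- function(bias_gyro = c(0, 0, 0),
                                bias_accel = c(0, 0, 0),
                                orientations = box_orientations(),
                                n_per_orientation = 100L,
                                noise_sd = 0.01,
                                gravity = 9.81,
                                seed = 1L) {
  stopifnot(length(bias_gyro) == 3L, length(bias_accel) == 3L,
            length(orientations) >= 1L, n_per_orientation >= 1L, noise_sd >= 0)
  with_seed(seed, {
    g_world <- c(0, 0, gravity)
    per <- lapply(seq_along(orientations), function(i) {
      R <- orientations[[i]]
      stopifnot(is.matrix(R), all(dim(R) == c(3L, 3L)))
      g_sens <- as.numeric(t(R) %*% g_world)
      n <- n_per_orientation
      acc <- matrix(rep(g_sens + bias_accel, each = n), n, 3L)
      gyr <- matrix(rep(bias_gyro, each = n), n, 3L)
      if (noise_sd > 0) {
        acc <- acc + matrix(stats::rnorm(3L * n, 0, noise_sd), n, 3L)
        gyr <- gyr + matrix(stats::rnorm(3L * n, 0, noise_sd), n, 3L)
      }
      list(acc = acc, gyr = gyr, idx = rep(i, n))
    })
    list(
      gyro = do.call(rbind, lapply(per, `[[`, "gyr")),
      accel = do.call(rbind, lapply(per, `[[`, "acc")),
      orientation = unlist(lapply(per, `[[`, "idx")),
      bias_gyro = bias_gyro, bias_accel = bias_accel, gravity = gravity
    )
  })
}

#' Six axis-aligned box orientations
#'
#' Rotation matrices that place each face of a rectangular box downward in
#' turn — the classic six-position accelerometer calibration.
#'
#' @return List of six 3x3 rotation matrices.
#' @export
box_orientations <- function() {
  rx <- function(a) matrix(c(1, 0, 0, 0, cos(a), sin(a), 0, -sin(a), cos(a)), 3, 3)
  ry <- function(a) matrix(c(cos(a), 0, -sin(a), 0, 1, 0, sin(a), 0, cos(a)), 3, 3)
  list(diag(3), rx(pi), rx(pi / 2), rx(-pi / 2), ry(pi / 2), ry(-pi / 2))
}
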