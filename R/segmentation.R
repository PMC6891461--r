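# Gait events, stride-level spatio-temporal parameters, normalized gait
# cycles and the duration-based outlier rule.

#' Detect initial contacts from heel and pelvis trajectories
#'
#' Coordinate-based detection: an initial contact (IC) is placed at each
#' local maximum of the heel-minus-pelvis forward (anterior) coordinate —
#' the instant the heel is furthest ahead of the body. Peaks closer than
#' half the median inter-peak interval are pruned (taller peak wins).
#'
#' @param heel,pelvis n-by-3 position matrices (m), column 1 = forward.
#' @param fs Sampling rate (Hz).
#' @param min_separation Minimum peak separation in seconds; default
#'   `0.5 * median(diff(candidate peak times))`.
#'
#' @return Event times in seconds (possibly empty). Fewer than two events
#'   triggers a warning (no stride can be formed).
#' @export
detect_initial_contacts <- function(heel, pelvis, fs, min_separation = NULL) {
  .detect_events(heel, pelvis, fs, min_separation, maxima = TRUE, what = "initial contacts")
}

#' Detect terminal contacts from toe and pelvis trajectories
#'
#' Terminal contacts (TC, toe-off) are placed at local minima of the
#' toe-minus-pelvis forward coordinate — the instant the toe is furthest
#' behind the body.
#'
#' @inheritParams detect_initial_contacts
#' @param toe n-by-3 toe position matrix (m).
#' @return Event times in seconds.
#' @export
detect_terminal_contacts <- function(toe, pelvis, fs, min_separation = NULL) {
  .detect_events(toe, pelvis, fs, min_separation, maxima = FALSE, what = "terminal contacts")
}

.detect_events <- function(seg, pelvis, fs, min_separation, maxima, what) {
  seg <- as.matrix(seg); pelvis <- as.matrix(pelvis)
  if (nrow(seg) != nrow(pelvis)) stop("trajectories must have the same length")
  if (fs <= 0) stop("fs must be positive")
  d <- seg[, 1] - pelvis[, 1]
  if (!maxima) d <- -d
  idx <- find_peaks(d)
  if (length(idx) >= 3L && is.null(min_separation)) {
    min_separation <- 0.5 * stats::median(diff(idx)) / fs
  }
  if (!is.null(min_separation)) {
    idx <- find_peaks(d, min_separation = min_separation * fs)
  }
  if (length(idx) < 2L) {
    warning(sprintf("fewer than 2 %s detected: no complete stride", what))
  }
  (idx - 1L) / fs
}

#' Gait event container
#'
#' @param ic_left,ic_right,tc_left,tc_right Ordered event times (s).
#' @return An object of class `gait_events`.
#' @export
gait_events <- function(ic_left, ic_right, tc_left = numeric(0),
                        tc_right = numeric(0)) {
  for (v in list(ic_left, ic_right, tc_left, tc_right)) {
    if (is.unsorted(v, strictly = TRUE) && length(v) > 1L) {
      stop("event times must be strictly increasing")
    }
  }
  structure(list(ic_left = ic_left, ic_right = ic_right,
                 tc_left = tc_left, tc_right = tc_right),
            class = "gait_events")
}

#' Detect all gait events of a trial
#'
#' Runs [detect_initial_contacts()] and [detect_terminal_contacts()] for
#' both feet of a [trial_recording][generate_subject].
#'
#' @param trial A `trial_recording`.
#' @return A [gait_events()] object.
#' @export
detect_gait_events <- function(trial) {
  p <- trial$positions
  gait_events(
    ic_left = detect_initial_contacts(p$heel_l, p$pelvis, trial$fs),
    ic_right = detect_initial_contacts(p$heel_r, p$pelvis, trial$fs),
    tc_left = detect_terminal_contacts(p$toe_l, p$pelvis, trial$fs),
    tc_right = detect_terminal_contacts(p$toe_r, p$pelvis, trial$fs)
  )
}

#' Stride-level spatio-temporal parameters
#'
#' For every pair of consecutive ipsilateral initial contacts: stride length
#' is the horizontal-plane (ground-projected) Euclidean distance between the
#' heel positions at the two contacts; stride time is the IC-to-IC interval;
#' cadence is 60 divided by the interval from the ipsilateral IC to the next
#' contralateral IC (steps/min, `NA` and flagged when no contralateral IC
#' falls inside the stride); speed is stride length over stride time.
#'
#' @param events A [gait_events()] object (ICs required).
#' @param heel_left,heel_right n-by-3 heel trajectories (m), column 3
#'   vertical.
#' @param fs Sampling rate (Hz) of the trajectories.
#'
#' @return `data.frame` with columns `side`, `index`, `t_ic`,
#'   `stride_length`, `stride_time`, `cadence`, `speed`, `flag` (`"ok"`,
#'   `"no_contralateral_ic"` or `"implausible_length"`).
#' @export
compute_stride_parameters <- function(events, heel_left, heel_right, fs) {
  one_side <- function(ic, ic_contra, heel, side) {
    if (length(ic) < 2L) stop(sprintf("need at least 2 %s initial contacts", side))
    heel <- as.matrix(heel)
    tt <- (seq_len(nrow(heel)) - 1L) / fs
    hx <- stats::approx(tt, heel[, 1], xout = ic, rule = 2)$y
    hy <- stats::approx(tt, heel[, 2], xout = ic, rule = 2)$y
    n <- length(ic) - 1L
    out <- data.frame(
      side = rep(side, n), index = seq_len(n), t_ic = ic[-length(ic)],
      stride_length = sqrt(diff(hx)^2 + diff(hy)^2),
      stride_time = diff(ic), cadence = NA_real_, speed = NA_real_,
      flag = rep("ok", n), stringsAsFactors = FALSE
    )
    out$speed <- out$stride_length / out$stride_time
    for (k in seq_len(n)) {
      nxt <- ic_contra[ic_contra > ic[k] & ic_contra < ic[k + 1L]]
      if (length(nxt)) {
        out$cadence[k] <- 60 / (nxt[1L] - ic[k])
      } else {
        out$flag[k] <- "no_contralateral_ic"
      }
    }
    out$flag[out$stride_length <= 1e-9 & out$flag == "ok"] <- "implausible_length"
    out
  }
  rbind(
    one_side(events$ic_left, events$ic_right, heel_left, "left"),
    one_side(events$ic_right, events$ic_left, heel_right, "right")
  )
}

#' Cut a channel into normalized gait cycles
#'
#' One cycle per consecutive pair of initial contacts, linearly resampled to
#' 101 points on the 0-100% gait-cycle axis (endpoints preserved).
#'
#' @param x Numeric channel series.
#' @param ic_times Initial-contact times (s), at least two, all inside the
#'   series.
#' @param fs Sampling rate (Hz).
#' @param channel,side Optional labels stored on each cycle.
#'
#' @return List of `gait_cycle` objects (fields `values` (length 101),
#'   `duration` (s), `channel`, `side`).
#' @export
segment_gait_cycles <- function(x, ic_times, fs, channel = NA_character_,
                                side = NA_character_) {
  if (length(ic_times) < 2L) stop("need at least 2 initial contacts")
  tt <- (seq_along(x) - 1L) / fs
  if (min(ic_times) < tt[1L] - 1e-9 || max(ic_times) > tt[length(tt)] + 1e-9) {
    stop("initial contact outside the recorded series")
  }
  lapply(seq_len(length(ic_times) - 1L), function(k) {
    xout <- seq(ic_times[k], ic_times[k + 1L], length.out = 101L)
    structure(list(
      values = stats::approx(tt, x, xout = xout, rule = 2)$y,
      duration = ic_times[k + 1L] - ic_times[k],
      channel = channel, side = side
    ), class = "gait_cycle")
  })
}

#' Remove cycles with outlying durations
#'
#' The boundary is computed once from all input durations: cycles whose
#' duration falls outside mean +/- 2 * SD (sample SD) are removed. The rule
#' is two-sided by default; `rule = "upper"` removes only cycles longer than
#' mean + 2 * SD. Because the bounds are computed once on the input, applying
#' the function twice is not guaranteed to be a no-op.
#'
#' @param cycles List of `gait_cycle` objects (or any objects with a
#'   `duration` field).
#' @param rule `"two-sided"` (default) or `"upper"`.
#'
#' @return The retained cycles, with attributes `removed` (indices removed)
#'   and `bounds` (lower/upper duration bounds).
#' @export
remove_outlier_cycles <- function(cycles, rule = c("two-sided", "upper")) {
  rule <- match.arg(rule)
  if (length(cycles) < 2L) return(cycles)
  durations <- vapply(cycles, function(cyc) cyc$duration, numeric(1))
  keep <- outlier_keep_mask(durations, rule)
  out <- cycles[keep]
  attr(out, "removed") <- which(!keep)
  attr(out, "bounds") <- attr(keep, "bounds")
  out
}

# Shared duration rule so feature assembly can filter parallel cycle lists
# with a single mask.
outlier_keep_mask <- function(durations, rule = c("two-sided", "upper")) {
  rule <- match.arg(rule)
  m <- mean(durations)
  s <- stats::sd(durations)
  lo <- if (rule == "two-sided") m - 2 * s else -Inf
  hi <- m + 2 * s
  keep <- durations >= lo & durations <= hi
  attr(keep, "bounds") <- c(lower = lo, upper = hi)
  keep
}
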