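# Per-gait-cycle feature computation: spatio-temporal Set 1 and
# joint-kinematic Set 2, and the labeled feature table.

#' Feature-set column names
#'
#' Column names of the Set 1 (spatio-temporal) and Set 2 (joint-kinematic)
#' features in a feature table.
#'
#' @param set `"set1"`, `"set2"` or `"all"`.
#' @return Character vector of column names.
#' @export
feature_set_columns <- function(set = c("all", "set1", "set2")) {
  set <- match.arg(set)
  set1 <- c("stride_length_m", "stride_time_s", "cadence_spm", "speed_mps")
  set2 <- c("hip_rom_sym_deg", "hip_maxflex_sym_deg", "hip_maxext_sym_deg",
            "pelvis_sag_rom_deg", "pelvis_front_rom_deg", "pelvis_trans_rom_deg")
  switch(set, set1 = set1, set2 = set2, all = c(set1, set2))
}

.cycle_values <- function(x) {
  v <- if (inherits(x, "gait_cycle")) x$values else x
  if (length(v) != 101L) stop("gait cycle must have exactly 101 samples")
  v
}

#' Joint-kinematic (Set 2) features of one gait cycle
#'
#' All cycles must be time-aligned to the same stride (same reference
#' initial contact). Symmetry features follow the left-minus-right
#' convention: ROM symmetry is (max-min of left) minus (max-min of right);
#' flexion symmetry is max(left) minus max(right); extension symmetry is
#' min(left) minus min(right), the extension peak being the sagittal-angle
#' minimum (extension negative). Pelvis ROM per plane is max minus min.
#'
#' @param left_hip,right_hip Sagittal hip-angle cycles (101 samples, deg).
#' @param pelvis Named list of pelvis cycles `tilt`, `obliquity`, `rotation`.
#' @return Named numeric vector of the six Set 2 features (deg).
#' @export
compute_set2 <- function(left_hip, right_hip, pelvis) {
  l <- .cycle_values(left_hip)
  r <- .cycle_values(right_hip)
  pt <- .cycle_values(pelvis$tilt)
  po <- .cycle_values(pelvis$obliquity)
  pr <- .cycle_values(pelvis$rotation)
  c(
    hip_rom_sym_deg = (max(l) - min(l)) - (max(r) - min(r)),
    hip_maxflex_sym_deg = max(l) - max(r),
    hip_maxext_sym_deg = min(l) - min(r),
    pelvis_sag_rom_deg = max(pt) - min(pt),
    pelvis_front_rom_deg = max(po) - min(po),
    pelvis_trans_rom_deg = max(pr) - min(pr)
  )
}

# Features of one trial; used by build_feature_table.
.trial_features <- function(trial, channel_source, smooth_cutoff_hz,
                            outlier_rule) {
  events <- detect_gait_events(trial)
  if (length(events$ic_left) < 2L || length(events$ic_right) < 1L) {
    return(NULL)
  }
  stp <- compute_stride_parameters(events, trial$positions$heel_l,
                                   trial$positions$heel_r, trial$fs)
  stp <- stp[stp$side == "left", , drop = FALSE]

  src <- if (channel_source == "reference") {
    if (is.null(trial$reference_channels)) {
      stop(sprintf("subject %s has no reference channels", trial$subject_id))
    }
    trial$reference_channels
  } else {
    trial$channels
  }
  smooth <- function(nm) {
    lowpass_filtfilt(src[[nm]], trial$fs, smooth_cutoff_hz)
  }
  seg <- function(x) segment_gait_cycles(x, events$ic_left, trial$fs)
  cyc <- list(
    hip_l = seg(smooth("hip_flexion_l")),
    hip_r = seg(smooth("hip_flexion_r")),
    tilt = seg(smooth("pelvis_tilt")),
    obl = seg(smooth("pelvis_obliquity")),
    rot = seg(smooth("pelvis_rotation"))
  )
  durations <- vapply(cyc$hip_l, function(x) x$duration, numeric(1))
  keep <- outlier_keep_mask(durations, outlier_rule)
  keep <- keep & !is.na(stp$cadence)
  if (!any(keep)) return(NULL)

  rows <- lapply(which(keep), function(k) {
    s2 <- compute_set2(cyc$hip_l[[k]], cyc$hip_r[[k]],
                       list(tilt = cyc$tilt[[k]], obliquity = cyc$obl[[k]],
                            rotation = cyc$rot[[k]]))
    data.frame(
      subject_id = trial$subject_id, cycle_index = k, label = trial$group,
      stride_length_m = stp$stride_length[k], stride_time_s = stp$stride_time[k],
      cadence_spm = stp$cadence[k], speed_mps = stp$speed[k],
      t(s2), stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

#' Build the labeled per-cycle feature table for a cohort
#'
#' Runs event detection, segmentation into left-foot-referenced gait cycles,
#' the duration outlier rule and feature computation for every trial, and
#' stacks the results into one table: one row per retained gait cycle with
#' the four Set 1 and six Set 2 features plus the class label. Angle
#' channels are conditioned with a zero-lag low-pass filter before per-cycle
#' extrema are taken (`smooth_cutoff_hz`, default 6 Hz; set `NULL` to
#' disable). Set 1 values are those of the left stride containing the cycle;
#' cycles without a contralateral initial contact (undefined cadence) are
#' dropped.
#'
#' @param cohort List of [trial_recording][generate_subject] objects.
#' @param channel_source `"truth"` (the trial's own channels) or
#'   `"reference"` (the paired reference channels).
#' @param smooth_cutoff_hz Low-pass cutoff in Hz, or `NULL` for none.
#' @param outlier_rule Passed to the duration outlier rule (`"two-sided"`
#'   or `"upper"`).
#'
#' @return `data.frame` with columns `subject_id`, `cycle_index`, `label`
#'   and the ten feature columns of [feature_set_columns()], ordered by
#'   subject then cycle. Trials where no cycle survives are skipped with a
#'   warning.
#' @export
build_feature_table <- function(cohort, channel_source = c("truth", "reference"),
                                smooth_cutoff_hz = 6,
                                outlier_rule = c("two-sided", "upper")) {
  channel_source <- match.arg(channel_source)
  outlier_rule <- match.arg(outlier_rule)
  tabs <- lapply(cohort, function(trial) {
    tab <- .trial_features(trial, channel_source, smooth_cutoff_hz, outlier_rule)
    if (is.null(tab)) {
      warning(sprintf("subject %s: no retained gait cycle, skipped", trial$subject_id))
    }
    tab
  })
  tabs <- tabs[!vapply(tabs, is.null, logical(1))]
  if (!length(tabs)) {
    cols <- c("subject_id", "cycle_index", "label", feature_set_columns("all"))
    out <- as.data.frame(setNames(rep(list(numeric(0)), length(cols)), cols))
    out$subject_id <- character(0); out$label <- character(0)
    return(out)
  }
  out <- do.call(rbind, tabs)
  out <- out[order(out$subject_id, out$cycle_index), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Pairwise Pearson correlation within a feature set
#'
#' @param table A feature table from [build_feature_table()].
#' @param set `"set1"`, `"set2"` or `"all"`.
#' @return Symmetric correlation matrix with unit diagonal; zero-variance
#'   features give `NA` rows/columns and are listed in
#'   `attr(, "zero_variance")`.
#' @export
feature_correlation_matrix <- function(table, set = c("set1", "set2", "all")) {
  set <- match.arg(set)
  cols <- feature_set_columns(set)
  X <- as.matrix(table[, cols, drop = FALSE])
  if (nrow(X) < 3L) stop("need at least 3 rows to correlate features")
  sds <- apply(X, 2, stats::sd)
  flat <- cols[sds == 0]
  r <- suppressWarnings(stats::cor(X))
  if (length(flat)) {
    r[flat, ] <- NA_real_
    r[, flat] <- NA_real_
    warning(sprintf("zero-variance feature(s): %s", paste(flat, collapse = ", ")))
  }
  attr(r, "zero_variance") <- flat
  r
}
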