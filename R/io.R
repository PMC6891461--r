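# Plain-text trial I/O: tidy CSV (time_s, channel, value) plus a JSON
# sidecar carrying sampling rate, labels and ground truth.

.pos_channel_names <- function(trial) {
  unlist(lapply(names(trial$positions), function(p) paste("pos", p, c("x", "y", "z"), sep = "_")))
}

#' Write a trial to a tidy CSV with a JSON sidecar
#'
#' The CSV holds one row per (time, channel) pair with columns `time_s`,
#' `channel`, `value`; angle channels keep their names, position components
#' become `pos_<segment>_<axis>`, reference channels are prefixed `ref_`.
#' Metadata (subject, group, operated side, sampling rate, ground truth,
#' reference offsets) goes to `<path>.json`.
#'
#' @param trial A [trial_recording][generate_subject].
#' @param path Output CSV path; the sidecar is written to `paste0(path,
#'   ".json")`.
#' @return `path`, invisibly.
#' @export
write_trial_csv <- function(trial, path) {
  stopifnot(inherits(trial, "trial_recording"))
  cols <- c(trial$channels,
            setNames(
              unlist(lapply(trial$positions, function(m) lapply(1:3, function(j) m[, j])),
                     recursive = FALSE),
              .pos_channel_names(trial)))
  if (!is.null(trial$reference_channels)) {
    ref <- trial$reference_channels
    cols <- c(cols, setNames(lapply(ref, identity), paste0("ref_", names(ref))))
  }
  long <- data.frame(
    time_s = rep(trial$time, times = length(cols)),
    channel = rep(names(cols), each = length(trial$time)),
    value = unlist(cols, use.names = FALSE)
  )
  utils::write.csv(format(long, digits = 17, scientific = FALSE, trim = TRUE),
                   path, row.names = FALSE, quote = FALSE)
  meta <- list(
    subject_id = trial$subject_id, group = trial$group,
    operated_side = trial$operated_side, fs = trial$fs,
    n_samples = length(trial$time), truth = trial$truth,
    ref_offsets = if (!is.null(trial$reference_channels)) {
      as.list(attr(trial$reference_channels, "offsets"))
    }
  )
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null")
  invisible(path)
}

#' Read a trial written by [write_trial_csv()]
#'
#' Columns are matched by name, so column order in the CSV is irrelevant;
#' missing required columns raise a schema error naming the column.
#'
#' @param path CSV path with its `<path>.json` sidecar alongside.
#' @return A [trial_recording][generate_subject].
#' @export
read_trial_csv <- function(path) {
  long <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (col in c("time_s", "channel", "value")) {
    if (!col %in% names(long)) {
      stop(sprintf("trial CSV schema error: missing column '%s'", col))
    }
  }
  meta_path <- paste0(path, ".json")
  if (!file.exists(meta_path)) stop("missing sidecar JSON: ", meta_path)
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  split_vals <- split(long[order(long$time_s), ], long$channel[order(long$time_s)])
  series <- lapply(split_vals, function(d) as.numeric(d$value))
  tt <- sort(unique(as.numeric(long$time_s)))
  n <- length(tt)
  if (any(vapply(series, length, integer(1)) != n)) {
    stop("trial CSV schema error: channels of unequal length")
  }

  nms <- names(series)
  ang <- nms[!startsWith(nms, "pos_") & !startsWith(nms, "ref_")]
  channels <- series[ang]
  pos_names <- unique(sub("_[xyz]$", "", sub("^pos_", "", nms[startsWith(nms, "pos_")])))
  positions <- lapply(pos_names, function(p) {
    m <- cbind(x = series[[paste0("pos_", p, "_x")]],
               y = series[[paste0("pos_", p, "_y")]],
               z = series[[paste0("pos_", p, "_z")]])
    if (any(!is.finite(m))) stop("non-finite position values for segment ", p)
    m
  })
  names(positions) <- pos_names
  refs <- NULL
  ref_nms <- nms[startsWith(nms, "ref_")]
  if (length(ref_nms)) {
    refs <- series[ref_nms]
    names(refs) <- sub("^ref_", "", ref_nms)
    if (!is.null(meta$ref_offsets)) {
      attr(refs, "offsets") <- unlist(meta$ref_offsets)
    }
  }
  structure(list(
    subject_id = meta$subject_id, group = meta$group,
    operated_side = meta$operated_side, fs = meta$fs,
    time = tt, channels = channels, positions = positions,
    reference_channels = refs, truth = meta$truth
  ), class = "trial_recording")
}

# Deterministic CSV/JSON writers for pipeline artifacts.
write_table_csv <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) {
    format(x, digits = 15, scientific = FALSE, trim = TRUE)
  })
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

write_report_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null", force = TRUE)
  invisible(path)
}
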