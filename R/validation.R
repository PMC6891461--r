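# Feature- and waveform-validation statistics against a paired reference
# measurement: RMSE/MAE with subject-level aggregation and 95% CI, Pearson
# r and r^2, range-of-motion error, the coefficient of multiple correlation,
# and group-difference tests.

#' Paired error statistics with subject-level aggregation
#'
#' RMSE and MAE are computed per subject over that subject's paired cycles,
#' then aggregated across subjects as mean, SD and a t-based 95% confidence
#' interval of the mean (`mean +/- t(0.975, n-1) * SD / sqrt(n)`). Pearson r
#' and r^2 are pooled over all cycles.
#'
#' @param a,b Equal-length paired per-cycle values (measurement and
#'   reference).
#' @param subject Subject identifier per element.
#' @param conf_level Confidence level for the CI (default 0.95).
#'
#' @return List with `per_subject` (data.frame subject/n/rmse/mae),
#'   `rmse_mean`, `rmse_sd`, `rmse_ci`, `mae_mean`, `mae_sd`, `mae_ci`,
#'   pooled `r` and `r_squared`, `n_subjects` and `ci_method`. With fewer
#'   than two subjects SD and CI are `NA` (flagged via `ci_defined`).
#' @export
paired_error_stats <- function(a, b, subject, conf_level = 0.95) {
  stopifnot(length(a) == length(b), length(a) == length(subject), length(a) >= 1L)
  d <- a - b
  per <- do.call(rbind, lapply(split(seq_along(d), subject), function(ix) {
    data.frame(subject = subject[ix[1L]], n = length(ix),
               rmse = sqrt(mean(d[ix]^2)), mae = mean(abs(d[ix])),
               stringsAsFactors = FALSE)
  }))
  rownames(per) <- NULL
  agg <- function(x) {
    n <- length(x)
    m <- mean(x)
    if (n < 2L) {
      return(list(mean = m, sd = NA_real_, ci = c(NA_real_, NA_real_)))
    }
    s <- stats::sd(x)
    half <- stats::qt(1 - (1 - conf_level) / 2, n - 1L) * s / sqrt(n)
    list(mean = m, sd = s, ci = c(m - half, m + half))
  }
  ar <- agg(per$rmse)
  am <- agg(per$mae)
  r <- if (stats::sd(a) > 0 && stats::sd(b) > 0) stats::cor(a, b) else NA_real_
  list(
    per_subject = per,
    rmse_mean = ar$mean, rmse_sd = ar$sd, rmse_ci = ar$ci,
    mae_mean = am$mean, mae_sd = am$sd, mae_ci = am$ci,
    r = r, r_squared = r^2,
    n_subjects = nrow(per), ci_defined = nrow(per) >= 2L,
    ci_method = "t-based CI of the across-subject mean"
  )
}

#' Range-of-motion error between two paired cycles
#'
#' The absolute difference between the ranges (max minus min) of two
#' time-aligned 101-sample gait cycles. Invariant to constant offsets on
#' either cycle.
#'
#' @param cycle_a,cycle_b `gait_cycle` objects or 101-sample numeric
#'   vectors.
#' @return Non-negative scalar, in the units of the input.
#' @export
rome <- function(cycle_a, cycle_b) {
  a <- .cycle_values(cycle_a)
  b <- .cycle_values(cycle_b)
  abs((max(a) - min(a)) - (max(b) - min(b)))
}

#' Coefficient of multiple correlation of a waveform set
#'
#' Kadaba-form within-condition CMC for P waveforms of T points:
#' `sqrt(1 - [sum_t sum_p (Y_pt - Ybar_t)^2 / (T (P-1))] /
#' [sum_t sum_p (Y_pt - Ybar)^2 / (P T - 1)])`, where `Ybar_t` is the
#' across-waveform mean at time t and `Ybar` the grand mean. When the
#' waveforms differ more among themselves than the set varies overall the
#' bracketed ratio exceeds one and the CMC is undefined; it is then reported
#' as `NA` with a reason attribute rather than clamped.
#'
#' @param waveforms P-by-T numeric matrix (rows = waveforms) or a list of
#'   equal-length numeric vectors / `gait_cycle` objects, P >= 2.
#' @return Scalar in `[0, 1]`, or `NA` with `attr(, "reason")` equal to
#'   `"imaginary"` (ratio > 1) or `"zero_denominator"` (all waveforms
#'   constant and equal).
#' @export
cmc <- function(waveforms) {
  Y <- if (is.matrix(waveforms)) {
    waveforms
  } else {
    do.call(rbind, lapply(waveforms, function(w) {
      if (inherits(w, "gait_cycle")) w$values else w
    }))
  }
  P <- nrow(Y); Tn <- ncol(Y)
  if (P < 2L) stop("CMC needs at least 2 waveforms")
  ybar_t <- colMeans(Y)
  ybar <- mean(Y)
  num <- sum(sweep(Y, 2, ybar_t)^2) / (Tn * (P - 1))
  den <- sum((Y - ybar)^2) / (P * Tn - 1)
  if (den <= .Machine$double.eps) {
    return(structure(NA_real_, reason = "zero_denominator"))
  }
  ratio <- num / den
  if (ratio > 1) {
    return(structure(NA_real_, reason = "imaginary"))
  }
  sqrt(1 - ratio)
}

# Chi-square goodness-of-fit of x against a fitted normal distribution.
# Sturges bins over the sample range, tails extended to +/-Inf, adjacent
# bins merged until every expected count is >= 5; df = bins - 3 (two
# estimated parameters).
chisq_normality <- function(x, min_expected = 5) {
  n <- length(x)
  if (n < 8L || stats::sd(x) == 0) {
    return(list(statistic = NA_real_, df = NA_real_, p_value = NA_real_,
                normal = NA))
  }
  m <- mean(x); s <- stats::sd(x)
  k <- grDevices::nclass.Sturges(x)
  breaks <- seq(min(x), max(x), length.out = k + 1L)
  breaks[1L] <- -Inf; breaks[length(breaks)] <- Inf
  obs <- as.numeric(table(cut(x, breaks, include.lowest = TRUE)))
  exp_p <- diff(stats::pnorm(breaks, m, s))
  expct <- n * exp_p
  # merge low-expectation bins left to right
  i <- 1L
  while (i < length(expct)) {
    if (expct[i] < min_expected) {
      expct[i + 1L] <- expct[i + 1L] + expct[i]
      obs[i + 1L] <- obs[i + 1L] + obs[i]
      expct <- expct[-i]; obs <- obs[-i]
    } else {
      i <- i + 1L
    }
  }
  if (length(expct) > 1L && expct[length(expct)] < min_expected) {
    k2 <- length(expct)
    expct[k2 - 1L] <- expct[k2 - 1L] + expct[k2]
    obs[k2 - 1L] <- obs[k2 - 1L] + obs[k2]
    expct <- expct[-k2]; obs <- obs[-k2]
  }
  df <- length(expct) - 3L
  if (df < 1L) {
    return(list(statistic = NA_real_, df = NA_real_, p_value = NA_real_,
                normal = NA))
  }
  stat <- sum((obs - expct)^2 / expct)
  p <- stats::pchisq(stat, df, lower.tail = FALSE)
  list(statistic = stat, df = df, p_value = p, normal = p > 0.05)
}

#' Two-sample group comparison with a normality check
#'
#' Two-sample independent t-test (pooled variance by default, Welch
#' optional) between two groups of values, each group also checked for
#' normality with a chi-square goodness-of-fit test against a fitted normal
#' distribution.
#'
#' @param values_a,values_b Numeric vectors, at least two values each.
#' @param var_equal Pooled-variance t-test if `TRUE` (default); Welch
#'   otherwise.
#' @return List with `t`, `df`, `p_value`, `mean_a`, `mean_b`, and
#'   `normality_a` / `normality_b` (each the output of the chi-square
#'   check).
#' @export
compare_groups <- function(values_a, values_b, var_equal = TRUE) {
  stopifnot(length(values_a) >= 2L, length(values_b) >= 2L)
  if (stats::sd(values_a) == 0 && stats::sd(values_b) == 0) {
    same <- isTRUE(all.equal(mean(values_a), mean(values_b)))
    return(list(t = if (same) 0 else Inf,
                df = length(values_a) + length(values_b) - 2L,
                p_value = if (same) 1 else 0,
                mean_a = mean(values_a), mean_b = mean(values_b),
                normality_a = chisq_normality(values_a),
                normality_b = chisq_normality(values_b)))
  }
  tt <- stats::t.test(values_a, values_b, var.equal = var_equal)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p_value = tt$p.value, mean_a = mean(values_a), mean_b = mean(values_b),
       normality_a = chisq_normality(values_a),
       normality_b = chisq_normality(values_b))
}

#' Validate measured features against paired reference features
#'
#' Joins two per-cycle feature tables (same cohort, one computed from the
#' measurement channels and one from the paired reference channels) on
#' subject and cycle, and computes [paired_error_stats()] per feature, plus
#' a group t-test comparing the per-subject RMSE between the patient and
#' healthy groups.
#'
#' @param table_meas,table_ref Feature tables from [build_feature_table()]
#'   for the same cohort (sources `"truth"` and `"reference"`, in either
#'   order).
#' @param features Feature columns to validate (default all ten).
#' @return Object of class `validation_report`: a `data.frame` with one row
#'   per feature (RMSE/MAE mean, SD and CI bounds, pooled r and r^2, group
#'   t statistic and p-value, normality flags) plus attributes `per_feature`
#'   (the full [paired_error_stats()] objects) and `ci_method`.
#' @export
validate_features <- function(table_meas, table_ref,
                              features = feature_set_columns("all")) {
  key <- c("subject_id", "cycle_index")
  merged <- merge(table_meas[, c(key, "label", features)],
                  table_ref[, c(key, features)],
                  by = key, suffixes = c("_meas", "_ref"))
  if (!nrow(merged)) stop("no overlapping cycles between the two tables")
  merged <- merged[order(merged$subject_id, merged$cycle_index), ]
  per_feature <- list()
  rows <- lapply(features, function(f) {
    st <- paired_error_stats(merged[[paste0(f, "_meas")]],
                             merged[[paste0(f, "_ref")]],
                             merged$subject_id)
    per_feature[[f]] <<- st
    ps <- st$per_subject
    grp <- vapply(ps$subject, function(s) merged$label[match(s, merged$subject_id)],
                  character(1))
    gt <- if (sum(grp == "patient") >= 2L && sum(grp == "healthy") >= 2L) {
      compare_groups(ps$rmse[grp == "patient"], ps$rmse[grp == "healthy"])
    } else {
      list(t = NA_real_, p_value = NA_real_,
           normality_a = list(normal = NA), normality_b = list(normal = NA))
    }
    data.frame(
      feature = f,
      rmse_mean = st$rmse_mean, rmse_sd = st$rmse_sd,
      rmse_ci_low = st$rmse_ci[1L], rmse_ci_high = st$rmse_ci[2L],
      mae_mean = st$mae_mean, mae_sd = st$mae_sd,
      mae_ci_low = st$mae_ci[1L], mae_ci_high = st$mae_ci[2L],
      r = st$r, r_squared = st$r_squared,
      t_group = gt$t, p_group = gt$p_value,
      normal_patient = gt$normality_a$normal %||% NA,
      normal_healthy = gt$normality_b$normal %||% NA,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "per_feature") <- per_feature
  attr(out, "ci_method") <- "t-based CI of the across-subject mean"
  class(out) <- c("validation_report", class(out))
  out
}

#' Waveform validation: per-channel ROME and CMC against the reference
#'
#' For every trial and angle channel, segments both the measurement and the
#' paired reference series into left-referenced gait cycles, computes the
#' range-of-motion error and the two-waveform CMC per cycle, aggregates per
#' subject and then across subjects (mean, SD, t-based 95% CI), and runs the
#' patient-versus-healthy group t-test on per-subject ROME.
#'
#' @param cohort List of trials carrying reference channels.
#' @param channels Angle channels to validate (default: all nine).
#' @param smooth_cutoff_hz Low-pass cutoff applied to both series (Hz).
#' @return `data.frame` with one row per channel: `rome_mean`, `rome_sd`,
#'   `rome_ci_low/high`, `cmc_mean`, `cmc_sd`, `cmc_undefined` (count of
#'   undefined per-cycle CMCs), `t_group`, `p_group`.
#' @export
validate_waveforms <- function(cohort,
                               channels = names(cohort[[1L]]$channels),
                               smooth_cutoff_hz = 6) {
  per_subject <- list()
  for (trial in cohort) {
    if (is.null(trial$reference_channels)) {
      stop(sprintf("subject %s has no reference channels", trial$subject_id))
    }
    events <- detect_gait_events(trial)
    if (length(events$ic_left) < 2L) next
    for (ch in channels) {
      mcyc <- segment_gait_cycles(
        lowpass_filtfilt(trial$channels[[ch]], trial$fs, smooth_cutoff_hz),
        events$ic_left, trial$fs)
      rcyc <- segment_gait_cycles(
        lowpass_filtfilt(trial$reference_channels[[ch]], trial$fs, smooth_cutoff_hz),
        events$ic_left, trial$fs)
      keep <- outlier_keep_mask(vapply(mcyc, function(x) x$duration, numeric(1)))
      romes <- mapply(rome, mcyc[keep], rcyc[keep])
      cmcs <- mapply(function(a, b) as.numeric(cmc(rbind(a$values, b$values))),
                     mcyc[keep], rcyc[keep])
      per_subject[[length(per_subject) + 1L]] <- data.frame(
        subject = trial$subject_id, group = trial$group, channel = ch,
        rome = mean(romes), cmc = mean(cmcs, na.rm = TRUE),
        cmc_undefined = sum(is.na(cmcs)), stringsAsFactors = FALSE
      )
    }
  }
  ps <- do.call(rbind, per_subject)
  rows <- lapply(unique(ps$channel), function(ch) {
    sub <- ps[ps$channel == ch, ]
    n <- nrow(sub)
    s <- stats::sd(sub$rome)
    half <- if (n >= 2L) stats::qt(0.975, n - 1L) * s / sqrt(n) else NA_real_
    gt <- if (sum(sub$group == "patient") >= 2L && sum(sub$group == "healthy") >= 2L) {
      compare_groups(sub$rome[sub$group == "patient"], sub$rome[sub$group == "healthy"])
    } else {
      list(t = NA_real_, p_value = NA_real_)
    }
    data.frame(
      channel = ch, rome_mean = mean(sub$rome), rome_sd = s,
      rome_ci_low = mean(sub$rome) - half, rome_ci_high = mean(sub$rome) + half,
      cmc_mean = mean(sub$cmc, na.rm = TRUE), cmc_sd = stats::sd(sub$cmc),
      cmc_undefined = sum(sub$cmc_undefined),
      t_group = gt$t, p_group = gt$p_value, stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "per_subject") <- ps
  out
}
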