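# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Zero-lag second-order Butterworth low-pass with reflective padding.
# Used to condition angle channels before per-cycle extrema are taken;
# cutoff >= Nyquist or NULL disables filtering.
lowpass_filtfilt <- function(x, fs, cutoff) {
  if (is.null(cutoff) || !is.finite(cutoff) || cutoff <= 0 || cutoff >= fs / 2) {
    return(x)
  }
  n <- length(x)
  if (n < 10L) return(x)
  bf <- signal::butter(2, cutoff / (fs / 2), type = "low")
  pad <- min(n - 1L, as.integer(round(2 * fs)))
  xl <- 2 * x[1L] - x[(pad + 1L):2L]
  xr <- 2 * x[n] - x[(n - 1L):(n - pad)]
  y <- signal::filtfilt(bf, c(xl, x, xr))
  y[(pad + 1L):(pad + n)]
}

# Strict local maxima of a numeric vector, pruned to a minimum separation
# (in samples). Taller peaks win; boundary samples are never peaks.
find_peaks <- function(x, min_separation = NULL) {
  n <- length(x)
  if (n < 3L) return(integer(0))
  d <- diff(x)
  idx <- which(d[-length(d)] > 0 & d[-1L] <= 0) + 1L
  if (length(idx) < 2L || is.null(min_separation) || min_separation <= 0) {
    return(idx)
  }
  ord <- idx[order(x[idx], decreasing = TRUE)]
  kept <- integer(0)
  for (i in ord) {
    if (!length(kept) || all(abs(kept - i) >= min_separation)) {
      kept <- c(kept, i)
    }
  }
  sort(kept)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
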