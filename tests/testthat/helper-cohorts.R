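# Shared fixtures built in code. Default-condition cohorts are memoised so
# that several test files can reuse them without regenerating.

.fixture_cache <- new.env(parent = emptyenv())

# Cohorts at the study conditions (generator defaults), seeds 1..n.
default_cohorts <- function(n = 10L) {
  key <- paste0("cohorts_", n)
  if (is.null(.fixture_cache[[key]])) {
    .fixture_cache[[key]] <- lapply(seq_len(n), function(s) {
      generate_cohort(cohort_config(seed = s))
    })
  }
  .fixture_cache[[key]]
}

# Feature tables for the default-condition cohorts, built once.
default_tables <- function(n = 10L, source = "truth") {
  key <- paste0("tables_", source, "_", n)
  if (is.null(.fixture_cache[[key]])) {
    .fixture_cache[[key]] <- lapply(default_cohorts(n), build_feature_table,
                                    channel_source = source)
  }
  .fixture_cache[[key]]
}

# A small, fast cohort for structural tests.
small_cohort <- function(seed = 11L, n_healthy = 3L, n_patient = 3L,
                         trial_duration = 15) {
  generate_cohort(cohort_config(n_healthy = n_healthy, n_patient = n_patient,
                                trial_duration = trial_duration, seed = seed))
}

# Deterministic, jitter-free configuration whose stride times fall on the
# 60 Hz sample grid.
noiseless_config <- function(n_healthy = 2L, n_patient = 2L, seed = 5L) {
  cohort_config(n_healthy = n_healthy, n_patient = n_patient,
                trial_duration = 15,
                stride_time_sd = 0, stride_length_sd = 0,
                stride_time_jitter = 0, stride_length_jitter = 0,
                intra_subject_sd = 0, inter_subject_sd = 0,
                ref_offset_range = 0, ref_noise_sd = 0, seed = seed)
}

fake_cycles <- function(durations) {
  lapply(durations, function(d) {
    structure(list(values = rep(0, 101), duration = d,
                   channel = NA, side = NA), class = "gait_cycle")
  })
}
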