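# The end-to-end synthetic cohorts are expensive (minutes); prepare each one
# once per test session and share it across the test files that need it.
.cohort_cache <- new.env(parent = emptyenv())

cohort_config <- function(scenario, seed = 20260) {
  experiment_config(
    synthetic_cohort_specs(n_subjects = 8, scenario = scenario, seed = seed),
    windowing = windowing_config(epoch_len_s = 10, preictal_window_min = 10,
                                 baseline_gap_min = 30, seed = seed),
    seed = seed)
}

cohort_prep <- function(scenario, seed = 20260) {
  key <- paste0(scenario, "_", seed)
  if (is.null(.cohort_cache[[key]])) {
    .cohort_cache[[key]] <- prepare_features(cohort_config(scenario, seed))
  }
  .cohort_cache[[key]]
}
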