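# Frozen default cohort shared by the end-to-end tests. Generated once per
# test run and cached; every quantity derived from it is deterministic.

cohort_cache <- new.env(parent = emptyenv())

frozen_cohort <- function() {
  if (is.null(cohort_cache$cohort)) {
    cohort_cache$cohort <- generate_cohort(simulation_config(n_patients = 20,
                                                             seed = 20230712L))
  }
  cohort_cache$cohort
}

frozen_cohort_scores <- function() {
  if (is.null(cohort_cache$scores)) {
    cohort_cache$scores <- score_cohort(frozen_cohort())
  }
  cohort_cache$scores
}

frozen_cohort_samples <- function() {
  if (is.null(cohort_cache$samples)) {
    cohort_cache$samples <- sample_timepoints(frozen_cohort_scores(),
                                              cohort_events(frozen_cohort()))
  }
  cohort_cache$samples
}

# A small recording with fixed events, for unit-scale pipeline tests.
small_recording <- function(seed = 11L, duration_s = 220, lor = 60, ror = 160) {
  generate_recording(simulation_config(n_patients = 1, duration_s = duration_s,
                                       lor_time_s = lor, ror_time_s = ror,
                                       seed = seed),
                     patient_seed = seed)
}
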