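# Shared, lazily computed evaluation runs so several tests can assert on
# the same cohorts without recomputing them.

.fusionhar_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fusionhar_cache)) {
    assign(key, force(expr), envir = .fusionhar_cache)
  }
  get(key, envir = .fusionhar_cache)
}

# A small 4-subject cohort (60 s per activity) for unit-level pipeline
# checks: feature matrix plus one LOSO run per scenario of interest.
small_cohort_features <- function() {
  memo("small_fm", {
    coh <- simulate_cohort(4, default_protocol(60), seed = 424242)
    cohort_features(coh)
  })
}

small_loso <- function(scenario_id) {
  memo(paste0("small_loso_", scenario_id), {
    loso_eval(small_cohort_features(), scenario_id, seed = 99)
  })
}

# The study-condition battery: 10 subjects, 120 s per activity, five
# master seeds; LOSO for scenarios 1-4 and subject-specific for 1-3.
ACCEPTANCE_SEEDS <- 1:5

acceptance_runs <- function() {
  memo("acceptance_runs", {
    lapply(ACCEPTANCE_SEEDS, function(seed) {
      coh <- simulate_cohort(10, default_protocol(120), seed = seed)
      fm <- cohort_features(coh)
      loso <- lapply(1:4, function(sc) loso_eval(fm, sc, seed = seed))
      ss <- lapply(1:3, function(sc) {
        suppressWarnings(subject_specific_cohort_eval(fm, sc, seed = seed))
      })
      list(seed = seed, features = fm, loso = loso, subject_specific = ss)
    })
  })
}
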