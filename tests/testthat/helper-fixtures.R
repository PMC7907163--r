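# Small cohorts and pattern sets shared across test files. Everything is
# generated in code under fixed seeds; sizes are kept small so the whole
# suite stays fast.

tiny_spec <- function(seed = 42, ...) {
  args <- list(n_per_group = 3, n_roi = 20, runs_per_condition = 2,
               volumes_per_run = 80, n_group_edges = 6, n_condition_edges = 6,
               seed = seed)
  args[names(list(...))] <- list(...)
  do.call(cohort_spec, args)
}

# cached tiny cohort + patterns (built once per test run)
tiny_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- generate_cohort(tiny_spec())
    cache
  }
})

tiny_patterns <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- build_pattern_set(tiny_cohort())
    cache
  }
})

# a medium cohort with a strong planted group effect, for learning checks
medium_patterns <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      co <- generate_cohort(cohort_spec(
        n_per_group = 6, n_roi = 30, runs_per_condition = 3,
        volumes_per_run = 120, n_group_edges = 10, n_condition_edges = 10,
        seed = 7))
      cache <<- list(cohort = co, patterns = build_pattern_set(co))
    }
    cache
  }
})

quick_config <- function(seed = 1, ...) {
  args <- list(max_epochs = 24, patience = 8, k_folds = 3, seed = seed)
  args[names(list(...))] <- list(...)
  do.call(training_config, args)
}
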