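# Shared study-scale pipeline runs, computed once and reused by the
# acceptance tests (criteria 3, 4 and 5 all measure the same fitted cohorts).
# The stated world: study-sized groups (119 YA, 164 OA) and the generator's strong
# separation regime (separation = 2). MCMC is run at 30000 iterations per
# seed instead of the 100000-iteration default purely for test runtime; the
# greedy fit already reaches the optimum on these instances (checked against
# the larger budget during development).
.acc_cache <- new.env(parent = emptyenv())

acc_study_config <- function(seed) {
  cohort_config(seed = seed, separation = 2)
}

acc_pipeline_runs <- function(seeds = 1:10) {
  key <- paste0("runs_", paste(seeds, collapse = "_"))
  if (!is.null(.acc_cache[[key]])) return(.acc_cache[[key]])
  runs <- lapply(seeds, function(s) {
    sim <- generate_cohort(acc_study_config(s))
    fit <- run_ebm_pipeline(sim$cohort, seed = s, n_iter = 30000L,
                            burn_in = 3000L)
    list(sim = sim, fit = fit)
  })
  .acc_cache[[key]] <- runs
  runs
}
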