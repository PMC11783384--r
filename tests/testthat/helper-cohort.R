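# shared small synthetic cohorts, memoized so several test files can reuse
# the same simulation without regenerating it
.cohort_cache <- new.env(parent = emptyenv())

small_cohort <- function(id = "exp2", n = 3, seed = 42, preset = "biased",
                         ...) {
  key <- paste(id, n, seed, preset, ..., sep = "_")
  if (is.null(.cohort_cache[[key]])) {
    .cohort_cache[[key]] <- simulateCohort(
      buildDesign(id), n, observerPopulation(preset = preset, ...),
      master_seed = seed)
  }
  .cohort_cache[[key]]
}

training_trials <- function(...) {
  tr <- small_cohort(...)
  filterTrials(tr[tr$phase == "training", ])$trials
}

# memoized small hierarchical fit shared by ddm/validation tests
small_fit <- function(model = 10, n = 3, seed = 42, fit_seed = 7) {
  key <- paste("fit", model, n, seed, fit_seed, sep = "_")
  if (is.null(.cohort_cache[[key]])) {
    .cohort_cache[[key]] <- fitHierarchical(
      training_trials(n = n, seed = seed), model,
      mcmcConfig(n_samples = 700, burn_in = 250, thin = 2, n_chains = 2),
      seed = fit_seed)
  }
  .cohort_cache[[key]]
}

# a hand-built ddm_fit-shaped object for accessor-level tests
fake_fit <- function(subject_draws, spec_id = 10, group = NULL,
                     deviance = NULL, d_hat = NULL) {
  ns <- dim(subject_draws)[2]
  structure(list(spec = modelSpec(spec_id), group = group,
                 subject = subject_draws, deviance = deviance,
                 d_hat = d_hat, subjects = seq_len(ns), converged = TRUE,
                 conf_mapping = "proportional"),
            class = "ddm_fit")
}
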