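# Shared study definition for the analysis scripts: one synthetic
# recording session at the design scale of the decoding study
# (100 neurons, 5 initial positions x 2 saccade directions x 20 trials),
# regenerated deterministically from fixed seeds so every script is
# self-contained.

library(gazedecode)

STUDY <- list(
  n_neurons = 100,
  trials_per_condition = 20,
  pop_seed = 1,
  session_seed = 2,
  cv_seed = 15,
  gamma = 30,
  n_sets = 50,
  lags = seq(-400, 400, by = 100)
)

study_session <- function() {
  task <- task_config(trials_per_condition = STUDY$trials_per_condition)
  pop <- sample_population(STUDY$n_neurons, seed = STUDY$pop_seed)
  simulate_session(pop, task, seed = STUDY$session_seed)
}

results_dir <- function() {
  dir.create("results", showWarnings = FALSE)
  "results"
}
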