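#!/usr/bin/env Rscript
# Simulate the synthetic recording session that stands in for the
# (undeposited) macaque recordings: 100 neurons with eye-position gain
# fields, tonic position-input delays spread over -100..+200 ms, and
# direction-specific peri-saccadic transients; 10 task conditions with 20
# trials each, spikes drawn by an inhomogeneous Poisson process.

source(file.path(dirname(sub("--file=", "", grep("--file=", commandArgs(),
                                                 value = TRUE))),
                 "00_common.R"))

ses <- study_session()
print(ses)

counts <- tabulate(ses$spikes$trial_id, nbins = nrow(ses$trials))
delays <- vapply(ses$ground_truth, `[[`, numeric(1), "position_input_delay")
cat(sprintf("mean spikes/trial: %.1f; tonic delays span %.0f..%.0f ms\n",
            mean(counts), min(delays), max(delays)))

out <- results_dir()
utils::write.csv(
  data.frame(neuron = ses$neurons,
             baseline = vapply(ses$ground_truth, `[[`, numeric(1), "baseline"),
             gain_x = vapply(ses$ground_truth, `[[`, numeric(1), "gain_x"),
             gain_y = vapply(ses$ground_truth, `[[`, numeric(1), "gain_y"),
             position_input_delay = delays),
  file.path(out, "population_parameters.csv"), row.names = FALSE)

# exercise the on-disk session format on a small excerpt
dir.create("scratch", showWarnings = FALSE)
small <- simulate_session(sample_population(5, seed = STUDY$pop_seed),
                          task_config(trials_per_condition = 6), seed = 99)
write_session(small, "scratch/example_session")
back <- read_session("scratch/example_session")
stopifnot(identical(nrow(back$spikes), nrow(small$spikes)))
cat("session format round-trip ok; population table written to",
    file.path(out, "population_parameters.csv"), "\n")
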