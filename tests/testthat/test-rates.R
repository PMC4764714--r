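# Minimal hand-built session: known spikes in known trials.
toy_session <- function(spikes, n_trials = 2) {
  trials <- data.frame(
    trial_id = seq_len(n_trials),
    position_index = rep(1, n_trials),
    direction = rep(c("rightward", "downward"), length.out = n_trials)
  )
  structure(list(neurons = 1L, trials = trials, spikes = spikes,
                 time_span = c(-900, 900), task = task_config()),
            class = "spike_session")
}

test_that("binning counts spikes in half-open sliding windows", {
  sp <- data.frame(trial_id = 1, neuron_id = 1,
                   spike_time_ms = c(-20, -10, 0, 10, 20))
  tensor <- bin_rates(toy_session(sp))
  # five spikes inside the 50 ms window centred at 0 -> 100 spikes/s
  expect_equal(tensor$rates[tensor$times == 0, 1, 1], 100)
  # the window is [t - 25, t + 25): a spike exactly at the right edge is
  # excluded, one at the left edge included
  edge <- data.frame(trial_id = 1, neuron_id = 1, spike_time_ms = 25)
  te <- bin_rates(toy_session(edge))
  expect_equal(te$rates[te$times == 0, 1, 1], 0)
  expect_equal(te$rates[te$times == 50, 1, 1], 20)
  # an empty trial gives an all-zero row
  expect_true(all(tensor$rates[, 1, 2] == 0))
  # the requested span must be covered by the session
  expect_error(bin_rates(toy_session(sp), span = c(-1000, 800)), "span")
})

test_that("overlapping windows conserve the total spike count", {
  task <- small_task(6)
  ses <- simulate_session(sample_population(2, seed = 3), task, seed = 21)
  tensor <- bin_rates(ses)
  # windows stepped by their full width are disjoint and tile the span
  disj <- bin_rates(ses, window_ms = 50, step_ms = 50, span = c(-775, 775))
  for (tr in c(1, 7)) {
    for (ni in 1:2) {
      counted <- sum(disj$rates[, ni, tr]) * 0.05
      truth <- sum(ses$spikes$trial_id == tr & ses$spikes$neuron_id == ni &
                     ses$spikes$spike_time_ms >= -800 &
                     ses$spikes$spike_time_ms < 800)
      expect_equal(counted, truth)
    }
  }
})

test_that("binned rates of homogeneous Poisson spiking match the rate", {
  task <- task_config(trials_per_condition = 50)
  pop <- list(neuron_params(baseline = 40))
  ses <- simulate_session(pop, task, seed = 17)
  tensor <- bin_rates(ses)
  psth <- rowMeans(tensor$rates[, 1, ])
  n_trials <- nrow(ses$trials)
  se <- sqrt(40 / (0.05 * n_trials))
  # total spike count is Poisson with mean 40 * 1.8 s per trial
  counts <- tabulate(ses$spikes$trial_id, nbins = n_trials)
  expect_lt(abs(mean(counts) - 72), 3 * sqrt(72 / n_trials))
  # pointwise, allow a multiplicity-adjusted band across the 65 windows
  expect_lt(max(abs(psth - 40)), qnorm(1 - 0.001 / 65) * se)
})

test_that("condition averages pool trials then positions", {
  # two neurons, rates depend only on position: the pooled mean is flat
  trials <- expand.grid(position_index = 1:5,
                        direction = c("rightward", "downward"),
                        rep = 1:2, stringsAsFactors = FALSE)
  trials$trial_id <- seq_len(nrow(trials))
  n_t <- 65
  rates <- array(0, dim = c(n_t, 1, nrow(trials)))
  per_pos <- c(10, 20, 15, 15, 15)
  for (i in seq_len(nrow(trials))) {
    rates[, 1, i] <- per_pos[trials$position_index[i]]
  }
  tensor <- structure(list(times = seq(-800, 800, 25), rates = rates,
                           trials = trials[, c("trial_id", "position_index",
                                               "direction")]),
                      class = "rate_tensor")
  rm <- condition_average(tensor)
  expect_equal(unname(rm$R$rightward[, 1]), rep(15, n_t))
  expect_equal(unname(rm$R$downward[, 1]), rep(15, n_t))
  # averaging is linear: doubling all rates doubles the average
  tensor2 <- tensor
  tensor2$rates <- 2 * tensor$rates
  expect_equal(condition_average(tensor2)$R$rightward,
               2 * rm$R$rightward)
  # restricting to an empty condition fails loudly
  expect_error(condition_average(tensor, trial_ids = 1:4), "no trials")
})

test_that("condition average recovers the gain field from simulation", {
  task <- task_config(trials_per_condition = 30)
  gx <- 1.5
  pop <- list(neuron_params(baseline = 30, gain_x = gx))
  ses <- simulate_session(pop, task, seed = 23)
  rm <- condition_average(bin_rates(ses))
  pre <- rm$times < -100
  post <- rm$times > 200
  step <- mean(rm$R$rightward[post, 1]) - mean(rm$R$rightward[pre, 1])
  # post- minus pre-saccadic mean equals gain_x * 10 deg for rightward
  expect_equal(step, gx * 10, tolerance = 0.1)
  # downward saccades do not move x: no step
  step_d <- mean(rm$R$downward[post, 1]) - mean(rm$R$downward[pre, 1])
  expect_lt(abs(step_d), 1)
})

test_that("trial splits partition every condition reproducibly", {
  task <- small_task(6)
  ses <- simulate_session(sample_population(1, seed = 2), task, seed = 6)
  sp <- split_trials(ses, seed = 10)
  expect_length(intersect(sp$train, sp$test), 0)
  expect_setequal(c(sp$train, sp$test), ses$trials$trial_id)
  # 6 trials per condition -> 3/3 within every condition
  key <- paste(ses$trials$direction, ses$trials$position_index)
  for (k in unique(key)) {
    ids <- ses$trials$trial_id[key == k]
    expect_length(intersect(ids, sp$train), 3)
  }
  expect_identical(sp, split_trials(ses, seed = 10))
  # odd counts put the extra trial in the training side
  ses7 <- simulate_session(sample_population(1, seed = 2),
                           task_config(trials_per_condition = 7), seed = 6)
  sp7 <- split_trials(ses7, seed = 10)
  key7 <- paste(ses7$trials$direction, ses7$trials$position_index)
  ids <- ses7$trials$trial_id[key7 == key7[1]]
  expect_length(intersect(ids, sp7$train), 4)
  expect_length(intersect(ids, sp7$test), 3)
})
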