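test_that("eye trajectory follows the scaled cumulative Gaussian", {
  task <- task_config()
  # midpoint of the transition: Phi(0) = 0.5 scaled by the 10 deg amplitude
  tr <- eye_trajectory("rightward", c(0, 0), task, times = 25)
  expect_equal(tr$x, 5.0)
  expect_equal(tr$y, 0)
  # deep in the pre-saccadic fixation nothing has moved
  tr <- eye_trajectory("downward", c(0, 0), task, times = -800)
  expect_equal(tr$x, 0)
  expect_equal(tr$y, 0, tolerance = 1e-12)
  # normal-CDF oracle at t = 48.3 ms: 10 * Phi((48.3 - 25)/10)
  tr <- eye_trajectory("rightward", c(0, 0), task, times = 48.3)
  expect_equal(tr$x, 10 * pnorm(2.33), tolerance = 1e-6)
  # downward is stored with its physical (negative-y) sign
  tr <- eye_trajectory("downward", c(-10, 10), task, times = 800)
  expect_equal(tr$y, 10 - 10, tolerance = 1e-10)
  expect_equal(tr$x, -10)
  expect_error(eye_trajectory("leftward", c(0, 0), task, times = 0))
})

test_that("rate profile combines baseline, gain field and transients", {
  task <- task_config()
  flat <- neuron_params(baseline = 20)
  expect_equal(rate_profile(flat, "rightward", c(0, 0), task,
                            seq(-500, 500, 100)),
               rep(20, 11))
  # post-saccadic eye position of a pure x gain-field neuron
  gx <- neuron_params(baseline = 0, gain_x = 1)
  expect_equal(rate_profile(gx, "rightward", c(0, 0), task, 800), 10,
               tolerance = 1e-10)
  # time-shift identity: a +100 ms position-input delay reproduces the
  # undelayed neuron's tonic rate 100 ms earlier
  del <- neuron_params(baseline = 5, gain_x = 1, position_input_delay = 100)
  und <- neuron_params(baseline = 5, gain_x = 1)
  expect_equal(rate_profile(del, "rightward", c(0, 0), task, 25),
               rate_profile(und, "rightward", c(0, 0), task, -75))
})

test_that("rates are rectified and symmetric under direction/axis swap", {
  task <- task_config()
  times <- seq(-800, 800, 25)
  # strong negative gain would drive the linear rate negative; output is 0
  neg <- neuron_params(baseline = 1, gain_x = -5)
  expect_true(all(rate_profile(neg, "rightward", c(10, 0), task, times) >= 0))
  # swapping direction labels and the x/y roles of the gains leaves the
  # tonic response from the centre position unchanged (x steps +10 for
  # rightward; y steps -10 for downward)
  a <- neuron_params(baseline = 10, gain_x = 0.7)
  b <- neuron_params(baseline = 10, gain_y = -0.7)
  expect_equal(rate_profile(a, "rightward", c(0, 0), task, times),
               rate_profile(b, "downward", c(0, 0), task, times))
})

test_that("sampled populations honour counts, ranges and determinism", {
  pop <- sample_population(276, seed = 4)
  expect_length(pop, 276)
  # degenerate zero-width ranges give one deterministic parameter set
  one <- sample_population(1, seed = 9,
                           ranges = list(baseline = c(12, 12),
                                         gain = c(0.5, 0.5),
                                         delay = c(40, 40),
                                         transient = c(0, 0),
                                         decay = c(0, 0), bump = c(0, 0),
                                         burst = c(2, 2)))[[1]]
  expect_equal(one$baseline, 12)
  expect_equal(one$gain_x, 0.5)
  expect_equal(one$position_input_delay, 40)
  expect_true(all(one$transient_amps == 0))
  # delays from different seeds are distinct draws from U(-100, 200)
  d1 <- vapply(sample_population(300, seed = 1), `[[`, numeric(1),
               "position_input_delay")
  d2 <- vapply(sample_population(300, seed = 2), `[[`, numeric(1),
               "position_input_delay")
  expect_false(identical(d1, d2))
  expect_gt(suppressWarnings(ks.test(d1, "punif", -100, 200)$p.value), 0.01)
  expect_gt(suppressWarnings(ks.test(d2, "punif", -100, 200)$p.value), 0.01)
})

test_that("simulated sessions are Poisson with the requested intensity", {
  task <- small_task(20)
  pop <- list(neuron_params(baseline = 100))
  ses <- simulate_session(pop, task, seed = 5)
  counts <- tabulate(ses$spikes$trial_id, nbins = nrow(ses$trials))
  # 100 spikes/s over the 1.8 s span: mean 180 within 3 SE over 200 trials
  expect_equal(mean(counts), 180,
               tolerance = 3 * sqrt(180 / length(counts)) / 180)
  # identical inputs and seed give byte-identical sessions
  expect_identical(ses, simulate_session(pop, task, seed = 5))
  # silent population
  silent <- list(neuron_params(baseline = 0))
  expect_equal(nrow(simulate_session(silent, task, seed = 5)$spikes), 0)
  expect_error(simulate_session(list(), task, seed = 1), "population")
})

test_that("simulated PSTH converges to the rate profile with trials", {
  task <- small_task(6)
  lam <- 40
  pop <- list(neuron_params(baseline = lam))
  err <- vapply(c(6, 24), function(tr) {
    ses <- simulate_session(pop, task_config(trials_per_condition = tr),
                            seed = 31)
    tensor <- bin_rates(ses)
    max(abs(rowMeans(tensor$rates[, 1, ]) - lam))
  }, numeric(1))
  # 4x the trials roughly halves the worst-case PSTH deviation
  expect_lt(err[2], err[1])
  expect_lt(err[2], 4 * sqrt(lam / (0.05 * 24 * 10)))
})

test_that("sessions round-trip through the JSON + CSV on-disk format", {
  task <- small_task(6)
  pop <- sample_population(3, seed = 8)
  ses <- simulate_session(pop, task, seed = 12)
  prefix <- file.path(withr::local_tempdir(), "ses")
  write_session(ses, prefix)
  back <- read_session(prefix)
  expect_equal(back$time_span, ses$time_span)
  expect_equal(back$trials$direction, ses$trials$direction)
  expect_equal(nrow(back$spikes), nrow(ses$spikes))
  expect_equal(sort(back$spikes$spike_time_ms), sort(ses$spikes$spike_time_ms))
  gt <- back$ground_truth[[2]]
  expect_equal(gt$gain_x, pop[[2]]$gain_x, tolerance = 1e-12)
  expect_equal(gt$transient_amps, pop[[2]]$transient_amps,
               tolerance = 1e-12)
  # binning the reloaded session reproduces the original rates
  expect_equal(bin_rates(back)$rates, bin_rates(ses)$rates)
})
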