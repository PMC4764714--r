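# gazedecode

Linear population decoding of time-lagged eye-position signals from
saccade-aligned spiking activity.

Neurons in the dorsal visual stream (LIP, VIP, MT/MST) carry tonic
eye-position signals in their firing rates, plus diverse transient
modulations around saccades. This package implements a population
read-out that quantifies how much continuous eye-position information —
current, past, and future — such activity supports: a pair of
"uber-neurons" whose outputs are fixed weighted sums of instantaneous
population rates,

    X_hat(t) = R(t) %*% beta_X + c_X
    Y_hat(t) = R(t) %*% beta_Y + c_Y

with weights estimated by cross-validated ridge regression (shrinkage
gamma = 30 on z-scored predictors) against a synthetic eye-position
target: a cumulative Gaussian (mu = 25 ms + target lag, sigma = 10 ms,
10 degree amplitude) shared across both saccade directions. Sweeping the
target lag from -400 to +400 ms probes predictive and delayed
representations; cumulative-Gaussian fits to the decoded time courses
report the achieved lag and the represented saccade duration.

Because no recordings are deposited with the study this analysis style
derives from, the package ships a seeded generative stand-in: rectified
linear-gain-field neurons with per-neuron tonic position-input delays on
[-100, +200] ms and a rich bank of direction-specific peri-saccadic
transients, spiking as an inhomogeneous Poisson process. Every session
carries its ground-truth parameters so decoding results can be scored
against truth. It is intended for method development, teaching, and
power/recovery analyses — anywhere the pipeline must be exercised without
animal data.

## Worked example

```r
library(gazedecode)

task <- task_config(trials_per_condition = 20)
pop  <- sample_population(100, seed = 1)
ses  <- simulate_session(pop, task, seed = 2)
ses
#> spike_session: 100 neurons, 200 trials, 643960 spikes
#>   time span: -900 to 900 ms; 5 positions x 2 directions

tensor  <- bin_rates(ses)                      # 50 ms windows, 25 ms steps
target  <- make_target(0)                      # zero-lag eye trajectory
decoded <- cross_validate(tensor, target, gamma = 30, n_sets = 50, seed = 15)
r_squared(decoded, target)                     # 0.997
r_squared(decoded, target, "perisaccadic")     # 0.994

fit <- fit_sigmoid_joint(decoded$X_hat$rightward$mean,
                         decoded$Y_hat$downward$mean, decoded$times)
fit
#> sigmoid_fit: mu = 25.0 ms (lag -0.0), sigma = 17.2 ms
#>              (duration 79.9 ms, ratio 1.72)
```

The decoded signal tracks the true eye with no lag. Sweeping the target
lag shows which shifted representations the same population supports:

```r
sw <- lag_sweep(tensor, lags = seq(-400, 400, 100), n_sets = 50, seed = 15)
sw$table[, c("lag", "achieved_lag", "duration_ratio", "r2_peri")]
#>   lag achieved_lag duration_ratio r2_peri
#>  -400       -155.7           1.54   0.21
#>  -300       -156.7           1.51   0.16
#>  -200       -155.9           1.48   0.75
#>  -100        -99.1           1.95   0.99
#>     0         -0.0           1.72   0.99
#>   100         99.5           1.93   0.99
#>   200        196.3           1.91   0.99
#>   300        264.7           2.15   0.84
#>   400        302.0           7.89   0.58
```

Within the band -100..+200 ms the achieved lags sit on the unity line and
the represented saccade duration stays under twice the true duration;
outside it the decode either saturates (extreme negative lags settle near
-156 ms, an oblique pre-saccadic drift) or smears (ratio 7.9 at +400 ms).

The numbered scripts under `analysis/` run the full study — simulation,
direction-specific PCA with neuron bootstrap, zero-lag decoding, the lag
sweep, pooling-weight summaries, and the fixation-only ("damped") decoder
— writing tables to `results/`:

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_population_dynamics.R   # top-3 PCs: 71% of variance
Rscript analysis/03_zero_lag_decode.R
Rscript analysis/04_lag_sweep.R
Rscript analysis/05_weights.R
Rscript analysis/06_fixation_only.R         # damping +17 ms; 0 in ablation
```

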