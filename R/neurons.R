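#' Peri-saccadic transient basis
#'
#' Direction-specific firing-rate modulations, evaluated on a time grid
#' relative to saccade onset, that together span the qualitative variety of
#' peri-saccadic dynamics seen in dorsal-stream populations — broad
#' enhancement and suppression, biphasic modulation, sustained steps, and
#' heterogeneity in the precise timing and decay of the modulation across
#' neurons:
#'
#' * `plateau` — a smooth enhancement/suppression plateau that rises near
#'   -100 ms and has decayed by about +150 ms;
#' * `biphasic` — a derivative-of-Gaussian modulation centred on the
#'   saccade (one lobe before, the opposite lobe after);
#' * `step` — a sustained pre- to post-saccadic change in rate;
#' * `decay200`, `decay400` — post-saccadic modulations that relax back to
#'   baseline with time constants of 200 and 400 ms (slowly fading memory
#'   of the movement);
#' * `bump_<t>` — brief (SD 20 ms) modulations centred at 50 ms intervals
#'   from -100 to +250 ms, modelling the spread of transient timing across
#'   neurons over the epoch in which population activity is still
#'   reorganizing after the eye lands.
#'
#' Each curve has unit peak magnitude so transient amplitudes are read
#' directly in spikes/s.
#'
#' @param times numeric vector of times in ms relative to saccade onset.
#' @return numeric matrix `length(times) x 13` with the columns above.
#' @export
transient_basis <- function(times) {
  plateau <- stats::pnorm((times + 100) / 25) * (1 - stats::pnorm((times - 150) / 40))
  s <- 50
  biphasic <- ((25 - times) / s) * exp(0.5 - (times - 25)^2 / (2 * s^2))
  step <- stats::pnorm((times - 25) / 15)
  decay200 <- step * exp(-pmax(times - 25, 0) / 200)
  decay400 <- step * exp(-pmax(times - 25, 0) / 400)
  centres <- seq(-100, 250, by = 50)
  bumps <- matrix(vapply(centres, function(c0) exp(-(times - c0)^2 / (2 * 20^2)),
                         numeric(length(times))),
                  nrow = length(times),
                  dimnames = list(NULL, paste0("bump_", centres)))
  cbind(plateau = plateau, biphasic = biphasic, step = step,
        decay200 = decay200, decay400 = decay400, bumps)
}

#' Number of transient-basis components
#' @return integer, the number of columns of [transient_basis()].
#' @export
n_transients <- function() ncol(transient_basis(0))

#' Direction-nonspecific peri-saccadic burst shape
#'
#' Unit-height Gaussian bump centred on the saccade (t = 25 ms, the mean of
#' the eye trajectory), width 30 ms.
#'
#' @param times numeric vector, ms relative to saccade onset.
#' @return numeric vector of the same length.
#' @export
burst_shape <- function(times) {
  exp(-(times - 25)^2 / (2 * 30^2))
}

#' Parameters of one simulated neuron
#'
#' A neuron's firing rate combines a tonic eye-position gain field (with a
#' per-neuron temporal offset of its position input) and direction-specific
#' peri-saccadic transients:
#' `lambda(t) = max(0, baseline + gain_x * x(t - delay) + gain_y * y(t - delay)
#'  + sum_c amp[c, dir] * phi_c(t) + burst_amp * psi(t))`.
#'
#' @param baseline tonic rate in spikes/s (>= 0).
#' @param gain_x,gain_y gain-field slopes in spikes/s per degree.
#' @param position_input_delay temporal offset of the tonic position input
#'   in ms; negative values are predictive.
#' @param transient_amps numeric `n_transients() x 2` matrix (rows: the
#'   [transient_basis()] components; columns: rightward, downward) of
#'   amplitudes in spikes/s.
#' @param burst_amp amplitude of the direction-nonspecific saccadic burst,
#'   spikes/s.
#'
#' @return an object of class `neuron_params`.
#' @export
neuron_params <- function(baseline = 20, gain_x = 0, gain_y = 0,
                          position_input_delay = 0,
                          transient_amps = matrix(0, n_transients(), 2),
                          burst_amp = 0) {
  stopifnot(baseline >= 0)
  k <- n_transients()
  transient_amps <- matrix(as.numeric(transient_amps), k, 2,
                           dimnames = list(colnames(transient_basis(0)),
                                           c("rightward", "downward")))
  structure(
    list(baseline = baseline, gain_x = gain_x, gain_y = gain_y,
         position_input_delay = position_input_delay,
         transient_amps = transient_amps, burst_amp = burst_amp),
    class = "neuron_params"
  )
}

#' Instantaneous firing rate of a simulated neuron
#'
#' Evaluates the rectified-linear rate model of [neuron_params()] for one
#' task condition. The tonic gain-field term reads the eye position at
#' `t - position_input_delay`, so positive delays make the tonic input lag
#' the eye and negative delays make it predictive.
#'
#' @param neuron a [neuron_params()].
#' @param direction saccade direction.
#' @param initial_position `(x, y)` starting fixation in degrees.
#' @param task a [task_config()].
#' @param times numeric vector, ms relative to saccade onset.
#'
#' @return numeric vector of rates in spikes/s (non-negative).
#' @export
rate_profile <- function(neuron, direction, initial_position,
                         task = task_config(), times) {
  eye <- eye_trajectory(direction, initial_position, task,
                        times - neuron$position_input_delay)
  phi <- transient_basis(times)
  amps <- neuron$transient_amps[, direction]
  lam <- neuron$baseline +
    neuron$gain_x * eye$x + neuron$gain_y * eye$y +
    drop(phi %*% amps) +
    neuron$burst_amp * burst_shape(times)
  pmax(lam, 0)
}

#' Draw a population of neuron parameter sets
#'
#' Samples `n_neurons` independent [neuron_params()] from uniform
#' distributions over documented ranges. The defaults emulate recordings
#' in near darkness: low tonic baselines, eye-position gain fields of a
#' few spikes/s per degree, tonic position-input delays spread uniformly
#' over \[-100, +200\] ms (so the population as a whole carries predictive
#' through post-dictive eye-position information), moderate canonical
#' peri-saccadic motifs, pronounced slowly-decaying post-saccadic
#' modulations, and strong brief direction-specific transients whose
#' timing varies across neurons.
#'
#' @param n_neurons number of neurons (>= 1).
#' @param seed integer seed; the draw is fully reproducible.
#' @param ranges named list of `c(min, max)` ranges:
#'   `baseline` (spikes/s), `gain` (spikes/s/degree, shared by x and y),
#'   `delay` (ms, tonic position-input delay), `transient` (spikes/s; the
#'   plateau, biphasic and step components), `decay` (spikes/s; the
#'   slow post-saccadic decay components), `bump` (spikes/s; the brief
#'   timed transients), `burst` (spikes/s, direction-nonspecific).
#'   Degenerate zero-width ranges are allowed.
#'
#' @return list of `neuron_params`, length `n_neurons`.
#' @export
sample_population <- function(n_neurons, seed,
                              ranges = list()) {
  stopifnot(n_neurons >= 1)
  defaults <- list(baseline = c(5, 25), gain = c(-2, 2),
                   delay = c(-100, 200), transient = c(-8, 8),
                   decay = c(-20, 20), bump = c(-35, 35),
                   burst = c(0, 10))
  ranges <- utils::modifyList(defaults, ranges)
  runif2 <- function(n, r) stats::runif(n, r[1], r[2])
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  cn <- colnames(transient_basis(0))
  n_bump <- sum(startsWith(cn, "bump_"))
  lapply(seq_len(n_neurons), function(i) {
    draw_amps <- function() c(runif2(3, ranges$transient),
                              runif2(2, ranges$decay),
                              runif2(n_bump, ranges$bump))
    neuron_params(
      baseline = runif2(1, ranges$baseline),
      gain_x = runif2(1, ranges$gain),
      gain_y = runif2(1, ranges$gain),
      position_input_delay = runif2(1, ranges$delay),
      transient_amps = cbind(draw_amps(), draw_amps()),
      burst_amp = runif2(1, ranges$burst)
    )
  })
}

# Save/restore the global RNG state so seeded helpers do not perturb the
# caller's random stream.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  invisible(NULL)
}
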