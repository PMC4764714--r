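#' Saccade-task configuration
#'
#' Describes the oculomotor task that the synthetic sessions emulate: the
#' animal fixates one of five initial positions (arranged like the five-spot
#' on a die), then makes a 10 degree saccade either rightward or downward.
#' The eye trajectory around the saccade is modelled as a scaled cumulative
#' Gaussian with mean `saccade_mu` and standard deviation `saccade_sigma`
#' relative to saccade onset.
#'
#' @param initial_positions list of `(x, y)` fixation positions in degrees.
#' @param saccade_amplitude saccade size in degrees (> 0).
#' @param directions character vector of the two saccade directions.
#' @param fixation_duration duration of each fixation interval in ms
#'   (documentation of the task; sessions are emitted saccade-aligned).
#' @param trials_per_condition trials recorded per (position x direction)
#'   condition; must be at least 6.
#' @param saccade_mu mean of the cumulative-Gaussian eye trajectory in ms
#'   relative to saccade onset.
#' @param saccade_sigma standard deviation of the trajectory in ms.
#'
#' @return an object of class `task_config`.
#' @export
task_config <- function(initial_positions = list(c(0, 0), c(-10, 10), c(10, 10),
                                                 c(10, -10), c(-10, -10)),
                        saccade_amplitude = 10,
                        directions = c("rightward", "downward"),
                        fixation_duration = 1000,
                        trials_per_condition = 20,
                        saccade_mu = 25,
                        saccade_sigma = 10) {
  stopifnot(saccade_amplitude > 0, saccade_sigma > 0)
  if (trials_per_condition < 6) {
    stop("trials_per_condition must be at least 6", call. = FALSE)
  }
  structure(
    list(
      initial_positions = initial_positions,
      saccade_amplitude = saccade_amplitude,
      directions = directions,
      fixation_duration = fixation_duration,
      trials_per_condition = trials_per_condition,
      saccade_mu = saccade_mu,
      saccade_sigma = saccade_sigma
    ),
    class = "task_config"
  )
}

#' Eye trajectory for one trial condition
#'
#' Horizontal and vertical eye position over time for a saccade in the given
#' direction starting from `initial_position`. The moving coordinate follows
#' `x0 + A * pnorm((t - mu) / sigma)` (rightward) or
#' `y0 - A * pnorm((t - mu) / sigma)` (downward; downward is negative y and
#' is stored with its physical sign). The orthogonal coordinate is constant.
#'
#' @param direction `"rightward"` or `"downward"`.
#' @param initial_position numeric `(x, y)` in degrees.
#' @param task a [task_config()].
#' @param times sorted numeric vector of times in ms relative to saccade
#'   onset.
#'
#' @return list with numeric vectors `x` and `y` in degrees.
#' @export
eye_trajectory <- function(direction, initial_position, task = task_config(),
                           times) {
  stopifnot(is.numeric(times), !is.unsorted(times))
  direction <- match.arg(direction, c("rightward", "downward"))
  step <- task$saccade_amplitude *
    stats::pnorm((times - task$saccade_mu) / task$saccade_sigma)
  x <- rep(initial_position[[1]], length(times))
  y <- rep(initial_position[[2]], length(times))
  if (direction == "rightward") {
    x <- x + step
  } else {
    y <- y - step
  }
  list(x = x, y = y)
}
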