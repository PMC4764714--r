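#' Simulate a saccade-aligned spiking session
#'
#' Draws spike trains for every neuron in `population` on every trial of the
#' task by an inhomogeneous Poisson process. The intensity is the neuron's
#' [rate_profile()] evaluated on a 1 ms lattice and interpolated
#' piecewise-linearly; spikes are drawn by thinning against the lattice
#' maximum. Each trial uses its own seeded random stream derived from
#' `seed`, so a subset of trials re-simulates identically regardless of the
#' other trials.
#'
#' @param population list of [neuron_params()].
#' @param task a [task_config()]; its `trials_per_condition` and
#'   `initial_positions` define the trial list.
#' @param seed integer master seed.
#' @param span `c(min, max)` time span in ms relative to saccade onset over
#'   which spikes are generated; defaults pad the -800..+800 ms analysis
#'   window so 50 ms counting windows at the edges are fully covered.
#'
#' @return an object of class `spike_session`: a list with
#'   * `neurons` — integer neuron ids,
#'   * `trials` — data.frame `(trial_id, position_index, direction)`,
#'   * `spikes` — data.frame `(trial_id, neuron_id, spike_time_ms)`,
#'   * `time_span`, `task`, `ground_truth` (the generating population).
#' @export
simulate_session <- function(population, task = task_config(), seed,
                             span = c(-900, 900)) {
  if (length(population) == 0) {
    stop("population must contain at least one neuron", call. = FALSE)
  }
  stopifnot(length(span) == 2, span[1] < span[2])
  n_neurons <- length(population)
  conditions <- expand.grid(position_index = seq_along(task$initial_positions),
                            direction = task$directions,
                            stringsAsFactors = FALSE)
  trials <- conditions[rep(seq_len(nrow(conditions)),
                           each = task$trials_per_condition), ]
  trials$trial_id <- seq_len(nrow(trials))
  rownames(trials) <- NULL
  trials <- trials[, c("trial_id", "position_index", "direction")]

  lattice <- seq(span[1], span[2], by = 1)
  dur_s <- (span[2] - span[1]) / 1000

  # intensity depends only on the condition, so evaluate once per condition
  lam_by_cond <- lapply(seq_len(nrow(conditions)), function(ci) {
    pos <- task$initial_positions[[conditions$position_index[ci]]]
    vapply(population, rate_profile, numeric(length(lattice)),
           direction = conditions$direction[ci], initial_position = pos,
           task = task, times = lattice)
  })
  cond_of_trial <- match(
    paste(trials$position_index, trials$direction),
    paste(conditions$position_index, conditions$direction)
  )

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))

  spike_list <- vector("list", nrow(trials))
  for (ti in seq_len(nrow(trials))) {
    set.seed((seed + 104729 * trials$trial_id[ti]) %% .Machine$integer.max)
    lam <- lam_by_cond[[cond_of_trial[ti]]]
    lam_max <- apply(lam, 2, max)
    per_neuron <- vector("list", n_neurons)
    for (ni in seq_len(n_neurons)) {
      if (lam_max[ni] <= 0) next
      n_prop <- stats::rpois(1, lam_max[ni] * dur_s)
      if (n_prop == 0) next
      t_prop <- stats::runif(n_prop, span[1], span[2])
      lam_at <- stats::approx(lattice, lam[, ni], xout = t_prop)$y
      keep <- stats::runif(n_prop) < lam_at / lam_max[ni]
      if (!any(keep)) next
      per_neuron[[ni]] <- sort(t_prop[keep])
    }
    ns <- lengths(per_neuron)
    if (sum(ns) > 0) {
      spike_list[[ti]] <- data.frame(
        trial_id = trials$trial_id[ti],
        neuron_id = rep(seq_len(n_neurons), ns),
        spike_time_ms = unlist(per_neuron)
      )
    }
  }
  spikes <- do.call(rbind, spike_list)
  if (is.null(spikes)) {
    spikes <- data.frame(trial_id = integer(), neuron_id = integer(),
                         spike_time_ms = numeric())
  }
  rownames(spikes) <- NULL

  structure(
    list(neurons = seq_len(n_neurons), trials = trials, spikes = spikes,
         time_span = span, task = task, ground_truth = population),
    class = "spike_session"
  )
}

#' @export
print.spike_session <- function(x, ...) {
  cat("spike_session:", length(x$neurons), "neurons,",
      nrow(x$trials), "trials,", nrow(x$spikes), "spikes\n")
  cat("  time span:", x$time_span[1], "to", x$time_span[2], "ms;",
      length(x$task$initial_positions), "positions x",
      length(x$task$directions), "directions\n")
  invisible(x)
}

#' Write a session to disk
#'
#' Serialises a session as a JSON header (`<prefix>_header.json`: task,
#' neuron count, time span, and the ground-truth parameters when present)
#' plus a flat CSV of spikes (`<prefix>_spikes.csv` with columns
#' `trial_id, neuron_id, position_index, direction, spike_time_ms`).
#'
#' @param session a `spike_session`.
#' @param prefix file path prefix.
#' @return the two file paths, invisibly.
#' @export
write_session <- function(session, prefix) {
  header <- list(
    task = unclass(session$task),
    n_neurons = length(session$neurons),
    time_span = session$time_span,
    trials = session$trials,
    ground_truth = if (!is.null(session$ground_truth)) {
      lapply(session$ground_truth, function(p) {
        list(baseline = p$baseline, gain_x = p$gain_x, gain_y = p$gain_y,
             position_input_delay = p$position_input_delay,
             transient_amps = as.vector(p$transient_amps),
             burst_amp = p$burst_amp)
      })
    }
  )
  hpath <- paste0(prefix, "_header.json")
  spath <- paste0(prefix, "_spikes.csv")
  jsonlite::write_json(header, hpath, auto_unbox = TRUE, digits = NA)
  tab <- merge(session$spikes, session$trials, by = "trial_id", sort = FALSE)
  tab <- tab[order(tab$trial_id, tab$neuron_id, tab$spike_time_ms),
             c("trial_id", "neuron_id", "position_index", "direction",
               "spike_time_ms")]
  utils::write.csv(tab, spath, row.names = FALSE)
  invisible(c(header = hpath, spikes = spath))
}

#' Read a session written by [write_session()]
#'
#' @param prefix file path prefix used when writing.
#' @return a `spike_session`.
#' @export
read_session <- function(prefix) {
  header <- jsonlite::read_json(paste0(prefix, "_header.json"),
                                simplifyVector = TRUE)
  tab <- utils::read.csv(paste0(prefix, "_spikes.csv"),
                         stringsAsFactors = FALSE)
  task <- header$task
  task$initial_positions <- lapply(seq_len(nrow(task$initial_positions)),
                                   function(i) as.numeric(task$initial_positions[i, ]))
  task <- do.call(task_config, task)
  gt <- NULL
  if (!is.null(header$ground_truth) && length(header$ground_truth) > 0) {
    gt <- lapply(seq_len(nrow(header$ground_truth)), function(i) {
      p <- header$ground_truth[i, ]
      neuron_params(baseline = p$baseline, gain_x = p$gain_x,
                    gain_y = p$gain_y,
                    position_input_delay = p$position_input_delay,
                    transient_amps = matrix(unlist(p$transient_amps),
                                            n_transients(), 2),
                    burst_amp = p$burst_amp)
    })
  }
  trials <- header$trials
  spikes <- tab[, c("trial_id", "neuron_id", "spike_time_ms")]
  structure(
    list(neurons = seq_len(header$n_neurons), trials = trials,
         spikes = spikes, time_span = as.numeric(header$time_span),
         task = task, ground_truth = gt),
    class = "spike_session"
  )
}
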