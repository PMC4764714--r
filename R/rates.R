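#' Bin spike trains into per-trial firing rates
#'
#' Converts spike timestamps into instantaneous firing rates with a sliding
#' counting window: at each grid time `t` (window centres, default -800 to
#' +800 ms in 25 ms steps) the rate is the spike count in the half-open
#' window `[t - w/2, t + w/2)` divided by the window width.
#'
#' @param session a `spike_session`.
#' @param window_ms counting-window width in ms.
#' @param step_ms grid step in ms.
#' @param span `c(min, max)` of grid centres in ms.
#'
#' @return an object of class `rate_tensor`: list with `times` (grid
#'   centres), `rates` (array `time x neuron x trial`, spikes/s), and the
#'   session's `trials` table.
#' @export
bin_rates <- function(session, window_ms = 50, step_ms = 25,
                      span = c(-800, 800)) {
  times <- seq(span[1], span[2], by = step_ms)
  if (span[1] - window_ms / 2 < session$time_span[1] ||
      span[2] + window_ms / 2 > session$time_span[2]) {
    stop("binning span (plus half a window) exceeds session time_span",
         call. = FALSE)
  }
  n_t <- length(times)
  n_neurons <- length(session$neurons)
  n_trials <- nrow(session$trials)
  rates <- array(0, dim = c(n_t, n_neurons, n_trials))

  sp <- session$spikes
  if (nrow(sp) > 0) {
    grp <- (match(sp$trial_id, session$trials$trial_id) - 1L) * n_neurons +
      sp$neuron_id
    by_grp <- split(sp$spike_time_ms, grp)
    left <- times - window_ms / 2
    right <- times + window_ms / 2
    for (g in names(by_grp)) {
      s <- sort(by_grp[[g]])
      counts <- findInterval(right, s, left.open = TRUE) -
        findInterval(left, s, left.open = TRUE)
      gi <- as.integer(g) - 1L
      rates[, gi %% n_neurons + 1L, gi %/% n_neurons + 1L] <-
        counts / (window_ms / 1000)
    }
  }
  structure(list(times = times, rates = rates, trials = session$trials),
            class = "rate_tensor")
}

#' Average per-trial rates into per-direction design matrices
#'
#' Averages the per-trial rate tensor within each of the 10 task conditions
#' (5 initial positions x 2 directions), then takes the unweighted mean of
#' the 5 position conditions to give one `time x neuron` matrix per saccade
#' direction — the design matrices of the linear decoder.
#'
#' @param tensor a `rate_tensor` from [bin_rates()].
#' @param trial_ids optional integer vector restricting the average to a
#'   subset of trials (e.g. one side of a [split_trials()] partition).
#'   Every condition must retain at least one trial.
#'
#' @return an object of class `rate_matrices`: list with `times` and `R`, a
#'   named list of `time x neuron` matrices (one per direction).
#' @export
condition_average <- function(tensor, trial_ids = NULL) {
  trials <- tensor$trials
  keep <- if (is.null(trial_ids)) trials$trial_id else trial_ids
  idx <- match(keep, trials$trial_id)
  if (anyNA(idx)) stop("unknown trial ids", call. = FALSE)
  sub <- trials[idx, ]
  dirs <- unique(trials$direction)
  positions <- sort(unique(trials$position_index))
  n_t <- dim(tensor$rates)[1]
  n_neurons <- dim(tensor$rates)[2]

  R <- lapply(dirs, function(d) {
    cond_means <- vapply(positions, function(p) {
      ids <- idx[sub$direction == d & sub$position_index == p]
      if (length(ids) == 0) {
        stop(sprintf("condition (%s, position %d) has no trials", d, p),
             call. = FALSE)
      }
      sl <- tensor$rates[, , ids, drop = FALSE]
      rowMeans(matrix(sl, n_t * n_neurons, length(ids)))
    }, numeric(n_t * n_neurons))
    matrix(rowMeans(cond_means), n_t, n_neurons)
  })
  names(R) <- dirs
  structure(list(times = tensor$times, R = R), class = "rate_matrices")
}

#' Randomly partition trials into train and test halves
#'
#' Splits the trials of every (position x direction) condition at random
#' into a training and a test set. With an odd trial count the extra trial
#' goes to the training set.
#'
#' @param session a `spike_session` (or anything with a `trials` table).
#' @param fraction fraction of each condition assigned to training.
#' @param seed integer seed; the partition is reproducible.
#'
#' @return an object of class `trial_split`: list with integer vectors
#'   `train` and `test` of trial ids, and the `seed`.
#' @export
split_trials <- function(session, fraction = 0.5, seed) {
  trials <- session$trials
  key <- paste(trials$direction, trials$position_index)
  counts <- table(key)
  if (any(counts < 2)) {
    stop("every condition needs at least 2 trials to split", call. = FALSE)
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  train <- integer(0)
  for (k in unique(key)) {
    ids <- trials$trial_id[key == k]
    n_train <- ceiling(fraction * length(ids))
    train <- c(train, sample(ids, n_train))
  }
  train <- sort(train)
  structure(list(train = train,
                 test = sort(setdiff(trials$trial_id, train)),
                 seed = seed),
            class = "trial_split")
}
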