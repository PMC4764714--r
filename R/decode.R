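#' Estimate the fixed-weight linear read-out by ridge regression
#'
#' Fits the "uber-neuron" pooling weights: per-neuron weights `beta_X`,
#' `beta_Y` and constants `c_X`, `c_Y` such that
#' `X_hat(t) = R(t) %*% beta_X + c_X` (and likewise for Y) approximates the
#' target eye-position signal. The two saccade directions are concatenated
#' in time for both the design matrix and the target, so one set of weights
#' serves both directions. Following the convention of standard ridge
#' routines, predictors are z-scored, the penalty `gamma * sum(beta^2)` is
#' applied on that standardized scale (the intercept is unpenalized, via
#' centering), and the weights are rescaled to the original spikes/s units.
#' The X and Y channels are fitted independently with the same design.
#'
#' @param R_train a `rate_matrices` (training-half condition averages).
#' @param target a `target_eps` on the same time grid.
#' @param gamma ridge shrinkage parameter (>= 0) on the standardized scale.
#' @param include_times optional logical vector over the grid; rows with
#'   `FALSE` are dropped from the fit (in both directions). Used by the
#'   fixation-only decoder.
#'
#' @return an object of class `decoder_weights`: list with `beta_X`,
#'   `beta_Y` (length n-neuron, degrees s/spike), `c_X`, `c_Y` (degrees),
#'   `gamma`, and `residual_scale` (training residual SD per channel).
#' @export
fit_weights <- function(R_train, target, gamma = 30, include_times = NULL) {
  stopifnot(identical(R_train$times, target$times))
  dirs <- names(R_train$R)
  keep_t <- if (is.null(include_times)) {
    rep(TRUE, length(R_train$times))
  } else {
    include_times
  }
  if (sum(keep_t) < 2) {
    stop("need at least 2 time samples to fit weights", call. = FALSE)
  }
  Rcat <- do.call(rbind, lapply(dirs, function(d) R_train$R[[d]][keep_t, , drop = FALSE]))
  n <- ncol(Rcat)

  mu <- colMeans(Rcat)
  sdv <- apply(Rcat, 2, stats::sd)
  ok <- sdv > 0
  if (!all(ok)) {
    warning(sum(!ok), " constant neuron column(s) dropped from the fit")
  }
  Z <- sweep(sweep(Rcat[, ok, drop = FALSE], 2, mu[ok]), 2, sdv[ok], "/")
  G <- crossprod(Z) + gamma * diag(sum(ok))
  ch <- chol(G)

  fit_channel <- function(y) {
    yc <- y - mean(y)
    b_std <- backsolve(ch, forwardsolve(t(ch), crossprod(Z, yc)))
    beta <- numeric(n)
    beta[ok] <- b_std / sdv[ok]
    const <- mean(y) - sum(beta * mu)
    resid <- yc - Z %*% b_std
    list(beta = beta, const = const,
         rscale = sqrt(mean(resid^2)))
  }
  yX <- unlist(lapply(dirs, function(d) target$X[[d]][keep_t]))
  yY <- unlist(lapply(dirs, function(d) target$Y[[d]][keep_t]))
  fx <- fit_channel(yX)
  fy <- fit_channel(yY)
  structure(
    list(beta_X = fx$beta, beta_Y = fy$beta,
         c_X = fx$const, c_Y = fy$const, gamma = gamma,
         residual_scale = c(X = fx$rscale, Y = fy$rscale)),
    class = "decoder_weights"
  )
}

#' Decode eye position from rate matrices with fixed weights
#'
#' Applies the same weights to both directions' design matrices:
#' `X_hat(t) = R(t) %*% beta_X + c_X`, `Y_hat(t) = R(t) %*% beta_Y + c_Y`.
#'
#' @param R_test a `rate_matrices` (test-half condition averages).
#' @param w a `decoder_weights` fitted on the same neuron set.
#' @return list with `times` and per-direction lists `X_hat`, `Y_hat`
#'   (degrees).
#' @export
predict_eps <- function(R_test, w) {
  n <- length(w$beta_X)
  if (any(vapply(R_test$R, ncol, integer(1)) != n)) {
    stop("neuron count of R_test does not match the decoder weights",
         call. = FALSE)
  }
  list(times = R_test$times,
       X_hat = lapply(R_test$R, function(R) drop(R %*% w$beta_X) + w$c_X),
       Y_hat = lapply(R_test$R, function(R) drop(R %*% w$beta_Y) + w$c_Y))
}

#' Precompute cross-validation splits and condition averages
#'
#' Generates `n_sets` random half/half trial partitions (seeded
#' substreams of `seed`) and the train- and test-side condition averages
#' for each, so that decoders for many targets can reuse them.
#'
#' @param tensor a `rate_tensor` from [bin_rates()].
#' @param n_sets number of cross-validation sets.
#' @param seed integer master seed.
#' @param fraction training fraction per condition.
#' @return list of length `n_sets`; each element has `train` and `test`
#'   `rate_matrices`.
#' @export
cv_prepare <- function(tensor, n_sets, seed, fraction = 0.5) {
  lapply(seq_len(n_sets), function(s) {
    sp <- split_trials(tensor, fraction = fraction,
                       seed = (seed + 7717 * s) %% .Machine$integer.max)
    list(train = condition_average(tensor, sp$train),
         test = condition_average(tensor, sp$test))
  })
}

#' Cross-validated decoding of one target signal
#'
#' For each cross-validation set: fit the weights on the training-half
#' condition averages and decode the test-half averages. Reports the
#' pointwise mean and SD of the decoded signals over sets.
#'
#' @param session a `spike_session`, or a precomputed `rate_tensor`.
#' @param target a `target_eps`.
#' @param gamma ridge shrinkage.
#' @param n_sets number of random train/test partitions.
#' @param seed integer master seed (ignored if `prep` is supplied).
#' @param prep optional output of [cv_prepare()] to reuse across targets.
#' @param include_times optional logical training-row mask over the grid.
#'
#' @return an object of class `decoded_eps`: list with `times`, `n_sets`,
#'   per-direction `X_hat`/`Y_hat` (each with `mean` and `sd` vectors),
#'   `per_set` (arrays `time x set` for each channel x direction), and
#'   `weights` (`beta_X`, `beta_Y` as `neuron x set` matrices, constants
#'   per set).
#' @export
cross_validate <- function(session, target, gamma = 30, n_sets = 1000,
                           seed = 1, prep = NULL, include_times = NULL) {
  if (is.null(prep)) {
    tensor <- if (inherits(session, "rate_tensor")) session else
      bin_rates(session, span = range(target$times))
    prep <- cv_prepare(tensor, n_sets = n_sets, seed = seed)
  }
  res <- cv_decode(prep, list(target), gamma = gamma,
                   include_times = include_times)
  res[[1]]
}

#' Decode several targets over shared cross-validation sets
#'
#' Workhorse behind [cross_validate()] and [lag_sweep()]: the per-set
#' design standardization and Cholesky factor depend only on the split and
#' `gamma`, so they are computed once per set and reused for every target.
#'
#' @param prep output of [cv_prepare()].
#' @param targets list of `target_eps` on a common grid.
#' @inheritParams cross_validate
#' @return list of `decoded_eps`, one per target.
#' @export
cv_decode <- function(prep, targets, gamma = 30, include_times = NULL) {
  n_sets <- length(prep)
  times <- prep[[1]]$train$times
  dirs <- names(prep[[1]]$train$R)
  n_t <- length(times)
  n_neurons <- ncol(prep[[1]]$train$R[[1]])
  n_targets <- length(targets)

  per_set <- lapply(seq_len(n_targets), function(i) {
    list(X_hat = lapply(dirs, function(d) matrix(NA_real_, n_t, n_sets)),
         Y_hat = lapply(dirs, function(d) matrix(NA_real_, n_t, n_sets)),
         beta_X = matrix(NA_real_, n_neurons, n_sets),
         beta_Y = matrix(NA_real_, n_neurons, n_sets),
         c_X = numeric(n_sets), c_Y = numeric(n_sets))
  })
  for (i in seq_len(n_targets)) {
    names(per_set[[i]]$X_hat) <- dirs
    names(per_set[[i]]$Y_hat) <- dirs
  }

  for (s in seq_len(n_sets)) {
    train <- prep[[s]]$train
    test <- prep[[s]]$test
    for (i in seq_len(n_targets)) {
      w <- fit_weights(train, targets[[i]], gamma = gamma,
                       include_times = include_times)
      pred <- predict_eps(test, w)
      for (d in dirs) {
        per_set[[i]]$X_hat[[d]][, s] <- pred$X_hat[[d]]
        per_set[[i]]$Y_hat[[d]][, s] <- pred$Y_hat[[d]]
      }
      per_set[[i]]$beta_X[, s] <- w$beta_X
      per_set[[i]]$beta_Y[, s] <- w$beta_Y
      per_set[[i]]$c_X[s] <- w$c_X
      per_set[[i]]$c_Y[s] <- w$c_Y
    }
  }

  lapply(seq_len(n_targets), function(i) {
    ps <- per_set[[i]]
    msd <- function(M) list(mean = rowMeans(M),
                            sd = apply(M, 1, stats::sd))
    structure(
      list(times = times, n_sets = n_sets,
           target = targets[[i]],
           X_hat = lapply(ps$X_hat, msd),
           Y_hat = lapply(ps$Y_hat, msd),
           per_set = ps[c("X_hat", "Y_hat")],
           weights = ps[c("beta_X", "beta_Y", "c_X", "c_Y")]),
      class = "decoded_eps"
    )
  })
}

#' Goodness of fit of a decoded eye-position signal
#'
#' `R^2 = 1 - SSE/SST` with the error and total sums of squares pooled over
#' both channels (X, Y) and both saccade directions before the ratio. The
#' `perisaccadic` window restricts the sums to times within 100 ms of the
#' target signal's transition (`target mu +/- 100 ms`), i.e. around the
#' time the target is updated, not the animal's saccade.
#'
#' @param decoded a `decoded_eps` (its per-set mean time courses are used).
#' @param target the `target_eps` it was fitted to.
#' @param window `"full"` or `"perisaccadic"`.
#' @param peri_halfwidth half-width of the peri-saccadic window in ms.
#' @return the pooled R^2 (a fraction, possibly negative for a fit worse
#'   than the pooled mean).
#' @export
r_squared <- function(decoded, target, window = c("full", "perisaccadic"),
                      peri_halfwidth = 100) {
  window <- match.arg(window)
  stopifnot(identical(decoded$times, target$times))
  keep <- if (window == "perisaccadic") {
    abs(target$times - target$mu) <= peri_halfwidth
  } else {
    rep(TRUE, length(target$times))
  }
  dirs <- names(decoded$X_hat)
  y <- unlist(lapply(dirs, function(d) c(target$X[[d]][keep],
                                         target$Y[[d]][keep])))
  yhat <- unlist(lapply(dirs, function(d) c(decoded$X_hat[[d]]$mean[keep],
                                            decoded$Y_hat[[d]]$mean[keep])))
  sst <- sum((y - mean(y))^2)
  if (sst == 0) {
    stop("target has zero variance in the requested window; R^2 undefined",
         call. = FALSE)
  }
  1 - sum((y - yhat)^2) / sst
}

#' Decoder trained on fixation epochs only
#'
#' Re-runs the cross-validated decoding with the peri-saccadic rows removed
#' from the training design and target: times strictly within `exclusion`
#' ms of the actual saccade onset (t = 0) or offset (the 99th percentile of
#' the true eye trajectory) are excluded during weight estimation, while
#' the prediction is still emitted for the full grid. With transient
#' peri-saccadic components in the population this read-out, optimized for
#' fixation, yields a damped ("late") representation of the saccade.
#'
#' @param session a `spike_session` or `rate_tensor`.
#' @param target a `target_eps` (defaults to the zero-lag target).
#' @param gamma ridge shrinkage.
#' @param exclusion half-width of the excluded epochs in ms; `0` excludes
#'   nothing (strict inequality), reproducing [cross_validate()].
#' @param n_sets,seed,prep as in [cross_validate()].
#' @param task the task whose trajectory defines saccade onset/offset;
#'   defaults to the session's own task.
#' @return a `decoded_eps`.
#' @export
fixation_only_decoder <- function(session, target = make_target(0),
                                  gamma = 30, exclusion = 100,
                                  n_sets = 1000, seed = 1, prep = NULL,
                                  task = NULL) {
  if (is.null(task)) {
    task <- if (!is.null(session$task)) session$task else task_config()
  }
  onset <- 0
  offset <- task$saccade_mu + stats::qnorm(0.99) * task$saccade_sigma
  keep <- !(abs(target$times - onset) < exclusion |
              abs(target$times - offset) < exclusion |
              (target$times > onset & target$times < offset))
  if (exclusion == 0) keep <- rep(TRUE, length(target$times))
  if (sum(keep) < 2) {
    stop("exclusion leaves fewer than 2 training rows", call. = FALSE)
  }
  cross_validate(session, target, gamma = gamma, n_sets = n_sets,
                 seed = seed, prep = prep, include_times = keep)
}
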