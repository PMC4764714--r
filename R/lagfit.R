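#' z-width of the 1st-99th percentile interval of a Gaussian
#'
#' The represented saccade duration is defined as the interval between the
#' 1st and 99th percentile of the fitted cumulative Gaussian, i.e.
#' `duration = (qnorm(0.99) - qnorm(0.01)) * sigma = 4.6527 * sigma`.
#' @export
DURATION_Z <- stats::qnorm(0.99) - stats::qnorm(0.01)

#' Joint cumulative-Gaussian fit to the two saccade channels
#'
#' Parameterizes the decoded eye-position signal with a cumulative Gaussian
#' `offset + amplitude * pnorm((t - mu)/sigma)`. One shared parameter set
#' `(mu, sigma, amplitude, offset)` is estimated by least squares
#' simultaneously across the two saccade channels — the horizontal channel
#' for rightward saccades and the vertical channel for downward saccades,
#' the latter entering with negated amplitude (downward is negative y) —
#' by accumulating squared residuals across both. Optimization uses
#' Levenberg-Marquardt with multiple deterministic starts (the transition
#' time initialized at the half-range crossing and at fixed offsets around
#' it); the best solution by SSE is kept.
#'
#' @param xhat_rwd decoded horizontal channel for rightward saccades.
#' @param yhat_dwd decoded vertical channel for downward saccades.
#' @param times common time grid in ms.
#' @param mu0_ref transition time of the zero-lag reference in ms; the
#'   achieved lag is `mu - mu0_ref`.
#' @param true_sigma transition width of the true eye in ms, used for the
#'   duration ratio.
#' @param n_starts number of initializations.
#'
#' @return an object of class `sigmoid_fit`: `mu`, `sigma`, `amplitude`,
#'   `offset`, `achieved_lag` (`= mu - mu0_ref`), `duration`
#'   (`= DURATION_Z * sigma`), `duration_ratio`
#'   (`= duration / (DURATION_Z * true_sigma)`), `sse`, `ci_mu`,
#'   `ci_sigma` (95% intervals from the Jacobian at the optimum), and
#'   `converged`.
#' @export
fit_sigmoid_joint <- function(xhat_rwd, yhat_dwd, times, mu0_ref = 25,
                              true_sigma = 10, n_starts = 5) {
  stopifnot(length(xhat_rwd) == length(times),
            length(yhat_dwd) == length(times))
  model <- function(p, t) p[4] + p[3] * stats::pnorm((t - p[1]) / p[2])
  residfun <- function(p) {
    c(xhat_rwd - model(p, times), yhat_dwd + model(p, times))
  }
  # data-driven initialization: plateaus from the grid ends, transition
  # time from the half-range crossing of the rightward channel
  n <- length(times)
  head_i <- seq_len(max(3, n %/% 8))
  tail_i <- seq(n - max(3, n %/% 8) + 1, n)
  off0 <- stats::median(xhat_rwd[head_i])
  amp0 <- stats::median(xhat_rwd[tail_i]) - off0
  if (abs(amp0) < 1e-12) amp0 <- 1
  half <- off0 + amp0 / 2
  cross <- which.min(abs(xhat_rwd - half))
  mu_starts <- times[cross] + c(0, -100, 100, -200, 200)[seq_len(n_starts)]

  best <- NULL
  for (m0 in mu_starts) {
    fit <- tryCatch(
      minpack.lm::nls.lm(
        par = c(mu = m0, sigma = 10, amplitude = amp0, offset = off0),
        fn = residfun,
        lower = c(-Inf, 1e-3, -Inf, -Inf),
        control = minpack.lm::nls.lm.control(maxiter = 500)
      ),
      error = function(e) NULL
    )
    if (is.null(fit)) next
    sse <- fit$deviance
    if (is.null(best) || sse < best$deviance) best <- fit
  }
  if (is.null(best)) {
    stop("sigmoid fit failed to converge from any start", call. = FALSE)
  }
  p <- stats::coef(best)
  # asymptotic 95% intervals from the Jacobian at the optimum
  J <- best$fjac
  dof <- length(residfun(p)) - length(p)
  s2 <- best$deviance / max(dof, 1)
  covm <- tryCatch(s2 * solve(crossprod(J)), error = function(e) NULL)
  ci <- function(j) {
    if (is.null(covm) || covm[j, j] < 0) return(c(NA_real_, NA_real_))
    p[j] + c(-1, 1) * stats::qt(0.975, dof) * sqrt(covm[j, j])
  }
  structure(
    list(mu = unname(p["mu"]), sigma = unname(p["sigma"]),
         amplitude = unname(p["amplitude"]), offset = unname(p["offset"]),
         achieved_lag = unname(p["mu"]) - mu0_ref,
         duration = DURATION_Z * unname(p["sigma"]),
         duration_ratio = unname(p["sigma"]) / true_sigma,
         sse = best$deviance,
         ci_mu = ci(1), ci_sigma = ci(2),
         converged = best$info %in% 1:4),
    class = "sigmoid_fit"
  )
}

#' @export
print.sigmoid_fit <- function(x, ...) {
  cat(sprintf(
    "sigmoid_fit: mu = %.1f ms (lag %.1f), sigma = %.1f ms (duration %.1f ms, ratio %.2f)\n",
    x$mu, x$achieved_lag, x$sigma, x$duration, x$duration_ratio))
  invisible(x)
}

#' Per-cross-validation-set variability of the sigmoid parameters
#'
#' Refits the cumulative Gaussian to every cross-validation set's decoded
#' time courses with the amplitude and offset fixed at the values of the
#' fit to the across-set mean (`reference`), estimating only `mu` and
#' `sigma`. Non-converged sets are flagged and excluded from the variance
#' summary.
#'
#' @param decoded a `decoded_eps` retaining `per_set` time courses.
#' @param reference a `sigmoid_fit` to the across-set mean.
#' @return list with `fits` (data.frame `set, mu, sigma, converged`),
#'   `sd_mu`, `sd_sigma`, and `n_excluded`.
#' @export
fit_sigmoid_per_set <- function(decoded, reference) {
  times <- decoded$times
  A <- reference$amplitude
  off <- reference$offset
  n_sets <- decoded$n_sets
  out <- data.frame(set = seq_len(n_sets), mu = NA_real_,
                    sigma = NA_real_, converged = FALSE)
  for (s in seq_len(n_sets)) {
    x <- decoded$per_set$X_hat$rightward[, s]
    y <- decoded$per_set$Y_hat$downward[, s]
    residfun <- function(p) {
      m <- off + A * stats::pnorm((times - p[1]) / p[2])
      c(x - m, y + m)
    }
    fit <- tryCatch(
      minpack.lm::nls.lm(par = c(mu = reference$mu, sigma = reference$sigma),
                         fn = residfun, lower = c(-Inf, 1e-3),
                         control = minpack.lm::nls.lm.control(maxiter = 300)),
      error = function(e) NULL
    )
    if (!is.null(fit) && fit$info %in% 1:4) {
      out$mu[s] <- fit$par[1]
      out$sigma[s] <- fit$par[2]
      out$converged[s] <- TRUE
    }
  }
  ok <- out$converged
  list(fits = out,
       sd_mu = stats::sd(out$mu[ok]),
       sd_sigma = stats::sd(out$sigma[ok]),
       n_excluded = sum(!ok))
}

#' Direction-specific component of the decoded signals
#'
#' Difference between the two saccade directions within each channel:
#' `dX(t) = X_hat_rwd(t) - X_hat_dwd(t)` and
#' `dY(t) = Y_hat_rwd(t) - Y_hat_dwd(t)`. A decoder that drifts equally in
#' both directions before the saccade cancels here, so these series isolate
#' when truly direction-specific information emerges. Values are stored
#' unflipped (for an ideal decoder dX rises to +10 and dY to -(-10) = +10
#' only after sign conventions; here dY rises 0 to +10 because the
#' downward channel is subtracted).
#'
#' @param decoded a `decoded_eps`.
#' @return list with `times`, `dX`, `dY` (degrees).
#' @export
direction_difference <- function(decoded) {
  list(times = decoded$times,
       dX = decoded$X_hat$rightward$mean - decoded$X_hat$downward$mean,
       dY = decoded$Y_hat$rightward$mean - decoded$Y_hat$downward$mean)
}

#' Decode and parameterize a sweep of target lags
#'
#' Runs the full pipeline for every target lag on shared cross-validation
#' sets: build the lagged target, cross-validated ridge decoding, joint
#' sigmoid fits to the raw decoded channels and to the direction-specific
#' differences, and full/peri-saccadic goodness of fit.
#'
#' @param session a `spike_session` or `rate_tensor`.
#' @param lags numeric vector of target lags in ms.
#' @param gamma ridge shrinkage.
#' @param n_sets cross-validation sets (shared across lags).
#' @param seed master seed.
#' @param amplitude,mu0,sigma target-signal parameters.
#' @param times analysis grid.
#'
#' @return an object of class `lag_sweep_result`: list with `table`
#'   (one row per lag: achieved lag and duration ratio of the raw and
#'   direction-difference fits, full and peri-saccadic R^2), `decoded`
#'   (list of `decoded_eps`), `fits_raw`, `fits_diff` (lists of
#'   `sigmoid_fit`), and the call parameters.
#' @export
lag_sweep <- function(session, lags = seq(-400, 400, by = 100), gamma = 30,
                      n_sets = 1000, seed = 1, amplitude = 10, mu0 = 25,
                      sigma = 10, times = seq(-800, 800, by = 25)) {
  tensor <- if (inherits(session, "rate_tensor")) session else
    bin_rates(session, span = range(times))
  prep <- cv_prepare(tensor, n_sets = n_sets, seed = seed)
  targets <- lapply(lags, make_target, amplitude = amplitude, mu0 = mu0,
                    sigma = sigma, times = times)
  decoded <- cv_decode(prep, targets, gamma = gamma)

  fits_raw <- vector("list", length(lags))
  fits_diff <- vector("list", length(lags))
  rows <- vector("list", length(lags))
  for (i in seq_along(lags)) {
    d <- decoded[[i]]
    fits_raw[[i]] <- fit_sigmoid_joint(d$X_hat$rightward$mean,
                                       d$Y_hat$downward$mean,
                                       d$times, mu0_ref = mu0,
                                       true_sigma = sigma)
    dd <- direction_difference(d)
    # dY rises where the downward channel falls; negate to match the
    # falling-channel convention of the joint fit
    fits_diff[[i]] <- fit_sigmoid_joint(dd$dX, -dd$dY, dd$times,
                                        mu0_ref = mu0, true_sigma = sigma)
    rows[[i]] <- data.frame(
      lag = lags[i],
      achieved_lag = fits_raw[[i]]$achieved_lag,
      duration_ratio = fits_raw[[i]]$duration_ratio,
      achieved_lag_diff = fits_diff[[i]]$achieved_lag,
      duration_ratio_diff = fits_diff[[i]]$duration_ratio,
      r2_full = r_squared(d, targets[[i]], "full"),
      r2_peri = r_squared(d, targets[[i]], "perisaccadic")
    )
  }
  structure(
    list(table = do.call(rbind, rows), lags = lags, decoded = decoded,
         fits_raw = fits_raw, fits_diff = fits_diff,
         gamma = gamma, n_sets = n_sets, seed = seed),
    class = "lag_sweep_result"
  )
}

#' @export
print.lag_sweep_result <- function(x, ...) {
  cat("lag_sweep_result over", length(x$lags), "target lags,",
      x$n_sets, "cross-validation sets\n")
  print(x$table, row.names = FALSE, digits = 3)
  invisible(x)
}
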