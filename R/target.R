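#' Time-lagged eye-position regression target
#'
#' Builds the synthetic eye-position signal the decoder is trained to
#' reproduce: a scaled cumulative Gaussian with transition time
#' `mu = mu0 + lag_ms` and width `sigma`, expressed relative to the
#' starting fixation. For rightward saccades the horizontal channel rises
#' from 0 to `amplitude` degrees and the vertical channel is 0; for
#' downward saccades the vertical channel falls from 0 to `-amplitude`
#' (downward stored as negative y) and the horizontal channel is 0.
#' Negative lags are predictive targets, positive lags delayed ones.
#'
#' @param lag_ms target lag in ms relative to the true eye trajectory.
#' @param amplitude saccade amplitude in degrees.
#' @param mu0 transition time of the true eye in ms (saccade-onset
#'   alignment puts it at 25 ms).
#' @param sigma transition width in ms (> 0).
#' @param times grid in ms; defaults to the analysis grid -800..+800 at
#'   25 ms.
#'
#' @return an object of class `target_eps`: list with `lag`, `times`, `mu`
#'   (`= mu0 + lag`), `sigma`, `amplitude`, and channel list `X`/`Y`, each
#'   holding `rightward` and `downward` vectors in degrees.
#' @export
make_target <- function(lag_ms, amplitude = 10, mu0 = 25, sigma = 10,
                        times = seq(-800, 800, by = 25)) {
  if (sigma <= 0) stop("sigma must be positive", call. = FALSE)
  stopifnot(!is.unsorted(times))
  mu <- mu0 + lag_ms
  step <- amplitude * stats::pnorm((times - mu) / sigma)
  zero <- numeric(length(times))
  structure(
    list(lag = lag_ms, times = times, mu = mu, sigma = sigma,
         amplitude = amplitude,
         X = list(rightward = step, downward = zero),
         Y = list(rightward = zero, downward = -step)),
    class = "target_eps"
  )
}

#' Similarity of the time-lagged targets
#'
#' The lagged targets differ only in the timing of a brief transition and
#' share long fixation plateaus, so they are highly correlated with one
#' another. This function quantifies that: for each lag it concatenates the
#' two saccade channels (the rightward horizontal channel and the downward
#' vertical channel, the latter sign-aligned so both rise 0 to amplitude)
#' and computes the Pearson correlation for every unordered pair of lags.
#'
#' @param lags numeric vector of target lags in ms.
#' @param times grid in ms.
#' @inheritParams make_target
#'
#' @return list with the correlation `matrix`, the `mean` over unordered
#'   pairs, and the `range`.
#' @export
target_correlations <- function(lags = seq(-400, 400, by = 100),
                                times = seq(-800, 800, by = 25),
                                amplitude = 10, mu0 = 25, sigma = 10) {
  signals <- vapply(lags, function(L) {
    tg <- make_target(L, amplitude = amplitude, mu0 = mu0, sigma = sigma,
                      times = times)
    c(tg$X$rightward, -tg$Y$downward)
  }, numeric(2 * length(times)))
  colnames(signals) <- as.character(lags)
  r <- stats::cor(signals)
  up <- r[upper.tri(r)]
  list(matrix = r, mean = mean(up), range = range(up))
}
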