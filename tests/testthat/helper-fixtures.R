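# Shared fixture builders. All randomness is seeded by the caller.

# A small task: fewer trials keeps simulation cheap.
small_task <- function(trials = 6) task_config(trials_per_condition = trials)

# Build rate_matrices directly from a function of (direction, times).
make_rm <- function(fun, times = seq(-800, 800, by = 25)) {
  R <- lapply(c(rightward = "rightward", downward = "downward"),
              function(d) fun(d, times))
  structure(list(times = times, R = R), class = "rate_matrices")
}

# Wrap plain per-direction predictions as a decoded_eps (zero SD) so that
# r_squared() and the sigmoid fits can consume single-shot decodes.
as_decoded <- function(pred) {
  msd <- function(v) list(mean = v, sd = rep(0, length(v)))
  structure(list(times = pred$times, n_sets = 1,
                 X_hat = lapply(pred$X_hat, msd),
                 Y_hat = lapply(pred$Y_hat, msd)),
            class = "decoded_eps")
}

# Noiseless population whose columns span the zero-lag target: the first
# two neurons carry the pure horizontal/vertical eye-position signals, the
# rest add fixed, linearly independent nuisance time courses (frozen
# pseudo-random so the design has full column rank at gamma = 0).
spanning_rm <- function(n, seed, target = make_target(0)) {
  set.seed(seed)
  n_t <- length(target$times)
  nuis <- list(rightward = matrix(rnorm(n_t * n, sd = 2), n_t, n),
               downward = matrix(rnorm(n_t * n, sd = 2), n_t, n))
  mix <- cbind(x = runif(n, -1, 1), y = runif(n, -1, 1))
  make_rm(function(d, times) {
    sapply(seq_len(n), function(i) {
      if (i == 1) 20 + target$X[[d]]
      else if (i == 2) 20 + target$Y[[d]]
      else 20 + mix[i, "x"] * target$X[[d]] + mix[i, "y"] * target$Y[[d]] +
          nuis[[d]][, i]
    })
  }, times = target$times)
}

# Independent closed-form ridge solution (penalized normal equations on
# z-scored predictors), used as the oracle for fit_weights().
ridge_oracle <- function(rm, y_by_dir, gamma) {
  Z0 <- do.call(rbind, rm$R)
  y <- unlist(y_by_dir)
  sdv <- apply(Z0, 2, sd)
  Z <- scale(Z0)
  b <- solve(crossprod(Z) + gamma * diag(ncol(Z0)),
             crossprod(Z, y - mean(y)))
  beta <- drop(b) / sdv
  list(beta = beta, const = mean(y) - sum(beta * colMeans(Z0)))
}
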