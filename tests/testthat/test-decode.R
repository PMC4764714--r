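test_that("lagged targets place the transition at mu0 + lag", {
  tg <- make_target(0)
  expect_equal(tg$X$rightward[tg$times == 25], 5.0)
  expect_equal(tg$mu, 25)
  # a -100 ms (predictive) lag shifts the midpoint to -75 ms
  tg2 <- make_target(-100)
  expect_equal(tg2$X$rightward[tg2$times == -75], 5.0)
  # orthogonal channels are identically zero at any lag
  for (L in c(-400, 0, 300)) {
    tgl <- make_target(L)
    expect_true(all(tgl$X$downward == 0))
    expect_true(all(tgl$Y$rightward == 0))
  }
  # downward is stored negative
  expect_equal(min(tg$Y$downward), -10, tolerance = 1e-6)
  expect_error(make_target(0, sigma = 0), "sigma")
})

test_that("ridge weights equal the closed-form penalized solution", {
  times <- seq(-800, 800, 25)
  tg <- make_target(0)
  for (n in c(4, 10)) {
    set.seed(n)
    rm <- make_rm(function(d, tt)
      matrix(runif(length(tt) * n, 0, 50), length(tt), n), times)
    w <- fit_weights(rm, tg, gamma = 30)
    orx <- ridge_oracle(rm, list(tg$X$rightward, tg$X$downward), 30)
    ory <- ridge_oracle(rm, list(tg$Y$rightward, tg$Y$downward), 30)
    expect_lt(max(abs(w$beta_X - orx$beta)), 1e-8)
    expect_lt(max(abs(w$beta_Y - ory$beta)), 1e-8)
    expect_equal(w$c_X, orx$const, tolerance = 1e-8)
    expect_equal(w$c_Y, ory$const, tolerance = 1e-8)
  }
})

test_that("interpolation, shrinkage limit and weight-norm monotonicity", {
  tg <- make_target(0)
  rm <- spanning_rm(20, seed = 1, target = tg)
  # gamma = 0 with columns spanning the target: exact reproduction
  w0 <- fit_weights(rm, tg, gamma = 0)
  pred <- predict_eps(rm, w0)
  expect_equal(pred$X_hat$rightward, tg$X$rightward, tolerance = 1e-8)
  expect_equal(pred$Y_hat$downward, tg$Y$downward, tolerance = 1e-8)
  # enormous shrinkage collapses to the training-mean constant
  wbig <- fit_weights(rm, tg, gamma = 1e12)
  expect_lt(max(abs(wbig$beta_X)), 1e-8)
  predbig <- predict_eps(rm, wbig)
  m <- mean(c(tg$X$rightward, tg$X$downward))
  expect_equal(predbig$X_hat$rightward, rep(m, 65), tolerance = 1e-4)
  # ||beta||_2 never increases with gamma
  norms <- vapply(c(0, 1, 10, 30, 100, 1000), function(g) {
    sqrt(sum(fit_weights(rm, tg, gamma = g)$beta_X^2))
  }, numeric(1))
  expect_true(all(diff(norms) <= 1e-12))
})

test_that("predictions use one weight set for both directions", {
  tg <- make_target(0)
  rm <- spanning_rm(8, seed = 2, target = tg)
  w <- fit_weights(rm, tg, gamma = 30)
  pred <- predict_eps(rm, w)
  # the same beta vector is applied to both design matrices
  expect_identical(drop(rm$R$rightward %*% w$beta_X) + w$c_X,
                   pred$X_hat$rightward)
  expect_identical(drop(rm$R$downward %*% w$beta_X) + w$c_X,
                   pred$X_hat$downward)
  # zero weights and c = 3 give a constant 3 degrees
  wc <- w
  wc$beta_X <- 0 * wc$beta_X
  wc$c_X <- 3
  expect_equal(predict_eps(rm, wc)$X_hat$downward, rep(3, 65))
  # neuron mismatch is rejected
  rm5 <- spanning_rm(5, seed = 3, target = tg)
  expect_error(predict_eps(rm5, w), "neuron")
})

test_that("cross-validation is deterministic and noise-free rates give SD 0", {
  task <- small_task(6)
  ses <- simulate_session(sample_population(5, seed = 3), task, seed = 4)
  tg <- make_target(0)
  d1 <- cross_validate(ses, tg, n_sets = 2, seed = 9)
  d2 <- cross_validate(ses, tg, n_sets = 2, seed = 9)
  expect_identical(d1$X_hat, d2$X_hat)
  expect_identical(d1$weights, d2$weights)
  # identical rates in every trial: every split decodes identically
  trials <- ses$trials
  n_tr <- nrow(trials)
  rates <- array(rep(matrix(runif(65 * 5, 10, 30), 65, 5), n_tr),
                 dim = c(65, 5, n_tr))
  tensor <- structure(list(times = seq(-800, 800, 25), rates = rates,
                           trials = trials), class = "rate_tensor")
  dflat <- cross_validate(tensor, tg, n_sets = 4, seed = 2)
  expect_lt(max(dflat$X_hat$rightward$sd), 1e-10)
  expect_lt(max(dflat$Y_hat$downward$sd), 1e-10)
})

test_that("pooled R^2 matches hand computation and flags zero variance", {
  times <- 1:4
  tg <- make_target(0, times = times)
  # overwrite with the documented toy: target (0,0,10,10), decode (0,0,5,10)
  tg$X$rightward <- c(0, 0, 10, 10)
  tg$X$downward <- rep(0, 4)
  tg$Y$rightward <- rep(0, 4)
  tg$Y$downward <- rep(0, 4)
  dec <- as_decoded(list(times = times,
                         X_hat = list(rightward = c(0, 0, 5, 10),
                                      downward = rep(0, 4)),
                         Y_hat = list(rightward = rep(0, 4),
                                      downward = rep(0, 4))))
  # SSE = 25; SST pooled over all four series around the pooled mean
  y <- c(c(0, 0, 10, 10), rep(0, 12))
  sst <- sum((y - mean(y))^2)
  expect_equal(r_squared(dec, tg), 1 - 25 / sst)
  # restricting to the toy's own channel: classic 1 - 25/100
  y1 <- c(0, 0, 10, 10)
  expect_equal(1 - 25 / sum((y1 - mean(y1))^2), 0.75)
  # perfect decode and mean-only decode
  tgf <- make_target(0)
  rmf <- spanning_rm(6, seed = 5, target = tgf)
  perfect <- as_decoded(predict_eps(rmf, fit_weights(rmf, tgf, gamma = 0)))
  expect_equal(r_squared(perfect, tgf), 1, tolerance = 1e-10)
  mean_dec <- as_decoded(list(
    times = tgf$times,
    X_hat = list(rightward = rep(2.5, 65), downward = rep(2.5, 65)),
    Y_hat = list(rightward = rep(-2.5, 65), downward = rep(-2.5, 65))))
  expect_lt(abs(r_squared(mean_dec, tgf)), 0.3)
  # a flat target has no variance to explain
  tg0 <- make_target(0, amplitude = 1e-300)
  expect_error(r_squared(perfect, tg0), "variance")
})

test_that("fixation-only training with zero exclusion reproduces the default", {
  task <- small_task(6)
  ses <- simulate_session(sample_population(6, seed = 13), task, seed = 14)
  tg <- make_target(0)
  tensor <- bin_rates(ses)
  d0 <- cross_validate(tensor, tg, n_sets = 3, seed = 5)
  dfix0 <- fixation_only_decoder(tensor, tg, exclusion = 0, n_sets = 3,
                                 seed = 5, task = task)
  expect_equal(dfix0$X_hat, d0$X_hat, tolerance = 1e-12)
  # prediction is still emitted for the full grid when rows are excluded
  dfix <- fixation_only_decoder(tensor, tg, exclusion = 100, n_sets = 3,
                                seed = 5, task = task)
  expect_length(dfix$X_hat$rightward$mean, 65)
  expect_error(fixation_only_decoder(tensor, tg, exclusion = 1e6,
                                     n_sets = 3, seed = 5, task = task),
               "training rows")
})
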