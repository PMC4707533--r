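test_that("observations reflect the input mode", {
  cfg <- target_config("D3")
  trial <- withr::with_seed(1, sample_trial(cfg, "right"))
  # zero sensory noise, exact mode: the observation IS the t-th dot
  obs <- make_observation(trial, 7, "exact", sigma_s = 0, config = cfg)
  expect_equal(obs$x_px, trial$x_px[7])
  expect_equal(obs$y_px, trial$y_px[7])
  # zero noise, DDM-equivalent mode: the true target mean, at any t
  for (t in c(1, 13, 25)) {
    obs <- make_observation(trial, t, "ddm", sigma_s = 0, config = cfg)
    expect_equal(obs$x_px, 40)
    expect_equal(obs$y_px, 0)
  }
  expect_error(make_observation(trial, 26, "exact", config = cfg), "step")
  # sensory noise is isotropic with SD sigma_s
  set.seed(2)
  reps <- purrr::map(1:20000, ~ make_observation(trial, 3, "exact", 25, cfg)) |>
    purrr::list_rbind()
  expect_equal(sd(reps$x_px), 25, tolerance = 0.03)
  expect_equal(sd(reps$y_px), 25, tolerance = 0.03)
  expect_lt(abs(cor(reps$x_px, reps$y_px)), 0.03)
})

test_that("belief updating is Bayesian and respects the leak exponent", {
  cfg <- target_config("D2")
  # observation on the vertical midline: equal likelihoods leave beliefs as
  # they are under lossless accumulation
  b <- belief_update(c(0.3, 0.7), c(0, 33), cfg, discount = 1)
  expect_equal(b, c(0.3, 0.7), tolerance = 1e-12)
  # discount 0: no accumulation, beliefs depend only on the current dot
  b1 <- belief_update(c(0.999, 0.001), c(20, 5), cfg, discount = 0)
  b2 <- belief_update(c(0.001, 0.999), c(20, 5), cfg, discount = 0)
  expect_equal(b1, b2, tolerance = 1e-12)
  ll <- c(dnorm(20, -25, 70, log = TRUE), dnorm(20, 25, 70, log = TRUE))
  expect_equal(b1, exp(ll) / sum(exp(ll)), tolerance = 1e-12)
  expect_error(belief_update(c(0.5, 0.5), c(NaN, 0), cfg), "finite")
})

test_that("recursive posteriors equal the batch Bayes posterior", {
  # batch oracle: posterior from all observations at once, in closed form
  cfg <- target_config("D1")
  set.seed(8)
  for (rep in 1:20) {
    obs <- matrix(rnorm(10, 0, 80), 5, 2)
    prior <- runif(1, 0.05, 0.95)
    beliefs <- c(prior, 1 - prior)
    for (t in 1:5) beliefs <- belief_update(beliefs, obs[t, ], cfg, 1)
    log_batch <- c(
      log(prior) + sum(dnorm(obs[, 1], cfg$mu_left_x, 70, log = TRUE)),
      log(1 - prior) + sum(dnorm(obs[, 1], cfg$mu_right_x, 70, log = TRUE))
    ) + sum(dnorm(obs[, 2], 0, 70, log = TRUE))
    batch <- exp(log_batch - max(log_batch))
    batch <- batch / sum(batch)
    expect_equal(beliefs, batch, tolerance = 1e-10)
  }
})

test_that("accumulation decides at the first bound crossing", {
  cfg <- target_config("D4")
  trial <- withr::with_seed(3, sample_trial(cfg, "right"))
  # bound 0.5 + 1e-12 is crossed immediately: one belief is always >= 0.5
  p <- model_params(sigma_s = 0, bound = 0.500000001, prior_left = 0.5)
  out <- run_accumulation(trial, p, "exact", "standard", cfg)
  expect_equal(out$kind, "decided")
  expect_equal(out$t_d, 1L)
  # an overwhelming prior decides at t = 1 regardless of the dots
  p2 <- model_params(sigma_s = 0, bound = 0.9, prior_left = 1 - 1e-9)
  out2 <- run_accumulation(trial, p2, "exact", "standard", cfg)
  expect_equal(out2$choice, "left")
  expect_equal(out2$t_d, 1L)
  # trajectory bookkeeping: decided => belief at t_d >= bound at t_d
  p3 <- ref_params("D4")
  out3 <- withr::with_seed(4, run_accumulation(trial, p3, "exact", "standard", cfg))
  if (out3$kind == "decided") {
    bl <- out3$trajectory$belief_left[out3$t_d]
    b <- out3$trajectory$bound[out3$t_d]
    expect_true(max(bl, 1 - bl) >= b)
  }
  expect_true(all(abs(out3$trajectory$belief_left +
                        (1 - out3$trajectory$belief_left) - 1) < 1e-12))
})
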