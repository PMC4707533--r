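test_that("the vectorised simulator agrees with a plainly coded oracle", {
  # independent re-implementation: explicit per-step likelihood-ratio loop
  # over 2-D Gaussians, no shared code with the engine
  cfg <- target_config("D2")
  trial <- withr::with_seed(21, sample_trial(cfg, "right"))
  p <- model_params(sigma_s = 30, ndt_mu = 6, ndt_sigma = 0.2, bound = 0.75,
                    prior_left = 0.45)
  n <- 10000
  oracle_run <- function() {
    pb <- c(p$prior_left, 1 - p$prior_left)
    for (t in 1:25) {
      ox <- trial$x_px[t] + rnorm(1, 0, p$sigma_s)
      oy <- trial$y_px[t] + rnorm(1, 0, p$sigma_s)
      lik <- c(dnorm(ox, -25, 70) * dnorm(oy, 0, 70),
               dnorm(ox, 25, 70) * dnorm(oy, 0, 70))
      pb <- lik * pb
      pb <- pb / sum(pb)
      if (max(pb) >= p$bound) {
        return(c(choice = if (pb[1] > pb[2]) 1 else 2, t_d = t))
      }
    }
    c(choice = 0, t_d = NA)
  }
  set.seed(31)
  orc <- t(replicate(n, oracle_run()))
  set.seed(32)
  sim <- simulate_responses(trial, p, mode = "exact", n_reps = n)

  p_left_o <- mean(orc[, "choice"] == 1)
  p_left_s <- mean(sim$choice == "left")
  p_to_o <- mean(orc[, "choice"] == 0)
  p_to_s <- mean(sim$choice == "timeout")
  se2 <- function(pp) sqrt(2 * pp * (1 - pp) / n)
  expect_lt(abs(p_left_o - p_left_s), 4 * se2(p_left_o) + 1e-9)
  expect_lt(abs(p_to_o - p_to_s), 4 * se2(max(p_to_o, 0.001)) + 0.004)
  td_o <- mean(orc[, "t_d"], na.rm = TRUE)
  td_s <- mean(sim$t_d, na.rm = TRUE)
  se_td <- sqrt(var(orc[, "t_d"], na.rm = TRUE) * 2 / n)
  expect_lt(abs(td_o - td_s), 4 * se_td)
})

test_that("degenerate parameters give exact reaction times", {
  cfg <- target_config("D4")
  trial <- withr::with_seed(9, sample_trial(cfg, "right"))
  p <- deterministic_params(bound = 0.8, ndt_mu = log(350))
  sim <- simulate_responses(trial, p, mode = "exact", seed = 1)
  ref <- run_accumulation(trial, p, "exact", "standard", cfg)
  expect_equal(sim$choice, ref$choice)
  expect_equal(sim$t_d, ref$t_d)
  expect_equal(sim$rt_ms, ref$t_d * 93.2 + 350, tolerance = 1e-9)
})

test_that("lapse trials dominate when forced", {
  trials <- generate_trials(target_config("D1"), per_side = 50, seed = 2)
  p_to <- model_params(lapse_p = 1, lapse_to_p = 1)
  sim <- simulate_responses(trials, p_to, seed = 3)
  expect_true(all(sim$choice == "timeout"))
  expect_true(all(is.na(sim$rt_ms)))
  expect_true(all(sim$provenance == "lapse_timeout"))

  p_rand <- model_params(lapse_p = 1, lapse_to_p = 0)
  sim2 <- simulate_responses(trials, p_rand, seed = 4)
  expect_true(all(sim2$provenance == "lapse_random"))
  expect_true(all(sim2$rt_ms > 0 & sim2$rt_ms <= 25 * 93.2))
  expect_equal(mean(sim2$choice == "left"), 0.5, tolerance = 0.15)
  # uniform RT: mean near half the deadline
  expect_equal(mean(sim2$rt_ms), 25 * 93.2 / 2, tolerance = 0.1)
})

test_that("variant reductions reproduce the standard model bit for bit", {
  trials <- generate_trials(target_config(c("D1", "D3")), per_side = 25, seed = 5)
  p <- model_params(sigma_s = 45, bound = 0.8, prior_left = 0.48,
                    lapse_p = 0.05, lapse_to_p = 0.2,
                    discount = 1, stretch = 0, shape = 1.7)
  std <- simulate_responses(trials, p, variant = "standard", seed = 77)
  leak <- simulate_responses(trials, p, variant = "leaky", seed = 77)
  coll <- simulate_responses(trials, p, variant = "collapsing", seed = 77)
  expect_identical(std, leak)
  expect_identical(std, coll)
  # trajectories too
  t_std <- belief_trajectories(trials, p, variant = "standard", seed = 78)
  t_leak <- belief_trajectories(trials, p, variant = "leaky", seed = 78)
  t_coll <- belief_trajectories(trials, p, variant = "collapsing", seed = 78)
  expect_identical(t_std, t_leak)
  expect_identical(t_std, t_coll)
})

test_that("a higher bound slows decisions and reduces evidence-route errors", {
  trials <- generate_trials(target_config("D2"), per_side = 50, seed = 6)
  truth <- dplyr::distinct(trials, trial_id, true_target)
  run <- function(b0, seed) {
    p <- model_params(sigma_s = 40, bound = b0, prior_left = 0.5)
    sim <- simulate_responses(trials, p, n_reps = 40, seed = seed)
    sim <- dplyr::left_join(sim, truth, by = "trial_id")
    live <- sim[sim$choice != "timeout", ]
    c(err = mean(live$choice != live$true_target), td = mean(live$t_d))
  }
  lo <- run(0.65, 91)
  hi <- run(0.92, 92)
  expect_gt(hi["td"], lo["td"])
  expect_lt(hi["err"], lo["err"])
})

test_that("leaky accumulation discounts past evidence", {
  # with discount 0 the decision depends only on the current dot, so
  # log-odds never accumulate; with discount 1 they do
  trials <- generate_trials(target_config("D4"), per_side = 20, seed = 13)
  p_leak <- model_params(sigma_s = 0, bound = 1 - 1e-9, discount = 0)
  traj <- belief_trajectories(trials, p_leak, variant = "leaky", seed = 14)
  lo <- qlogis(traj$belief_left)
  # every step's log-odds is bounded by a single-dot contribution
  max_single <- max(abs(-2 * 55 * trials$x_px / 70^2))
  expect_lt(max(abs(lo)), max_single + 1e-6)
})
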