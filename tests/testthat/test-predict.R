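test_that("posterior predictive likelihood spans its trivial extremes", {
  cfg <- target_config("D4")
  trial <- withr::with_seed(51, sample_trial(cfg, "right"))
  p <- deterministic_params(bound = 0.75, ndt_mu = log(380))
  fit <- prior_fit(degenerate_transforms(p), mode = "exact")
  # the deterministic response of this trial
  det <- simulate_responses(trial, p, mode = "exact", seed = 1)
  expect_true(det$choice != "timeout")
  # an observation equal to the deterministic response is always matched
  ppl1 <- posterior_predictive(trial, det[, c("trial_id", "choice", "rt_ms")],
                               fit, n = 500, seed = 2)
  expect_equal(ppl1$ppl, 1)
  expect_equal(ppl1$log_ppl, 0)
  # an observation no simulation can reach hits the floor
  impossible <- tibble::tibble(trial_id = det$trial_id, choice = det$choice,
                               rt_ms = det$rt_ms + 1000)
  ppl0 <- posterior_predictive(trial, impossible, fit, n = 500, seed = 3)
  expect_equal(ppl0$ppl, 0)
  expect_equal(ppl0$log_ppl, log(1 / 501))
})

test_that("PPL estimates are consistent across simulation counts", {
  cfg <- target_config("D2")
  trial <- withr::with_seed(52, sample_trial(cfg, "left"))
  p <- ref_params("D2")
  fit <- prior_fit(degenerate_transforms(p), mode = "exact")
  obs <- simulate_responses(trial, p, mode = "exact", seed = 4)
  obs <- obs[, c("trial_id", "choice", "rt_ms")]
  small <- posterior_predictive(trial, obs, fit, n = 15000, seed = 5)
  big <- posterior_predictive(trial, obs, fit, n = 150000, seed = 6)
  se <- sqrt(big$ppl * (1 - big$ppl) / 15000)
  expect_lt(abs(small$ppl - big$ppl), 4 * se + 1e-6)
})

test_that("point predictions reproduce a deterministic response exactly", {
  cfg <- target_config("D4")
  trial <- withr::with_seed(53, sample_trial(cfg, "right"))
  p <- deterministic_params(bound = 0.75, ndt_mu = log(380))
  fit <- prior_fit(degenerate_transforms(p), mode = "exact")
  det <- simulate_responses(trial, p, mode = "exact", seed = 1)
  pred <- point_prediction(trial, fit, n = 300, seed = 7)
  expect_equal(pred$choice, det$choice)
  # modal RT bin midpoint is within half a dot duration of the true RT
  expect_lt(abs(pred$rt_ms - det$rt_ms), 93.2 / 2 + 1e-9)
})

test_that("point predictions time out when every simulation does", {
  cfg <- target_config("D1")
  trial <- withr::with_seed(54, sample_trial(cfg, "left"))
  p <- model_params(lapse_p = 1, lapse_to_p = 1)
  fit <- prior_fit(degenerate_transforms(p), mode = "exact")
  pred <- point_prediction(trial, fit, n = 200, seed = 8)
  expect_equal(pred$choice, "timeout")
  expect_true(is.na(pred$rt_ms))
})

test_that("the match table cross-tabulates model and participant correctness", {
  truth <- tibble::tibble(trial_id = 1:4,
                          true_target = c("left", "right", "left", "right"))
  resp <- tibble::tibble(trial_id = 1:4,
                         choice = c("left", "right", "left", "right"))
  # perfect agreement: all mass in the (correct, correct) cell
  mt <- match_table(resp, resp, truth)
  expect_equal(mt$match_rate, 1)
  cell <- mt$table$proportion[mt$table$model_correct &
                                mt$table$participant_correct]
  expect_equal(cell, 1)
  expect_equal(sum(mt$table$proportion), 1)

  # independent coin-flip predictions and responses: all cells near 1/4
  set.seed(55)
  n <- 20000
  truth_big <- tibble::tibble(
    trial_id = 1:n,
    true_target = sample(c("left", "right"), n, TRUE)
  )
  pred <- tibble::tibble(trial_id = 1:n,
                         choice = sample(c("left", "right"), n, TRUE))
  obs <- tibble::tibble(trial_id = 1:n,
                        choice = sample(c("left", "right"), n, TRUE))
  mt2 <- match_table(pred, obs, truth_big)
  expect_true(all(abs(mt2$table$proportion - 0.25) < 0.02))
  expect_equal(mt2$match_rate, 0.5, tolerance = 0.02)

  expect_error(match_table(pred[0, ], obs, truth_big), "empty")
})
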