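test_that("the response distance criterion matches choices and RT windows", {
  r <- function(ch, rt) tibble::tibble(choice = ch, rt_ms = rt)
  expect_true(response_distance_ok(r("left", 500), r("left", 500)))
  expect_false(response_distance_ok(r("right", 500), r("left", 500)))
  # strict inequality: a difference of exactly eps does not match
  expect_false(response_distance_ok(r("left", 546.6), r("left", 500), 46.6))
  expect_true(response_distance_ok(r("left", 546.5), r("left", 500), 46.6))
  # timeouts match timeouts, RT-free
  expect_true(response_distance_ok(r("timeout", NA), r("timeout", NA)))
  expect_false(response_distance_ok(r("timeout", NA), r("left", 300)))
  expect_false(response_distance_ok(r("left", 300), r("timeout", NA)))
})

test_that("EP-ABC matches the analytic posterior on a conjugate toy", {
  # theta ~ N(0,1); "rt" = 100*theta + N(0,50); observed rt = 150
  # posterior: precision 1 + 4 = 5, mean 4*1.5/5 = 1.2, var 0.2
  tf <- param_transform("theta", "identity", mu = 0, sigma = 1)
  obs <- tibble::tibble(choice = "left", rt_ms = 150)
  fit <- ep_abc(obs, toy_sim(100, 50), tf,
                fit_settings(eps_ms = 5, min_accepted = 5000, passes = 2,
                             damping = 1, max_proposals = 2e6,
                             batch_size = 5e4),
                seed = 101)
  expect_equal(unname(fit$mean), 1.2, tolerance = 0.05)
  expect_equal(unname(fit$cov[1, 1]), 0.2, tolerance = 0.05)
  # log evidence: N(150; 0, sqrt(50^2 + 100^2)) in closed form
  expect_equal(fit$log_evidence, dnorm(150, 0, sqrt(12500), log = TRUE),
               tolerance = 0.05)
})

test_that("an uninformative data point leaves the posterior at the prior", {
  tf <- dplyr::bind_rows(
    param_transform("a", "identity"),
    param_transform("b", "identity")
  )
  accept_all <- function(i, params) {
    tibble::tibble(choice = rep("left", nrow(params)),
                   rt_ms = rep(100, nrow(params)))
  }
  obs <- tibble::tibble(choice = "left", rt_ms = 100)
  fit <- ep_abc(obs, accept_all, tf,
                fit_settings(min_accepted = 5000, passes = 1, damping = 1,
                             batch_size = 5000),
                seed = 5)
  expect_equal(unname(fit$mean), c(0, 0), tolerance = 0.1)
  expect_equal(unname(diag(fit$cov)), c(1, 1), tolerance = 0.1)
  expect_equal(fit$acceptance, 1)
})

test_that("impossible data points are skipped with a warning", {
  tf <- param_transform("theta", "identity")
  never <- function(i, params) {
    tibble::tibble(choice = rep("right", nrow(params)),
                   rt_ms = rep(0, nrow(params)))
  }
  obs <- tibble::tibble(choice = "left", rt_ms = 100)
  st <- fit_settings(min_accepted = 50, max_proposals = 500,
                     passes = 1, max_skip_frac = 1)
  expect_warning(fit <- ep_abc(obs, never, tf, st, seed = 6), "skipped")
  expect_true(fit$skipped[1])
  expect_equal(unname(fit$mean), 0, tolerance = 1e-9) # posterior = prior
  # with a strict skip threshold the fit errors out
  expect_error(
    suppressWarnings(
      ep_abc(obs, never, tf,
             fit_settings(min_accepted = 50, max_proposals = 500,
                          passes = 1, max_skip_frac = 0.1), seed = 6)
    ),
    "failed"
  )
})

test_that("an empty dataset returns the prior with zero evidence", {
  tf <- default_transforms("standard")
  fit <- ep_abc(tibble::tibble(choice = character(), rt_ms = numeric()),
                function(i, params) stop("no data"), tf, fit_settings())
  expect_equal(unname(fit$mean), rep(0, 7))
  expect_equal(unname(fit$cov), diag(7))
  expect_equal(fit$log_evidence, 0)
})

test_that("fits are bit-reproducible given a seed", {
  cfg <- target_config("D4")
  trials <- generate_trials(cfg, per_side = 5, seed = 41)
  p <- ref_params("D4")
  resp <- simulate_responses(trials, p, seed = 42)[, c("trial_id", "choice", "rt_ms")]
  st <- fit_settings(min_accepted = 40, passes = 1, max_proposals = 4000)
  f1 <- suppressWarnings(fit_decision_model(trials, resp, settings = st, seed = 7))
  f2 <- suppressWarnings(fit_decision_model(trials, resp, settings = st, seed = 7))
  expect_identical(f1$mean, f2$mean)
  expect_identical(f1$cov, f2$cov)
  expect_identical(f1$log_evidence, f2$log_evidence)
  # posterior covariance is symmetric PSD
  expect_equal(f1$cov, t(f1$cov))
  expect_true(all(eigen(f1$cov, symmetric = TRUE)$values > 0))
  # and tidy/glance expose the broom-style surface
  ti <- tidy(f1)
  expect_equal(ti$term, default_transforms("standard")$name)
  expect_true(all(ti$conf.low <= ti$estimate & ti$estimate <= ti$conf.high))
  gl <- glance(f1)
  expect_equal(gl$n_trials, nrow(resp))
})

test_that("rejection ABC recovers the prior when the tolerance is huge", {
  tf <- param_transform("theta", "identity")
  obs <- tibble::tibble(choice = "left", rt_ms = 0)
  rej <- rejection_abc(obs, toy_sim(100, 50), tf, eps_ms = 1e9,
                       n_samples = 2e4, seed = 9)
  expect_equal(rej$acceptance_rate, 1)
  expect_equal(mean(rej$z), 0, tolerance = 0.03)
  expect_equal(sd(rej$z), 1, tolerance = 0.03)
})

test_that("rejection ABC with a deterministic simulator accepts exactly the matching draws", {
  tf <- param_transform("theta", "identity")
  step_sim <- function(i, params) {
    tibble::tibble(choice = rep("left", nrow(params)),
                   rt_ms = 100 * (params$theta > 0))
  }
  obs <- tibble::tibble(choice = "left", rt_ms = 100)
  rej <- rejection_abc(obs, step_sim, tf, eps_ms = 1, n_samples = 2e4, seed = 10)
  expect_true(all(rej$z > 0))
  expect_equal(rej$acceptance_rate, 0.5, tolerance = 0.02)
  # zero acceptances error out
  obs2 <- tibble::tibble(choice = "right", rt_ms = 100)
  expect_error(rejection_abc(obs2, step_sim, tf, 1, 1000, seed = 11),
               "no acceptances")
})

test_that("EP-ABC and rejection ABC agree on a one-trial problem", {
  tf <- param_transform("theta", "identity")
  obs <- tibble::tibble(choice = "left", rt_ms = 120)
  sim <- toy_sim(100, 60)
  rej <- rejection_abc(obs, sim, tf, eps_ms = 20, n_samples = 1e5, seed = 12)
  fit <- ep_abc(obs, sim, tf,
                fit_settings(eps_ms = 20, min_accepted = 3000, passes = 2,
                             damping = 1, batch_size = 2e4,
                             max_proposals = 1e6),
                seed = 13)
  expect_equal(unname(fit$mean), mean(rej$z), tolerance = 0.06)
  expect_equal(sqrt(fit$cov[1, 1]), sd(rej$z), tolerance = 0.06)
})
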