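# Shared fixtures, built in code.

# Parameter set of the reference fits for one condition and input mode.
ref_params <- function(cond, mode = "exact") {
  ref <- reference_params(mode)
  ref <- ref[ref$condition == cond, ]
  model_params(
    sigma_s = ref$sigma_s, ndt_mu = ref$ndt_mu, ndt_sigma = ref$ndt_sigma,
    bound = ref$bound, prior_left = ref$prior_left,
    lapse_p = ref$lapse_p, lapse_to_p = ref$lapse_to_p
  )
}

# A parameter set that makes the simulator fully deterministic: no sensory
# noise, (almost) point-mass NDT, no lapses.
deterministic_params <- function(bound = 0.8, prior_left = 0.5,
                                 ndt_mu = log(400)) {
  model_params(sigma_s = 0, ndt_mu = ndt_mu, ndt_sigma = 0,
               bound = bound, prior_left = prior_left,
               lapse_p = 0, lapse_to_p = 0)
}

# Transforms that pin every decision-model parameter at (roughly) a constant,
# making posterior draws degenerate.
degenerate_transforms <- function(params) {
  bind_rows_tf <- function(...) dplyr::bind_rows(...)
  bind_rows_tf(
    param_transform("sigma_s", "exponential",
                    mu = log(max(params$sigma_s, 1e-12)), sigma = 1e-9),
    param_transform("ndt_mu", "identity", mu = params$ndt_mu, sigma = 1e-9),
    param_transform("ndt_sigma", "exponential",
                    mu = log(max(params$ndt_sigma, 1e-12)), sigma = 1e-9),
    param_transform("bound", "uniform", offset = params$bound - 1e-9,
                    range = 2e-9),
    param_transform("prior_left", "uniform",
                    offset = params$prior_left - 1e-9, range = 2e-9),
    param_transform("lapse_p", "uniform",
                    offset = max(params$lapse_p - 1e-9, 0), range = 2e-9),
    param_transform("lapse_to_p", "uniform",
                    offset = max(params$lapse_to_p - 1e-9, 0), range = 2e-9)
  )
}

# An epabc_fit whose posterior is the prior (no data), used to drive the
# posterior-predictive machinery with known parameter draws.
prior_fit <- function(transforms, mode = "exact", variant = "standard") {
  fit <- ep_abc(tibble::tibble(choice = character(), rt_ms = numeric()),
                function(i, params) stop("never called"),
                transforms, fit_settings(min_accepted = 1))
  fit$model <- list(mode = mode, variant = variant, ndt_deadline = FALSE)
  fit
}

# Linear-Gaussian toy simulator: one scalar parameter theta with prior
# N(0, 1) (identity transform), simulated "RT" = scale * theta + noise.
toy_sim <- function(scale = 100, noise_sd = 50) {
  function(i, params) {
    n <- nrow(params)
    tibble::tibble(choice = rep("left", n),
                   rt_ms = scale * params$theta + rnorm(n, 0, noise_sd))
  }
}
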