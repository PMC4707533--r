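#' Decision-model parameters
#'
#' Constructs (and validates) a one-row tibble holding the free parameters of
#' the Bayesian response model in natural units. The seven core parameters
#' are shared by all accumulation variants; `discount` is active in the leaky
#' variant, `stretch` and `shape` in the collapsing-bound variant.
#'
#' @param sigma_s Sensory noise SD in pixels (>= 0): isotropic Gaussian noise
#'   added to the stimulus-driven observation means.
#' @param ndt_mu Location of the log-normal non-decision time, on the log-ms
#'   scale.
#' @param ndt_sigma Scale of the log-normal non-decision time (>= 0).
#' @param bound Confidence bound on the posterior belief, in (0.5, 1] (the
#'   initial bound for the collapsing variant).
#' @param prior_left A-priori probability that the dots come from the left
#'   target, in (0, 1); 0.5 is unbiased, values below 0.5 favour `right`.
#' @param lapse_p Probability that a trial is a lapse (answered at random or
#'   timed out irrespective of the evidence), in \[0, 1\].
#' @param lapse_to_p Probability that a lapse trial times out, in \[0, 1\].
#' @param discount Leak exponent on the previous posterior belief, in
#'   \[0, 1\]; 1 is lossless accumulation, 0 no accumulation.
#' @param stretch Collapse fraction of the time-varying bound, in \[0, 1\];
#'   0 keeps the bound fixed, 1 collapses it fully to 0.5 at the deadline.
#' @param shape Collapse-timing parameter (> 0); values below ~1 collapse
#'   early, above ~1 late.
#' @return A one-row tibble with the ten parameter columns.
#' @examples
#' model_params(sigma_s = 38.22, bound = 0.88, prior_left = 0.42)
#' @export
model_params <- function(sigma_s = 50,
                         ndt_mu = log(400),
                         ndt_sigma = 0.3,
                         bound = 0.8,
                         prior_left = 0.5,
                         lapse_p = 0,
                         lapse_to_p = 0,
                         discount = 1,
                         stretch = 0,
                         shape = 1) {
  p <- tibble(
    sigma_s = sigma_s, ndt_mu = ndt_mu, ndt_sigma = ndt_sigma,
    bound = bound, prior_left = prior_left,
    lapse_p = lapse_p, lapse_to_p = lapse_to_p,
    discount = discount, stretch = stretch, shape = shape
  )
  validate_params(p)
  p
}

param_names <- function(variant = c("standard", "leaky", "collapsing")) {
  variant <- arg_match(variant)
  core <- c("sigma_s", "ndt_mu", "ndt_sigma", "bound", "prior_left",
            "lapse_p", "lapse_to_p")
  switch(variant,
    standard = core,
    leaky = c(core, "discount"),
    collapsing = c(core, "stretch", "shape")
  )
}

validate_params <- function(p) {
  chk <- function(ok, msg) if (!all(ok)) abort(paste0("invalid parameters: ", msg))
  chk(p$sigma_s >= 0, "sigma_s must be >= 0")
  chk(p$ndt_sigma >= 0, "ndt_sigma must be >= 0")
  chk(p$bound > 0.5 - 1e-12 & p$bound <= 1, "bound must be in (0.5, 1]")
  chk(p$prior_left > 0 & p$prior_left < 1, "prior_left must be in (0, 1)")
  chk(p$lapse_p >= 0 & p$lapse_p <= 1, "lapse_p must be in [0, 1]")
  chk(p$lapse_to_p >= 0 & p$lapse_to_p <= 1, "lapse_to_p must be in [0, 1]")
  chk(p$discount >= 0 & p$discount <= 1, "discount must be in [0, 1]")
  chk(p$stretch >= 0 & p$stretch <= 1, "stretch must be in [0, 1]")
  chk(p$shape > 0, "shape must be > 0")
  invisible(p)
}

#' Mode and SD of the log-normal non-decision time
#'
#' Converts the log-normal parameters `(ndt_mu, ndt_sigma)` into the summary
#' used when reporting fits: the mode `exp(ndt_mu - ndt_sigma^2)` and the
#' standard deviation `sqrt((exp(ndt_sigma^2) - 1) * exp(2*ndt_mu +
#' ndt_sigma^2))`, both in ms.
#'
#' @param ndt_mu,ndt_sigma Log-normal location (log-ms) and scale.
#' @return A tibble with columns `mode_ms` and `sd_ms`.
#' @examples
#' ndt_summary(log(400), 0.3)
#' @export
ndt_summary <- function(ndt_mu, ndt_sigma) {
  stopifnot(all(ndt_sigma >= 0))
  tibble(
    mode_ms = exp(ndt_mu - ndt_sigma^2),
    sd_ms = sqrt((exp(ndt_sigma^2) - 1) * exp(2 * ndt_mu + ndt_sigma^2))
  )
}

#' Log-normal parameters from a non-decision-time mode and SD
#'
#' Numerically inverts [ndt_summary()]: given a mode and SD in ms, recovers
#' the `(ndt_mu, ndt_sigma)` of the log-normal distribution with exactly that
#' mode and SD. Needed to drive simulations from reported fits, which quote
#' the NDT as mode and SD.
#'
#' @param mode_ms Mode of the non-decision time in ms (> 0).
#' @param sd_ms Standard deviation in ms (>= 0).
#' @return A tibble with columns `ndt_mu` and `ndt_sigma`.
#' @examples
#' p <- ndt_params_from_summary(399.35, 167.54)
#' ndt_summary(p$ndt_mu, p$ndt_sigma) # round-trips
#' @export
ndt_params_from_summary <- function(mode_ms, sd_ms) {
  stopifnot(all(mode_ms > 0), all(sd_ms >= 0))
  one <- function(m, s) {
    if (s == 0) return(c(log(m), 0))
    # for fixed sigma, mu = log(m) + sigma^2; solve the SD identity in sigma
    f <- function(sig) {
      mu <- log(m) + sig^2
      sqrt((exp(sig^2) - 1) * exp(2 * mu + sig^2)) - s
    }
    sol <- tryCatch(
      uniroot(f, lower = 1e-8, upper = 5, tol = 1e-12),
      error = function(e) abort(paste0(
        "ndt_params_from_summary failed to converge for mode=", m,
        ", sd=", s, ": ", conditionMessage(e)
      ))
    )
    sig <- sol$root
    c(log(m) + sig^2, sig)
  }
  res <- purrr::map2(mode_ms, sd_ms, one)
  tibble(
    ndt_mu = map_dbl(res, 1),
    ndt_sigma = map_dbl(res, 2)
  )
}

#' Reference fitted parameter sets per difficulty level
#'
#' Mean fitted parameter values of the standard-accumulation decision model
#' for each difficulty level of the original dot-tracking cohort, for both
#' input modes. These drive the parameter-based simulation checks and the
#' `"table"` truth mode of [cohort_spec()]. The non-decision time is quoted
#' as mode and SD in ms; `ndt_mu`/`ndt_sigma` columns hold the corresponding
#' log-normal parameters (via [ndt_params_from_summary()]).
#'
#' @param mode Input mode the parameters were fitted under: `"exact"`
#'   (exact input model) or `"ddm"` (DDM-equivalent model).
#' @return A tibble with one row per condition D1-D4 and the decision-model
#'   parameter columns.
#' @examples
#' reference_params("exact")
#' @export
reference_params <- function(mode = c("exact", "ddm")) {
  mode <- arg_match(mode)
  base <- if (mode == "exact") {
    tibble(
      condition = c("D1", "D2", "D3", "D4"),
      sigma_s = c(95.63, 58.27, 52.10, 38.22),
      ndt_mode_ms = c(520.73, 415.96, 382.16, 399.35),
      ndt_sd_ms = c(201.66, 181.27, 172.54, 167.54),
      bound = c(0.65, 0.77, 0.87, 0.88),
      prior_left = c(0.47, 0.47, 0.44, 0.42),
      lapse_p = c(0.02, 0.02, 0.02, 0.02),
      lapse_to_p = c(0.24, 0.17, 0.18, 0.15)
    )
  } else {
    tibble(
      condition = c("D1", "D2", "D3", "D4"),
      sigma_s = c(236.70, 76.90, 70.73, 51.29),
      ndt_mode_ms = c(563.26, 453.31, 431.24, 430.51),
      ndt_sd_ms = c(195.17, 121.61, 137.60, 164.97),
      bound = c(0.71, 0.74, 0.83, 0.83),
      prior_left = c(0.46, 0.46, 0.46, 0.43),
      lapse_p = c(0.03, 0.03, 0.02, 0.03),
      lapse_to_p = c(0.24, 0.16, 0.18, 0.14)
    )
  }
  ndt <- ndt_params_from_summary(base$ndt_mode_ms, base$ndt_sd_ms)
  base |>
    mutate(
      ndt_mu = ndt$ndt_mu, ndt_sigma = ndt$ndt_sigma,
      discount = 1, stretch = 0, shape = 1,
      .after = "ndt_sd_ms"
    )
}
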