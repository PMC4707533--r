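#' Observations entering the decision model
#'
#' Generates the noisy observation the decision model receives at step `t` of
#' a trial. In `"exact"` mode (exact input model, ExaM) the observation mean
#' is the actual dot position shown at step `t`; in `"ddm"` mode
#' (DDM-equivalent model) it is the fixed location of the true target,
#' regardless of `t`. Isotropic Gaussian sensory noise with SD `sigma_s` is
#' added in both modes.
#'
#' @param trial One trial in long form (rows = dots), as from
#'   [sample_trial()].
#' @param t Step index, 1-based, at most the number of dots.
#' @param mode `"exact"` or `"ddm"`.
#' @param sigma_s Sensory noise SD in pixels.
#' @param config Optional single-row [target_config()]; inferred from the
#'   trial's condition label when omitted.
#' @return A tibble with one row: `t`, `x_px`, `y_px`.
#' @export
make_observation <- function(trial, t, mode = c("exact", "ddm"), sigma_s = 0,
                             config = NULL) {
  mode <- arg_match(mode)
  if (is.null(config)) config <- target_config(trial$condition[[1]])
  if (length(t) != 1 || t < 1 || t > nrow(trial)) {
    abort("`t` must be a single step within the trial's dot sequence")
  }
  if (mode == "exact") {
    row <- trial[trial$dot_index == t, ]
    if (nrow(row) != 1) abort("`t` out of range for this trial")
    mu <- c(row$x_px, row$y_px)
  } else {
    mu_x <- if (trial$true_target[[1]] == "left") config$mu_left_x else config$mu_right_x
    mu <- c(mu_x, config$mu_y)
  }
  obs <- mu + rnorm(2, 0, sigma_s)
  tibble(t = t, x_px = obs[1], y_px = obs[2])
}

#' One recursive belief update
#'
#' Updates the posterior beliefs over the two targets after one observation.
#' The new beliefs are proportional to the likelihood of the observation
#' under each target's generative density (isotropic Gaussian, mean at the
#' target, SD `sigma_stim`) times the previous beliefs raised to the leak
#' exponent `discount`, renormalised. With `discount = 1` this is exact
#' Bayesian accumulation; with `discount = 0` the beliefs reflect the current
#' likelihood only. At the first step the previous posterior is the prior.
#' Beliefs are clamped to `[1e-12, 1 - 1e-12]` before renormalisation for
#' numerical safety.
#'
#' @param beliefs Length-2 numeric `(left, right)` summing to 1.
#' @param obs Length-2 numeric observation `(x, y)` in pixels.
#' @param config Single-row [target_config()].
#' @param discount Leak exponent in \[0, 1\].
#' @return Updated length-2 belief vector.
#' @examples
#' cfg <- target_config("D4")
#' belief_update(c(0.5, 0.5), c(55, 0), cfg)
#' @export
belief_update <- function(beliefs, obs, config, discount = 1) {
  if (!all(is.finite(obs))) abort("observation must be finite")
  stopifnot(length(beliefs) == 2, abs(sum(beliefs) - 1) < 1e-9)
  b <- pmin(pmax(beliefs, 1e-12), 1 - 1e-12)
  s <- config$sigma_stim
  ll <- c(
    dnorm(obs[1], config$mu_left_x, s, log = TRUE) +
      dnorm(obs[2], config$mu_y, s, log = TRUE),
    dnorm(obs[1], config$mu_right_x, s, log = TRUE) +
      dnorm(obs[2], config$mu_y, s, log = TRUE)
  )
  lw <- discount * log(b) + ll
  w <- exp(lw - max(lw))
  w / sum(w)
}

#' Run the evidence accumulation of a single trial
#'
#' Iterates observation generation and belief updating over the dots of one
#' trial and reports the first bound crossing. The decision step `t_d` counts
#' observed dots (1-based); if no belief reaches the bound within the trial's
#' dots the outcome is `no_crossing` (a timeout, absent lapses).
#'
#' @param trial One trial in long form.
#' @param params One-row parameter tibble from [model_params()].
#' @param mode `"exact"` or `"ddm"`.
#' @param variant `"standard"`, `"leaky"` or `"collapsing"`. The standard
#'   variant forces `discount = 1` and `stretch = 0`.
#' @param config Optional [target_config()] row; inferred when omitted.
#' @return A list with `kind` (`"decided"` or `"no_crossing"`), `choice`
#'   (`"left"`, `"right"` or `NA`), `t_d`, and `trajectory`: a tibble of
#'   `t`, `belief_left`, `bound`.
#' @export
run_accumulation <- function(trial, params,
                             mode = c("exact", "ddm"),
                             variant = c("standard", "leaky", "collapsing"),
                             config = NULL) {
  mode <- arg_match(mode); variant <- arg_match(variant)
  if (is.null(config)) config <- target_config(trial$condition[[1]])
  validate_params(params)
  p <- apply_variant(params, variant)
  T <- nrow(trial)
  beliefs <- c(p$prior_left, 1 - p$prior_left)
  traj <- tibble(t = seq_len(T), belief_left = NA_real_, bound = NA_real_)
  outcome <- list(kind = "no_crossing", choice = NA_character_, t_d = NA_integer_)
  for (t in seq_len(T)) {
    obs <- make_observation(trial, t, mode, p$sigma_s, config)
    beliefs <- belief_update(beliefs, c(obs$x_px, obs$y_px), config, p$discount)
    b_t <- bound_value(t, config$max_dots, p$bound, p$stretch, p$shape)
    traj$belief_left[t] <- beliefs[1]
    traj$bound[t] <- b_t
    if (is.na(outcome$t_d) && max(beliefs) >= b_t) {
      ch <- if (beliefs[1] > beliefs[2]) "left"
            else if (beliefs[2] > beliefs[1]) "right"
            else sample(c("left", "right"), 1)
      outcome <- list(kind = "decided", choice = ch, t_d = t)
    }
  }
  c(outcome, list(trajectory = traj))
}

# Resolve variant-gated parameters: the standard variant accumulates
# losslessly with a fixed bound whatever the inactive columns say.
apply_variant <- function(params, variant) {
  p <- as.list(params[1, ])
  if (variant == "standard") { p$discount <- 1; p$stretch <- 0 }
  if (variant == "leaky") p$stretch <- 0
  if (variant == "collapsing") p$discount <- 1
  p
}
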