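# Vectorised simulation engine.
#
# Simulates n responses in one shot, either many trials under one parameter
# set or one trial under many parameter sets (proposals). Works on the
# log-odds of the left target: for mirror-symmetric targets at +/- o with a
# shared isotropic generative SD sigma_stim, the vertical coordinate cancels
# from the likelihood ratio and each observation contributes the increment
#   delta = -2 * o * x_obs / sigma_stim^2
# to log(P(left)/P(right)). Leak multiplies the previous log-odds by the
# discount; a crossing happens when |log-odds| reaches the logit of the
# (possibly collapsing) bound.
#
# Arguments are length-n vectors or scalars; xh is the n x T matrix of
# observation means (dot x-positions in exact mode, the true target x in
# ddm mode). Returns a list of vectors.
sim_engine <- function(xh, offset, par, sigma_stim, dt_ms, t_max,
                       ndt_deadline = FALSE, return_logodds = FALSE) {
  n <- nrow(xh); T <- ncol(xh)
  stopifnot(T == t_max)
  g <- function(v) rep_len(v, n)
  sigma_s <- g(par$sigma_s); prior_left <- g(par$prior_left)
  discount <- g(par$discount)
  offset <- g(offset)

  LMAX <- qlogis(1 - 1e-12) # belief floor of 1e-12 on either side

  obs <- xh + sigma_s * matrix(rnorm(n * T), n, T)
  delta <- (-2 * offset / sigma_stim^2) * obs
  L <- matrix(0, n, T)
  prev <- qlogis(pmin(pmax(prior_left, 1e-12), 1 - 1e-12))
  if (all(discount == 1)) {
    for (t in seq_len(T)) {
      prev <- pmin(pmax(prev + delta[, t], -LMAX), LMAX)
      L[, t] <- prev
    }
  } else {
    for (t in seq_len(T)) {
      prev <- pmin(pmax(discount * prev + delta[, t], -LMAX), LMAX)
      L[, t] <- prev
    }
  }

  th <- bound_logit_matrix(n, T, g(par$bound), g(par$stretch), g(par$shape))
  crossed <- abs(L) >= th
  t_d <- max.col(crossed, ties.method = "first")
  decided <- crossed[cbind(seq_len(n), t_d)]
  lo_at <- L[cbind(seq_len(n), t_d)]
  coin <- runif(n) < 0.5 # tie-break at exactly zero log-odds (bound = 0.5)
  choice <- ifelse(lo_at > 0 | (lo_at == 0 & coin), "left", "right")

  ndt <- rlnorm(n, g(par$ndt_mu), g(par$ndt_sigma))
  rt <- t_d * dt_ms + ndt
  timeout <- !decided
  if (ndt_deadline) timeout <- timeout | (rt > t_max * dt_ms)

  provenance <- rep("evidence", n)
  u <- runif(n); v <- runif(n)
  lapse <- u < g(par$lapse_p)
  lapse_to <- lapse & (v < g(par$lapse_to_p))
  lapse_resp <- lapse & !lapse_to
  lap_choice <- ifelse(runif(n) < 0.5, "left", "right")
  lap_rt <- runif(n, 0, t_max * dt_ms)
  choice[lapse_resp] <- lap_choice[lapse_resp]
  rt[lapse_resp] <- lap_rt[lapse_resp]
  timeout[lapse_resp] <- FALSE
  timeout[lapse_to] <- TRUE
  provenance[lapse_resp] <- "lapse_random"
  provenance[lapse_to] <- "lapse_timeout"

  choice[timeout] <- "timeout"
  rt[timeout] <- NA_real_
  t_d[!decided] <- NA_integer_

  out <- list(choice = choice, rt_ms = rt, t_d = t_d, timeout = timeout,
              provenance = provenance)
  if (return_logodds) out$logodds <- L
  out
}

# Observation-mean matrix for a compiled trial set (see compile_trials).
# rep_rows: replicate each trial's row this many times (for n_reps > 1 the
# replication is trial-major: all reps of trial 1, then trial 2, ...).
obs_mean_matrix <- function(ct, mode, idx) {
  if (mode == "exact") {
    ct$x[idx, , drop = FALSE]
  } else {
    matrix(ct$true_sign[idx] * ct$offset[idx], length(idx), ct$max_dots)
  }
}

#' Simulate responses of the decision model
#'
#' Simulates one (or `n_reps`) response(s) for every trial in `trials` under
#' a single parameter set: a lapse with probability `lapse_p` (timing out
#' with probability `lapse_to_p`, otherwise a fair-coin choice with a
#' uniform RT on `(0, deadline]`), and otherwise an evidence-based response
#' whose RT is `t_d * dt_ms` plus a log-normal non-decision-time draw.
#' Trials whose beliefs never reach the bound within `max_dots` steps time
#' out.
#'
#' @param trials Long trials tibble ([generate_trials()]).
#' @param params One-row parameter tibble ([model_params()]).
#' @param mode Input mode: `"exact"` (dot positions as observations) or
#'   `"ddm"` (constant true-target observations).
#' @param variant Accumulation variant: `"standard"`, `"leaky"` or
#'   `"collapsing"`.
#' @param n_reps Simulated responses per trial (default 1).
#' @param seed Optional integer seed.
#' @param config Optional [target_config()] tibble; inferred from the trial
#'   conditions when omitted.
#' @param ndt_deadline If `TRUE`, responses whose total RT (decision time
#'   plus non-decision time) exceeds the trial deadline of
#'   `max_dots * dt_ms` are also recorded as timeouts. Off by default: the
#'   deadline is applied to the decision step only.
#' @return A tibble with columns `trial_id`, `rep` (if `n_reps > 1`),
#'   `choice` (`left`/`right`/`timeout`), `rt_ms` (`NA` for timeouts),
#'   `t_d`, and `provenance` (`evidence`, `lapse_random`, `lapse_timeout`).
#' @examples
#' trials <- generate_trials(target_config("D4"), per_side = 10, seed = 1)
#' simulate_responses(trials, model_params(bound = 0.8), seed = 2)
#' @export
simulate_responses <- function(trials, params,
                               mode = c("exact", "ddm"),
                               variant = c("standard", "leaky", "collapsing"),
                               n_reps = 1, seed = NULL, config = NULL,
                               ndt_deadline = FALSE) {
  mode <- arg_match(mode); variant <- arg_match(variant)
  validate_params(params)
  if (!is.null(seed)) set.seed(seed)
  ct <- compile_trials(trials, config)
  n_tr <- length(ct$trial_id)
  idx <- rep(seq_len(n_tr), each = n_reps)
  par <- apply_variant(params, variant)
  xh <- obs_mean_matrix(ct, mode, idx)
  res <- sim_engine(xh, ct$offset[idx], par, ct$sigma_stim, ct$dt_ms,
                    ct$max_dots, ndt_deadline = ndt_deadline)
  out <- tibble(
    trial_id = ct$trial_id[idx],
    rep = rep.int(seq_len(n_reps), n_tr),
    choice = res$choice,
    rt_ms = res$rt_ms,
    t_d = res$t_d,
    provenance = res$provenance
  )
  if (n_reps == 1) out$rep <- NULL
  out
}

#' Simulate one response
#'
#' Convenience wrapper around [simulate_responses()] for a single trial.
#'
#' @inheritParams simulate_responses
#' @param trial One trial in long form.
#' @return A one-row response tibble.
#' @export
simulate_response <- function(trial, params, mode = c("exact", "ddm"),
                              variant = c("standard", "leaky", "collapsing"),
                              seed = NULL, config = NULL, ndt_deadline = FALSE) {
  simulate_responses(trial, params, mode, variant, n_reps = 1, seed = seed,
                     config = config, ndt_deadline = ndt_deadline)
}

#' Sample a non-decision time
#'
#' Draws strictly positive non-decision times (ms) from the model's
#' log-normal NDT distribution.
#'
#' @param n Number of draws.
#' @param ndt_mu,ndt_sigma Log-normal location (log-ms) and scale.
#' @return Numeric vector of ms.
#' @export
sample_ndt <- function(n, ndt_mu, ndt_sigma) {
  stopifnot(ndt_sigma >= 0)
  rlnorm(n, ndt_mu, ndt_sigma)
}

#' Belief trajectories for plotting
#'
#' Computes, for each trial, the belief-in-left trajectory and the bound
#' over decision steps under one parameter set — the single-trial view of
#' the accumulation process.
#'
#' @inheritParams simulate_responses
#' @return A tibble `trial_id`, `step`, `belief_left`, `bound`.
#' @export
belief_trajectories <- function(trials, params,
                                mode = c("exact", "ddm"),
                                variant = c("standard", "leaky", "collapsing"),
                                seed = NULL, config = NULL) {
  mode <- arg_match(mode); variant <- arg_match(variant)
  validate_params(params)
  if (!is.null(seed)) set.seed(seed)
  ct <- compile_trials(trials, config)
  n_tr <- length(ct$trial_id)
  par <- apply_variant(params, variant)
  xh <- obs_mean_matrix(ct, mode, seq_len(n_tr))
  res <- sim_engine(xh, ct$offset, par, ct$sigma_stim, ct$dt_ms, ct$max_dots,
                    return_logodds = TRUE)
  b <- bound_value(rep(seq_len(ct$max_dots), each = n_tr), ct$max_dots,
                   par$bound, par$stretch, par$shape)
  tibble(
    trial_id = rep.int(ct$trial_id, ct$max_dots),
    step = rep(seq_len(ct$max_dots), each = n_tr),
    belief_left = plogis(as.vector(res$logodds)),
    bound = b
  ) |> arrange(.data$trial_id, .data$step)
}
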