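#' Posterior predictive likelihood of observed responses
#'
#' Estimates, per trial, the probability of the observed response under the
#' fitted model: `n` parameter sets are drawn from the EP-ABC posterior,
#' transformed to model space, one response is simulated per set on the
#' trial's actual dots, and the PPL is the fraction of simulated responses
#' that reproduce the observed one under the fitting distance criterion
#' (matching choice, RT within `eps_ms`). Zero-count PPLs are floored at
#' `1/(n + 1)` before the log transform.
#'
#' @param trials Long trials tibble.
#' @param responses Observed responses (`trial_id`, `choice`, `rt_ms`).
#' @param fit `epabc_fit` from [fit_decision_model()].
#' @param n Posterior draws / simulations per trial (default 15000).
#' @param eps_ms RT tolerance; defaults to the tolerance the fit used.
#' @param seed Optional integer seed.
#' @param config Optional [target_config()] tibble.
#' @return A tibble `trial_id`, `ppl`, `log_ppl`.
#' @export
posterior_predictive <- function(trials, responses, fit, n = 15000,
                                 eps_ms = NULL, seed = NULL, config = NULL) {
  stopifnot(inherits(fit, "epabc_fit"), n >= 1)
  if (is.null(eps_ms)) eps_ms <- fit$settings$eps_ms
  if (!is.null(seed)) set.seed(seed)
  sims <- predictive_simulations(trials, fit, n, config)
  ct <- sims$ct
  ord <- match(responses$trial_id, ct$trial_id)
  if (anyNA(ord)) abort("responses refer to trial_ids absent from `trials`")
  ppl <- map_dbl(seq_len(nrow(responses)), function(i) {
    s <- sims$responses[[ord[i]]]
    mean(response_distance_ok(s, responses[i, ], eps_ms))
  })
  floor_p <- 1 / (n + 1)
  tibble(
    trial_id = responses$trial_id,
    ppl = ppl,
    log_ppl = log(pmax(ppl, floor_p))
  )
}

# Shared machinery: n posterior-predictive simulated responses per trial.
predictive_simulations <- function(trials, fit, n, config = NULL) {
  ct <- compile_trials(trials, config)
  draws <- complete_params(sample_posterior(fit, n))
  par <- as.list(draws)
  mode <- fit$model$mode %||% "exact"
  ndt_deadline <- isTRUE(fit$model$ndt_deadline)
  responses <- map(seq_along(ct$trial_id), function(row) {
    xh <- obs_mean_matrix(ct, mode, rep.int(row, n))
    res <- sim_engine(xh, ct$offset[row], par, ct$sigma_stim, ct$dt_ms,
                      ct$max_dots, ndt_deadline = ndt_deadline)
    tibble(choice = res$choice, rt_ms = res$rt_ms)
  })
  list(ct = ct, responses = responses)
}

#' Point predictions of choice and RT per trial
#'
#' The predicted choice of a trial is the modal alternative among `n`
#' posterior-predictive simulations (timeouts excluded; a 50/50 split is
#' broken toward the alternative with more total simulated mass, then
#' toward `left`). The predicted RT is the modal `dt_ms`-wide RT bin among
#' the simulations with the predicted choice (bins aligned to the decision
#' grid; ties broken toward the earlier bin), reported as the bin midpoint.
#' If every simulation times out the prediction is a timeout.
#'
#' @inheritParams posterior_predictive
#' @return A tibble `trial_id`, `choice`, `rt_ms`.
#' @export
point_prediction <- function(trials, fit, n = 15000, seed = NULL,
                             config = NULL) {
  stopifnot(inherits(fit, "epabc_fit"), n >= 1)
  if (!is.null(seed)) set.seed(seed)
  sims <- predictive_simulations(trials, fit, n, config)
  ct <- sims$ct
  dt <- ct$dt_ms
  out <- map(seq_along(ct$trial_id), function(row) {
    s <- sims$responses[[row]]
    live <- s[s$choice != "timeout", ]
    if (nrow(live) == 0) {
      return(tibble(trial_id = ct$trial_id[row], choice = "timeout",
                    rt_ms = NA_real_))
    }
    n_left <- sum(live$choice == "left")
    n_right <- nrow(live) - n_left
    choice <- if (n_left > n_right) "left"
              else if (n_right > n_left) "right"
              else "left"
    rts <- live$rt_ms[live$choice == choice]
    bin <- floor(rts / dt) # bin k covers [k*dt, (k+1)*dt)
    tab <- table(bin)
    kbest <- as.numeric(names(tab)[which.max(tab)]) # which.max: earliest tie
    tibble(trial_id = ct$trial_id[row], choice = choice,
           rt_ms = (kbest + 0.5) * dt)
  })
  list_rbind(out)
}

#' Choice-match confusion table between model and participant
#'
#' Cross-tabulates model correctness against participant correctness over
#' aligned trials: proportions of trials in which the model's point
#' prediction and the participant's response were each correct (matched the
#' true target). Also reports the overall match rate — the fraction of
#' trials where prediction and response agree.
#'
#' @param predictions Point predictions (`trial_id`, `choice`).
#' @param observed Observed responses (`trial_id`, `choice`).
#' @param truth Tibble with `trial_id` and `true_target`.
#' @return A list with `table` (tibble of the 2x2 proportions) and
#'   `match_rate`.
#' @export
match_table <- function(predictions, observed, truth) {
  if (nrow(predictions) == 0 || nrow(observed) == 0) {
    abort("empty input to match_table")
  }
  truth <- distinct(truth[, c("trial_id", "true_target")])
  df <- predictions |>
    select("trial_id", model_choice = "choice") |>
    dplyr::inner_join(select(observed, "trial_id", obs_choice = "choice"),
                      by = "trial_id") |>
    dplyr::inner_join(truth, by = "trial_id")
  if (nrow(df) != nrow(predictions)) {
    abort("predictions, observed and truth must cover the same trials")
  }
  df <- df |>
    mutate(
      model_correct = .data$model_choice == .data$true_target,
      participant_correct = .data$obs_choice == .data$true_target
    )
  tab <- df |>
    count(.data$model_correct, .data$participant_correct) |>
    mutate(proportion = n / sum(n)) |>
    select(-"n") |>
    tidyr::complete(
      model_correct = c(TRUE, FALSE), participant_correct = c(TRUE, FALSE),
      fill = list(proportion = 0)
    )
  list(
    table = tab,
    match_rate = mean(df$model_choice == df$obs_choice)
  )
}
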