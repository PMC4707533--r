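#' Specification of a synthetic cohort
#'
#' Describes a simulated study with the structure of the dot-tracking
#' experiment: one shared stimulus set, shown to every participant in
#' randomised order, with responses generated from the decision model under
#' known ground-truth parameters.
#'
#' @param n_participants Number of participants (default 24).
#' @param conditions Difficulty labels (default D1-D4).
#' @param trials_per_condition Trials per condition, split evenly between
#'   sides (default 200, i.e. 100 left + 100 right).
#' @param truth_mode How ground-truth parameters are assigned: `"table"`
#'   uses the reference fitted values per condition ([reference_params()]),
#'   identical across participants; `"sampled"` draws each
#'   participant-condition's truth from the fitting priors
#'   ([default_transforms()]); `"fixed"` uses `truth_params` for everyone.
#' @param mode Generating input mode (`"exact"` or `"ddm"`).
#' @param variant Generating accumulation variant.
#' @param truth_params One-row parameter tibble, required for
#'   `truth_mode = "fixed"`.
#' @param config Optional [target_config()]; built from `conditions`
#'   otherwise.
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_participants = 24,
                        conditions = c("D1", "D2", "D3", "D4"),
                        trials_per_condition = 200,
                        truth_mode = c("table", "sampled", "fixed"),
                        mode = c("exact", "ddm"),
                        variant = c("standard", "leaky", "collapsing"),
                        truth_params = NULL,
                        config = NULL) {
  truth_mode <- arg_match(truth_mode)
  mode <- arg_match(mode); variant <- arg_match(variant)
  stopifnot(n_participants >= 0, trials_per_condition >= 2)
  if (truth_mode == "fixed" && is.null(truth_params)) {
    abort("truth_mode = 'fixed' needs `truth_params`")
  }
  if (is.null(config)) config <- target_config(conditions)
  structure(
    list(n_participants = n_participants, conditions = conditions,
         trials_per_condition = trials_per_condition,
         truth_mode = truth_mode, mode = mode, variant = variant,
         truth_params = truth_params, config = config),
    class = "cohort_spec"
  )
}

#' Generate a synthetic cohort with known ground truth
#'
#' Builds the shared trial set ([generate_trials()]), per-participant
#' presentation orders ([shuffle_sessions()]), ground-truth parameters per
#' participant-condition, and responses simulated from the decision model
#' under those truths. Fully reproducible given `(spec, seed)`; the truth is
#' returned alongside the data but nothing in the fitting interface reads
#' it.
#'
#' @param spec A [cohort_spec()].
#' @param seed Optional integer seed.
#' @return A list of class `dot_cohort`: `trials` (shared stimulus set),
#'   `orders` (participant, position, trial_id), `responses` (participant,
#'   trial_id, choice, rt_ms, t_d, provenance), `truth` (participant,
#'   condition, parameter columns), and `spec`.
#' @examples
#' spec <- cohort_spec(n_participants = 2, conditions = "D4",
#'                     trials_per_condition = 10)
#' coh <- make_cohort(spec, seed = 1)
#' dplyr::count(coh$responses, participant)
#' @export
make_cohort <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (!is.null(seed)) set.seed(seed)
  per_side <- spec$trials_per_condition %/% 2
  trials <- generate_trials(spec$config, per_side = per_side)
  orders <- shuffle_sessions(trials, spec$n_participants)
  trial_key <- distinct(trials[, c("trial_id", "condition")])

  truth <- make_truth(spec)
  responses <- vector("list", spec$n_participants * length(spec$conditions))
  k <- 0
  for (p in seq_len(spec$n_participants)) {
    for (cond in spec$conditions) {
      k <- k + 1
      ids <- trial_key$trial_id[trial_key$condition == cond]
      tr <- trials[trials$trial_id %in% ids, ]
      pars <- truth[truth$participant == p & truth$condition == cond, ]
      resp <- simulate_responses(
        tr, pars[, setdiff(names(pars), c("participant", "condition"))],
        mode = spec$mode, variant = spec$variant, config = spec$config
      )
      resp$participant <- p
      responses[[k]] <- resp
    }
  }
  resp_all <- if (k > 0) {
    list_rbind(responses[seq_len(k)]) |>
      select("participant", dplyr::everything())
  } else {
    tibble(participant = integer(), trial_id = integer(),
           choice = character(), rt_ms = numeric())
  }
  structure(
    list(trials = trials, orders = orders, responses = resp_all,
         truth = truth, spec = spec),
    class = "dot_cohort"
  )
}

# Ground-truth parameter table per participant-condition.
make_truth <- function(spec) {
  grid <- tidyr::expand_grid(
    participant = seq_len(spec$n_participants),
    condition = spec$conditions
  )
  if (spec$truth_mode == "table") {
    ref <- reference_params(if (spec$mode == "exact") "exact" else "ddm")
    pars <- ref[match(grid$condition, ref$condition),
                c(param_names("standard"), "discount", "stretch", "shape")]
    return(dplyr::bind_cols(grid, pars))
  }
  if (spec$truth_mode == "fixed") {
    pars <- spec$truth_params[rep(1, nrow(grid)), ]
    return(dplyr::bind_cols(grid, pars))
  }
  # sampled: draw each participant-condition truth from the fitting priors
  tf <- default_transforms(spec$variant)
  z <- matrix(rnorm(nrow(grid) * nrow(tf)), nrow(grid), nrow(tf))
  pars <- complete_params(to_model_space(z, tf))
  dplyr::bind_cols(grid, pars)
}

#' Parameter- and model-recovery experiment
#'
#' Generates a synthetic cohort, fits the decision model to every
#' participant-condition dataset, and scores the fits against the known
#' truth: per-parameter bias and RMSE of the posterior means and the
#' coverage of central 95% posterior intervals. Optionally also fits a
#' second, mismatched input mode to every dataset and runs [rfx_bms()] on
#' the evidences (model recovery).
#'
#' @param spec A [cohort_spec()].
#' @param settings [fit_settings()] used for every fit.
#' @param seed Optional integer seed.
#' @param fit_modes Input modes to fit; the first is scored for parameter
#'   recovery. Default: the generating mode only.
#' @param conf_level Credible-interval mass for coverage (default 0.95).
#' @param n_draws Posterior draws per fit for interval estimation.
#' @return A list of class `recovery_report`: `estimates` (one row per
#'   participant-condition-parameter: truth, posterior mean, interval,
#'   covered), `summary` (per-parameter bias, rmse, coverage), `evidence`
#'   (participant-condition x mode log evidences), `bms` (a `bms_result`,
#'   when more than one mode was fitted), `errors` (per-cell fit failures).
#' @export
recovery_experiment <- function(spec, settings = fit_settings(), seed = NULL,
                                fit_modes = NULL, conf_level = 0.95,
                                n_draws = 4000) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (!is.null(seed)) set.seed(seed)
  if (is.null(fit_modes)) fit_modes <- spec$mode
  if (spec$n_participants * length(spec$conditions) == 0) {
    return(structure(list(estimates = tibble(), summary = tibble(),
                          evidence = tibble(), bms = NULL, errors = tibble()),
                     class = "recovery_report"))
  }
  coh <- make_cohort(spec)
  tf <- default_transforms(spec$variant)
  free <- tf$name
  trial_key <- distinct(coh$trials[, c("trial_id", "condition")])

  estimates <- list(); evid <- list(); errors <- list()
  for (p in seq_len(spec$n_participants)) {
    for (cond in spec$conditions) {
      ids <- trial_key$trial_id[trial_key$condition == cond]
      tr <- coh$trials[coh$trials$trial_id %in% ids, ]
      resp <- coh$responses[coh$responses$participant == p &
                              coh$responses$trial_id %in% ids, ]
      truth_row <- coh$truth[coh$truth$participant == p &
                               coh$truth$condition == cond, ]
      for (m in fit_modes) {
        fit <- tryCatch(
          fit_decision_model(tr, resp[, c("trial_id", "choice", "rt_ms")],
                             mode = m, variant = spec$variant,
                             transforms = tf, settings = settings,
                             config = spec$config),
          error = function(e) e
        )
        if (inherits(fit, "error")) {
          errors[[length(errors) + 1]] <- tibble(
            participant = p, condition = cond, mode = m,
            message = conditionMessage(fit)
          )
          next
        }
        evid[[length(evid) + 1]] <- tibble(
          participant = p, condition = cond, mode = m,
          log_evidence = fit$log_evidence
        )
        if (m == fit_modes[[1]]) {
          ti <- tidy(fit, n_draws = n_draws, conf_level = conf_level)
          ti$truth <- as.numeric(truth_row[1, ti$term])
          estimates[[length(estimates) + 1]] <- ti |>
            mutate(participant = p, condition = cond,
                   covered = .data$truth >= .data$conf.low &
                     .data$truth <= .data$conf.high)
        }
      }
    }
  }
  estimates <- list_rbind(estimates)
  evid <- list_rbind(evid)
  summary <- if (nrow(estimates)) {
    estimates |>
      group_by(.data$term) |>
      summarise(
        bias = mean(.data$estimate - .data$truth),
        rmse = sqrt(mean((.data$estimate - .data$truth)^2)),
        coverage = mean(.data$covered),
        .groups = "drop"
      )
  } else tibble()
  bms <- NULL
  if (length(fit_modes) > 1 && nrow(evid)) {
    wide <- tidyr::pivot_wider(evid, names_from = "mode",
                               values_from = "log_evidence")
    mat <- as.matrix(wide[, fit_modes])
    if (all(is.finite(mat))) bms <- rfx_bms(mat)
  }
  structure(
    list(estimates = estimates, summary = summary, evidence = evid,
         bms = bms, errors = list_rbind(errors), truth = coh$truth),
    class = "recovery_report"
  )
}

#' @export
print.recovery_report <- function(x, ...) {
  cat("Recovery experiment:", nrow(x$estimates), "interval checks\n")
  if (nrow(x$summary)) print(x$summary, ...)
  if (!is.null(x$bms)) { cat("\nModel recovery:\n"); print(x$bms) }
  if (nrow(x$errors)) cat("\n", nrow(x$errors), "fit(s) failed\n")
  invisible(x)
}
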