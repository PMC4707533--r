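#' Acceptance criterion of the likelihood-free fit
#'
#' A simulated response reproduces an observed one iff the choices are equal
#' and either both are timeouts (timeouts carry no RT) or the absolute RT
#' difference is strictly smaller than `eps_ms`.
#'
#' @param sim,obs Response tibbles (columns `choice`, `rt_ms`) of equal
#'   length, or `obs` a single row recycled against `sim`.
#' @param eps_ms RT tolerance in ms; the default 46.6 is half the dot
#'   duration.
#' @return Logical vector.
#' @examples
#' response_distance_ok(
#'   tibble::tibble(choice = "left", rt_ms = 500),
#'   tibble::tibble(choice = "left", rt_ms = 540)
#' )
#' @export
response_distance_ok <- function(sim, obs, eps_ms = 46.6) {
  same <- sim$choice == rep_len(obs$choice, nrow(sim))
  to <- sim$choice == "timeout"
  drt <- abs(sim$rt_ms - rep_len(obs$rt_ms, nrow(sim)))
  ok <- same & (to | (drt < eps_ms))
  ok & !is.na(ok) # a non-finite simulated RT cannot match
}

#' Settings of the EP-ABC fit
#'
#' @param eps_ms ABC distance tolerance in ms (default 46.6, half the dot
#'   duration).
#' @param min_accepted Accepted samples required before a site update
#'   (default 300).
#' @param passes Sweeps through all data points (default 4).
#' @param max_proposals Proposal budget per site and pass (default
#'   `500 * min_accepted`, so that data points with acceptance rates down to
#'   ~0.2% still reach `min_accepted`; trials only matchable through the
#'   lapse route live in that regime, and skipping them biases the lapse
#'   parameters).
#' @param batch_size Proposals simulated per batch (default
#'   `max(2000, 4 * min_accepted)`).
#' @param damping Step size of site updates in (0, 1] (default 0.5). Full
#'   updates (1) let the Monte-Carlo noise of the moment estimates
#'   accumulate across sites; damping stabilises the sweep.
#' @param min_eig Eigenvalue floor used when repairing covariance/precision
#'   matrices.
#' @param cavity_min_prec Eigenvalue floor on the cavity precision
#'   (default 0.04, i.e. proposal SDs capped at five prior SDs): keeps
#'   proposals finite when a site leaves the cavity near-singular.
#' @param max_skip_frac Fit error if more than this fraction of sites is
#'   skipped within one pass.
#' @return A list of settings.
#' @export
fit_settings <- function(eps_ms = 46.6, min_accepted = 300, passes = 4,
                         max_proposals = 500 * min_accepted,
                         batch_size = max(2000, 4 * min_accepted),
                         damping = 0.5, min_eig = 1e-8, cavity_min_prec = 0.04,
                         max_skip_frac = 0.2) {
  stopifnot(eps_ms > 0, min_accepted >= 1, passes >= 1,
            max_proposals >= min_accepted, damping > 0, damping <= 1)
  list(eps_ms = eps_ms, min_accepted = min_accepted, passes = passes,
       max_proposals = max_proposals, batch_size = batch_size,
       damping = damping, min_eig = min_eig,
       cavity_min_prec = cavity_min_prec, max_skip_frac = max_skip_frac)
}

# log-partition of an unnormalised Gaussian exp(-z'Qz/2 + r'z):
# log integral = (d/2) log 2pi - logdet(Q)/2 + r'Q^{-1}r/2
gauss_logpart <- function(r, Q) {
  ch <- chol(Q)
  x <- backsolve(ch, forwardsolve(t(ch), r))
  0.5 * (length(r) * log(2 * pi)) - sum(log(diag(ch))) + 0.5 * sum(r * x)
}

# Symmetrise and floor the eigenvalues of a precision/covariance matrix.
repair_psd <- function(M, min_eig) {
  M <- (M + t(M)) / 2
  e <- eigen(M, symmetric = TRUE)
  if (all(e$values >= min_eig)) return(list(M = M, repaired = FALSE))
  v <- pmax(e$values, min_eig)
  list(M = e$vectors %*% (v * t(e$vectors)), repaired = TRUE)
}

#' Likelihood-free posterior inference with EP-ABC
#'
#' Fits a simulator-defined model to a set of observed data points with
#' expectation-propagation approximate Bayesian computation. The posterior
#' over the unconstrained parameter vector is a product of the standard
#' normal prior and one Gaussian site factor per data point. Each site
#' update draws proposals from the cavity distribution (the posterior with
#' that site removed), simulates one response per proposal, accepts
#' proposals whose simulated response reproduces the observed one
#' ([response_distance_ok()]), and moment-matches the posterior to the
#' accepted samples once `min_accepted` of them have been collected. Sites
#' whose proposal budget is exhausted first are skipped with a warning.
#' Several passes are made over the data to let the approximation converge,
#' and the log marginal likelihood (model evidence) is accumulated from the
#' per-site acceptance rates with the usual EP normalisation corrections.
#'
#' This engine is simulator-agnostic; [fit_decision_model()] wires it to the
#' dot-tracking decision model.
#'
#' @param observed Tibble of observed data points, columns `choice` and
#'   `rt_ms`, one row per data point (trial).
#' @param simulate_fn `function(i, params)` returning a tibble with columns
#'   `choice`, `rt_ms` — one simulated response of data point `i` per row of
#'   the model-space parameter tibble `params`.
#' @param transforms Transform tibble defining the parameters and their
#'   priors ([default_transforms()], [param_transform()]).
#' @param settings [fit_settings()].
#' @param seed Optional integer seed; fits are reproducible given
#'   `(observed, settings, seed)`.
#' @return An object of class `epabc_fit`: a list with `mean`, `cov` (the
#'   Gaussian posterior over unconstrained parameters), `sites` (per-trial
#'   natural parameters), `log_evidence`, `transforms`, `settings`, and
#'   per-site diagnostics (`acceptance`, `skipped`).
#' @references Barthelme & Chopin (2014), Expectation propagation for
#'   likelihood-free inference, JASA 109(505).
#' @export
ep_abc <- function(observed, simulate_fn, transforms,
                   settings = fit_settings(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  d <- nrow(transforms)
  n_obs <- nrow(observed)
  if (any(observed$choice != "timeout" & !is.finite(observed$rt_ms))) {
    abort("non-timeout observations must have finite rt_ms")
  }

  r_prior <- rep(0, d); Q_prior <- diag(d)
  r_glob <- r_prior; Q_glob <- Q_prior
  sites <- replicate(n_obs,
                     list(r = rep(0, d), Q = matrix(0, d, d), log_s = 0),
                     simplify = FALSE)
  acc_rate <- rep(NA_real_, n_obs)
  skipped <- rep(FALSE, n_obs)
  if (n_obs == 0) {
    return(new_epabc_fit(r_glob, Q_glob, sites, 0, transforms, settings,
                         acc_rate, skipped, n_obs))
  }

  for (pass in seq_len(settings$passes)) {
    n_skip <- 0L
    for (i in seq_len(n_obs)) {
      obs_i <- observed[i, ]
      rc <- r_glob - sites[[i]]$r
      Qc <- Q_glob - sites[[i]]$Q
      Qc <- repair_psd(Qc, settings$cavity_min_prec %||% 0.04)$M
      Sc <- chol2inv(chol(Qc))
      mc <- drop(Sc %*% rc)
      cS <- chol(Sc)

      acc <- matrix(numeric(0), 0, d)
      proposed <- 0L
      while (nrow(acc) < settings$min_accepted &&
             proposed < settings$max_proposals) {
        nb <- min(settings$batch_size, settings$max_proposals - proposed)
        z <- matrix(rnorm(nb * d), nb, d) %*% cS +
          matrix(mc, nb, d, byrow = TRUE)
        sim <- simulate_fn(i, to_model_space(z, transforms))
        ok <- response_distance_ok(sim, obs_i, settings$eps_ms)
        if (any(ok)) acc <- rbind(acc, z[ok, , drop = FALSE])
        proposed <- proposed + nb
      }
      n_acc <- nrow(acc)
      acc_rate[i] <- n_acc / proposed
      # site likelihood estimate: acceptance probability, normalised by the
      # 2*eps RT window for non-timeout data (density), raw for timeouts.
      lhat <- if (n_acc > 0) n_acc / proposed else 1 / (proposed + 1)
      log_lhat <- log(lhat) -
        (if (obs_i$choice == "timeout") 0 else log(2 * settings$eps_ms))

      if (n_acc >= settings$min_accepted) {
        mhat <- colMeans(acc)
        Chat <- cov(acc)
        rep_h <- repair_psd(Chat, settings$min_eig)
        # debias inv(sample cov): E[inv(C_hat)] = Q*(M-1)/(M-d-2); without
        # this the posterior precision inflates multiplicatively per site
        # and the fit collapses over passes
        deb <- max(n_acc - d - 2, 1) / (n_acc - 1)
        Qnew <- deb * chol2inv(chol(rep_h$M))
        rnew <- drop(Qnew %*% mhat)
        a <- settings$damping
        r_site <- a * (rnew - rc) + (1 - a) * sites[[i]]$r
        Q_site <- a * (Qnew - Qc) + (1 - a) * sites[[i]]$Q
        r_new_glob <- rc + r_site
        Q_new_glob <- repair_psd(Qc + Q_site, settings$min_eig)$M
        sites[[i]]$r <- r_new_glob - rc
        sites[[i]]$Q <- Q_new_glob - Qc
        r_glob <- r_new_glob
        Q_glob <- Q_new_glob
        skipped[i] <- FALSE
      } else {
        n_skip <- n_skip + 1L
        skipped[i] <- TRUE
        warn(paste0("EP-ABC site ", i, " skipped in pass ", pass, ": ",
                    n_acc, "/", proposed,
                    " proposals accepted (< min_accepted)"))
      }
      sites[[i]]$log_s <- log_lhat + gauss_logpart(rc, Qc) -
        gauss_logpart(r_glob, Q_glob)
    }
    if (n_skip / n_obs > settings$max_skip_frac) {
      abort(paste0("EP-ABC fit failed: ", n_skip, " of ", n_obs,
                   " sites skipped in pass ", pass))
    }
  }

  log_ev <- sum(map_dbl(sites, "log_s")) +
    gauss_logpart(r_glob, Q_glob) - gauss_logpart(r_prior, Q_prior)
  new_epabc_fit(r_glob, Q_glob, sites, log_ev, transforms, settings,
                acc_rate, skipped, n_obs)
}

new_epabc_fit <- function(r, Q, sites, log_ev, transforms, settings,
                          acc_rate, skipped, n_obs) {
  S <- chol2inv(chol(Q))
  m <- drop(S %*% r)
  names(m) <- transforms$name
  dimnames(S) <- list(transforms$name, transforms$name)
  structure(
    list(mean = m, cov = S, precision = Q, shift = r, sites = sites,
         log_evidence = log_ev, transforms = transforms, settings = settings,
         acceptance = acc_rate, skipped = skipped, n_trials = n_obs),
    class = "epabc_fit"
  )
}

#' Fit the decision model to one participant-condition dataset
#'
#' Runs [ep_abc()] with the dot-tracking decision model as simulator: one
#' data point per trial (the observed choice and RT), proposals simulated on
#' that trial's actual dot sequence.
#'
#' @param trials Long trials tibble for one condition.
#' @param responses Response tibble (`trial_id`, `choice`, `rt_ms`) of one
#'   participant on those trials.
#' @param mode Input mode, `"exact"` or `"ddm"`.
#' @param variant Accumulation variant.
#' @param transforms Transform tibble (default [default_transforms()] for
#'   the variant).
#' @param settings [fit_settings()].
#' @param seed Optional integer seed.
#' @param config Optional [target_config()] tibble.
#' @param ndt_deadline Passed to the simulator; see [simulate_responses()].
#' @return An `epabc_fit` (see [ep_abc()]), with the mode/variant recorded
#'   in `$model`.
#' @examples
#' \donttest{
#' trials <- generate_trials(target_config("D4"), per_side = 10, seed = 1)
#' truth <- model_params(sigma_s = 40, bound = 0.85, prior_left = 0.45)
#' resp <- simulate_responses(trials, truth, seed = 2)
#' fit <- fit_decision_model(trials, resp,
#'   settings = fit_settings(min_accepted = 50, passes = 1), seed = 3)
#' tidy(fit)
#' }
#' @export
fit_decision_model <- function(trials, responses,
                               mode = c("exact", "ddm"),
                               variant = c("standard", "leaky", "collapsing"),
                               transforms = NULL,
                               settings = fit_settings(), seed = NULL,
                               config = NULL, ndt_deadline = FALSE) {
  mode <- arg_match(mode); variant <- arg_match(variant)
  if (is.null(transforms)) transforms <- default_transforms(variant)
  ct <- compile_trials(trials, config)
  ord <- match(responses$trial_id, ct$trial_id)
  if (anyNA(ord)) abort("responses refer to trial_ids absent from `trials`")
  sim_fn <- function(i, params) {
    par <- complete_params(params)
    par <- as.list(par)
    n <- length(par[[1]])
    row <- ord[i]
    xh <- obs_mean_matrix(ct, mode, rep.int(row, n))
    res <- sim_engine(xh, ct$offset[row], par, ct$sigma_stim, ct$dt_ms,
                      ct$max_dots, ndt_deadline = ndt_deadline)
    tibble(choice = res$choice, rt_ms = res$rt_ms)
  }
  fit <- ep_abc(responses, sim_fn, transforms, settings, seed)
  fit$model <- list(mode = mode, variant = variant,
                    ndt_deadline = ndt_deadline)
  fit$trial_id <- responses$trial_id
  fit
}

#' Draw model-space parameter samples from a fitted posterior
#'
#' @param fit An `epabc_fit`.
#' @param n Number of draws.
#' @return A tibble of model-space parameters, one row per draw.
#' @export
sample_posterior <- function(fit, n = 1000) {
  d <- length(fit$mean)
  z <- matrix(rnorm(n * d), n, d) %*% chol(fit$cov) +
    matrix(fit$mean, n, d, byrow = TRUE)
  to_model_space(z, fit$transforms)
}

#' @export
print.epabc_fit <- function(x, ...) {
  cat("EP-ABC fit (", x$n_trials, " trials, ",
      x$settings$passes, " passes)\n", sep = "")
  if (!is.null(x$model)) {
    cat("model: ", x$model$mode, " input, ", x$model$variant,
        " accumulation\n", sep = "")
  }
  cat("log evidence: ", format(x$log_evidence, digits = 6), "\n", sep = "")
  print(tidy(x), ...)
  invisible(x)
}

#' @rdname tidy.epabc_fit
#' @export
glance.epabc_fit <- function(x, ...) {
  tibble(
    log_evidence = x$log_evidence,
    n_trials = x$n_trials,
    passes = x$settings$passes,
    eps_ms = x$settings$eps_ms,
    mean_acceptance = mean(x$acceptance, na.rm = TRUE),
    n_skipped = sum(x$skipped)
  )
}

#' Tidy summaries of an EP-ABC fit
#'
#' `tidy()` reports per-parameter posterior summaries in model space,
#' estimated by transforming draws from the Gaussian posterior; `glance()`
#' reports fit-level quantities (log evidence, acceptance diagnostics).
#'
#' @param x An `epabc_fit`.
#' @param n_draws Posterior draws used for the model-space summaries.
#' @param conf_level Central credible-interval mass (default 0.95).
#' @param ... Unused.
#' @return A tibble with columns `term`, `estimate` (posterior mean),
#'   `conf.low`, `conf.high`.
#' @export
tidy.epabc_fit <- function(x, n_draws = 4000, conf_level = 0.95, ...) {
  draws <- sample_posterior(x, n_draws)
  a <- (1 - conf_level) / 2
  tibble(
    term = names(draws),
    estimate = map_dbl(draws, mean),
    conf.low = map_dbl(draws, quantile, probs = a),
    conf.high = map_dbl(draws, quantile, probs = 1 - a)
  )
}
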