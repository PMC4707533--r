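#' Plot single-trial belief trajectories
#'
#' The classic single-trial view of the accumulation process: the posterior
#' belief in the left target over decision steps, with the (possibly
#' collapsing) bound overlaid for both alternatives.
#'
#' @inheritParams belief_trajectories
#' @param n_reps Trajectories per trial (independent sensory-noise draws).
#' @return A ggplot object.
#' @export
plot_belief_trajectories <- function(trials, params,
                                     mode = c("exact", "ddm"),
                                     variant = c("standard", "leaky", "collapsing"),
                                     n_reps = 20, seed = NULL, config = NULL) {
  mode <- arg_match(mode); variant <- arg_match(variant)
  if (!is.null(seed)) set.seed(seed)
  traj <- purrr::map(seq_len(n_reps), function(r) {
    belief_trajectories(trials, params, mode, variant, config = config) |>
      mutate(rep = r)
  }) |> list_rbind()
  ggplot2::ggplot(traj, ggplot2::aes(x = .data$step, y = .data$belief_left,
                                     group = .data$rep)) +
    ggplot2::geom_line(alpha = 0.4, colour = "steelblue") +
    ggplot2::geom_line(ggplot2::aes(y = .data$bound, group = NULL),
                       colour = "black") +
    ggplot2::geom_line(ggplot2::aes(y = 1 - .data$bound, group = NULL),
                       colour = "black") +
    ggplot2::facet_wrap(ggplot2::vars(.data$trial_id)) +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "decision step (dots seen)",
                  y = "posterior belief (left target)")
}

#' @export
autoplot.epabc_fit <- function(object, n_draws = 4000, ...) {
  draws <- sample_posterior(object, n_draws)
  long <- tidyr::pivot_longer(draws, dplyr::everything(),
                              names_to = "term", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$value)) +
    ggplot2::geom_density(fill = "steelblue", alpha = 0.5) +
    ggplot2::facet_wrap(ggplot2::vars(.data$term), scales = "free") +
    ggplot2::labs(x = "parameter value (model space)", y = "posterior density")
}

#' @export
autoplot.bms_result <- function(object, ...) {
  df <- tidy(object) |>
    tidyr::pivot_longer(c("expected_frequency", "pxp"),
                        names_to = "quantity", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$model, y = .data$value)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::facet_wrap(ggplot2::vars(.data$quantity)) +
    ggplot2::geom_hline(yintercept = 0.95, linetype = "dashed",
                        colour = "red") +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(y = NULL, x = NULL)
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
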