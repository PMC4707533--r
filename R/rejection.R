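#' Brute-force rejection ABC
#'
#' Plain rejection sampling for tiny datasets, used as an independent oracle
#' for [ep_abc()]: draw parameter vectors from the standard-normal prior on
#' the unconstrained scale, simulate the FULL dataset for each draw, and
#' accept a draw iff every simulated data point reproduces its observed one
#' under [response_distance_ok()].
#'
#' @param observed Tibble of observed data points (`choice`, `rt_ms`).
#'   Intended for very small datasets (a handful of trials).
#' @param simulate_fn As in [ep_abc()]: `function(i, params)` simulating
#'   data point `i` once per parameter row.
#' @param transforms Transform tibble.
#' @param eps_ms RT tolerance in ms.
#' @param n_samples Prior draws.
#' @param seed Optional integer seed.
#' @param batch_size Draws simulated per batch.
#' @return A list with `z` (matrix of accepted unconstrained draws),
#'   `params` (their model-space values), and `acceptance_rate`.
#' @export
rejection_abc <- function(observed, simulate_fn, transforms, eps_ms = 46.6,
                          n_samples = 1e5, seed = NULL, batch_size = 1e4) {
  if (!is.null(seed)) set.seed(seed)
  d <- nrow(transforms)
  n_obs <- nrow(observed)
  acc <- matrix(numeric(0), 0, d)
  done <- 0
  while (done < n_samples) {
    nb <- min(batch_size, n_samples - done)
    z <- matrix(rnorm(nb * d), nb, d)
    params <- to_model_space(z, transforms)
    ok <- rep(TRUE, nb)
    for (i in seq_len(n_obs)) {
      if (!any(ok)) break
      sim <- simulate_fn(i, params)
      ok <- ok & response_distance_ok(sim, observed[i, ], eps_ms)
    }
    acc <- rbind(acc, z[ok, , drop = FALSE])
    done <- done + nb
  }
  if (nrow(acc) == 0) {
    abort("rejection_abc: no acceptances within the sampling budget")
  }
  colnames(acc) <- transforms$name
  list(
    z = acc,
    params = to_model_space(acc, transforms),
    acceptance_rate = nrow(acc) / n_samples
  )
}
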