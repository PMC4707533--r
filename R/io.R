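#' Read and write trial tables
#'
#' Trials are stored as long-format CSV (UTF-8, comma separated, header
#' row): one row per dot with columns `trial_id`, `condition`,
#' `true_target`, `dot_index` (1-based), `x_px`, `y_px`. Coordinates are
#' written with 6 decimal places, and a write-read round trip reproduces
#' the table exactly at that precision. The reader validates structure:
#' every trial's `dot_index` must run 1..max without gaps or duplicates and
#' all coordinates must be numeric.
#'
#' @param trials Long trials tibble.
#' @param path File path.
#' @return `read_trials()` returns the trials tibble; `write_trials()`
#'   returns `path` invisibly.
#' @export
write_trials <- function(trials, path) {
  stopifnot(all(c("trial_id", "condition", "true_target", "dot_index",
                  "x_px", "y_px") %in% names(trials)))
  out <- trials |>
    mutate(
      x_px = sprintf("%.6f", .data$x_px),
      y_px = sprintf("%.6f", .data$y_px)
    )
  readr::write_csv(out, path)
  invisible(path)
}

#' @rdname write_trials
#' @export
read_trials <- function(path) {
  tr <- readr::read_csv(
    path,
    col_types = readr::cols(
      trial_id = readr::col_integer(),
      condition = readr::col_character(),
      true_target = readr::col_character(),
      dot_index = readr::col_integer(),
      x_px = readr::col_double(),
      y_px = readr::col_double()
    ),
    progress = FALSE
  )
  prob <- readr::problems(tr)
  if (nrow(prob) > 0) {
    abort(paste0("parse error in ", path, ", line ", prob$row[1] + 1, ": ",
                 prob$expected[1], " expected"))
  }
  if (!all(tr$true_target %in% c("left", "right"))) {
    abort("true_target must be 'left' or 'right'")
  }
  if (anyNA(tr$x_px) || anyNA(tr$y_px)) abort("non-numeric coordinate")
  bad <- tr |>
    group_by(.data$trial_id) |>
    summarise(ok = identical(sort(.data$dot_index), seq_len(dplyr::n())),
              .groups = "drop") |>
    filter(!.data$ok)
  if (nrow(bad) > 0) {
    abort(paste0("trial ", bad$trial_id[1],
                 ": dot_index must run 1..n without gaps or duplicates"))
  }
  tr
}

#' Read and write response tables
#'
#' Responses are stored as CSV with columns `trial_id`, `choice`
#' (`left`/`right`/`timeout`) and `rt_ms`; timeout rows have an empty
#' `rt_ms` field. The reader rejects negative or zero RTs and RTs attached
#' to timeouts; RTs beyond the trial deadline raise a warning (or an error
#' with `strict = TRUE`).
#'
#' @param responses Response tibble.
#' @param path File path.
#' @param deadline_ms Deadline used for the over-deadline check (default
#'   25 * 93.2).
#' @param strict Treat over-deadline RTs as errors instead of warnings.
#' @return `read_responses()` returns the tibble; `write_responses()`
#'   returns `path` invisibly.
#' @export
write_responses <- function(responses, path) {
  stopifnot(all(c("trial_id", "choice", "rt_ms") %in% names(responses)))
  readr::write_csv(responses[, c("trial_id", "choice", "rt_ms")], path,
                   na = "")
  invisible(path)
}

#' @rdname write_responses
#' @export
read_responses <- function(path, deadline_ms = 25 * 93.2, strict = FALSE) {
  rs <- readr::read_csv(
    path,
    col_types = readr::cols(
      trial_id = readr::col_integer(),
      choice = readr::col_character(),
      rt_ms = readr::col_double()
    ),
    progress = FALSE
  )
  if (!all(rs$choice %in% c("left", "right", "timeout"))) {
    abort("choice must be left, right or timeout")
  }
  to <- rs$choice == "timeout"
  if (any(!is.na(rs$rt_ms[to]))) {
    abort(paste0("trial ", rs$trial_id[to & !is.na(rs$rt_ms)][1],
                 ": rt_ms present for a timeout"))
  }
  if (any(is.na(rs$rt_ms[!to]))) {
    abort(paste0("trial ", rs$trial_id[!to & is.na(rs$rt_ms)][1],
                 ": missing rt_ms for a non-timeout response"))
  }
  if (any(rs$rt_ms[!to] <= 0)) {
    abort(paste0("trial ", rs$trial_id[!to][which(rs$rt_ms[!to] <= 0)[1]],
                 ": rt_ms must be positive"))
  }
  over <- !to & rs$rt_ms > deadline_ms
  if (any(over)) {
    msg <- paste0(sum(over), " response(s) exceed the deadline of ",
                  deadline_ms, " ms")
    if (strict) abort(msg) else warn(msg)
  }
  rs
}

#' Serialise a fitted posterior to JSON
#'
#' Writes (and reads back) an `epabc_fit` as JSON: transforms, posterior
#' mean and covariance (row-major), per-site natural parameters, log
#' evidence and settings. The round trip reproduces the posterior exactly
#' at double precision.
#'
#' @param fit An `epabc_fit`.
#' @param path File path.
#' @return `read_fit()` returns the `epabc_fit`; `write_fit()` returns
#'   `path` invisibly.
#' @export
write_fit <- function(fit, path) {
  stopifnot(inherits(fit, "epabc_fit"))
  obj <- list(
    transforms = fit$transforms,
    mean = unname(fit$mean),
    cov = as.vector(t(fit$cov)),
    precision = as.vector(t(fit$precision)),
    shift = unname(fit$shift),
    sites = map(fit$sites, function(s) {
      list(r = s$r, Q = as.vector(t(s$Q)), log_s = s$log_s)
    }),
    log_evidence = fit$log_evidence,
    settings = fit$settings,
    acceptance = fit$acceptance,
    skipped = fit$skipped,
    n_trials = fit$n_trials,
    model = fit$model,
    trial_id = fit$trial_id
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_fit
#' @export
read_fit <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  d <- length(obj$mean)
  tf <- as_tibble(obj$transforms)
  sites <- if (length(obj$sites)) {
    # sites arrive as a data frame of list-columns after simplification
    purrr::map(seq_len(obj$n_trials), function(i) {
      list(r = as.numeric(obj$sites$r[[i]]),
           Q = matrix(as.numeric(obj$sites$Q[[i]]), d, d, byrow = TRUE),
           log_s = obj$sites$log_s[[i]])
    })
  } else list()
  fit <- new_epabc_fit(
    r = as.numeric(obj$shift),
    Q = matrix(as.numeric(obj$precision), d, d, byrow = TRUE),
    sites = sites,
    log_ev = obj$log_evidence,
    transforms = tf,
    settings = obj$settings,
    acc_rate = as.numeric(obj$acceptance),
    skipped = as.logical(obj$skipped),
    n_obs = obj$n_trials
  )
  fit$model <- obj$model
  fit$trial_id <- obj$trial_id
  fit
}
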