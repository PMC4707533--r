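#' Stimulus geometry for the dot-tracking task
#'
#' Builds the per-condition stimulus configuration of the single-dot tracking
#' task: two mirror-symmetric targets on the horizontal meridian, at
#' `+/- offset` pixels from the screen centre, around which the white dot
#' jumps. The coordinate frame has its origin at the screen centre, x positive
#' rightward, y positive downward; both targets sit on the centre row (the
#' task defines only horizontal offsets, so the vertical placement is a
#' documented convention).
#'
#' The canonical design has four difficulty levels, `D1` (hardest, offset
#' 10 px) through `D4` (easiest, offset 55 px); dot positions are drawn from
#' an isotropic 2-D Gaussian with SD 70 px per axis centred on the true
#' target, one dot every 93.2 ms, at most 25 dots per trial.
#'
#' @param condition Character vector of difficulty labels. The canonical
#'   labels `"D1"`, `"D2"`, `"D3"`, `"D4"` map to offsets 10, 25, 40, 55 px;
#'   other labels require an explicit `offset`.
#' @param offset Optional numeric vector of horizontal target offsets in
#'   pixels (recycled against `condition`). Overrides the canonical mapping.
#' @param sigma_stim Stimulus SD in pixels per axis (default 70).
#' @param dt_ms Duration of each dot in ms (default 93.2).
#' @param max_dots Maximum number of dots per trial (default 25).
#'
#' @return A tibble with one row per condition and columns `condition`,
#'   `offset`, `mu_left_x`, `mu_right_x`, `mu_y`, `sigma_stim`, `dt_ms`,
#'   `max_dots`.
#' @examples
#' target_config()
#' target_config("D4") # easiest: targets at +/- 55 px
#' @export
target_config <- function(condition = c("D1", "D2", "D3", "D4"),
                          offset = NULL,
                          sigma_stim = 70,
                          dt_ms = 93.2,
                          max_dots = 25) {
  stopifnot(is.character(condition), length(condition) >= 1)
  if (sigma_stim <= 0) abort("`sigma_stim` must be > 0")
  if (dt_ms <= 0) abort("`dt_ms` must be > 0")
  if (max_dots < 1) abort("`max_dots` must be >= 1")
  canonical <- c(D1 = 10, D2 = 25, D3 = 40, D4 = 55)
  if (is.null(offset)) {
    unknown <- setdiff(condition, names(canonical))
    if (length(unknown) > 0) {
      abort(paste0(
        "Unknown condition label(s): ", paste(unknown, collapse = ", "),
        ". Use D1-D4 or supply `offset` explicitly."
      ))
    }
    offset <- unname(canonical[condition])
  } else {
    offset <- rep_len(offset, length(condition))
  }
  if (any(offset <= 0)) abort("`offset` must be > 0")
  tibble(
    condition = condition,
    offset = offset,
    mu_left_x = -offset,
    mu_right_x = offset,
    mu_y = 0,
    sigma_stim = sigma_stim,
    dt_ms = dt_ms,
    max_dots = as.integer(max_dots)
  )
}

#' Sample the dot positions of a single trial
#'
#' Draws the full dot sequence of one trial: `max_dots` i.i.d. positions from
#' an isotropic 2-D Gaussian centred on the true target with SD `sigma_stim`
#' per axis. All dots are generated up front, as in the experiment, even
#' though a response may truncate viewing.
#'
#' @param config A single-row tibble from [target_config()].
#' @param true_target `"left"` or `"right"`.
#' @param trial_id Identifier stored in the output (default 1).
#' @return A tibble with columns `trial_id`, `condition`, `true_target`,
#'   `dot_index`, `x_px`, `y_px` and `max_dots` rows.
#' @examples
#' cfg <- target_config("D4")
#' sample_trial(cfg, "right")
#' @export
sample_trial <- function(config, true_target = c("left", "right"), trial_id = 1L) {
  true_target <- arg_match(true_target)
  stopifnot(is.data.frame(config), nrow(config) == 1)
  n <- config$max_dots
  mu_x <- if (true_target == "left") config$mu_left_x else config$mu_right_x
  tibble(
    trial_id = as.integer(trial_id),
    condition = config$condition,
    true_target = true_target,
    dot_index = seq_len(n),
    x_px = rnorm(n, mu_x, config$sigma_stim),
    y_px = rnorm(n, config$mu_y, config$sigma_stim)
  )
}

#' Generate a full session of trials
#'
#' Generates the complete stimulus set of a session: `per_side` left and
#' `per_side` right trials for every condition in `config` (canonical design:
#' 100 + 100 per condition over D1-D4, i.e. 800 trials). The same set is
#' intended to be shown to every participant, in per-participant randomised
#' order (see [shuffle_sessions()]).
#'
#' @param config Conditions tibble from [target_config()].
#' @param per_side Trials per (condition, side); scalar or vector over
#'   conditions (default 100).
#' @param seed Optional integer seed; when supplied the trial set is a pure
#'   function of `(config, per_side, seed)`.
#' @return A long tibble of trials; one row per dot, `max_dots` rows per
#'   trial, with columns as in [sample_trial()].
#' @examples
#' trials <- generate_trials(target_config("D4"), per_side = 5, seed = 1)
#' dplyr::n_distinct(trials$trial_id)
#' @export
generate_trials <- function(config = target_config(), per_side = 100, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  per_side <- rep_len(as.integer(per_side), nrow(config))
  if (any(per_side < 0)) abort("`per_side` must be non-negative")
  out <- vector("list", nrow(config))
  next_id <- 1L
  for (i in seq_len(nrow(config))) {
    cfg <- config[i, ]
    n_tr <- 2L * per_side[i]
    if (n_tr == 0L) next
    sides <- rep(c("left", "right"), each = per_side[i])
    T <- cfg$max_dots
    mu_x <- ifelse(sides == "left", cfg$mu_left_x, cfg$mu_right_x)
    # one rnorm call per coordinate block keeps generation fast and seed-stable
    x <- rnorm(n_tr * T, mean = rep(mu_x, each = T), sd = cfg$sigma_stim)
    y <- rnorm(n_tr * T, mean = cfg$mu_y, sd = cfg$sigma_stim)
    out[[i]] <- tibble(
      trial_id = rep(seq.int(next_id, length.out = n_tr), each = T),
      condition = cfg$condition,
      true_target = rep(sides, each = T),
      dot_index = rep.int(seq_len(T), n_tr),
      x_px = x,
      y_px = y
    )
    next_id <- next_id + n_tr
  }
  bind_rows(out)
}

#' Per-participant presentation orders of one shared trial set
#'
#' The experiment showed every participant the exact same trial set in
#' randomised order. This returns independent permutations of the trial ids
#' of `trials`, one per participant.
#'
#' @param trials Long trials tibble from [generate_trials()].
#' @param n_participants Number of orderings to draw.
#' @param seed Optional integer seed.
#' @return A tibble with columns `participant`, `position` (presentation
#'   rank) and `trial_id`; each participant's `trial_id` column is a
#'   permutation of the shared set.
#' @export
shuffle_sessions <- function(trials, n_participants = 24, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ids <- unique(trials$trial_id)
  purrr::map(seq_len(n_participants), function(p) {
    tibble(
      participant = p,
      position = seq_along(ids),
      trial_id = sample(ids)
    )
  }) |> list_rbind()
}

# Compile a long trials tibble into the matrix form used by the simulator:
# a list with x (n_trials x max_dots matrix of dot x-coordinates), offsets,
# true-target signs (+1 right, -1 left) and per-trial metadata.
compile_trials <- function(trials, config = NULL) {
  stopifnot(all(c("trial_id", "condition", "true_target", "dot_index", "x_px") %in%
                  names(trials)))
  if (is.null(config)) {
    conds <- unique(trials$condition)
    config <- target_config(conds)
  }
  key <- trials[trials$dot_index == 1L, c("trial_id", "condition", "true_target")]
  key <- key[!duplicated(key$trial_id), ]
  ord <- order(match(trials$trial_id, key$trial_id), trials$dot_index)
  tr <- trials[ord, ]
  T <- max(tr$dot_index)
  n <- nrow(key)
  if (nrow(tr) != n * T) {
    abort("trials table is ragged: every trial must have the same number of dots")
  }
  cfg_row <- match(key$condition, config$condition)
  if (anyNA(cfg_row)) abort("condition missing from `config`")
  list(
    trial_id = key$trial_id,
    condition = key$condition,
    true_sign = ifelse(key$true_target == "right", 1, -1),
    offset = config$offset[cfg_row],
    x = matrix(tr$x_px, nrow = n, ncol = T, byrow = TRUE),
    sigma_stim = config$sigma_stim[[1]],
    dt_ms = config$dt_ms[[1]],
    max_dots = T
  )
}
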