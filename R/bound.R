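#' Time-varying decision bound
#'
#' Value of the (possibly collapsing) confidence bound at decision step `t`.
#' The bound starts at `b0` and decays towards 0.5 as the trial deadline
#' approaches:
#'
#' \deqn{b(t) = 0.5 + (b_0 - 0.5)\,\bigl(1 - s\,(t/t_{max})^{k}\bigr)}
#'
#' `s = 0` keeps the bound fixed at `b0`; `s = 1` collapses it completely to
#' 0.5 at `t = t_max`. The shape `k` controls the timing: `k < 1` collapses
#' early in the trial, `k > 1` late. The bound is monotonically
#' non-increasing in `t` and never falls below 0.5.
#'
#' @param t Decision step(s), in dot counts; `t = 0` means stimulus onset.
#' @param t_max Deadline in dot counts (default 25).
#' @param b0 Initial bound, in (0.5, 1].
#' @param s Stretch (collapse fraction), in \[0, 1\].
#' @param k Shape (> 0).
#' @return Numeric vector of bound values, same length as `t`.
#' @examples
#' bound_value(0:25, b0 = 0.9, s = 1, k = 1)
#' @export
bound_value <- function(t, t_max = 25, b0 = 0.8, s = 0, k = 1) {
  if (any(b0 <= 0.5 - 1e-12 | b0 > 1)) abort("`b0` must be in (0.5, 1]")
  if (any(s < 0 | s > 1)) abort("`s` must be in [0, 1]")
  if (any(k <= 0)) abort("`k` must be > 0")
  if (any(t < 0)) abort("`t` must be >= 0")
  0.5 + (b0 - 0.5) * (1 - s * (t / t_max)^k)
}

# Matrix of logit-bounds over proposals x steps. Parameters are length-n
# (or scalar) vectors; returns an n x t_max matrix. abs(log-odds) >= this
# threshold is the crossing criterion.
bound_logit_matrix <- function(n, t_max, b0, s, k) {
  b0 <- rep_len(b0, n); s <- rep_len(s, n); k <- rep_len(k, n)
  if (all(s == 0)) {
    th <- qlogis(pmin(b0, 1 - 1e-12))
    return(matrix(th, n, t_max))
  }
  # (t/t_max)^k row-wise: exp(k * log(u))
  lu <- log(matrix(seq_len(t_max) / t_max, n, t_max, byrow = TRUE))
  b <- 0.5 + (b0 - 0.5) * (1 - s * exp(k * lu))
  qlogis(pmin(pmax(b, 0.5), 1 - 1e-12))
}
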