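#' Parameter transforms between the unconstrained and model space
#'
#' EP-ABC works on an unconstrained vector `z` with a standard-normal prior;
#' each model parameter is obtained from its own component of `z` through a
#' transform that simultaneously encodes the prior:
#'
#' * `identity`: `theta = mu + sigma * z` (normal prior `N(mu, sigma^2)`),
#' * `exponential`: `theta = exp(mu + sigma * z)` (log-normal prior),
#' * `uniform`: `theta = offset + range * pnorm(z)` (uniform prior on
#'   `[offset, offset + range]`).
#'
#' @param name Parameter name.
#' @param kind `"identity"`, `"exponential"` or `"uniform"`.
#' @param mu,sigma Location/scale of the affine map inside the identity and
#'   exponential transforms.
#' @param offset,range Interval of the uniform transform.
#' @return A one-row tibble describing the transform.
#' @examples
#' param_transform("bound", "uniform", offset = 0.5, range = 0.5)
#' @export
param_transform <- function(name, kind = c("identity", "exponential", "uniform"),
                            mu = 0, sigma = 1, offset = 0, range = 1) {
  kind <- arg_match(kind)
  if (sigma <= 0 && kind != "uniform") abort("`sigma` must be > 0")
  if (range <= 0 && kind == "uniform") abort("`range` must be > 0")
  tibble(name = name, kind = kind, mu = mu, sigma = sigma,
         offset = offset, range = range)
}

#' Default transforms (priors) per accumulation variant
#'
#' One transform per free parameter, in the model's parameter order. The
#' implied priors are wide enough to cover all plausible values of the
#' dot-tracking task while honouring the parameters' ranges: positive scales
#' get log-normal priors, probabilities uniform priors (the bound on
#' `(0.5, 1]`, the lapse probability on `(0, 0.3)` since lapses are rare).
#'
#' @param variant `"standard"`, `"leaky"` or `"collapsing"`.
#' @return A tibble of transforms, one row per parameter.
#' @export
default_transforms <- function(variant = c("standard", "leaky", "collapsing")) {
  variant <- arg_match(variant)
  tf <- bind_rows(
    param_transform("sigma_s", "exponential", mu = 4, sigma = 1),
    param_transform("ndt_mu", "identity", mu = 6, sigma = 0.5),
    param_transform("ndt_sigma", "exponential", mu = -1, sigma = 0.5),
    param_transform("bound", "uniform", offset = 0.5, range = 0.5),
    param_transform("prior_left", "uniform", offset = 0, range = 1),
    param_transform("lapse_p", "uniform", offset = 0, range = 0.3),
    param_transform("lapse_to_p", "uniform", offset = 0, range = 1)
  )
  extra <- switch(variant,
    standard = NULL,
    leaky = param_transform("discount", "uniform", offset = 0, range = 1),
    collapsing = bind_rows(
      param_transform("stretch", "uniform", offset = 0, range = 1),
      param_transform("shape", "exponential", mu = 0, sigma = 0.5)
    )
  )
  bind_rows(tf, extra)
}

#' Map unconstrained draws to model parameters
#'
#' Applies the transforms element-wise to a matrix of unconstrained draws
#' (rows = draws, columns = parameters in transform order).
#'
#' @param z Numeric matrix (or vector, treated as one row).
#' @param transforms Transform tibble ([default_transforms()]).
#' @return A tibble of model-space parameters with one row per draw.
#' @export
to_model_space <- function(z, transforms) {
  if (is.null(dim(z))) z <- matrix(z, nrow = 1)
  if (ncol(z) != nrow(transforms)) {
    abort("`z` must have one column per transform")
  }
  cols <- lapply(seq_len(nrow(transforms)), function(j) {
    tf <- transforms[j, ]
    switch(tf$kind,
      identity = tf$mu + tf$sigma * z[, j],
      exponential = exp(tf$mu + tf$sigma * z[, j]),
      uniform = tf$offset + tf$range * pnorm(z[, j])
    )
  })
  names(cols) <- transforms$name
  as_tibble(cols)
}

#' Map model parameters back to the unconstrained space
#'
#' Exact inverse of [to_model_space()] on the interior of each transform's
#' image.
#'
#' @param params Data frame with the transform-named columns.
#' @param transforms Transform tibble.
#' @return Numeric matrix of unconstrained values.
#' @export
from_model_space <- function(params, transforms) {
  z <- matrix(NA_real_, nrow(params), nrow(transforms))
  for (j in seq_len(nrow(transforms))) {
    tf <- transforms[j, ]
    th <- params[[tf$name]]
    if (is.null(th)) abort(paste0("missing parameter column: ", tf$name))
    z[, j] <- switch(tf$kind,
      identity = (th - tf$mu) / tf$sigma,
      exponential = {
        if (any(th <= 0)) abort(paste0(tf$name, ": value outside the image of the exponential transform"))
        (log(th) - tf$mu) / tf$sigma
      },
      uniform = {
        u <- (th - tf$offset) / tf$range
        if (any(u <= 0 | u >= 1)) abort(paste0(tf$name, ": value outside the image of the uniform transform"))
        qnorm(u)
      }
    )
  }
  colnames(z) <- transforms$name
  z
}

# Complete a transformed parameter tibble with the variant-inactive columns
# so it can be fed to the simulator.
complete_params <- function(params) {
  defaults <- c(discount = 1, stretch = 0, shape = 1,
                lapse_p = 0, lapse_to_p = 0)
  for (nm in names(defaults)) {
    if (is.null(params[[nm]])) params[[nm]] <- defaults[[nm]]
  }
  params
}
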