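# dotddm

Single-trial Bayesian evidence-accumulation modelling of two-alternative
perceptual decisions about a tracked dot.

## The problem

In the single-dot tracking task, a participant watches a white dot jump to a
new screen position every 93.2 ms (at most 25 jumps, ≈ 2.33 s) around one of
two candidate targets placed mirror-symmetrically at ±10, ±25, ±40 or ±55 px
from the screen centre (difficulty levels D1–D4). Dot positions are i.i.d.
draws from an isotropic 2-D Gaussian with SD 70 px centred on the true
target. The participant reports *left* or *right* as fast and as accurately
as possible, or the trial times out.

Because the full stimulus — every dot position the observer saw — is known,
choices and reaction times can be modelled *per trial* rather than on
average. `dotddm` implements the complete analysis pipeline for this kind of
data: stimulus generation, a Bayesian observer model of the response,
likelihood-free posterior inference per participant and condition, and
formal model comparison. For researchers in perceptual decision making it
provides, in one tidyverse-native package, the machinery to ask whether
behaviour tracks the exact spatio-temporal input ("exact input model",
ExaM) or only its average (the DDM-equivalent model), and which
accumulation mechanism (standard, leaky, collapsing bound) describes it
best.

## The model

At step `t` the observer receives a noisy observation of the stimulus,

    o_t = x_t + ε_t,            ε_t ~ N(0, σ_s² I)   (exact input model)
    o_t = μ_true + ε_t                               (DDM-equivalent model)

where `x_t` is the dot position actually shown and `μ_true` the true target
location. Beliefs over the two targets are updated by Bayes' rule with the
stimulus generative densities `N(μ_i, 70² I)` as likelihoods; on the
log-odds of the left target this is the accumulation

    L_t = λ · L_(t-1) + log N(o_t; μ_L, 70² I) − log N(o_t; μ_R, 70² I),
    L_0 = logit(prior),

with leak exponent `λ = 1` for lossless (standard) accumulation. A response
is committed at the first step where either posterior belief reaches the
bound `b(t)`; the collapsing-bound variant lets the bound decay,

    b(t) = 0.5 + (b₀ − 0.5)(1 − s·(t/t_max)^k),

from `b₀` toward 0.5 (stretch `s`, shape `k`). The reaction time is
`t_d · 93.2 ms` plus a log-normal non-decision time; trials without a bound
crossing within 25 steps time out, and a lapse mixture (random response or
lapse-timeout) completes the response model.

Parameters are fitted per participant-condition with EP-ABC
(expectation-propagation approximate Bayesian computation): one Gaussian
factor per trial, updated by moment-matching parameter samples whose
simulated response reproduces the observed one (same choice, RT within
ε = 46.6 ms). The fit yields a full posterior and the log model evidence.
Models are compared by posterior predictive likelihoods per trial and by
random-effects Bayesian model selection with protected exceedance
probabilities.

## Worked example

Generate one condition's session, simulate a synthetic participant with
known parameters, and fit the model to their responses:

```r
library(dotddm)
library(dplyr)

cfg       <- target_config("D2")                     # targets at ±25 px
trials    <- generate_trials(cfg, per_side = 100, seed = 1)
truth     <- model_params(sigma_s = 58, ndt_mu = 6.15, ndt_sigma = 0.35,
                          bound = 0.77, prior_left = 0.47,
                          lapse_p = 0.02, lapse_to_p = 0.17)
responses <- simulate_responses(trials, truth, mode = "exact", seed = 2)

responses |>
  left_join(distinct(trials, trial_id, true_target), by = "trial_id") |>
  filter(choice != "timeout") |>
  summarise(accuracy = mean(choice == true_target), mean_rt = mean(rt_ms))
#>   accuracy mean_rt
#> 1     0.74    822.

fit <- fit_decision_model(trials, responses[, c("trial_id", "choice", "rt_ms")],
                          mode = "exact", seed = 3)
fit
#> EP-ABC fit (200 trials, 4 passes)
#> model: exact input, standard accumulation
#> log evidence: -1351.96
#> # A tibble: 7 × 4
#>   term       estimate    conf.low conf.high
#> 1 sigma_s    59.5     45.3          77.3
#> 2 ndt_mu      6.19     6.01          6.36
#> 3 ndt_sigma   0.360    0.264         0.481
#> 4 bound       0.774    0.734         0.812
#> 5 prior_left  0.515    0.402         0.624
#> 6 lapse_p     0.00954  0.00000390    0.0665
#> 7 lapse_to_p  0.433    0.000301      0.997
```

The fitted posterior recovers the generating parameters (compare `estimate`
to `truth`); `accuracy` is the fraction of correct non-timeout responses
and `mean_rt` their average reaction time in ms. Downstream,
`posterior_predictive()` scores each observed trial under the fit,
`point_prediction()` + `match_table()` build choice-match tables, per-fit
`$log_evidence` values feed `rfx_bms()` for model selection, and
`make_cohort()` / `recovery_experiment()` run whole-cohort parameter- and
model-recovery studies.

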