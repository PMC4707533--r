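---
title: "Modelling single-dot tracking decisions with dotddm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling single-dot tracking decisions with dotddm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`dotddm` models two-alternative perceptual decisions about a single tracked
dot at the level of individual trials. This vignette explains the model and
its assumptions, the inference machinery, the numerical choices the
implementation makes, and what the synthetic-data tools do and do not
establish.

## The task and its generative model

A trial shows a white dot that jumps to a fresh position every
`dt_ms = 93.2` ms, for at most `max_dots = 25` jumps. Dot positions are
i.i.d. draws from an isotropic bivariate Gaussian with SD
`sigma_stim = 70` px centred on the true target; the two candidate targets
sit at `±offset` px on the horizontal meridian (10/25/40/55 px for
difficulty levels D1–D4). The observer answers *left* or *right*, or the
trial times out after the 25th dot (≈ 2330 ms).

Two conventions in `target_config()` deserve flagging. The coordinate frame
puts the origin at the screen centre (x rightward, y downward, px). The
task specifies only horizontal target offsets, so both targets are placed
on the centre row; the vertical placement is an assumption, though an
inconsequential one — for mirror-symmetric targets with a shared isotropic
generative SD, the vertical coordinate cancels from every likelihood ratio.
All 25 dots of a trial are generated up front even though a response
truncates viewing, mirroring an experiment whose stimuli are pre-generated;
the decision model only consumes the first `t_d` of them.

## The response model

The observer receives, at step `t`, a noisy observation of the stimulus.
Its mean is the actual dot position in the exact input model (ExaM) and
the constant true-target position in the DDM-equivalent model; isotropic
sensory noise with SD `sigma_s` is added in both. Beliefs over the targets
are updated recursively by Bayes' rule, using the same Gaussian densities
that generate the stimuli as likelihoods. The sensory noise deliberately
does *not* widen the observer's likelihood: `sigma_s` is pure observation
corruption, and the generative SD stays at the stimulus value of 70 px.
(The alternative — an observer that knows its own noise level and uses the
total variance — was checked against the task's empirical regime during
development and produces runaway reaction times and timeout rates at the
hardest difficulty; it is also a different model than intended here.)

On the log-odds of the left target the update is linear:
`L_t = discount * L_(t-1) + delta_t`, with `delta_t` the log-likelihood
ratio of observation `t` and `L_0` the prior log-odds. `discount = 1` is
lossless (standard) accumulation; `discount < 1` leaks past evidence, and
`discount = 0` bases each step on the current dot alone. A response is
committed at the first step where a posterior belief reaches the bound.

The collapsing-bound variant uses

`b(t) = 0.5 + (b0 - 0.5) * (1 - s * (t / t_max)^k)`

which satisfies the contract the mechanism requires: `b(0) = b0`; `s = 0`
keeps the bound fixed; `s = 1` collapses it exactly to 0.5 (indifference)
at the deadline; `k < 1` spends the collapse early in the trial, `k > 1`
late; the bound is monotone non-increasing and never falls below 0.5. The
exact parametric family is a design choice — any smooth family with these
limits would serve — and `bound_value()` is the single point of truth for
it.

Reaction time is `t_d * dt_ms` plus a non-decision time drawn from a
log-normal distribution (`ndt_mu` on the log-ms scale, `ndt_sigma`);
log-normality enforces positivity, and fits are reported as the
distribution's mode and SD in ms (`ndt_summary()`, with the numerical
inverse `ndt_params_from_summary()` for driving simulations from reported
values). A lapse mixture completes the model: with probability `lapse_p` a
trial ignores the evidence entirely and either times out (probability
`lapse_to_p`) or draws a fair-coin choice with a uniform RT on
`(0, deadline]`.

One ambiguity is resolved by a switch. The experiment's deadline could
apply to the decision step only, or to the full RT including the
non-decision time. `simulate_responses(ndt_deadline = FALSE)` — the
default — times out exactly the trials whose beliefs never reach the bound
within 25 steps; setting `ndt_deadline = TRUE` additionally converts
responses whose total RT exceeds `25 * 93.2` ms into timeouts. Both rules
are implemented because the task description supports either reading; the
decision-step rule is the default since the deadline is defined on the
stimulus presentation.

### Numerical choices in the simulator

* Beliefs are clamped to `[1e-12, 1 - 1e-12]` (log-odds to ≈ ±27.6)
  before each update, so extreme observations cannot produce `log(0)`
  under the leak exponent. At any practically fitted bound this never
  affects a decision.
* All likelihood computation happens in log space. The vectorised engine
  exploits the symmetry noted above: only the horizontal observation
  coordinate carries evidence, so one trial's 25 two-dimensional updates
  reduce to 25 scalar increments. The exported `belief_update()` computes
  the full 2-D form, and the test suite pins the two to each other and to
  a batch-Bayes closed form.
* Bound ties cannot occur for `bound > 0.5` (beliefs sum to 1); at
  `bound = 0.5` the larger belief wins and an exactly tied log-odds of 0
  falls to a fair coin.
* Decision steps are 1-based (first dot = step 1) and RT conversion uses
  exactly `dt_ms = 93.2`.

## Inference: EP-ABC

The model's likelihood is intractable but simulation is cheap, so
parameters are fitted with expectation-propagation approximate Bayesian
computation (`ep_abc()`, wrapped for this model by
`fit_decision_model()`). The posterior over an unconstrained parameter
vector with a standard-normal prior is approximated by a Gaussian times
one Gaussian site factor per trial. A site update draws proposals from the
cavity (posterior minus that site), simulates one response per proposal on
that trial's actual dots, accepts proposals whose response reproduces the
observed one — same choice and RT within `eps_ms`, strictly — and
moment-matches the posterior to the accepted sample once `min_accepted`
have been collected. Timeouts carry no RT, so a simulated timeout matches
an observed one on choice alone. The log model evidence accumulates the
per-site acceptance rates (normalised by the `2 * eps_ms` RT window for
non-timeout data) with the usual EP Gaussian corrections, and is exactly 0
for an empty dataset.

Parameter constraints live in the transforms (`param_transform()`,
`default_transforms()`): exponential transforms give positive scales
log-normal priors, probit-uniform transforms give probabilities uniform
priors. The defaults were chosen once to cover all plausible values for
this task: `sigma_s ~ logN(4, 1)` px; `ndt_mu ~ N(6, 0.5)` log-ms (median
≈ 400 ms); `ndt_sigma ~ logN(-1, 0.5)`; `bound ~ U(0.5, 1)`;
`prior_left ~ U(0, 1)`; `lapse_p ~ U(0, 0.3)` (lapses are rare; a full
`U(0, 1)` would put most prior mass on behaviour no attentive participant
shows); `lapse_to_p ~ U(0, 1)`; `discount ~ U(0, 1)`; `stretch ~ U(0, 1)`;
`shape ~ logN(0, 0.5)`. Every hyperparameter is an argument, so other
choices drop in verbatim.

### Tunable fit settings and why their defaults are what they are

* `eps_ms = 46.6` — half the dot duration: the natural resolution at which
  two RTs are behaviourally indistinguishable in this task.
* `min_accepted = 300` — accepted samples per site update; the moment
  estimates' Monte-Carlo error scales as `1/sqrt(300)`.
* `passes = 4` — sweeps over all trials; the first pass processes early
  trials against a prior-dominated cavity, later passes correct this.
* `max_proposals = 500 * min_accepted` per site and pass. The budget
  determines which trials can be fitted at all: a trial only matchable
  through the lapse route has acceptance probability on the order of
  `lapse_p * 2*eps_ms / deadline` ≈ 0.2%, and a budget that cannot reach
  `min_accepted` there silently drops exactly the lapse-informative
  trials, biasing `lapse_p` downward (this was observed and fixed during
  calibration testing). Sites that still exhaust the budget are skipped
  with a warning; their acceptance rate still enters the evidence. A fit
  aborts if more than `max_skip_frac = 20%` of sites skip in one pass.
* `damping = 0.5` — site updates move halfway to the moment-matched
  solution. Full updates let the Monte-Carlo noise of 300-sample moment
  estimates accumulate across hundreds of site updates and can destabilise
  later passes; damping halves the per-update noise injection at the cost
  of slower convergence (hence 4 passes).
* Two numerical guards: the moment-matched precision is debiased by the
  inverse-Wishart factor `(M - d - 2)/(M - 1)` — without it each update
  inflates the posterior precision by roughly `(d + 1)/M` and the fit
  collapses multiplicatively over a few hundred updates — and the cavity
  precision's eigenvalues are floored at `cavity_min_prec = 0.04`
  (proposal SDs capped at five prior SDs), so a site with aggressive
  natural parameters cannot demand proposals from a near-singular cavity.
  Global covariance repairs use an eigenvalue floor of `min_eig = 1e-8`
  and all matrices are re-symmetrised after updates.

`rejection_abc()` provides the brute-force oracle — prior draws, simulate
the whole dataset, accept only perfect reproductions — which is tractable
for a handful of trials and anchors the EP-ABC tests, together with a
linear-Gaussian toy whose posterior and evidence are known in closed form.

## Model comparison

`posterior_predictive()` estimates each trial's posterior predictive
likelihood as the fraction of `n = 15000` posterior-parameter simulations
reproducing the observed response under the same distance criterion the
fit used. Zero matches are floored at `1/(n + 1)` before taking logs — the
resolution limit of the estimator, which keeps log-PPL sums finite without
inventing precision. `point_prediction()` reports the modal choice among
non-timeout simulations (a 50/50 split falls to the alternative with more
total mass, then to *left*) and the modal RT bin — bins are `dt_ms` wide
and aligned to the decision grid, matching the model's discrete decision
times convolved with the NDT — reported as the bin midpoint, earlier bin
on ties. `match_table()` cross-tabulates model and participant correctness.

`rfx_bms()` performs random-effects Bayesian model selection on a
participants-by-models log-evidence matrix: variational Dirichlet
estimation of the population model frequencies (uniform `Dirichlet(1)`
prior), exceedance probabilities by Monte-Carlo over the Dirichlet
posterior (`n_mc = 1e6` draws), and protected exceedance probabilities
`PXP = EP * (1 - BOR) + BOR / M`, where the Bayes omnibus risk compares
the random-effects free energy against the equal-frequency null model.

## Synthetic cohorts and what they establish

`make_cohort()` reproduces the study design: one shared stimulus set (by
default 800 trials — 100 per side per difficulty level), shown to every
participant in an independently shuffled order, with responses simulated
from the decision model under known ground truth. Truths come from the
reference fitted parameter table (`truth_mode = "table"`), from the
fitting priors (`"sampled"`, the well-specified calibration case), or are
fixed by the caller. `recovery_experiment()` closes the loop: fit every
participant-condition, score bias, RMSE and 95%-interval coverage against
the truth, and optionally fit a second input mode for model recovery via
`rfx_bms()`.

The generator emulates the study's *structure* — trial counts, shared
stimuli, randomised orders, response model — with the published group-mean
parameters standing in for participants. It does not emulate
between-participant parameter variability around those means, learning or
fatigue across a session, sequential dependencies between trials, or any
deviation of real observers from the response model itself. Passing
recovery tests therefore show that the inference machinery is calibrated
and selective *when the model is true*; they cannot show that the model is
true of human observers. The parameter-driven simulation checks
(`scripts/acceptance.R`) inherit the same caveat in reverse: they simulate
at cohort-mean parameters, and a nonlinear model simulated at the mean of
individually fitted parameters need not reproduce the mean of individual
behaviour exactly — mean RTs land close, accuracies a few percentage
points below the group means, and that gap is an honest property of the
construction, not a tuning target.

## Problem sizes in the test suite

The test suite exercises full-scale properties where they are cheap
(closed-form identities, 100-sequence batch-vs-recursive checks, 1e5-step
increment moments, 15000-vs-150000-simulation PPL consistency) and runs
the expensive inference checks at sizes chosen to keep a complete run on a
single CPU comfortable: parameter-recovery calibration uses 10
participant-conditions of 200 trials with prior-drawn truths at the
default fit settings, and model recovery uses 5 cohorts of 8 participants
with 40 trials each at `min_accepted = 150`, `passes = 2` — the evidence
separation between input modes at those sizes is already an order of
magnitude larger than its variability. These sizes are the package's
standing choices for its own regression tests, not statements about the
smallest designs the methods support.

## Known limitations

* The Gaussian EP posterior cannot represent multimodality or strong
  skew; `lapse_to_p` in particular is weakly identified when timeouts are
  rare, and its posterior honestly spans most of its range.
* Evidence estimates inherit Monte-Carlo noise from acceptance rates;
  comparisons should rest on evidence *differences* well above a few
  units, or on repeated fits.
* The simulator is discrete-time by construction (93.2 ms steps); the
  package does not approximate continuous-time diffusion within a step.
* Two alternatives only; no hierarchical pooling across participants; no
  within-trial attention, confidence, or learning processes.
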