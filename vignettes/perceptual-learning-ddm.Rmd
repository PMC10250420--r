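---
title: "Continuous-time drift diffusion models of perceptual learning"
author: "ddmlearn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Continuous-time drift diffusion models of perceptual learning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ddmlearn)
```

## The problem

In multi-day perceptual training, performance improves both within a
session and across sessions, and the two kinds of change need not reflect
the same process.  Fitting a separate model per session assumes away any
within-session learning; `ddmlearn` instead models every trial of a
multi-day random-dot-motion discrimination experiment with a drift
diffusion model (DDM) whose parameters are continuous functions of trial
number.  Decomposing behavior into drift rate (DR; perceptual
sensitivity), response boundary (RB; response caution), starting-point
bias and non-decision time (NDT) lets the data say *which* component
changes on *which* timescale.

## The model

Each trial's joint likelihood of choice and response time is the
first-passage density of a Wiener diffusion with unit diffusion
coefficient between two absorbing boundaries: drift `v`, boundary
separation `a`, relative start `z`, non-decision time `t0`.  The density
is evaluated with the standard dual series — a small-time and a
large-time expansion, switching by whichever needs fewer terms at a
truncation error of 1e-7.  Responses are accuracy-coded: the upper
boundary is the correct response, and drift is positive toward correct.
Drift is a linear function of median-centered stimulus coherence (the
design median, 6.4%), with a per-subject intercept and slope; the
comparison of linear versus log coherence scaling is available via
`coherence_link`.  RB evolves on the log scale (guaranteeing `a > 0`),
bias on the logit scale, and `t0 = 0.001 + offset` with `offset > 0`.
Bias and NDT are constant over time within a participant; only DR and RB
carry learning dynamics — time-varying NDT is deliberately excluded
because NDT changes are poorly recoverable from RB changes.

Every time-varying parameter follows the exponential learning curve

    param(trial) = asymptote + (start - asymptote) * 2^((1 - trial) / (2 + 2^rate))

so `param(1) = start` exactly, the curve moves monotonically to
`asymptote`, and `rate` is the binary log of a time-to-50%-of-change
constant: `T50 = 2 + 2^rate`, always above 2 trials, which keeps the
curve identifiable at short timescales.  Four dynamics are supported:
*constant*; *continuous* (one curve in cumulative trial number);
*day-resetting* (one curve in within-day trial number, repeated each
day); and *flexible* (within-day curves with day-specific starts and
asymptotes and one shared rate per parameter per subject).  The six
candidate models combine these: A constant/constant, B
continuous/continuous, C continuous/day-resetting, D
continuous/flexible, E flexible/continuous, F flexible/flexible (DR form
first, RB second).  The DR coherence slope follows the same dynamics as
the DR intercept with a shared rate, mirroring the always-present
by-subject coherence slope on both endpoints of the trajectory.

Priors (used by the Bayesian backend, the MAP penalty, and restart
initialization): Student-t(3, 1, 10) on drift-scale parameters,
normal(-0.6, 1.3) on log-RB, normal(0, 1) on logit bias, exponential
(mean 0.15 s) on the NDT offset, and normal(log2(0.25 × max trial), 1)
on rates — centered on a quarter of the within-day trial count for
within-day forms and of the whole-experiment count for continuous forms,
placing ±2 SD between 1/16 of the timescale and the full timescale.

## Fitting backends

`fit_mle()` is the desk-scale default: independent per-participant fits
by bounded quasi-Newton optimization over an unconstrained transform
(drift parameters and rates free within sanity boxes; log-RB free; logit
bias; NDT mapped by a scaled logit into (0.001 s, min RT − 1e-4 s), so
the likelihood is finite everywhere the optimizer can step).  Each
subject gets a moment-based (EZ-style) start plus jittered restarts; the
best of `n_restarts` wins; everything is deterministic given `seed`.

Three numerical choices matter and are deliberate:

* **Rate bounds.** A time-to-half longer than the relevant timescale's
  trial count makes the asymptote an unconstrained extrapolation, so
  rates are optimized within [0, log2(max trial)] (T50 between 3 trials
  and the design length plus 2).  This mirrors the rate prior's support
  statement rather than inventing new information.
* **MAP penalty.** `penalty = "prior"` adds the model's own priors to
  the objective.  For trajectory models this is recommended: it is the
  same regularization the Bayesian backend applies, and it stabilizes
  the start/asymptote/rate decomposition at a few hundred trials per
  subject.
* **Group shrinkage.** `shrink = c(rate_dr = 0.3, rate_rb = 0.3)` runs a
  second pass penalizing the named parameters toward the first-pass
  group means — a desk-scale stand-in for the hierarchical
  random-effects structure, with one tuning SD per parameter.  Rates
  benefit most, because they are shared-shape parameters that the
  hierarchical model would pool anyway.

`fit_bayes()` samples the same transformed space with an adaptive
random-walk Metropolis sampler (Robbins-Monro scale adaptation to ~30%
acceptance, proposal covariance re-estimated during warmup), retains
per-draw pointwise log-likelihoods for PSIS-LOO and the joint
unnormalized log-posterior for bridge sampling, and reports split R-hat
(convergence bar 1.03) and an autocorrelation-based effective sample
size.  It is meant for modest problems; full hierarchical MCMC of all
subjects jointly is out of desk scope by design.

## Model comparison

`psis_loo()` implements Pareto-smoothed importance-sampling leave-one-out
cross-validation: per observation, the top 20% of importance weights are
replaced by expected order statistics of a generalized Pareto fit
(Zhang–Stephens profile-posterior estimator with the standard
weakly-informative shape regularization), truncated at the largest raw
weight.  It reports LOOIC on the deviance scale with its SE and per-point
Pareto-k diagnostics, and is validated in the tests against brute-force
exact leave-one-out refits on a conjugate toy.  `compare()` ranks
Bayesian fits by LOOIC with pairwise difference SEs and flags differences
larger than 4 that also exceed several SEs; for maximum-likelihood fits it
reports AIC and BIC and ranks by AIC by default, because AIC, like LOOIC,
estimates cross-validated deviance (BIC's heavier penalty is available
via `mle_criterion = "BIC"`).

`bridge_log3_bf()` estimates each model's log marginal likelihood by the
iterative optimal-bridge estimator with a warped (moment-matched
multivariate normal) proposal, repeats the procedure 15 times, and
reports the most equivocal run — the base-3 log Bayes factor closest to
0, so ±1 marks the conventional "substantial evidence" threshold.  Runs
whose proposal fails to overlap the posterior return an infinite
sentinel rather than a number.  The iteration cap and tolerance are
exposed as arguments.

## The synthetic-data generator

`generate_design()` reproduces the study design: 4 days × 700 trials per
participant, 100 trials of each of 7 coherence levels (0.8 to 51.2%,
doubling) in randomized order per day, left/right balanced at random.
`sample_ground_truth()` draws subject parameters around the group-level
point estimates of the best-fitting analysis: DR start 0.44 and
asymptote 0.96 at the median coherence (asymptote SD 0.175, matching the
reported spread of DR change), time-to-half 1261 trials on the
2800-trial design, log-RB around 1.9 falling toward 1.4-1.5 with a clear
day-1 to day-2 drop, NDT near 0.3 s, bias near 0.5.  Coherence slopes
(0.02 to 0.05 per %) are chosen so accuracy spans ~55% at 0.8% coherence
to ~99% at 51.2% — values a motion-discrimination practitioner would
call realistic.  Time-to-half constants rescale proportionally on
reduced designs so the same relative dynamics are expressed.  Trials are
sampled exactly by numerical inversion of the first-passage CDF on dense
per-trial grids (self-consistent with the likelihood; an independent
Euler-Maruyama simulator is kept as an oracle and cross-checked by
chi-square and KS tests), plus a 0.5% contaminant fraction with uniform
(0.05, 3.0) s RTs to exercise the exclusion filter (RTs below 0.16 s or
above 2.5 s excluded; boundary values retained).

What the generator does *not* emulate: sequential dependencies, fatigue,
feedback-driven strategy shifts, non-stationary lapsing, or any
deviation from the Wiener likelihood itself.  Passing recovery tests
therefore demonstrates internal consistency of the estimation machinery
under the model's own assumptions — not that real data obey those
assumptions.

## Problem sizes

The package's tests and the acceptance script use reduced designs chosen
once: recovery uses 12 subjects × 4 days × 203 trials (29 per coherence
level — day lengths must be multiples of the 7 levels); model-selection
recovery uses 8 subjects × 4 × 98 trials with 10 replicates per
generating model; the logistic baseline uses the full 2800-trial design
with 8 subjects.  The full 21-subject, 2800-trial hierarchical analysis
is supported as a run mode but is not part of the automated checks.

## The logistic baseline

`fit_logistic_dynamics()` is the accuracy-only comparison: a logistic
psychometric function `p(right) = lapse/2 + (1 - lapse) ·
logistic(signed coherence / threshold)` with a fixed 1% lapse, whose
log-threshold follows continuous, day-resetting, flexible, or
continuous-plus-day-resetting dynamics (the latter adds a day-resetting
offset decaying to zero within each day to the continuous curve — an
offset, not a second full curve, so the combined model nests the
continuous one at zero amplitude).  Z-scored RTs enter as by-subject
slopes on the starting and asymptotic log-thresholds; the additive-on-log
link is our choice where the parameterization was open, keeping
thresholds positive.  Thresholds-as-inverse-slope is likewise our
parameterization choice.

## Degenerate inputs and edge cases

`rt <= t0` yields a log-density of −Inf by default (optimizers must be
able to probe infeasible NDT values) and can be made an error.  An
all-excluded subject, a single-response subject in the logistic fit, and
constant predictions in `absolute_fit()` are flagged rather than
silently dropped.  Blocks in `absolute_fit()` are formed on retained
trials in table order; with `n` not divisible by the block length the
remainder joins the last block, keeping the partition exact with
floor(n/25) blocks.  Day-1 versus last-day comparisons report paired t
and Wilcoxon tests side by side; which test the original aggregated
comparisons used is not specified, so both are given.  Block-level
correlations pool all subjects' cells; pooling versus per-subject
averaging was an open choice and is documented here.

## Known limitations

Per-subject fits with optional shrinkage approximate, but do not
reproduce, a full crossed random-effects posterior; random effects are
uncorrelated by construction.  The Metropolis sampler is adequate for
per-subject posteriors of 5-16 dimensions but no substitute for
gradient-based samplers on the joint hierarchical model.  Bridge
sampling with a moment-matched normal proposal can fail to overlap for
strongly non-normal posteriors — reported as the infinite sentinel, not
hidden.  Inter-trial variability parameters of extended DDMs (sv, sz,
st0) are intentionally absent.
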