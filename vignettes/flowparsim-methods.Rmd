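---
title: "Modelling self-motion biases in speed perception and motion extrapolation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling self-motion biases in speed perception and motion extrapolation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flowparsim)
```

## The scientific problem

When an observer translates through the world while watching a moving object,
part of the retinal motion is caused by their own movement. The visual system
is thought to *flow-parse*: it subtracts the retinal motion predicted from its
self-motion estimate and attributes the remainder to the object. When flow
parsing is incomplete, a fraction of the self-motion is wrongly attributed to
the object, biasing its perceived speed; the subtraction should also inject
noise, lowering precision. Both effects should propagate into *motion
extrapolation*: the timing of when an occluded object will arrive at a target
depends on its perceived speed.

`flowparsim` implements the full computational machinery to study this chain
with two simulated tasks:

* a **prediction task** — a ball crosses the field of view at 8 m depth for
  0.5 s at 4, 5 or 6 m/s, then travels occluded for 0.5-0.7 s; the simulated
  participant presses a button when they believe it reaches the target; and
* a **2IFC speed-estimation task** — the same ball is compared against a
  ball cloud whose speed is driven by a modified PEST staircase; cumulative
  Gaussian psychometric fits yield a PSE and JND per condition.

During the visible interval the observer may experience lateral visual
self-motion in the ball's direction ("same"), against it ("opposite"), or
none ("static").

## The generative observer model

Perceived ball speed in a trial is drawn as

$$v_\mathrm{perc} \sim \mathcal N\!\big(v + \beta\, v_\mathrm{self},\;
  w_v\,(v + \beta\, v_\mathrm{self})\,(1 + \pi)\big),$$

where $\beta$ is the accuracy effect (fraction of the nominal self-motion
speed attributed to the ball), $\pi$ the precision effect (fractional noise
inflation), and $w_v$ the speed Weber fraction. Default population values: $\beta$ has population mean 0.20 and
between-participant SD 0.30 for the opposite direction and is 0 for same and
static; $\pi$ likewise 0.20 (SD 0.30); $w_v$ has mean 0.10 (SD 0.015,
truncated above 0.01). The occluded distance is perceived with a fixed 5%
Weber fraction. The button press occurs at the extrapolated time

$$t_\mathrm{extrapolated} = d_\mathrm{perc} / v_\mathrm{perc},$$

an identity the simulator honours to machine precision on every trial. In the
2IFC task the cloud percept carries only baseline Weber noise (the comparison
interval involves no self-motion), so the choice function's 50% point sits at
the biased ball percept — e.g. at $4 + 0.2 \times 3.6 = 4.72$ m/s.

### The nominal self-motion speed is 3.6 m/s, not 4 m/s

The self-motion profile ramps up over 50 ms, holds 4 m/s for 400 ms and ramps
down over 50 ms, covering 1.8 m in 0.5 s. The bias is scaled by the
*time-averaged* speed of 3.6 m/s rather than the 4 m/s peak: the effect
parameter is defined as a fraction of the self-motion actually presented
during the trial, and using the peak would overstate that by 11% and break
the correspondence between a fitted accuracy parameter of $a$ and a PSE
shift of $a \times 3.6$ m/s.

The ramp is a truncated, rescaled Gaussian CDF, time-symmetric about its
midpoint — the only Gaussian-shaped ramp consistent with the 1.8 m total
displacement (each ramp must average exactly half the peak). A linear ramp
is available for sensitivity checks; it preserves the displacement identity.

### Retinal-speed table

`retinal_speed_table()` reports mean absolute retinal speeds per motion
profile and ball speed from the clean geometry (translating, non-rotating
observer; angle $\arctan(\text{offset}/8\,\mathrm m)$). Such summaries are
convention-dependent — averaging window, reference frame and eccentricity
handling all move the numbers — so values derived under other conventions
need not agree with these. The package commits to the clean geometric
definition: the static-observer case reduces to the closed form
$2\arctan(vT/2d)/T$ (28.5 deg/s at 4 m/s), which the tests use as the
oracle, and the ordering (opposite > static > same) holds under any
convention.

## The PEST staircase

Each condition runs two staircases starting 30% above and below the ball
speed, bounded in $[v/3,\,3v]$. Step-size rules are the classic
sequential-testing heuristics: halve on a reversal, double from the third
same-direction step, deferring the doubling by one step when the last
reversal immediately followed a doubled step. Two modifications are layered on top: the applied step is pinned to 1.2 m/s for the first ten
trials (to spread levels for stable JND estimates), and termination occurs at
37 trials, or from 30 trials on once the internal step falls below 0.03 m/s.
The rule set deliberately omits the Wald sequential-run criterion of the
original PEST formulation — each response moves the track, which is the
simplest variant consistent with two staircases bracketing a PSE — and it is
isolated in one function (`update_staircase()`) so an alternative rule set
can be substituted. During the
early phase the internal step stays at its 0.6 m/s initial value and rule
bookkeeping restarts on trial 11, with the last early-phase direction
remembered only for reversal detection; this matches the documented
trial-11-reversal behaviour (0.6 halves to 0.3).

Consequences that the tests pin down: every staircase runs 30-37 trials, so
one participant contributes between 540 and 666 trials over their 18
staircases; a responder that reverses on every trial terminates at exactly
30; a responder that never reverses terminates at exactly 37.

## Psychometric fitting

`fit_cumulative_gaussian()` maximises the Bernoulli likelihood of
$P(\text{choose comparison}) = \Phi((x - \mathrm{PSE})/\mathrm{JND})$ with no
lapse or guess parameters (the standard two-parameter fit of common
psychometric toolboxes, and all that a PSE/JND readout needs). Optimisation
is bounded quasi-Newton with an analytic
gradient from four deterministic starts (PSE at the level mean ± one level
SD; JND at 0.5 and 1.5 level SDs), best likelihood winning, ties to the first
start. The JND is constrained to $[10^{-3}, 3 \times \text{level range}]$.
Complete separation or single-level data return `converged = FALSE` with a
diagnostic instead of an error. A brute-force likelihood grid is the test
oracle.

## The confirmatory statistical pipeline

Exclusion rules: prediction trials with a response later than three times the
occlusion duration are dropped (strict inequality); staircases with more than
20% of levels exactly at a bound are dropped whole; condition cells with an
extrapolated-time SD at or below 0.01 s are excluded from precision analyses;
head-rotation filtering engages only when head-bin columns exist.

The accuracy models are linear mixed models fitted by maximum likelihood with
`lme4` — timing error (or PSE) on motion profile with static as reference, a
random ball-speed slope per participant, and (for the prediction task) a
random occlusion-duration intercept. `lme4` supports these crossed random
effects directly, so no structural fallback is needed; a singular
random-effect covariance triggers a flagged refit with a diagonal covariance.
Precision analyses are likelihood-ratio tests of the profile term on log SDs
(log JNDs), controlling for the mean (PSE), because accuracy shifts
mechanically rescale variability. Cross-task analyses regress per-participant
opposite-minus-static differences of one task on the other. Confidence
intervals for confirmatory fixed effects come from a parametric bootstrap
(default 500 replicates, percentile intervals, seed-deterministic).

Inside Monte Carlo power loops, significance for the fixed-effect accuracy
tests uses a Wald z-test on the `lme4` t-value: the Satterthwaite
approximation sometimes used to speed up mixed-model p-values is not
available in this environment, and with thousands of residual degrees of freedom the
normal approximation is equivalent at the third decimal. The LRT-based tests
are identical in and outside power loops.

## Two-step simulation-based parameter fitting

For each participant, task and direction the package fits an accuracy
parameter $a \in [-1, 1]$ (fraction of nominal self-motion speed) and then a
precision parameter $p \in (-0.9, 3]$, by minimising the median across
simulated datasets (50 for prediction, 25 for speed estimation) of the root
median squared error between observed and simulated opposite/same-minus-static
difference summaries — cell mean timing errors, then cell SDs (prediction),
or PSEs, then JNDs (speed estimation). Scalar minimisation uses Brent's
method (`stats::optimize`, tolerance $10^{-3}$, below the Monte Carlo
resolution of the objective).

Design choices worth recording:

* **Common random numbers.** Regenerating datasets on every objective
  evaluation makes the objective stochastic and a derivative-free bracketing
  search ill-posed. Here all standard-normal draws are made once per
  optimisation and reused across candidate parameter values, so the
  objective is smooth in the parameter while the estimand is unchanged.
* **Percept floor.** Percepts are floored at 0.1 m/s. The trial simulators
  floor by resampling; the CRN objective uses a hard clamp so the objective
  stays deterministic — at realistic parameters the floor essentially never
  binds.
* **Precision search bound.** Only the accuracy bounds (±100%) are part of
  the fitting contract;
  the precision search is bounded at 3 (up to a four-fold SD inflation),
  wide enough for every generative value considered.
* **Two-step ordering.** Precision is fitted with accuracy already fixed,
  since biases shift means (and mechanically scale SDs) whereas precision
  effects do not move means.
* The speed-estimation objective refits psychometric functions to every
  simulated staircase run, using a single data-driven optimiser start per
  cell (the public four-start fit is used for observed data); the staircase
  simulation itself uses the full engine.

With 40 participants drawn at the default generative values, the cohort-mean
fitted opposite-direction accuracy parameter recovers the 0.20 population
mean (acceptance tests bound it in [0.15, 0.25] for both tasks), and because
one shared per-participant bias drives both tasks, the cross-task regression
slope is statistically indistinguishable from 1. Per-participant precision
estimates are markedly noisier than accuracy estimates — three JND-difference
cells carry little information about a noise-inflation factor — so
cohort-level conclusions about precision require the full 40-participant
design.

## Power analysis and calibration

`run_power()` simulates complete experiments (one observer cohort shared by
both tasks), runs the requested confirmatory tests and reports rejection
proportions with exact binomial intervals. The default simulation count is
250, with 100 as the documented desk-scale preset. At the chosen design — 40
participants, 13 repetitions per prediction condition, 30-37-trial staircases
(roughly 70 trials per speed-estimation condition) — the opposite-direction
accuracy tests exceed 0.85 power. With all effects zero, each confirmatory
test rejects at a rate compatible with the nominal 0.05.

The calibration suite runs at 40 participants with 5 repetitions and the
20-27-trial staircase window (both grid points of the power analysis) to stay
inside a desk-scale time budget; cohort size is kept at 40 because the
small-sample behaviour of the df = 1 likelihood-ratio tests depends mainly on
the number of participants.

## What the synthetic generator does and does not emulate

The generator reproduces the declared generative world: factorial designs and
trial counts, Gaussian between-participant effect distributions, Weber-scaled
multiplicative percept noise, staircase-driven comparison levels, and shared
per-participant parameters across tasks. It does **not** emulate several
features of real data: no motor or response-execution noise beyond perceptual
noise, no lapses or attention failures (the outlier filters therefore drop
essentially nothing on synthetic data), no within-trial temporal integration
or transient-weighting of the ramped profile, no Bayesian priors pulling
responses toward the session mean, and no head-movement artefacts. A green
test establishes that the pipeline recovers what this model generates — not
that the model captures every mechanism in human data (compensatory
precision mechanisms during self-motion, in particular, are outside it).

## Numerical notes and degenerate inputs

Noise-free configurations are handled exactly (zero-SD draws return the
mean; the distance product and extrapolation identity are exact), so
arithmetic oracles hold to machine precision. Psychometric fits flag boundary
solutions rather than erroring. Mixed-model fits use loosened optimiser
stopping rules (`xtol_abs = ftol_abs = 1e-6`, no derivative check) that leave
log-likelihoods unchanged to ~1e-6 while halving fit time; likelihood-ratio
statistics are clipped at zero against roundoff. Cross-task regressions
refuse degenerate regressors (constant differences) and cohorts below five
participants with explicit diagnostics.
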