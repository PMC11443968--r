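---
title: "The CEI model of dyadic merging: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The CEI model of dyadic merging: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ceimerge)
```

## The scenario and the model

`ceimerge` simulates two drivers resolving a symmetric merging conflict on a
simplified track: a 50 m tunnel, a 50 m approach, a merge point where the two
roads join, and a 50 m car-following section. Vehicles are point masses
(4.5 m x 1.8 m only for collision detection) subject to a quadratic
resistance `0.5 + 0.005 v^2` m/s^2, integrated semi-implicitly at
`dt = 0.05` s. In the tunnel the drivers can observe each other but have no
control; once a front bumper passes the tunnel exit, that driver controls
the vehicle's acceleration. A kinematic condition fixes the projected
headway (the front-to-front distance the vehicles would have at the merge
point if they kept their initial velocities; -4...4 m) and the initial
relative velocity (+-0.8 or 0 m/s around 10 m/s). Every default condition
ends in a collision if nobody acts.

Each driver is a Communication-Enabled Interaction (CEI) agent with four
coupled components:

* **Plan.** A constant acceleration over a 6 s horizon, chosen by minimizing
  `sum_t (v_t - v_d)^2 + sum_t a^2` subject to a cap on perceived risk. The
  cost contains no collision term: safety lives entirely in the constraint.
  Because the decision variable is one scalar, the solver is a deterministic
  401-point grid scan with a 1e-4 refinement; it matches a 1e-3 brute-force
  grid to 1e-3 m/s^2 (a property the test suite checks against an
  independent R implementation). The executed input is the planned one plus
  a single frozen noise draw (sd 0.14 m/s^2) representing imperfect pedal
  control; it stays constant until the next replan.
* **Communication / perception.** Position and acceleration of the other
  vehicle are observed perfectly; velocity is perceived through evidence
  accumulation: `v_p += alpha (v_real - v_p) + beta dW` per step. At the
  defaults (`alpha = 0.5`, `beta = 0.6`) the stationary error sd is
  `sqrt(beta^2 dt / (1 - (1 - alpha)^2)) = 0.155` m/s; the ~5 s tunnel lets
  this distribution develop before control begins, which is what makes
  drivers sometimes brake and sometimes accelerate in the same condition.
* **Belief.** At each step the agent projects the other vehicle forward at
  24 lead times (4 Hz over 6 s) using constant-acceleration kinematics with
  a normally distributed acceleration: mean = the average observed (net)
  acceleration over the last 4 s, variance = `(a_c/3)^2` plus the population
  variance of that memory, so erratic behavior widens the belief. Each
  belief point is an equal-weight two-component Gaussian mixture with
  variances `sigma_t^2` and `phi sigma_t^2` (`phi = 3`): a kinematically
  plausible core plus a heavy shoulder for unexpected maneuvers.
* **Risk and thresholds.** The perceived risk is the probability that the
  other vehicle lies within the collision bounds around the ego's planned
  position, maximized over belief points. The ego positions come from the
  plan's own waypoints, not from the vehicle's true state: the driver
  believes they are on-plan, so execution-noise drift goes unnoticed until
  the next replan — this is the mechanism behind the occasional simulated
  collisions. A replan fires when risk exceeds the upper threshold (new cap
  `0.8 rho_l`), when risk stays below the lower threshold for
  `tau = 1.6` s (relaxation, cap `0.6 rho_u`), or when the desired velocity
  is reached under a nonzero input. Infeasible optimizations fall back to
  full braking (behind) or full acceleration (ahead), retried every step.

Thresholds are personal (Table of `driver_thresholds()`) and dynamic: a
linear incentive function of the relative position and velocity from the
driver's perspective raises or lowers them, encoding that the disadvantaged
driver has more reason to act.

## Design decisions on genuinely open points

**Belief width.** The belief-width recursion can be read as scaling the
standard deviation (`sigma_t = 0.5 (t-t0)^2 sigma_a`) or the variance. We
default to the standard-deviation reading and expose the other
(`belief_sigma_mode`). The decisive argument is internal consistency with
the fitted threshold scale: under the sd reading the noise-free perceived
risk at control onset in the head-on condition 0_0 is 0.55, which falls
between the fitted upper thresholds of pair 3's drivers (0.488 and 0.631) —
so the left driver acts and the right "barely acts", as observed — and
inside the calibration grid's upper range [0.3, 0.9], which makes the grid
search discriminative. Under the variance reading the onset risk saturates
near 1 and every driver would trigger immediately, inconsistent with those
fitted values.

**Risk aggregation.** How the 24 per-point collision probabilities combine
into one scalar is not fixed by the model's description. We default to the
maximum (conservative, scale-free, keeps risk in [0, 1] and consistent with
the onset-risk analysis above); a sum capped at 1 is available via
`risk_aggregation = "sum"`.

**Incentive covariates.** The incentive coefficients are fitted on the
condition design, whose covariates span only +-4 m of projected headway and
+-0.8 m/s of relative velocity, with an interaction term. Inside a trial we
therefore feed the incentive function the *instantaneous projected headway
at the merge point* (constant-velocity projection using the ego's true and
the other's perceived velocity) and the instantaneous relative velocity,
both clamped to the fitted support (`incentive_dp_max`,
`incentive_dv_max`). Feeding raw front-bumper differences instead
extrapolates the fitted interaction to covariate products hundreds of times
outside its support, which pins both thresholds at their guard bounds for
seconds and produces multi-second braking ramps and unrealistically large
gaps.

**Threshold guards.** The linear incentive terms can invert the thresholds
at extreme relative states. Both thresholds are clamped to
`(1e-6, 1 - 1e-6)` and the lower one is kept at most `0.99 rho_u`:
strictly below the upper threshold but strictly positive, so the relaxation
trigger remains reachable. (Forcing `rho_l = rho_u - 1e-6` instead sets
`rho_l = 0` whenever `rho_u` sits at its floor, which permanently disables
relaxation and deadlocks trials after the conflict is resolved.)

**Initial placement.** The disadvantaged (or slower) vehicle starts at
`s = 0`; the other vehicle's offset is solved so the projected headway is
met exactly at the first merge arrival. Offsets may be negative (the tunnel
extends conceptually backwards). This convention makes mirrored conditions
exact left-right swaps, a property the tests verify to machine precision.

**Other conventions.** The desired-velocity trigger fires on a sign change
of `v - v_d`, or within 0.01 m/s of `v_d` if the plan was created away from
`v_d` (the guard stops it from re-firing every step once the speed is
held). Ties in the fallback direction (equal positions) brake. The observed
acceleration entering the belief memory is the realized net `dv/dt` of the
other vehicle (zero in the tunnel); the memory is seeded with a single zero
at trial start. Per-trial seeds are derived from the batch seed and the
pair/condition/repetition indices, so any trial is reproducible in
isolation.

## Calibration pipeline

Fitting mirrors the three-stage procedure used for the human data:

1. `grid_response_lookup()` simulates, per condition, one deterministic
   trial (all noise off, incentives off) of a single CEI driver against a
   constant-velocity opponent for each of 625 threshold cells (upper in
   [0.3, 0.9], lower in [0.01, 0.4]), recording the signed velocity
   deviation 1.0 s after control onset.
2. `match_trial_thresholds()` maps an observed deviation to the nearest
   cell; ties (every sufficiently passive cell explains a zero deviation)
   break towards the most passive cell, the unique order-stable
   representative.
3. `fit_incentive()` fits two random-intercept linear mixed-effects models
   (`theta ~ dp * dv + (1 | participant)`, REML via `lme4`): fixed slopes
   become the population incentive coefficients, intercepts the per-driver
   base thresholds. `tidy()` and `glance()` expose the fits.

`synth_participants()` generates deviation datasets from known thresholds
for parameter-recovery studies. With noise off, recovery of the upper
threshold is limited by the time discretization: perceived risk at the
tunnel exit rises by roughly 0.05–0.1 per 0.05 s step, so several adjacent
`theta_u` cells share a trigger step and hence produce identical 1.0 s
deviations; matching then recovers `theta_u` only to within ~2–3 grid steps
(0.05–0.075) for some cells. This is an inherent imprecision of
threshold-triggered grid search, not of the estimator around it; the
mixed-effects stage recovers injected incentive slopes of the published
magnitude within two standard errors.

## What the simulations reproduce, and what they do not

A full default campaign (9 fitted pairs x 11 conditions x 10 repetitions =
990 trials, roughly two minutes on one core) yields, under the batch seed
used in `scripts/acceptance.R`: a grand mean merge gap of ~4.3 m
(published model value: 4.8 m, human 4.5 m), 22 collision trials
(published: 29/990), mean trial duration 16.7 s (published: 14.2 s), and a
mean absolute maximum velocity deviation of ~2.0 m/s, somewhat larger than
the published model-vs-human comparison implies. The qualitative structure
— intermittent piece-wise-constant control with triangular velocity
excursions, the within-pair asymmetry of contributions tracking the fitted
thresholds, who-merges-first probabilities increasing with projected
headway advantage, and rare collisions in all conditions — reproduces well.
The mean gap is sensitive to two points the model description leaves open:
at which crossing instant the gap is measured (the trailing vehicle's
crossing, used here, gives ~4.3 m; the leader's crossing gives ~2.9 m) and
which 11 of the 15 design cells constitute the condition set (up to
+-0.3 m). We fixed both choices a priori and report the discrepancy rather
than selecting post hoc.

The synthetic campaign emulates the study's *structure* (design, trial
counts, noise sources), not human drivers: passing tests demonstrate
internal consistency of the model and pipeline, and agreement with the
published model-level statistics — they cannot certify agreement with human
behavior, for which the original human dataset would be required.

## Numerical choices

Simulation and planning use the same semi-implicit Euler rollout (velocity
first, clamped at zero, then position), with resistance included in the
planner's internal model by default so that, without noise, plan waypoints
and executed motion coincide exactly. Belief lead times are multiples of
`1/(dt fb)` steps, so plan waypoints are read at belief times without
interpolation. Merge-point crossing times in the metrics are linearly
interpolated between steps. Trials are capped at 60 s of simulated time as
a guard; ordinary trials end around 15-20 s when both vehicles have left
the track.

## Example

```{r example, eval = FALSE}
th <- driver_thresholds()
pair3 <- dplyr::filter(th, pair == 3)
trial <- run_trial(
  condition("0_0"),
  risk_thresholds(pair3$theta_l[1], pair3$theta_u[1]),
  risk_thresholds(pair3$theta_l[2], pair3$theta_u[2]),
  seed = 4
)
trial$outcome$who_first
autoplot(trial)

batch <- run_batch(reps = 2, base_seed = 11)
batch_summary(batch, "condition")
plot_batch_summary(batch, "gap")
```
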