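# ceimerge

Simulation and calibration of a **Communication-Enabled Interaction (CEI)
model of dyadic merging**: two simulated human drivers approach a merge
point on converging roads, each holding a deterministic
constant-acceleration plan, perceiving the other's velocity through noisy
evidence accumulation, maintaining a probabilistic belief about the other's
future positions, and replanning only when their perceived collision risk
crosses personal dynamic thresholds. The package is for researchers in
driver behavior modeling, traffic interaction, and human factors who want a
reproducible implementation of risk-threshold intermittent control in a
coupled two-agent setting — including the grid-search plus mixed-effects
procedure used to calibrate per-driver thresholds and population incentive
coefficients.

## The model in brief

Each driver minimizes a comfort/speed cost over a 6 s horizon,

J = Σ<sub>t</sub> (v<sub>t</sub> − v<sub>d</sub>)² + a<sub>t</sub>²,

over a single constant input a ∈ [−a<sub>max</sub>, a<sub>max</sub>],
subject to a cap on perceived risk; collision avoidance enters only through
that constraint. The belief about the other vehicle at lead time t − t₀ is
an equal-weight two-component Gaussian mixture

b<sub>t</sub> = ½ N(μ<sub>t</sub>, σ<sub>t</sub>²) + ½ N(μ<sub>t</sub>, φσ<sub>t</sub>²),
  μ<sub>t</sub> = ½(t−t₀)² μ<sub>a</sub> + v<sup>p</sup>(t−t₀) + p,

with μ<sub>a</sub>, σ<sub>a</sub> from a 4 s memory of observed
accelerations and v<sup>p</sup> the noisily perceived velocity
(v<sup>p</sup> ← v<sup>p</sup> + α(v − v<sup>p</sup>) + β dW). Perceived
risk is the believed probability that the other vehicle lies within the
collision bounds around the ego's planned position, compared against
dynamic thresholds ρ<sub>u</sub>, ρ<sub>l</sub> = θ + λ₁Δp + λ₂Δv + λ₃ΔpΔv:
exceeding ρ<sub>u</sub> forces an evasive replan (risk cap 0.8ρ<sub>l</sub>),
staying under ρ<sub>l</sub> for τ = 1.6 s triggers a return-to-normal replan
(cap 0.6ρ<sub>u</sub>). See the methods vignette
(`vignettes/cei-merging-model.Rmd`) for every component, default, and
design decision.

## Worked example

Simulate one head-on trial (condition `0_0`: no initial advantage) for the
fitted driver pair 3, whose left driver has the lower risk tolerance:

```r
library(ceimerge)
th <- driver_thresholds()           # fitted per-driver base thresholds
pair3 <- dplyr::filter(th, pair == 3)
trial <- run_trial(
  condition("0_0"),
  risk_thresholds(pair3$theta_l[1], pair3$theta_u[1]),   # left: 0.058/0.488
  risk_thresholds(pair3$theta_l[2], pair3$theta_u[2]),   # right: 0.245/0.631
  seed = 4
)
trial
#> <cei_trial> condition 0_0 | duration 17.85 s | first: right gap: 8.2 m
trial$outcome$max_abs_dev
#>  left right
#>  4.07  1.20
```

The left driver (upper threshold 0.488) perceives the onset risk as above
threshold, brakes, and yields; the right driver (0.631) barely acts — the
asymmetry of contributions is carried entirely by the fitted thresholds.
The trial log (`trial$log`) holds per-timestep positions, velocities,
inputs, risk traces, dynamic thresholds and replanning events;
`autoplot(trial)` draws the velocity and risk traces.

Batch simulation and summaries:

```r
b <- run_batch(pairs = pair3, reps = 5, base_seed = 11)
batch_summary(b, "condition")[, c("condition", "n", "mean_gap", "p_left_first")]
#>    condition     n mean_gap p_left_first
#>  1 -2_0          5     7.35          0
#>  2 -4_-8         5     5.49          0
#>  ...
#> 10 4_0           5     3.61          0.2
#> 11 4_8           5     2.75          0.6
```

With pair 3, the left driver goes first only when holding a projected
headway advantage (`4_0`, `4_8`); `mean_gap` is the bumper-to-bumper safety
margin at the merge point, collisions excluded.

Calibration pipeline (thresholds from trial-level velocity deviations):

```r
lk   <- grid_response_lookup(condition("0_0"))   # 625-cell response grid
devs <- synth_participants(tibble::tibble(
  participant = "s01", side = "left", theta_l = 0.1, theta_u = 0.5),
  conditions = condition("0_0"), reps = 10)
est  <- calibrate_trials(devs, list("0_0" = lk))
# with >= 2 participants and conditions: fit_incentive(est), tidy(), glance()
```

## Configuration and CLI

All track, simulation, and model constants can be overridden through a
YAML config (`read_cei_config()` / `write_cei_config()`, sections `track`,
`sim`, `conditions`). Thin command-line wrappers live in `inst/cli/`:
`simulate.R` (batch → trials CSV + summary JSON), `metrics.R` (summary JSON
→ grouped metrics CSV), and `calibrate.R` (deviation CSV → fitted
thresholds and incentive coefficients; `--make-fixtures` generates
synthetic deviation datasets).
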