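# prefgait

Tools for asking what a prosthesis user's *preferred* ankle stiffness
optimizes. People walking on a variable-stiffness prosthetic ankle converge
on a preferred dorsiflexion stiffness with a control dial; `prefgait`
implements the analysis chain that relates that preference to metabolic
cost, gait biomechanics and walking performance:

* **Metabolic estimation** — steady-state net metabolic rate per trial from
  breath-by-breath data recorded over consecutive stiffness trials, via the
  first-order relaxation model `dy/dt = (x(t) − y(t))/τ` (τ = 42 s),
  discretized by exact exponential propagation and solved by pseudoinverse
  least squares (the prediction is affine in the per-trial steady states).
* **Gait processing** — zero-phase 4th-order Butterworth filtering (15 Hz),
  gait-cycle and stance segmentation from per-leg vertical GRF, percent-
  gait-cycle normalization, net joint power, and a registry of 25
  biomechanical descriptors (per-side ROM and signed peaks, cross-leg
  symmetry measures, pelvic tilt variance, step proportions).
* **Trend inference** — for each descriptor, a quadratic mixed-effects model
  in preference-normalized stiffness `d = 100·(k/k_pref − 1)` with a speed
  fixed effect and per-subject random intercept and speed slope:
  `y = β₀ + β_L d + β_Q d² + β_S v + u_i + w_i v + ε`, fit by maximum
  likelihood with Wald tests; the vertex `−β_L/(2β_Q)` gets a 95 %
  delta-method confidence interval, and each trend is classified as none /
  linear / quadratic-far / quadratic-near (vertex within 10 % of
  preferred). Staged preference-vs-speed, body-mass regression and 10-meter
  walk test analyses round out the statistics.
* **Synthetic study generator** — emits the full crossover design
  (3 speeds × 5 stiffness levels around preference, block trial schedules
  of 4/4/4/3/3 and 4/3/3/3/3 minutes, preference logs, 10MWT records) with
  the statistical structure the analysis assumes and a ground-truth sidecar,
  so every estimator is validated by recovery.

Intended users: rehabilitation-biomechanics and wearable-robotics
researchers analyzing preference experiments, and methodologists who need a
tested reference implementation of dynamic metabolic estimation or
vertex-CI inference.

## Worked example

Estimate per-trial steady-state metabolic rates from one synthetic
five-trial block, then fit a stiffness trend with a planted vertex:

```r
library(prefgait)

sch <- trial_schedule(c(4, 4, 4, 3, 3) * 60,
                      stiffness_rel = c(-30, 15, 0, 30, -15))
sub <- gen_subjects(1, seed = 2)[[1]]
bb  <- gen_breath_block(sub, sch, speed_rel = 0, seed = 3)
net <- net_rate(bb$series, sub$resting_rate)
estimate_steady_states(net, sch, tau = 42)
#> Steady-state metabolic estimate (tau = 42 s, y0 = first_breath)
#>  trial stiffness_rel x_hat_w n_breaths
#>      1           -30  212.24        83
#>      2            15  211.70        80
#>      3             0  212.83        77
#>      4            30  218.05        62
#>      5           -15  210.32        58
#> residual RMS: 20.31 W
```

The generated truth for all five trials is 212.6 W (this subject's net
walking rate; stiffness has no metabolic effect by default), so with 20 W
breath noise the estimator lands within a few watts of truth on three-
minute trials — the point of the dynamic method, which needs no steady-
state wait.

```r
rec <- gen_descriptor_records(7, beta_L = -2 * 0.002 * 5, beta_Q = 0.002,
                              sd_resid = 1.5, seed = 4)   # vertex planted at +5
fit_stiffness_trend(rec)
#> Quadratic stiffness trend for 'value' (105 obs, 7 subjects)
#>   beta_L = -0.01513 (p = 0.0156), beta_Q = 0.001791 (p = 3.78e-07 *)
#>   vertex at 4.22% deviation from preferred [0.43, 8.02]
#>   category: quadratic_near
```

The planted vertex (+5 % deviation) is recovered at 4.22 % with a CI that
covers it, and the trend is classified "quadratic_near": this descriptor's
extremum sits at the preferred stiffness. The full pipeline runs with

```r
cfg <- run_config(seed = 7, n_subjects = 7, out_dir = "run1")
run_all(cfg)            # simulate -> metabolic -> descriptors -> trends
render_report("run1")   # Markdown summary incl. ground-truth recovery
```

writing `steady_states.csv`, `descriptors.csv`, `trends.csv` (25
descriptors + the normalized metabolic ratio), `report.json`, and a
manifest with per-stage status and file hashes. A thin CLI wrapper lives at
`inst/cli/prefgait.R` (`simulate`, `run`, `report` subcommands).

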