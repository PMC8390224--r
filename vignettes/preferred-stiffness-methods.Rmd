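---
title: "Methods: analyzing user-preferred prosthetic ankle stiffness"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: analyzing user-preferred prosthetic ankle stiffness}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prefgait)
```

## The problem

People walking on a variable-stiffness prosthetic ankle can use a control
dial to converge on a *preferred* dorsiflexion stiffness. A natural research
question is what that preference encodes: does the preferred setting
minimize metabolic cost, maximize gait symmetry, maximize self-selected
walking speed — or none of these? `prefgait` implements the full analysis
chain for a crossover experiment built around this question: per-subject
preference identification at three treadmill speeds (−30 %, +0 %, +30 % of
self-selected), metabolic and biomechanics trials at five stiffness levels
around the preferred value (+0 %, ±15 %, ±30 %), and overground
10-meter-walk-test (10MWT) performance, all expressed on the
*preference-normalized* stiffness axis

$$d = 100\,(k / k_\text{pref} - 1) \; [\%],$$

so that each subject's preferred setting sits at $d = 0$ and extrema of
fitted trends can be read directly as "at or near preference" (within 10 %)
or not. The reference device spans 3.4–23.3 Nm/deg in dorsiflexion
stiffness; all stiffness values are validated against these bounds.

Because human-subject recordings of this kind are not redistributable, the
package ships a synthetic-data generator that reproduces the *statistical
structure* the analysis assumes — with known ground truth — so that every
stage can be validated by recovery rather than by reproducing any
particular cohort's numbers.

## Steady-state metabolic rate from breath-by-breath data

Each metabolic block holds five consecutive stiffness trials at one speed
(durations 4/4/4/3/3 minutes for the subject's first block, 4/3/3/3/3
thereafter). Because stiffness switches mid-walk in a step, breath-by-breath
measurements never settle within a trial; the steady-state rate for each
trial is instead estimated through a first-order dynamic model,

$$\dot y(t) = \frac{1}{\tau}\bigl(x(t) - y(t)\bigr),$$

where $y$ is the measured breath value, $x(t)$ the piecewise-constant
steady-state rate (one unknown per trial) and $\tau$ the time constant,
fixed at 42 s, the standard walking value. Resting rate from quiet standing
is subtracted first; by linearity of the model the order of subtraction and
fitting is immaterial, which the test suite verifies.

**Discretization.** Between consecutive breaths the model has the exact
solution $y(t) = x_j + (y(t_0) - x_j)\,e^{-(t - t_0)/\tau}$ within trial
$j$, propagated continuously across trial boundaries. `prefgait`
discretizes by this exact propagation rather than a forward-Euler step: it
is exact for piecewise-constant $x$ at *any* breath spacing, which matters
because real inter-breath intervals are irregular (the generator draws them
from a truncated normal, mean 3 s, SD 0.8 s, floor 1 s, precisely to
exercise the uneven-step path).

**Estimation.** Conditioned on the initial value, the predicted breath
vector is *affine* in $(x_1,\dots,x_K)$. `estimate_steady_states()` builds
the coefficient matrix of that affine map and solves the least-squares
problem by SVD pseudoinverse (minimum-norm solution). The default
initial-state policy fixes $y(t_1)$ at the first measured breath
(`"first_breath"`); a `"free"` mode appends the initial state as an extra
unknown for sensitivity analysis. Negative estimates are possible under
heavy noise and are returned flagged rather than clipped — silent clipping
would bias recovery simulations. A breath falling exactly on a boundary
belongs to the later trial (half-open trial intervals), consistent with the
step change occurring at the boundary.

`estimate_tau()` profiles the residual RMS over a grid of candidate time
constants; the pipeline still fixes $\tau = 42$ s, and the profiler exists
for subject-specific sensitivity checks on the 4-minute trials.

Validation is by construction: the generator's forward model and the
estimator share the same exact solution, so a noiseless round trip must
recover steady states to numerical precision (observed ~4e-13 W), and at
20 W breath noise the pseudoinverse solution must agree with direct
nonlinear least squares over the five unknowns (BFGS on the squared
prediction error, using the forward predictor directly) to well under
0.5 W — observed below 1e-6 W, as expected for an affine model where both
routes minimize the same convex objective.

## Gait processing

Signals (per-leg vertical GRF, hip/knee/ankle angles and net moments per
side, pelvic tilt, per-side hip height and anterior foot position) are
low-pass filtered with a zero-phase fourth-order Butterworth at 15 Hz.
Two passes square the magnitude response, so gain at the cutoff is 0.5.
`signal::filtfilt` applies no edge treatment, which leaves large start-up
transients even on constant signals; `lowpass_filter()` therefore removes
the mean, pads by odd reflection over `3·fs/cutoff` samples, runs the two
filter passes, and restores the mean. This keeps DC exact and passband
sinusoids phase-true at the edges of trial-length records.

Stance is any contiguous run of vertical GRF above 5 % of body weight
sustained at least 0.2 s (the threshold fraction and debounce are
configurable; the underlying notion is "sustained, positive vertical GRF").
Heel-strike is the first sample of a qualifying run; a gait cycle runs
heel-strike to the next ipsilateral heel-strike, so partial first/last
cycles drop out by construction. Cycles overlapping a crossover flag
(stance not isolated to one force plate) are excluded with a recorded
reason; the crossover decision itself is consumed as a precomputed flag
since plate-assignment rules are instrumentation-specific.

Each retained cycle is linearly interpolated onto 101 points (0–100 % gait
cycle), and separately onto a 101-point grid spanning stance only. Net
joint power is net moment × angular velocity, with angular velocity the
central-difference derivative of the angle (one-sided at record ends,
radians before multiplication).

**Descriptors.** Twenty-five descriptors are extracted per
subject–speed–stiffness condition (`descriptor_registry()`): per-side ROM
and signed peak angles/moments/powers, cross-leg trajectory RMS
differences, cross-leg differences of stepwise scalars, pelvic tilt
variance, and step proportions of stride duration and distance. Sign
convention: positive is extension/dorsiflexion, so "peak flexion
(plantarflexion) moment" is the magnitude of the most negative value;
flipping the convention (`sign = -1`) exactly swaps flexion/extension
peaks, which is tested. Choices made where the field's wording is loose:

* extrema and ROM are taken over stance by default (descriptors are
  defined as stance-phase averages); `extent = "cycle"` is available;
* "early" features use the first half of stance;
* cross-leg RMS differences re-normalize each side's stance to its own
  101-point grid before differencing, so unequal stance durations remain
  comparable;
* stride pairing matches each affected cycle with the unaffected cycle
  whose heel-strike falls inside it; unpaired strides drop out of
  cross-leg descriptors only;
* pelvic tilt variance is computed over the whole analyzed span after
  filtering (a per-stride variance would be downward-biased on ~1 s
  windows);
* the affected step proportion of stride distance divides the affected
  step's anterior foot-position increment (affected minus contralateral
  foot position at the affected heel-strike) by the sum of both steps'
  increments;
* moments are used in Nm as provided, not mass-normalized.

Every descriptor is cross-checked against an independent brute-force
implementation (plain per-stride loops) to 1e-9, and against closed forms
on constructed waveforms (constant-offset RMS, planted sinusoid extrema,
zero power at constant angle).

## Trend inference

Each descriptor (and the normalized metabolic ratio, and normalized 10MWT
speed) is modelled as

$$y_{is} = \beta_0 + \beta_L d + \beta_Q d^2 + \beta_S v + u_i + w_i v +
\varepsilon,$$

with stiffness deviation $d$ (%), relative speed $v$, random intercept
$u_i$ and random speed slope $w_i$ per subject (treated as independent —
the smallest identifiable structure at seven subjects). Estimation is by
maximum likelihood through `lme4`, with Wald $z$ tests on the fixed
effects: Wald tests supply the $(\beta_L, \beta_Q)$ covariance block that
the delta method needs. On convergence failure the model falls back to a
random intercept only and is flagged.

The vertex sits at $-\beta_L / (2\beta_Q)$. Its 95 % confidence interval
comes from first-order error propagation with gradient
$(-1/(2\beta_Q),\; \beta_L/(2\beta_Q^2))$ and normal quantile 1.959964 (no
small-sample $t$ correction — the delta method is asymptotic, and the fixed
quantile keeps results reproducible). Trends are classified into four
categories: quadratic with vertex within 10 % of preferred
(`quadratic_near`), quadratic with a far vertex, linear, or none — using
raw $\alpha = 0.05$, while Bonferroni-corrected flags ($\alpha/25$) are
reported alongside, mirroring the dual convention customary for such
descriptor tables. Whether the correction applies jointly or per term is
not settled; both raw p-values and per-term corrected stars are emitted so
either convention can be read off. Descriptor models pool all three speeds
with a speed fixed effect (the model structure implies pooling); per-speed
fitting can be had by subsetting the records.

The preference-versus-speed analysis is staged exactly: a first-order
mixed model of dial-selected preference on relative speed; only if its
linear term is not significant is the second-order model fit, reporting the
quadratic p-value and, when the parabola opens upward, the implied speed of
minimum preference. Body mass versus mean preference is ordinary least
squares. The 10MWT analysis normalizes each trial's speed (distance/time)
to the subject's daily-use baseline, fits first- and second-order models in
$d$, and runs a post-hoc two-sample $t$ test of subject-condition means
below versus at/above preferred; two-sample on condition means is the
default because the exact test variant behind such post-hoc comparisons is
conventionally underspecified.

## The synthetic study

`gen_study()` emits the complete crossover design: 3 preference repetitions
× 3 speeds (63 rows at 7 subjects), one 5-trial metabolic block per
subject-speed, gait trials over the full 3 × 5 condition grid, and 3 10MWT
repetitions per stiffness level plus daily-use baselines, together with a
ground-truth sidecar. Defaults encode the study conditions: masses uniform
on 58.6–99.2 kg, preferred stiffness inside the device range (base value
7–16 Nm/deg so the ±30 % grid stays achievable), $\tau = 42$ s, the block
durations above, and a U-shaped preference-speed profile (quadratic with
minimum at self-selected speed, relative curvature 1.2 — at ±30 % speed the
preferred stiffness rises ~11 %, a magnitude chosen as physiologically
plausible since intra-subject preference variability is not quantified in
the literature; the per-repetition dial SD of 0.5 Nm/deg is likewise a
configurable default, not a calibrated value).

Gait waveforms are sums of harmonics of gait-cycle phase — generic gait
shapes under analytic control, not digitized subject curves. The
unaffected side is stiffness-independent; affected-side amplitudes scale
linearly with stiffness deviation (ankle angle −0.30, knee angle −0.20,
ankle moment +0.40, pelvic tilt +0.50 per 100 % deviation; signs follow the
direction of the corresponding published linear trends: a stiffer ankle
deflects less and transmits more moment), and the affected ankle carries an
additional asymmetry term proportional to the deviation from a planted
vertex. Cross-leg RMS differences of coupled channels are therefore
V-shaped with a minimum at the planted vertex — the fitted quadratic of a
symmetric V has its vertex exactly there — and pelvic tilt variance is an
exact quadratic with a far vertex ($-100/\text{slope} = -200\,\%$).
Stride-to-stride variability is multiplicative amplitude jitter (SD 0.02),
duration jitter (SD 0.02 s) and additive channel noise; GRF is a
double-peaked stance template with zero-force swing, duty factor 0.62, so
stance detection is well-posed. Stride timing is quantized to the sample
grid so that in the noise-free limit both sides sample identical phase
lattices and planted symmetry is recovered exactly. 10MWT speeds drop 5 %
below preferred stiffness and are flat at/above — the qualitative published
pattern, without asserting magnitudes as truth.

What the generator does *not* emulate: marker-level kinematics and
inverse-dynamics error structure, breath-gas artifacts and drift,
dial-exploration dynamics, real crossover-step physics (contamination is
planted as flags), and correlated residuals across descriptors. Passing
recovery tests therefore demonstrates correctness of the estimators under
the model's assumptions, not robustness to every artifact of real
recordings.

## Validation experiments and problem sizes

The packaged experiments (`metabolic_recovery_check()`,
`vertex_coverage_sim()`, `classification_recovery_sim()`) run at the study
scale: 7 subjects, 3 speeds × 5 stiffness levels (105 records per
dataset). Coverage uses 500 simulated datasets with the residual SD (1.5)
calibrated so the quadratic Wald statistic is near 5, the regime where the
first-order delta approximation should be accurate; observed coverage is
94–95 %. Classification uses 200 replicates per planted condition with
effect sizes giving Wald statistics of 5–7 (≥ 99 % power for the active
terms); the null condition doubles as the type-I check of the quadratic
term (observed 0.03–0.07). Note that "correct classification" of a true
null is bounded by one minus the combined false-positive rate of two tests
at raw $\alpha = 0.05$, i.e. ~90 % by construction — a property of the
classification rule, not of the implementation. The metabolic
oracle-equivalence check runs 100 replicates of the 18-minute block
(~360 breaths each). These sizes keep the full validation under two
minutes on one core while leaving Monte-Carlo error well inside the
asserted bands.

## Known limitations

* Wald z-tests at seven subjects are asymptotic; no Kenward–Roger or
  Satterthwaite correction is offered, matching the delta-method framing.
* The random-effects covariance is diagonal by design; correlated
  intercept-slope structures are not identifiable at this cohort size.
* The vertex CI degenerates when $\beta_Q \to 0$ (the ratio's distribution
  becomes heavy-tailed); vertices are reported for all fits but are only
  meaningful, and only classified, when the quadratic term is significant.
* Descriptor ground-truth categories for affected-side scalar extrema are
  nominally linear but inherit mild convexity from the symmetry term (a
  maximum over phase of linearly-varying curves is piecewise linear in the
  coupling), so end-to-end category matching for those descriptors is
  informational; formal recovery guarantees are stated at the
  mixed-model level, where truth is exact.
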