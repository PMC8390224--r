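#' Generator settings for the synthetic study
#'
#' Central configuration for the synthetic-data generator. Defaults encode
#' the crossover study design the analysis assumes: seven subjects, body
#' mass uniform on 58.6-99.2 kg, a stiffness grid of +0/±15/±30 % around
#' each subject's preferred value, treadmill speeds at -30/+0/+30 % of
#' self-selected, metabolic blocks of five consecutive trials (4/4/4/3/3
#' minutes for the first block of a session, 4/3/3/3/3 thereafter), and
#' device stiffness bounded to 3.4-23.3 Nm/deg.
#'
#' @param mass_range Body-mass range in kg (uniform draw).
#' @param speed_mean,speed_sd Self-selected treadmill speed distribution
#'   (m/s), truncated to `speed_range`.
#' @param speed_range Allowed self-selected speed range (m/s).
#' @param resting_range Quiet-standing resting metabolic rate range (W).
#' @param pref_base_range Range of preferred stiffness at self-selected
#'   speed (Nm/deg); kept inside the device range so the ±30 % grid stays
#'   achievable.
#' @param u_shaped_preference If `TRUE`, preferred stiffness vs relative
#'   speed is quadratic with its minimum at relative speed 0.
#' @param pref_curvature Relative curvature of the preference-speed profile:
#'   preferred stiffness at relative speed `v` is
#'   `base * (1 + pref_curvature * v^2)`.
#' @param pref_noise_sd SD (Nm/deg) of the per-repetition dial-selected
#'   preference around the subject's true preferred value.
#' @param stiffness_bounds Device stiffness range (Nm/deg).
#' @param tau First-order metabolic time constant (s).
#' @param breath_interval_mean,breath_interval_sd,breath_interval_min
#'   Truncated-normal inter-breath interval parameters (s).
#' @param breath_noise_sd Additive breath-to-breath noise SD (W).
#' @param wkg_coefs Coefficients `(a, b, c)` of net walking metabolic
#'   intensity in W/kg as a function of relative speed `v`:
#'   `a + b*v + c*v^2`.
#' @param sd_met_wkg Between-subject SD of metabolic intensity (W/kg).
#' @param stiffness_met_effect Quadratic effect of stiffness deviation on
#'   metabolic intensity (W/kg per (% dev)^2); 0 by default — stiffness
#'   changes of this size do not measurably move metabolic rate.
#' @param sample_rate Gait sampling rate (Hz).
#' @param stride_duration Stride duration at self-selected speed (s).
#' @param stride_duration_speed_slope Fractional change of stride duration
#'   per unit relative speed (negative: faster cadence at higher speed).
#' @param duty Stance fraction of the gait cycle.
#' @param n_strides Strides generated per gait trial.
#' @param ank_amp_slope,knee_amp_slope,mom_amp_slope,pelvic_amp_slope
#'   Fractional amplitude change of the affected-side ankle angle, knee
#'   angle, ankle moment and pelvic tilt per 100 % stiffness deviation.
#'   Signs follow the observed trends: a stiffer prosthetic ankle deflects
#'   less (negative angle slopes) and transmits a larger moment.
#' @param sym_slope Ankle-angle asymmetry scale (deg per 100 % deviation
#'   from the planted symmetry vertex).
#' @param planted_vertex Stiffness deviation (%) at which the affected-side
#'   ankle trajectory exactly matches the unaffected template.
#' @param amp_jitter_sd Stride-to-stride multiplicative amplitude jitter SD.
#' @param duration_jitter_sd Stride-to-stride duration jitter SD (s).
#' @param angle_noise_sd,moment_noise_sd,grf_noise_sd,misc_noise_sd Additive
#'   measurement noise SDs (deg, Nm, N, signal units).
#' @param crossover_rate Probability that a stride is contaminated by a
#'   crossover step onto the wrong force plate (flagged, to be excluded).
#' @param tenmwt_penalty Fractional reduction of self-selected overground
#'   speed at stiffness below preferred.
#' @param tenmwt_noise_sd SD of normalized 10-meter-walk-test speed.
#' @param tenmwt_distance Course length (m).
#' @param sd_intercept,sd_speed_slope Between-subject SD of the descriptor
#'   random intercept (descriptor units) and of the random speed slope.
#' @return A named list of class `synth_config`.
#' @export
synth_config <- function(mass_range = c(58.6, 99.2),
                         speed_mean = 1.1, speed_sd = 0.15,
                         speed_range = c(0.6, 1.6),
                         resting_range = c(80, 120),
                         pref_base_range = c(7, 16),
                         u_shaped_preference = TRUE,
                         pref_curvature = 1.2,
                         pref_noise_sd = 0.5,
                         stiffness_bounds = c(3.4, 23.3),
                         tau = 42,
                         breath_interval_mean = 3,
                         breath_interval_sd = 0.8,
                         breath_interval_min = 1,
                         breath_noise_sd = 20,
                         wkg_coefs = c(3.0, 2.5, 4.0),
                         sd_met_wkg = 0.25,
                         stiffness_met_effect = 0,
                         sample_rate = 100,
                         stride_duration = 1.15,
                         stride_duration_speed_slope = -0.25,
                         duty = 0.62,
                         n_strides = 12,
                         ank_amp_slope = -0.30,
                         knee_amp_slope = -0.20,
                         mom_amp_slope = 0.40,
                         pelvic_amp_slope = 0.50,
                         sym_slope = 4,
                         planted_vertex = 0,
                         amp_jitter_sd = 0.02,
                         duration_jitter_sd = 0.02,
                         angle_noise_sd = 0.3,
                         moment_noise_sd = 1,
                         grf_noise_sd = 8,
                         misc_noise_sd = 0.003,
                         crossover_rate = 0,
                         tenmwt_penalty = 0.05,
                         tenmwt_noise_sd = 0.03,
                         tenmwt_distance = 10,
                         sd_intercept = 0.3,
                         sd_speed_slope = 0.5) {
  cfg <- as.list(environment())
  validate_synth_config(cfg)
  structure(cfg, class = "synth_config")
}

validate_synth_config <- function(cfg) {
  chk_range <- function(r, nm) {
    if (length(r) != 2L || any(!is.finite(r)) || r[1] > r[2])
      stop(sprintf("degenerate range for `%s`", nm))
  }
  chk_range(cfg$mass_range, "mass_range")
  chk_range(cfg$resting_range, "resting_range")
  chk_range(cfg$pref_base_range, "pref_base_range")
  chk_range(cfg$speed_range, "speed_range")
  chk_range(cfg$stiffness_bounds, "stiffness_bounds")
  if (cfg$tau <= 0) stop("`tau` must be positive")
  if (cfg$breath_noise_sd < 0) stop("`breath_noise_sd` must be non-negative")
  if (cfg$duty <= 0 || cfg$duty >= 1) stop("`duty` must be in (0, 1)")
  if (cfg$sample_rate <= 0) stop("`sample_rate` must be positive")
  if (cfg$pref_base_range[2] * (1 + abs(cfg$pref_curvature) * 0.09) * 1.3 >
      cfg$stiffness_bounds[2])
    stop("`pref_base_range` too high: +30% grid would exceed the device maximum")
  if (cfg$pref_base_range[1] * 0.7 < cfg$stiffness_bounds[1])
    stop("`pref_base_range` too low: -30% grid would fall below the device minimum")
  invisible(cfg)
}

# Deterministic substream seeds: master seed plus a stage tag and unit index,
# folded into the 32-bit integer range.
derive_seed <- function(seed, stage, unit = 0L) {
  stage_code <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.double(seed) * 7919 + stage_code * 131 + unit) %% 2147483647)
}

#' Study design grids
#'
#' The fixed condition grids of the crossover design: relative treadmill
#' speeds and stiffness deviations from preferred.
#' @return Named list with `speed_levels` (fractions of self-selected) and
#'   `stiffness_levels` (% deviation from preferred).
#' @export
study_grids <- function() {
  list(speed_levels = c(-0.3, 0, 0.3),
       stiffness_levels = c(-30, -15, 0, 15, 30))
}

# Block durations in seconds: first visited speed block 4/4/4/3/3 min,
# later blocks 4/3/3/3/3 min.
block_durations <- function(first_block) {
  if (first_block) c(4, 4, 4, 3, 3) * 60 else c(4, 3, 3, 3, 3) * 60
}
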