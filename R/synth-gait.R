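# Waveform templates for the synthetic gait generator. Each template is a
# smooth sum of harmonics of the gait-cycle phase p in [0, 1); stance spans
# [0, duty). Offsets are kept separate from deviations so stiffness-coupled
# amplitude scaling acts on the deviation only (ROM and peaks then scale
# exactly linearly with the coupling gain).
gait_templates <- function() {
  stance_s <- function(p, duty) ifelse(p < duty, p / duty, NA_real_)
  list(
    grf = function(p, duty) {
      s <- p / duty
      ifelse(p < duty, pmax(sin(pi * s) + 0.25 * sin(3 * pi * s), 0), 0)
    },
    ank = list(offset = 2, dev = function(p)
      8 * sin(2 * pi * p + 0.2) + 2.5 * sin(4 * pi * p - 0.5)),
    knee = list(offset = 22, dev = function(p)
      -18 * cos(2 * pi * p - 2.6) - 10 * cos(4 * pi * p - 0.9)),
    hip = list(offset = 10, dev = function(p)
      28 * cos(2 * pi * p + 0.3)),
    ank_mom = function(p, duty) {
      s <- stance_s(p, duty)
      out <- -60 * sin(pi * s) * s
      out[is.na(out)] <- 0
      out
    },
    knee_mom = function(p, duty) {
      s <- stance_s(p, duty)
      out <- 40 * sin(2 * pi * s) * sin(pi * s)
      out[is.na(out)] <- 0
      out
    },
    hip_mom = function(p, duty) {
      s <- stance_s(p, duty)
      out <- 55 * cos(pi * s) * sin(pi * s)
      out[is.na(out)] <- 0
      out
    },
    sym = function(p) sin(2 * pi * p + 1.1) + 0.5 * sin(6 * pi * p),
    hip_ht = function(p) 0.92 + 0.025 * cos(4 * pi * p + 0.5),
    foot_ap = function(p, amp) amp * cos(2 * pi * p)
  )
}

# Phase of each integer sample index relative to a side's heel-strike
# sequence (also in samples), with one virtual stride prepended/appended so
# edge samples stay defined. Working in integer samples keeps both sides on
# the same exact phase lattice when stride durations are equal.
phase_from_hs <- function(k, hs) {
  hs_ext <- c(hs[1] - (hs[2] - hs[1]), hs,
              hs[length(hs)] + (hs[length(hs)] - hs[length(hs) - 1]))
  i <- findInterval(k, hs_ext)
  i <- pmax(pmin(i, length(hs_ext) - 1L), 1L)
  (k - hs_ext[i]) / (hs_ext[i + 1L] - hs_ext[i])
}

#' Generate a synthetic gait trial
#'
#' Builds a multichannel gait recording for one subject-speed-stiffness
#' condition: per-side vertical GRF with a double-peak stance template and
#' zero-force swing (stance detection is therefore well-posed), hip/knee/
#' ankle angles and net moments per side, pelvic tilt, per-side hip height
#' and anterior foot position, with stride-to-stride duration jitter,
#' multiplicative amplitude jitter and additive measurement noise.
#'
#' The unaffected side is a stiffness-independent template. Affected-side
#' amplitudes scale linearly with stiffness deviation from preferred (per
#' the configured coupling slopes), and the affected ankle angle carries an
#' additional asymmetry term proportional to the deviation from the planted
#' symmetry vertex, so that the pointwise affected-unaffected difference
#' vanishes exactly at `stiffness = preferred * (1 + planted_vertex/100)`
#' when couplings other than the symmetry term are inactive there.
#'
#' @param subject A `subject_spec`.
#' @param speed_rel Relative treadmill speed (-0.3, 0, +0.3).
#' @param stiffness Absolute stiffness (Nm/deg), inside the device range.
#' @param n_strides Number of affected-side strides to generate (>= 3).
#' @param seed Integer seed.
#' @param config A [synth_config()].
#' @return List with `recording` (class `gait_recording`: `sample_rate`,
#'   `time_s`, `channels` named list, `crossover` 0/1 flags, `meta`) and
#'   `truth` (planted vertex, stiffness deviation, duty factor, gains).
#' @export
gen_gait_trial <- function(subject, speed_rel = 0, stiffness = NULL,
                           n_strides = NULL, seed = 1,
                           config = synth_config()) {
  stopifnot(inherits(subject, "subject_spec"))
  pref <- subject$preferred_stiffness_by_speed[[as.character(speed_rel)]]
  if (is.null(pref) || !is.finite(pref))
    stop("subject has no preferred stiffness for this speed")
  if (is.null(stiffness)) stiffness <- pref
  if (is.null(n_strides)) n_strides <- config$n_strides
  if (n_strides < 3) stop("`n_strides` must be at least 3")
  if (stiffness < config$stiffness_bounds[1] ||
      stiffness > config$stiffness_bounds[2])
    stop("`stiffness` outside the device range")
  set.seed(derive_seed(seed, "gait"))

  dev <- 100 * (stiffness / pref - 1)
  tpl <- gait_templates()
  fs <- config$sample_rate
  duty <- config$duty
  bw <- subject$body_mass * 9.81

  # stride timing on the integer sample grid: n_strides affected strides
  # plus one lead-in/out stride; unaffected heel-strikes fall mid-stride
  T0 <- config$stride_duration *
    (1 + config$stride_duration_speed_slope * speed_rel)
  nT <- n_strides + 2L
  Ns <- pmax(round(fs * (T0 + stats::rnorm(nT, 0, config$duration_jitter_sd))),
             round(0.4 * fs))
  hs_aff <- cumsum(c(0L, Ns))                     # affected heel-strikes (samples)
  hs_una <- hs_aff[-length(hs_aff)] + round(Ns / 2)
  total_n <- hs_aff[length(hs_aff)]
  k <- 0:total_n
  time_s <- k / fs

  p_aff <- phase_from_hs(k, hs_aff)
  p_una <- phase_from_hs(k, hs_una)

  # amplitude couplings with stiffness deviation (affected side only) and a
  # mild symmetric speed scaling on both sides
  g_ank <- 1 + config$ank_amp_slope * dev / 100
  g_knee <- 1 + config$knee_amp_slope * dev / 100
  g_mom <- 1 + config$mom_amp_slope * dev / 100
  g_spd_ang <- 1 + 0.15 * speed_rel
  g_spd_mom <- 1 + 0.30 * speed_rel
  d_sym <- config$sym_slope * (dev - config$planted_vertex) / 100

  # per-stride multiplicative jitter, indexed by the stride containing each
  # sample on each side
  jit <- function(hs) {
    idx <- findInterval(k, hs) + 1L
    g <- 1 + stats::rnorm(length(hs) + 2L, 0, config$amp_jitter_sd)
    g[pmax(pmin(idx, length(g)), 1L)]
  }
  j_aff <- jit(hs_aff)
  j_una <- jit(hs_una)

  add_noise <- function(x, sd) {
    if (sd > 0) x + stats::rnorm(length(x), 0, sd) else x
  }

  ang <- function(side_tpl, p, gain, j)
    side_tpl$offset + gain * g_spd_ang * j * side_tpl$dev(p)

  ch <- list()
  ch$vgrf_aff <- pmax(add_noise(bw * 1.05 * j_aff * tpl$grf(p_aff, duty),
                                config$grf_noise_sd), 0)
  ch$vgrf_una <- pmax(add_noise(bw * 1.05 * j_una * tpl$grf(p_una, duty),
                                config$grf_noise_sd), 0)
  ch$hip_ang_aff <- add_noise(ang(tpl$hip, p_aff, 1, j_aff), config$angle_noise_sd)
  ch$hip_ang_una <- add_noise(ang(tpl$hip, p_una, 1, j_una), config$angle_noise_sd)
  ch$knee_ang_aff <- add_noise(ang(tpl$knee, p_aff, g_knee, j_aff), config$angle_noise_sd)
  ch$knee_ang_una <- add_noise(ang(tpl$knee, p_una, 1, j_una), config$angle_noise_sd)
  ch$ank_ang_aff <- add_noise(ang(tpl$ank, p_aff, g_ank, j_aff) +
                                d_sym * tpl$sym(p_aff), config$angle_noise_sd)
  ch$ank_ang_una <- add_noise(ang(tpl$ank, p_una, 1, j_una), config$angle_noise_sd)
  ch$hip_mom_aff <- add_noise(g_spd_mom * j_aff * tpl$hip_mom(p_aff, duty),
                              config$moment_noise_sd)
  ch$hip_mom_una <- add_noise(g_spd_mom * j_una * tpl$hip_mom(p_una, duty),
                              config$moment_noise_sd)
  ch$knee_mom_aff <- add_noise(g_spd_mom * j_aff * tpl$knee_mom(p_aff, duty),
                               config$moment_noise_sd)
  ch$knee_mom_una <- add_noise(g_spd_mom * j_una * tpl$knee_mom(p_una, duty),
                               config$moment_noise_sd)
  ch$ank_mom_aff <- add_noise(g_mom * g_spd_mom * j_aff * tpl$ank_mom(p_aff, duty),
                              config$moment_noise_sd)
  ch$ank_mom_una <- add_noise(g_spd_mom * j_una * tpl$ank_mom(p_una, duty),
                              config$moment_noise_sd)
  pelvic_amp <- 2 * (1 + config$pelvic_amp_slope * dev / 100)
  ch$pelvic_tilt <- add_noise(5 + pelvic_amp * sin(4 * pi * p_aff + 0.7),
                              config$angle_noise_sd)
  ch$hip_ht_aff <- add_noise(tpl$hip_ht(p_aff), config$misc_noise_sd)
  ch$hip_ht_una <- add_noise(tpl$hip_ht(p_una), config$misc_noise_sd)
  ch$foot_ap_aff <- add_noise(tpl$foot_ap(p_aff, 0.36), config$misc_noise_sd)
  ch$foot_ap_una <- add_noise(tpl$foot_ap(p_una, 0.34), config$misc_noise_sd)

  crossover <- integer(length(k))
  if (config$crossover_rate > 0) {
    flagged <- which(stats::runif(length(hs_aff) - 1L) < config$crossover_rate)
    for (s in flagged) {
      in_stance <- k >= hs_aff[s] & k < hs_aff[s] + duty * Ns[s]
      crossover[in_stance] <- 1L
    }
  }

  rec <- structure(list(
    sample_rate = fs, time_s = time_s, channels = ch, crossover = crossover,
    meta = list(subject_id = subject$subject_id, speed_rel = speed_rel,
                stiffness = stiffness, stiffness_rel = dev,
                body_mass = subject$body_mass)),
    class = "gait_recording")
  list(recording = rec,
       truth = list(planted_vertex = config$planted_vertex,
                    stiffness_dev = dev, duty = duty,
                    gains = c(ank = g_ank, knee = g_knee, mom = g_mom),
                    d_sym = d_sym))
}

#' @export
print.gait_recording <- function(x, ...) {
  cat(sprintf("<gait_recording %s: %.1f s at %g Hz, %d channels, speed %+d%%, stiffness %+.0f%%>\n",
              x$meta$subject_id, max(x$time_s), x$sample_rate,
              length(x$channels), round(100 * x$meta$speed_rel),
              x$meta$stiffness_rel))
  invisible(x)
}

# Intended trend category per descriptor implied by the generator couplings;
# this is the ground truth that end-to-end recovery reports compare against.
# Trajectory-RMS and variance measures have exact planted shapes: an
# affected-side amplitude coupling makes the cross-leg RMS difference
# V-shaped with its minimum at zero deviation (quadratic category), and the
# pelvic tilt variance is an exact quadratic in deviation with vertex at
# -100 / pelvic_amp_slope. Affected-side scalar extrema are linear in the
# coupling gain up to the mild convexity inherited from the symmetry term,
# so their planted category is "linear".
descriptor_truth <- function(config = synth_config()) {
  reg <- descriptor_registry()
  quad_cat <- function(v) if (abs(v) <= 10) "quadratic_near" else "quadratic_far"
  cat_of <- function(nm) {
    if (nm == "cross_leg_rms_diff_ankle_angle") {
      quad_cat(config$planted_vertex)
    } else if (nm == "cross_leg_rms_diff_knee_angle") {
      if (config$knee_amp_slope != 0) quad_cat(0) else "none"
    } else if (nm == "cross_leg_rms_diff_ankle_moment") {
      if (config$mom_amp_slope != 0) quad_cat(0) else "none"
    } else if (nm == "pelvic_tilt_variance") {
      if (config$pelvic_amp_slope != 0)
        quad_cat(-100 / config$pelvic_amp_slope) else "none"
    } else if (nm %in% c("affected_ankle_peak_df_angle", "affected_ankle_rom")) {
      if (config$ank_amp_slope != 0) "linear" else "none"
    } else if (nm %in% c("affected_ankle_peak_pf_moment", "affected_ankle_peak_power",
                         "cross_leg_diff_peak_ankle_pf_moment",
                         "cross_leg_diff_peak_ankle_power")) {
      if (config$mom_amp_slope != 0) "linear" else "none"
    } else if (nm == "affected_knee_rom") {
      if (config$knee_amp_slope != 0) "linear" else "none"
    } else "none"
  }
  vx_of <- function(nm) {
    if (nm == "cross_leg_rms_diff_ankle_angle") config$planted_vertex
    else if (nm %in% c("cross_leg_rms_diff_knee_angle",
                       "cross_leg_rms_diff_ankle_moment")) 0
    else if (nm == "pelvic_tilt_variance" && config$pelvic_amp_slope != 0)
      -100 / config$pelvic_amp_slope
    else NA_real_
  }
  data.frame(descriptor = reg,
             category = vapply(reg, cat_of, character(1)),
             vertex = vapply(reg, vx_of, numeric(1)),
             row.names = NULL)
}
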