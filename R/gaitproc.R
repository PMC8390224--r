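#' Zero-phase Butterworth low-pass filter
#'
#' Forward-reverse (zero-phase) fourth-order Butterworth low-pass, the
#' standard smoothing applied to gait kinematics, kinetics and ground
#' reaction forces before event detection and descriptor extraction. Two
#' passes square the filter magnitude, so the amplitude response at the
#' cutoff is 0.5 rather than the single-pass -3 dB.
#'
#' @param x Numeric signal.
#' @param sample_rate Sampling rate in Hz; must exceed twice the cutoff.
#' @param cutoff Cutoff frequency in Hz (default 15).
#' @param order Filter order per pass (default 4).
#' @return Filtered signal, same length as `x`.
#' @export
lowpass_filter <- function(x, sample_rate, cutoff = 15, order = 4) {
  if (!is.finite(sample_rate) || sample_rate <= 2 * cutoff)
    stop("`sample_rate` must exceed twice the cutoff (Nyquist)")
  n <- length(x)
  bf <- signal::butter(order, cutoff / (sample_rate / 2), type = "low")
  # odd-reflection padding long enough for the start-up transient to decay,
  # after removing the mean (keeps the DC response exact at the edges)
  L <- min(n - 1L, ceiling(3 * sample_rate / cutoff))
  mu <- mean(x)
  xc <- x - mu
  xp <- c(2 * xc[1] - xc[(L + 1L):2L], xc, 2 * xc[n] - xc[(n - 1L):(n - L)])
  y <- signal::filter(bf, xp)
  y <- rev(as.numeric(signal::filter(bf, rev(as.numeric(y)))))
  y[(L + 1L):(L + n)] + mu
}

#' Filter all channels of a gait recording
#'
#' Applies [lowpass_filter()] to every channel of a recording, returning a
#' recording with the same structure. Run before gait-event detection and
#' descriptor extraction in the standard pipeline.
#'
#' @param recording A `gait_recording`.
#' @inheritParams lowpass_filter
#' @return A filtered `gait_recording`.
#' @export
filter_recording <- function(recording, cutoff = 15, order = 4) {
  stopifnot(inherits(recording, "gait_recording"))
  recording$channels <- lapply(recording$channels, lowpass_filter,
                               sample_rate = recording$sample_rate,
                               cutoff = cutoff, order = order)
  recording
}

#' Detect gait cycles and stance phases from vertical GRF
#'
#' Per side, stance is any contiguous run of samples where the vertical
#' ground reaction force exceeds a body-weight-scaled threshold for at least
#' `min_stance_s` (debouncing short spikes). Heel-strike is the first sample
#' of each qualifying run; a gait cycle spans heel-strike to the next
#' ipsilateral heel-strike, so the partial cycles before the first and after
#' the last detected heel-strike are dropped by construction. Cycles whose
#' span overlaps any crossover-contamination flag (stance not isolated to a
#' single force plate) are marked excluded with reason `"crossover"`.
#'
#' @param recording A `gait_recording` with `vgrf_aff`/`vgrf_una` channels
#'   and `body_mass` in its metadata.
#' @param threshold_frac_bw Stance threshold as a fraction of body weight
#'   (default 0.05).
#' @param min_stance_s Minimum sustained-contact duration in seconds
#'   (default 0.2).
#' @return A data frame of class `stride_set`: one row per gait cycle with
#'   columns `side` ("affected"/"unaffected"), `start`, `end` (sample
#'   indices, 1-based; `end` is the next ipsilateral heel-strike),
#'   `stance_len` (samples), `excluded`, `reason`.
#' @export
detect_gait_cycles <- function(recording, threshold_frac_bw = 0.05,
                               min_stance_s = 0.2) {
  stopifnot(inherits(recording, "gait_recording"))
  if (is.null(recording$channels$vgrf_aff) || is.null(recording$channels$vgrf_una))
    stop("missing vertical GRF channel(s)")
  if (is.null(recording$meta$body_mass))
    stop("recording metadata must include `body_mass` for threshold scaling")
  thr <- threshold_frac_bw * recording$meta$body_mass * 9.81
  min_len <- ceiling(min_stance_s * recording$sample_rate)

  one_side <- function(grf, side) {
    r <- rle(grf > thr)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- r$values & r$lengths >= min_len
    hs <- starts[keep]
    slen <- r$lengths[keep]
    if (length(hs) < 2L)
      stop(sprintf("no complete gait cycle found on %s side", side))
    n <- length(hs) - 1L
    data.frame(side = side, start = hs[seq_len(n)], end = hs[-1L],
               stance_len = slen[seq_len(n)],
               excluded = FALSE, reason = NA_character_)
  }
  out <- rbind(one_side(recording$channels$vgrf_aff, "affected"),
               one_side(recording$channels$vgrf_una, "unaffected"))
  if (any(recording$crossover > 0)) {
    flagged <- which(recording$crossover > 0)
    hit <- vapply(seq_len(nrow(out)), function(i)
      any(flagged >= out$start[i] & flagged < out$end[i]), logical(1))
    out$excluded[hit] <- TRUE
    out$reason[hit] <- "crossover"
  }
  class(out) <- c("stride_set", "data.frame")
  out
}

# Linear interpolation of one channel onto `npts` evenly spaced sample
# positions spanning [from, to] (1-based sample indices).
resample_span <- function(x, from, to, npts = 101L) {
  if (to - from + 1L < 3L) stop("stride shorter than 3 samples")
  stats::approx(x = seq_along(x), y = x,
                xout = seq(from, to, length.out = npts))$y
}

#' Time-normalize strides to percent gait cycle
#'
#' Linearly interpolates every channel of each non-excluded stride onto 101
#' evenly spaced points spanning 0-100 % of the gait cycle, and additionally
#' onto a 101-point grid spanning the stance phase only (used by cross-leg
#' trajectory comparisons, so unequal stance durations remain comparable).
#'
#' @param recording A `gait_recording`.
#' @param strides A `stride_set` from [detect_gait_cycles()].
#' @return List of `normalized_stride` objects, each a list with `side`,
#'   `start`, `end`, `stance_end` (% gait cycle), `cycle` (named list of
#'   101-point arrays) and `stance` (named list of 101-point stance-only
#'   arrays).
#' @export
time_normalize <- function(recording, strides) {
  stopifnot(inherits(recording, "gait_recording"), inherits(strides, "stride_set"))
  keep <- which(!strides$excluded)
  lapply(keep, function(i) {
    s <- strides[i, ]
    cyc <- lapply(recording$channels, resample_span, from = s$start, to = s$end)
    stn <- lapply(recording$channels, resample_span,
                  from = s$start, to = s$start + s$stance_len - 1L)
    stance_end <- 100 * s$stance_len / (s$end - s$start)
    structure(list(side = s$side, start = s$start, end = s$end,
                   stance_len = s$stance_len, stance_end = stance_end,
                   cycle = cyc, stance = stn),
              class = "normalized_stride")
  })
}

#' Net joint power from moment and angle
#'
#' Joint angular velocity is the discrete time derivative of the joint angle
#' (central differences, one-sided at the ends), converted to rad/s; net
#' joint power is the product of net joint moment and angular velocity.
#'
#' @param moment Net joint moment (Nm).
#' @param angle Joint angle (deg), same length.
#' @param sample_rate Sampling rate (Hz).
#' @return Net joint power (W), same length.
#' @export
joint_power <- function(moment, angle, sample_rate) {
  n <- length(angle)
  if (length(moment) != n) stop("`moment` and `angle` lengths differ")
  if (n < 3L) stop("signals too short for differentiation")
  rad <- angle * pi / 180
  vel <- numeric(n)
  vel[2:(n - 1)] <- (rad[3:n] - rad[1:(n - 2)]) * sample_rate / 2
  vel[1] <- (rad[2] - rad[1]) * sample_rate
  vel[n] <- (rad[n] - rad[n - 1]) * sample_rate
  moment * vel
}

#' Registry of the 25 biomechanical descriptors
#'
#' Fixed names of the descriptor set extracted per subject-speed-stiffness
#' condition: hip, knee and ankle angle/moment/power features per side,
#' cross-leg symmetry measures, pelvic tilt variance, and step-timing/
#' step-length proportions.
#'
#' @return Character vector of 25 descriptor names.
#' @export
descriptor_registry <- function() {
  c("cross_leg_diff_max_hip_height",
    "cross_leg_rms_diff_hip_angle",
    "cross_leg_rms_diff_hip_moment",
    "pelvic_tilt_variance",
    "affected_knee_rom",
    "affected_knee_peak_flex_moment",
    "affected_knee_peak_ext_moment",
    "unaffected_knee_rom",
    "unaffected_knee_peak_early_flex_angle",
    "unaffected_knee_peak_early_ext_moment",
    "cross_leg_rms_diff_knee_angle",
    "cross_leg_rms_diff_knee_moment",
    "cross_leg_diff_peak_knee_ext_moment",
    "affected_ankle_peak_df_angle",
    "affected_ankle_rom",
    "affected_ankle_peak_pf_moment",
    "affected_ankle_peak_power",
    "unaffected_ankle_rom",
    "unaffected_ankle_peak_pf_moment",
    "cross_leg_rms_diff_ankle_angle",
    "cross_leg_rms_diff_ankle_moment",
    "cross_leg_diff_peak_ankle_pf_moment",
    "cross_leg_diff_peak_ankle_power",
    "affected_step_prop_stride_duration",
    "affected_step_prop_stride_distance")
}

# Pair each non-excluded affected stride with the non-excluded unaffected
# stride whose heel-strike falls within it. Returns a data frame of row
# indices into `strides`.
pair_strides <- function(strides) {
  aff <- which(strides$side == "affected" & !strides$excluded)
  una <- which(strides$side == "unaffected" & !strides$excluded)
  if (length(aff) == 0L || length(una) == 0L)
    stop("cross-leg pairing impossible: one side has no valid strides")
  pairs <- lapply(aff, function(i) {
    hit <- una[strides$start[una] >= strides$start[i] &
                 strides$start[una] < strides$end[i]]
    if (length(hit) >= 1L) data.frame(aff = i, una = hit[1L]) else NULL
  })
  do.call(rbind, pairs)
}

#' Compute the descriptor table for one recording
#'
#' Extracts all 25 registry descriptors from a segmented gait recording.
#' Scalar features (ROM, signed peaks) are computed per stride over the
#' stance phase (or the full cycle, per `extent`) and averaged across
#' strides; cross-leg trajectory measures interpolate each side's stance
#' onto a common 101-point grid, take the RMS of the pointwise difference
#' per stride pair, and average across pairs; cross-leg scalar differences
#' are per-pair (affected minus unaffected) averages. Sign convention:
#' positive is extension/dorsiflexion, so a "peak flexion (plantarflexion)
#' moment" is the magnitude of the most negative value and a "peak
#' dorsiflexion angle" the maximum; `sign = -1` flips the convention.
#' "Early" features are restricted to the first half of stance. Pelvic tilt
#' variance is the variance of the pelvic tilt signal over the analyzed
#' span. Step proportions divide the affected step (affected heel-strike to
#' the paired unaffected heel-strike) by the full stride, in time and in
#' anterior foot-position increments respectively.
#'
#' @param recording A `gait_recording` (filter first via
#'   [filter_recording()] in the standard pipeline).
#' @param strides A `stride_set`; at least one valid stride per side.
#' @param extent `"stance"` (default) or `"cycle"`: span over which scalar
#'   extrema and ROM are taken.
#' @param sign +1 (extension/dorsiflexion positive, default) or -1.
#' @return Data frame with columns `subject_id`, `speed_rel`,
#'   `stiffness_rel`, `descriptor_name`, `value`, `n_strides_used`.
#' @export
compute_descriptors <- function(recording, strides,
                                extent = c("stance", "cycle"), sign = 1) {
  stopifnot(inherits(recording, "gait_recording"), inherits(strides, "stride_set"))
  extent <- match.arg(extent)
  ch <- recording$channels
  fs <- recording$sample_rate
  ch$ank_pow_aff <- joint_power(ch$ank_mom_aff, ch$ank_ang_aff, fs)
  ch$ank_pow_una <- joint_power(ch$ank_mom_una, ch$ank_ang_una, fs)

  aff <- strides[strides$side == "affected" & !strides$excluded, , drop = FALSE]
  una <- strides[strides$side == "unaffected" & !strides$excluded, , drop = FALSE]
  if (nrow(aff) == 0L || nrow(una) == 0L)
    stop("need at least one valid stride per side")
  pairs <- pair_strides(strides)
  if (is.null(pairs)) stop("cross-leg pairing impossible: no overlapping strides")

  span_of <- function(s) {
    if (extent == "stance") c(s$start, s$start + s$stance_len - 1L) else c(s$start, s$end)
  }
  seg <- function(x, s, early = FALSE) {
    sp <- span_of(s)
    if (early) sp[2] <- sp[1] + floor((sp[2] - sp[1]) / 2)
    x[sp[1]:sp[2]]
  }
  # per-stride scalar features, averaged over strides of one side
  avg_scalar <- function(side_df, f) mean(vapply(seq_len(nrow(side_df)), function(i)
    f(side_df[i, ]), numeric(1)))
  rom <- function(x) function(s) {
    v <- seg(ch[[x]], s); max(v) - min(v)
  }
  peak_pos <- function(x, early = FALSE) function(s) max(sign * seg(ch[[x]], s, early))
  peak_neg <- function(x, early = FALSE) function(s) abs(min(sign * seg(ch[[x]], s, early)))
  peak_max <- function(x) function(s) max(seg(ch[[x]], s))

  # stance-grid RMS difference per pair
  rms_pair <- function(x) {
    vapply(seq_len(nrow(pairs)), function(k) {
      sa <- strides[pairs$aff[k], ]
      su <- strides[pairs$una[k], ]
      va <- resample_span(ch[[paste0(x, "_aff")]], sa$start, sa$start + sa$stance_len - 1L)
      vu <- resample_span(ch[[paste0(x, "_una")]], su$start, su$start + su$stance_len - 1L)
      sqrt(mean((va - vu)^2))
    }, numeric(1))
  }
  # per-pair difference of a per-stride scalar
  diff_pair <- function(f_aff, f_una) {
    vapply(seq_len(nrow(pairs)), function(k)
      f_aff(strides[pairs$aff[k], ]) - f_una(strides[pairs$una[k], ]), numeric(1))
  }

  span_all <- range(c(aff$start, aff$end, una$start, una$end))
  pelvic_var <- stats::var(ch$pelvic_tilt[span_all[1]:span_all[2]])

  step_prop_dur <- vapply(seq_len(nrow(pairs)), function(k) {
    sa <- strides[pairs$aff[k], ]
    (strides$start[pairs$una[k]] - sa$start) / (sa$end - sa$start)
  }, numeric(1))
  step_prop_dist <- vapply(seq_len(nrow(pairs)), function(k) {
    ha <- strides$start[pairs$aff[k]]
    hu <- strides$start[pairs$una[k]]
    step_aff <- ch$foot_ap_aff[ha] - ch$foot_ap_una[ha]
    step_una <- ch$foot_ap_una[hu] - ch$foot_ap_aff[hu]
    step_aff / (step_aff + step_una)
  }, numeric(1))

  vals <- c(
    cross_leg_diff_max_hip_height = mean(diff_pair(peak_max("hip_ht_aff"), peak_max("hip_ht_una"))),
    cross_leg_rms_diff_hip_angle = mean(rms_pair("hip_ang")),
    cross_leg_rms_diff_hip_moment = mean(rms_pair("hip_mom")),
    pelvic_tilt_variance = pelvic_var,
    affected_knee_rom = avg_scalar(aff, rom("knee_ang_aff")),
    affected_knee_peak_flex_moment = avg_scalar(aff, peak_neg("knee_mom_aff")),
    affected_knee_peak_ext_moment = avg_scalar(aff, peak_pos("knee_mom_aff")),
    unaffected_knee_rom = avg_scalar(una, rom("knee_ang_una")),
    unaffected_knee_peak_early_flex_angle = avg_scalar(una, peak_neg("knee_ang_una", early = TRUE)),
    unaffected_knee_peak_early_ext_moment = avg_scalar(una, peak_pos("knee_mom_una", early = TRUE)),
    cross_leg_rms_diff_knee_angle = mean(rms_pair("knee_ang")),
    cross_leg_rms_diff_knee_moment = mean(rms_pair("knee_mom")),
    cross_leg_diff_peak_knee_ext_moment = mean(diff_pair(peak_pos("knee_mom_aff"), peak_pos("knee_mom_una"))),
    affected_ankle_peak_df_angle = avg_scalar(aff, peak_pos("ank_ang_aff")),
    affected_ankle_rom = avg_scalar(aff, rom("ank_ang_aff")),
    affected_ankle_peak_pf_moment = avg_scalar(aff, peak_neg("ank_mom_aff")),
    affected_ankle_peak_power = avg_scalar(aff, peak_max("ank_pow_aff")),
    unaffected_ankle_rom = avg_scalar(una, rom("ank_ang_una")),
    unaffected_ankle_peak_pf_moment = avg_scalar(una, peak_neg("ank_mom_una")),
    cross_leg_rms_diff_ankle_angle = mean(rms_pair("ank_ang")),
    cross_leg_rms_diff_ankle_moment = mean(rms_pair("ank_mom")),
    cross_leg_diff_peak_ankle_pf_moment = mean(diff_pair(peak_neg("ank_mom_aff"), peak_neg("ank_mom_una"))),
    cross_leg_diff_peak_ankle_power = mean(diff_pair(peak_max("ank_pow_aff"), peak_max("ank_pow_una"))),
    affected_step_prop_stride_duration = mean(step_prop_dur),
    affected_step_prop_stride_distance = mean(step_prop_dist))

  n_map <- c(cross_leg_diff_max_hip_height = nrow(pairs),
             cross_leg_rms_diff_hip_angle = nrow(pairs),
             cross_leg_rms_diff_hip_moment = nrow(pairs),
             pelvic_tilt_variance = nrow(aff),
             affected_knee_rom = nrow(aff),
             affected_knee_peak_flex_moment = nrow(aff),
             affected_knee_peak_ext_moment = nrow(aff),
             unaffected_knee_rom = nrow(una),
             unaffected_knee_peak_early_flex_angle = nrow(una),
             unaffected_knee_peak_early_ext_moment = nrow(una),
             cross_leg_rms_diff_knee_angle = nrow(pairs),
             cross_leg_rms_diff_knee_moment = nrow(pairs),
             cross_leg_diff_peak_knee_ext_moment = nrow(pairs),
             affected_ankle_peak_df_angle = nrow(aff),
             affected_ankle_rom = nrow(aff),
             affected_ankle_peak_pf_moment = nrow(aff),
             affected_ankle_peak_power = nrow(aff),
             unaffected_ankle_rom = nrow(una),
             unaffected_ankle_peak_pf_moment = nrow(una),
             cross_leg_rms_diff_ankle_angle = nrow(pairs),
             cross_leg_rms_diff_ankle_moment = nrow(pairs),
             cross_leg_diff_peak_ankle_pf_moment = nrow(pairs),
             cross_leg_diff_peak_ankle_power = nrow(pairs),
             affected_step_prop_stride_duration = nrow(pairs),
             affected_step_prop_stride_distance = nrow(pairs))

  reg <- descriptor_registry()
  data.frame(subject_id = recording$meta$subject_id %||% NA_character_,
             speed_rel = recording$meta$speed_rel %||% NA_real_,
             stiffness_rel = recording$meta$stiffness_rel %||% NA_real_,
             descriptor_name = reg,
             value = unname(vals[reg]),
             n_strides_used = unname(n_map[reg]),
             row.names = NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Full gait processing for one recording
#'
#' Standard per-trial chain: zero-phase low-pass filtering of all channels,
#' gait-cycle and stance detection from vertical GRF, and descriptor
#' extraction.
#'
#' @param recording A raw `gait_recording`.
#' @param cutoff,order Filter settings (Hz / poles per pass).
#' @param threshold_frac_bw,min_stance_s Stance detection settings.
#' @param extent,sign Descriptor settings (see [compute_descriptors()]).
#' @return The descriptor table for this recording.
#' @export
process_gait_recording <- function(recording, cutoff = 15, order = 4,
                                   threshold_frac_bw = 0.05, min_stance_s = 0.2,
                                   extent = "stance", sign = 1) {
  filt <- filter_recording(recording, cutoff = cutoff, order = order)
  filt$channels$vgrf_aff <- pmax(filt$channels$vgrf_aff, 0)
  filt$channels$vgrf_una <- pmax(filt$channels$vgrf_una, 0)
  strides <- detect_gait_cycles(filt, threshold_frac_bw, min_stance_s)
  compute_descriptors(filt, strides, extent = extent, sign = sign)
}
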