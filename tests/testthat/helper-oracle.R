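# Independent brute-force re-implementation of the 25 descriptors, written
# as plain per-stride loops with no code shared with the package internals
# beyond base R. Used to cross-check compute_descriptors() on arbitrary
# recordings.

oracle_interp <- function(x, a, b, n = 101L) {
  xs <- seq(a, b, length.out = n)
  out <- numeric(n)
  for (i in seq_len(n)) {
    lo <- floor(xs[i]); hi <- ceiling(xs[i])
    w <- xs[i] - lo
    out[i] <- if (lo == hi) x[lo] else (1 - w) * x[lo] + w * x[hi]
  }
  out
}

oracle_power <- function(mom, ang, fs) {
  n <- length(ang)
  rad <- ang * pi / 180
  vel <- numeric(n)
  for (i in 2:(n - 1)) vel[i] <- (rad[i + 1] - rad[i - 1]) * fs / 2
  vel[1] <- (rad[2] - rad[1]) * fs
  vel[n] <- (rad[n] - rad[n - 1]) * fs
  mom * vel
}

oracle_descriptors <- function(rec, strides, extent = "stance", sgn = 1) {
  ch <- rec$channels
  ch$ank_pow_aff <- oracle_power(ch$ank_mom_aff, ch$ank_ang_aff, rec$sample_rate)
  ch$ank_pow_una <- oracle_power(ch$ank_mom_una, ch$ank_ang_una, rec$sample_rate)

  aff <- strides[strides$side == "affected" & !strides$excluded, ]
  una <- strides[strides$side == "unaffected" & !strides$excluded, ]

  # pairing: unaffected heel-strike inside the affected cycle
  pa <- list()
  for (i in seq_len(nrow(aff))) {
    for (j in seq_len(nrow(una))) {
      if (una$start[j] >= aff$start[i] && una$start[j] < aff$end[i]) {
        pa[[length(pa) + 1]] <- c(i, j)
        break
      }
    }
  }

  win <- function(s, early = FALSE) {
    a <- s$start
    b <- if (extent == "stance") s$start + s$stance_len - 1 else s$end
    if (early) b <- a + floor((b - a) / 2)
    c(a, b)
  }
  scal <- function(df, fun) {
    v <- numeric(nrow(df))
    for (i in seq_len(nrow(df))) v[i] <- fun(df[i, ])
    mean(v)
  }
  seg_vals <- function(x, s, early = FALSE) {
    w <- win(s, early); x[w[1]:w[2]]
  }
  pair_vals <- function(fun) {
    v <- numeric(length(pa))
    for (k in seq_along(pa)) v[k] <- fun(aff[pa[[k]][1], ], una[pa[[k]][2], ])
    v
  }
  rms_d <- function(chan) {
    mean(pair_vals(function(sa, su) {
      va <- oracle_interp(ch[[paste0(chan, "_aff")]], sa$start,
                          sa$start + sa$stance_len - 1)
      vu <- oracle_interp(ch[[paste0(chan, "_una")]], su$start,
                          su$start + su$stance_len - 1)
      sqrt(mean((va - vu)^2))
    }))
  }

  span <- c(min(aff$start, una$start), max(aff$end, una$end))
  res <- c(
    cross_leg_diff_max_hip_height = mean(pair_vals(function(sa, su)
      max(seg_vals(ch$hip_ht_aff, sa)) - max(seg_vals(ch$hip_ht_una, su)))),
    cross_leg_rms_diff_hip_angle = rms_d("hip_ang"),
    cross_leg_rms_diff_hip_moment = rms_d("hip_mom"),
    pelvic_tilt_variance = var(ch$pelvic_tilt[span[1]:span[2]]),
    affected_knee_rom = scal(aff, function(s) {
      v <- seg_vals(ch$knee_ang_aff, s); max(v) - min(v)
    }),
    affected_knee_peak_flex_moment = scal(aff, function(s)
      abs(min(sgn * seg_vals(ch$knee_mom_aff, s)))),
    affected_knee_peak_ext_moment = scal(aff, function(s)
      max(sgn * seg_vals(ch$knee_mom_aff, s))),
    unaffected_knee_rom = scal(una, function(s) {
      v <- seg_vals(ch$knee_ang_una, s); max(v) - min(v)
    }),
    unaffected_knee_peak_early_flex_angle = scal(una, function(s)
      abs(min(sgn * seg_vals(ch$knee_ang_una, s, early = TRUE)))),
    unaffected_knee_peak_early_ext_moment = scal(una, function(s)
      max(sgn * seg_vals(ch$knee_mom_una, s, early = TRUE))),
    cross_leg_rms_diff_knee_angle = rms_d("knee_ang"),
    cross_leg_rms_diff_knee_moment = rms_d("knee_mom"),
    cross_leg_diff_peak_knee_ext_moment = mean(pair_vals(function(sa, su)
      max(sgn * seg_vals(ch$knee_mom_aff, sa)) -
        max(sgn * seg_vals(ch$knee_mom_una, su)))),
    affected_ankle_peak_df_angle = scal(aff, function(s)
      max(sgn * seg_vals(ch$ank_ang_aff, s))),
    affected_ankle_rom = scal(aff, function(s) {
      v <- seg_vals(ch$ank_ang_aff, s); max(v) - min(v)
    }),
    affected_ankle_peak_pf_moment = scal(aff, function(s)
      abs(min(sgn * seg_vals(ch$ank_mom_aff, s)))),
    affected_ankle_peak_power = scal(aff, function(s)
      max(seg_vals(ch$ank_pow_aff, s))),
    unaffected_ankle_rom = scal(una, function(s) {
      v <- seg_vals(ch$ank_ang_una, s); max(v) - min(v)
    }),
    unaffected_ankle_peak_pf_moment = scal(una, function(s)
      abs(min(sgn * seg_vals(ch$ank_mom_una, s)))),
    cross_leg_rms_diff_ankle_angle = rms_d("ank_ang"),
    cross_leg_rms_diff_ankle_moment = rms_d("ank_mom"),
    cross_leg_diff_peak_ankle_pf_moment = mean(pair_vals(function(sa, su)
      abs(min(sgn * seg_vals(ch$ank_mom_aff, sa))) -
        abs(min(sgn * seg_vals(ch$ank_mom_una, su))))),
    cross_leg_diff_peak_ankle_power = mean(pair_vals(function(sa, su)
      max(seg_vals(ch$ank_pow_aff, sa)) - max(seg_vals(ch$ank_pow_una, su)))),
    affected_step_prop_stride_duration = mean(pair_vals(function(sa, su)
      (su$start - sa$start) / (sa$end - sa$start))),
    affected_step_prop_stride_distance = mean(pair_vals(function(sa, su) {
      sA <- ch$foot_ap_aff[sa$start] - ch$foot_ap_una[sa$start]
      sU <- ch$foot_ap_una[su$start] - ch$foot_ap_aff[su$start]
      sA / (sA + sU)
    })))
  res
}
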