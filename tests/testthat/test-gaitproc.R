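test_that("zero-phase filter passes DC and low bands, halves the cutoff", {
  fs <- 1000
  t <- seq(0, 5, by = 1 / fs)
  expect_equal(lowpass_filter(rep(3.7, 1000), fs), rep(3.7, 1000),
               tolerance = 1e-9)
  mid <- 1500:3500
  # 5 Hz: amplitude preserved within 1%, no phase lag
  x5 <- sin(2 * pi * 5 * t)
  y5 <- lowpass_filter(x5, fs)
  expect_lt(abs(max(y5[mid]) - 1), 0.01)
  cc <- ccf(y5[mid], x5[mid], lag.max = 5, plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], 0)
  # 15 Hz (cutoff): two passes of -3 dB gives amplitude 0.5 within 5%
  x15 <- sin(2 * pi * 15 * t)
  y15 <- lowpass_filter(x15, fs)
  expect_equal(max(abs(y15[mid])), 0.5, tolerance = 0.05)
  # idempotence on a band-limited signal
  x2 <- sin(2 * pi * 2 * t)
  once <- lowpass_filter(x2, fs)
  twice <- lowpass_filter(once, fs)
  expect_lt(abs(max(twice[mid]) / max(once[mid]) - 1), 0.01)
  expect_error(lowpass_filter(x2, 25), "Nyquist")
})

test_that("cycle detection counts strides and honors crossover flags", {
  cfg <- quiet_config()
  sub <- one_subject(config = cfg)
  g <- gen_gait_trial(sub, 0, n_strides = 10, seed = 1, config = cfg)
  st <- detect_gait_cycles(g$recording)
  # 12 stance onsets per side (10 strides + lead-in/out), 11 complete cycles
  expect_equal(sum(st$side == "affected"), 11)
  expect_equal(sum(st$side == "unaffected"), 11)
  expect_equal(sum(st$excluded), 0)

  # flag the 4th affected stance: that stride must be excluded as crossover
  rec <- g$recording
  aff <- st[st$side == "affected", ]
  rec$crossover[aff$start[4]:(aff$start[4] + aff$stance_len[4] - 1)] <- 1L
  st2 <- detect_gait_cycles(rec)
  aff2 <- st2[st2$side == "affected", ]
  expect_true(aff2$excluded[4])
  expect_equal(aff2$reason[4], "crossover")
  expect_equal(sum(aff2$excluded), 1)

  rec$channels$vgrf_una <- NULL
  expect_error(detect_gait_cycles(rec), "missing")
})

test_that("stance onset is robust to the body-weight threshold choice", {
  cfg <- quiet_config()
  sub <- one_subject(config = cfg)
  g <- gen_gait_trial(sub, 0, n_strides = 8, seed = 2, config = cfg)
  onsets <- lapply(c(0.02, 0.05, 0.10), function(th) {
    st <- detect_gait_cycles(g$recording, threshold_frac_bw = th)
    st$start[st$side == "affected"]
  })
  expect_true(all(abs(onsets[[1]] - onsets[[3]]) <= 2))
  expect_true(all(abs(onsets[[1]] - onsets[[2]]) <= 2))
})

test_that("time normalization interpolates onto 101 points correctly", {
  cfg <- quiet_config()
  sub <- one_subject(config = cfg)
  g <- gen_gait_trial(sub, 0, n_strides = 6, seed = 3, config = cfg)
  rec <- g$recording
  st <- detect_gait_cycles(rec)
  # constant channel stays constant; ramp hits its endpoint samples
  rec$channels$const_ch <- rep(2.5, length(rec$time_s))
  rec$channels$ramp_ch <- seq_along(rec$time_s) * 0.1
  ns <- time_normalize(rec, st)
  expect_true(all(vapply(ns, function(s) length(s$cycle$const_ch), integer(1)) == 101L))
  expect_equal(ns[[1]]$cycle$const_ch, rep(2.5, 101))
  s1 <- st[!st$excluded, ][1, ]
  expect_equal(ns[[1]]$cycle$ramp_ch[c(1, 101)],
               c(s1$start, s1$end) * 0.1, tolerance = 1e-10)
  expect_true(all(vapply(ns, function(s) s$stance_end > 0 && s$stance_end < 100,
                         logical(1))))
  # dense sinusoid: interpolation error well under 1e-3 of amplitude
  rec$channels$sin_ch <- sin(2 * pi * rec$time_s)
  ns2 <- time_normalize(rec, st)
  s <- st[!st$excluded, ][1, ]
  tt <- seq(rec$time_s[s$start], rec$time_s[s$end], length.out = 101)
  expect_lt(max(abs(ns2[[1]]$cycle$sin_ch - sin(2 * pi * tt))), 1e-3)
})

test_that("joint power equals moment times angular velocity", {
  fs <- 100
  n <- 200
  expect_equal(joint_power(rnorm(n), rep(12, n), fs), rep(0, n))
  # linear angle ramp: omega constant, exact for central differences
  ang <- (1:n) * 0.5           # deg per sample -> 50 deg/s
  p <- joint_power(rep(2, n), ang, fs)
  expect_equal(p[2:(n - 1)], rep(2 * 50 * pi / 180, n - 2), tolerance = 1e-9)
  # sinusoid: second-order convergence in the sampling interval
  err_at <- function(fs) {
    t <- seq(0, 1, by = 1 / fs)
    ang <- 10 * sin(2 * pi * 2 * t)
    mom <- 5 + 3 * cos(2 * pi * 2 * t)
    truth <- mom * (10 * pi / 180) * 2 * pi * 2 * cos(2 * pi * 2 * t)
    p <- joint_power(mom, ang, fs)
    inner <- 5:(length(t) - 4)
    max(abs(p[inner] - truth[inner]))
  }
  expect_gt(err_at(100) / err_at(200), 3)   # ~4x for O(dt^2)
  expect_error(joint_power(1:5, 1:4, fs), "differ")
})

test_that("descriptors match closed forms on constructed trajectories", {
  cfg <- quiet_config()
  sub <- one_subject(config = cfg)
  g <- gen_gait_trial(sub, 0, n_strides = 8, seed = 4, config = cfg)
  rec <- g$recording
  st <- detect_gait_cycles(rec)

  # identical sides: all cross-leg descriptors vanish
  rec0 <- rec
  for (ch in c("hip_ang", "hip_mom", "knee_ang", "knee_mom", "ank_ang",
               "ank_mom", "hip_ht", "foot_ap", "vgrf")) {
    rec0$channels[[paste0(ch, "_una")]] <- rec0$channels[[paste0(ch, "_aff")]]
  }
  st0 <- detect_gait_cycles(rec0)
  d0 <- compute_descriptors(rec0, st0)
  cross_rms <- grep("cross_leg_rms", d0$descriptor_name)
  expect_true(all(abs(d0$value[cross_rms]) < 1e-9))
  cross_diff <- grep("cross_leg_diff", d0$descriptor_name)
  expect_true(all(abs(d0$value[cross_diff]) < 1e-9))

  # constant 3 deg offset during the whole trial -> RMS difference exactly 3
  rec3 <- rec0
  rec3$channels$ank_ang_aff <- rec0$channels$ank_ang_aff + 3
  d3 <- compute_descriptors(rec3, detect_gait_cycles(rec3))
  expect_equal(d3$value[d3$descriptor_name == "cross_leg_rms_diff_ankle_angle"],
               3, tolerance = 1e-9)

  # ankle angle = 8 sin(pi s) over stance, 0 in swing: ROM and peak DF are 8
  rec8 <- rec
  aff <- st[st$side == "affected" & !st$excluded, ]
  x <- numeric(length(rec8$time_s))
  for (i in seq_len(nrow(aff))) {
    len <- aff$stance_len[i]
    if (len %% 2L == 0L) len <- len - 1L   # keep the s = 0.5 peak on a sample
    idx <- aff$start[i]:(aff$start[i] + len - 1)
    s <- seq(0, 1, length.out = len)
    x[idx] <- 8 * sin(pi * s)
  }
  rec8$channels$ank_ang_aff <- x
  d8 <- compute_descriptors(rec8, st)
  expect_equal(d8$value[d8$descriptor_name == "affected_ankle_rom"], 8,
               tolerance = 1e-6)
  expect_equal(d8$value[d8$descriptor_name == "affected_ankle_peak_df_angle"], 8,
               tolerance = 1e-6)
})

test_that("descriptors match an independent brute-force implementation", {
  cfg <- synth_config()   # noise on: arbitrary trajectories
  sub <- one_subject(seed = 3, config = cfg)
  g <- gen_gait_trial(sub, 0.3, n_strides = 20, seed = 5, config = cfg)
  st <- detect_gait_cycles(g$recording)
  for (extent in c("stance", "cycle")) {
    d <- compute_descriptors(g$recording, st, extent = extent)
    o <- oracle_descriptors(g$recording, st, extent = extent)
    expect_equal(stats::setNames(d$value, d$descriptor_name), o[d$descriptor_name],
                 tolerance = 1e-9)
  }
})

test_that("crossover exclusion never increases strides used", {
  cfg <- synth_config(crossover_rate = 0)
  sub <- one_subject(config = cfg)
  g <- gen_gait_trial(sub, 0, n_strides = 10, seed = 6, config = cfg)
  d_clean <- compute_descriptors(g$recording, detect_gait_cycles(g$recording))
  rec <- g$recording
  st <- detect_gait_cycles(rec)
  aff <- st[st$side == "affected", ]
  rec$crossover[aff$start[3]:aff$end[3]] <- 1L
  d_flag <- compute_descriptors(rec, detect_gait_cycles(rec))
  expect_true(all(d_flag$n_strides_used <= d_clean$n_strides_used))
  expect_lt(sum(d_flag$n_strides_used), sum(d_clean$n_strides_used))
})

test_that("flipping the sign convention swaps flexion and extension peaks", {
  cfg <- synth_config()
  sub <- one_subject(config = cfg)
  g <- gen_gait_trial(sub, 0, n_strides = 8, seed = 7, config = cfg)
  st <- detect_gait_cycles(g$recording)
  d_pos <- compute_descriptors(g$recording, st, sign = 1)
  d_neg <- compute_descriptors(g$recording, st, sign = -1)
  v <- function(d, nm) d$value[d$descriptor_name == nm]
  expect_equal(v(d_neg, "affected_knee_peak_flex_moment"),
               v(d_pos, "affected_knee_peak_ext_moment"))
  expect_equal(v(d_neg, "affected_knee_peak_ext_moment"),
               v(d_pos, "affected_knee_peak_flex_moment"))
  # unsigned descriptors are untouched
  expect_equal(v(d_neg, "affected_ankle_rom"), v(d_pos, "affected_ankle_rom"))
  expect_equal(v(d_neg, "cross_leg_rms_diff_ankle_angle"),
               v(d_pos, "cross_leg_rms_diff_ankle_angle"))
  # and the whole pipeline is deterministic
  expect_identical(d_pos, compute_descriptors(g$recording, st, sign = 1))
})
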