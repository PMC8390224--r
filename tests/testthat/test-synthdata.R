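test_that("subject generation respects ranges and determinism", {
  subs <- gen_subjects(7, seed = 1)
  masses <- vapply(subs, `[[`, numeric(1), "body_mass")
  expect_true(all(masses >= 58.6 & masses <= 99.2))
  prefs <- unlist(lapply(subs, `[[`, "preferred_stiffness_by_speed"))
  expect_true(all(prefs >= 3.4 & prefs <= 23.3 & prefs > 0))
  expect_identical(gen_subjects(1, seed = 1), gen_subjects(1, seed = 1))
  expect_false(identical(gen_subjects(1, seed = 1), gen_subjects(1, seed = 2)))
  expect_error(gen_subjects(0), "positive")
  expect_error(gen_subjects(3, config = synth_config(mass_range = c(90, 80))),
               "degenerate")
})

test_that("u-shaped preference puts the minimum at self-selected speed", {
  subs <- gen_subjects(100, seed = 2,
                       config = synth_config(u_shaped_preference = TRUE))
  at_min <- vapply(subs, function(s) {
    p <- s$preferred_stiffness_by_speed
    p[["0"]] < p[["-0.3"]] && p[["0"]] < p[["0.3"]]
  }, logical(1))
  expect_gte(sum(at_min), 95)
})

test_that("breath blocks follow the block design and the forward model", {
  cfg <- quiet_config()
  sub <- one_subject(config = cfg)
  sch <- block_schedule(first = TRUE)
  expect_equal(sch$end_s[5] - sch$start_s[1], 18 * 60)
  bb <- gen_breath_block(sub, sch, speed_rel = 0, seed = 3, config = cfg)
  # noiseless output equals the forward model pointwise
  expect_equal(bb$series$rates,
               predict_response(bb$truth$x_gross, sch, cfg$tau,
                                bb$truth$y0, bb$series$times),
               tolerance = 1e-12)
  expect_true(all(diff(bb$series$times) > 0))
  # determinism
  bb2 <- gen_breath_block(sub, sch, speed_rel = 0, seed = 3, config = cfg)
  expect_identical(bb$series$rates, bb2$series$rates)
  expect_error(gen_breath_block(sub, sch, noise_sd = -1, config = cfg),
               "non-negative")
})

test_that("equilibrium start makes every noiseless breath a fixed point", {
  cfg <- quiet_config(stiffness_met_effect = 0)
  sub <- one_subject(config = cfg)
  sch <- trial_schedule(rep(180, 5), stiffness_rel = rep(0, 5))
  bb <- gen_breath_block(sub, sch, speed_rel = 0, seed = 4, config = cfg)
  # all trials share one steady state; start the model there and predict
  x <- bb$truth$x_gross
  expect_equal(diff(range(x)), 0)
  y_eq <- predict_response(x, sch, cfg$tau, x[1], bb$series$times)
  expect_equal(y_eq, rep(x[1], length(y_eq)), tolerance = 1e-10)
})

test_that("a step between trials rises with the 42 s time constant", {
  cfg <- quiet_config()
  sub <- one_subject(seed = 6, config = cfg)
  sch <- trial_schedule(c(240, 240), stiffness_rel = c(0, 15),
                        )
  # plant distinct steady states via a stiffness effect on metabolic rate
  cfg2 <- quiet_config(stiffness_met_effect = 40)
  bb <- gen_breath_block(sub, sch, speed_rel = 0, seed = 7, config = cfg2)
  x <- bb$truth$x_gross
  expect_gt(abs(x[2] - x[1]), 10)
  # closed form after the jump, assuming trial 1 (5.7 tau long) equilibrated
  t_star_idx <- which.min(abs(bb$series$times - (240 + 42)))
  t_star <- bb$series$times[t_star_idx]
  y_closed <- x[2] + (x[1] - x[2]) * exp(-(t_star - 240) / 42)
  expect_equal(bb$series$rates[t_star_idx], y_closed,
               tolerance = 0.02 * abs(x[2] - x[1]) / abs(y_closed))
  # and the 63.2% landmark is approximately attained at one time constant
  expect_lt(abs(bb$series$rates[t_star_idx] - (x[1] + 0.632 * (x[2] - x[1]))),
            0.12 * abs(x[2] - x[1]))
})

test_that("noise-free gait trials plant an exact symmetry vertex", {
  cfg <- quiet_config(planted_vertex = 0)
  sub <- one_subject(config = cfg)
  pref <- sub$preferred_stiffness_by_speed[["0"]]
  rms_at <- function(k) {
    g <- gen_gait_trial(sub, 0, stiffness = k, n_strides = 8, seed = 5,
                        config = cfg)
    st <- detect_gait_cycles(g$recording)
    d <- compute_descriptors(g$recording, st)
    d$value[d$descriptor_name == "cross_leg_rms_diff_ankle_angle"]
  }
  expect_lt(rms_at(pref), 1e-9)
  expect_equal(rms_at(0.85 * pref), rms_at(1.15 * pref), tolerance = 1e-9)
})

test_that("generated gait respects stance duty cycle and signal invariants", {
  cfg <- synth_config()
  sub <- one_subject(config = cfg)
  g <- gen_gait_trial(sub, 0, n_strides = 10, seed = 8, config = cfg)
  expect_true(all(g$recording$channels$vgrf_aff >= 0))
  expect_true(all(g$recording$channels$vgrf_una >= 0))
  st <- detect_gait_cycles(g$recording)
  frac <- st$stance_len / (st$end - st$start)
  expect_true(all(frac >= 0.55 & frac <= 0.70))
  expect_error(gen_gait_trial(sub, 0, n_strides = 2, config = cfg),
               "at least 3")
  expect_error(gen_gait_trial(sub, 0, stiffness = 30, config = cfg),
               "device range")
})

test_that("full study emits the crossover design with exact counts", {
  dir1 <- file.path(tempdir(), "study_counts")
  unlink(dir1, recursive = TRUE)
  cfg <- synth_config(n_strides = 6)
  gen_study(7, seed = 1, config = cfg, out_dir = dir1)
  pref <- read.csv(file.path(dir1, "preference_log.csv"))
  expect_equal(nrow(pref), 7 * 3 * 3)
  expect_equal(length(list.files(file.path(dir1, "gait"))), 7 * 3 * 5)
  ten <- read.csv(file.path(dir1, "tenmwt.csv"))
  expect_equal(sum(ten$device == "vspa"), 7 * 5 * 3)
  sched <- read.csv(file.path(dir1, "trial_schedule.csv"))
  expect_equal(nrow(sched), 7 * 3 * 5)
  # every subject has one 4/4/4/3/3 block and two 4/3/3/3/3 blocks
  per_block <- aggregate(duration_s ~ subject_id + speed_rel, sched, sum)
  expect_true(all(sort(unique(per_block$duration_s)) == c(960, 1080)))
  expect_equal(sum(per_block$duration_s == 1080), 7)
  pl <- read.csv(file.path(dir1, "preference_log.csv"))
  expect_true(all(pl$preferred_stiffness_nm_per_deg >= 3.4 &
                    pl$preferred_stiffness_nm_per_deg <= 23.3))
  unlink(dir1, recursive = TRUE)
})

test_that("study generation is byte-deterministic and fail-fast", {
  d1 <- file.path(tempdir(), "det1"); d2 <- file.path(tempdir(), "det2")
  unlink(c(d1, d2), recursive = TRUE)
  cfg <- synth_config(n_strides = 5)
  gen_study(2, seed = 9, config = cfg, out_dir = d1)
  gen_study(2, seed = 9, config = cfg, out_dir = d2)
  f1 <- list.files(d1, recursive = TRUE)
  expect_identical(f1, list.files(d2, recursive = TRUE))
  h1 <- unname(tools::md5sum(file.path(d1, f1)))
  h2 <- unname(tools::md5sum(file.path(d2, f1)))
  expect_identical(h1, h2)
  d3 <- file.path(tempdir(), "det3")
  expect_error(gen_study(0, out_dir = d3), "positive")
  expect_false(dir.exists(d3))
  unlink(c(d1, d2), recursive = TRUE)
})
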