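#' Generate the full synthetic study
#'
#' Emits every input of the analysis pipeline for a synthetic cohort, as CSV
#' files in `out_dir`: the crossover design with three preference
#' repetitions at each of three treadmill speeds, one five-trial metabolic
#' block per subject-speed (trial durations 4/4/4/3/3 minutes in the first
#' visited block, 4/3/3/3/3 thereafter), one gait trial per
#' subject-speed-stiffness cell on the +0/±15/±30 % grid, and three
#' 10-meter-walk-test repetitions per stiffness level plus daily-use
#' baselines. A `ground_truth.json` sidecar records the quantities the
#' pipeline is supposed to recover.
#'
#' Output files: `subjects.csv`, `preference_log.csv`, `breaths.csv`,
#' `trial_schedule.csv`, `gait/<subject>_spd<s>_stf<d>.csv`, `tenmwt.csv`,
#' `ground_truth.json`.
#'
#' @param n_subjects Number of subjects (>= 1).
#' @param seed Integer master seed; all substreams derive from it.
#' @param config A [synth_config()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with `dir`, `files` (paths), `subjects`,
#'   `truth` and `config`.
#' @export
gen_study <- function(n_subjects = 7, seed = 1, config = synth_config(),
                      out_dir = tempfile("prefgait_study_")) {
  if (!is.numeric(n_subjects) || n_subjects < 1)
    stop("`n_subjects` must be a positive count")
  validate_synth_config(config)
  grids <- study_grids()
  subjects <- gen_subjects(n_subjects, seed = seed, config = config)

  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(out_dir, "gait"), showWarnings = FALSE)

  # preference logs: 3 repetitions x 3 speeds per subject
  pref_rows <- list()
  set.seed(derive_seed(seed, "preflog"))
  for (sub in subjects) {
    for (v in grids$speed_levels) {
      truep <- sub$preferred_stiffness_by_speed[[as.character(v)]]
      sel <- truep + stats::rnorm(3, 0, config$pref_noise_sd)
      sel <- pmin(pmax(sel, config$stiffness_bounds[1]), config$stiffness_bounds[2])
      pref_rows[[length(pref_rows) + 1L]] <- data.frame(
        subject_id = sub$subject_id, speed_rel = v, repetition = 1:3,
        preferred_stiffness_nm_per_deg = sel)
    }
  }
  pref_log <- do.call(rbind, pref_rows)

  # preference anchor per subject-speed: mean of the three dial selections
  anchor <- stats::aggregate(preferred_stiffness_nm_per_deg ~ subject_id + speed_rel,
                             data = pref_log, FUN = mean)
  get_anchor <- function(id, v)
    anchor$preferred_stiffness_nm_per_deg[anchor$subject_id == id &
                                            anchor$speed_rel == v]

  # metabolic blocks and schedules
  breath_rows <- list(); sched_rows <- list(); met_truth <- list()
  set.seed(derive_seed(seed, "design"))
  speed_order <- lapply(subjects, function(s) sample(grids$speed_levels))
  stiff_orders <- lapply(seq_along(subjects), function(i)
    lapply(1:3, function(j) sample(grids$stiffness_levels)))
  unit <- 0L
  for (i in seq_along(subjects)) {
    sub <- subjects[[i]]
    for (j in seq_along(speed_order[[i]])) {
      v <- speed_order[[i]][j]
      devs <- stiff_orders[[i]][[j]]
      sched <- trial_schedule(block_durations(first_block = (j == 1L)),
                              stiffness_rel = devs)
      unit <- unit + 1L
      bb <- gen_breath_block(sub, sched, speed_rel = v,
                             seed = derive_seed(seed, "block", unit),
                             config = config)
      idx <- assign_trial(sched, bb$series$times)
      breath_rows[[unit]] <- data.frame(
        subject_id = sub$subject_id, speed_rel = v,
        time_s = bb$series$times, power_w = bb$series$rates,
        trial_index = idx)
      sched_rows[[unit]] <- data.frame(
        subject_id = sub$subject_id, speed_rel = v, trial_index = sched$trial,
        stiffness_rel = sched$stiffness_rel, start_s = sched$start_s,
        duration_s = sched$end_s - sched$start_s)
      met_truth[[unit]] <- list(subject_id = sub$subject_id, speed_rel = v,
                                stiffness_rel = devs, x_net = bb$truth$x_net,
                                x_gross = bb$truth$x_gross, y0 = bb$truth$y0)
    }
  }

  # gait trials on the anchored stiffness grid
  gait_files <- character(0)
  unit <- 0L
  for (sub in subjects) {
    for (v in grids$speed_levels) {
      anc <- get_anchor(sub$subject_id, v)
      for (dv in grids$stiffness_levels) {
        unit <- unit + 1L
        k <- min(max(anc * (1 + dv / 100), config$stiffness_bounds[1]),
                 config$stiffness_bounds[2])
        tr <- gen_gait_trial(sub, speed_rel = v, stiffness = k,
                             n_strides = config$n_strides,
                             seed = derive_seed(seed, "gaittrial", unit),
                             config = config)
        rec <- tr$recording
        rec$meta$stiffness_rel <- dv   # design label, preference-anchored
        df <- data.frame(time_s = rec$time_s, rec$channels,
                         crossover = rec$crossover)
        fn <- file.path(out_dir, "gait",
                        sprintf("%s_spd%d_stf%d.csv", sub$subject_id,
                                round(100 * v), dv))
        utils::write.csv(df, fn, row.names = FALSE)
        gait_files <- c(gait_files, fn)
      }
    }
  }

  # 10MWT: daily-use baselines plus 3 repetitions per stiffness level
  set.seed(derive_seed(seed, "tenmwt"))
  ten_rows <- list()
  for (sub in subjects) {
    base_speed <- sub$self_selected_speed * 1.05
    sp <- base_speed * (1 + stats::rnorm(3, 0, config$tenmwt_noise_sd))
    ten_rows[[length(ten_rows) + 1L]] <- data.frame(
      subject_id = sub$subject_id, stiffness_rel = NA_real_, repetition = 1:3,
      distance_m = config$tenmwt_distance,
      time_s = config$tenmwt_distance / sp, device = "daily_use")
    for (dv in grids$stiffness_levels) {
      mult <- if (dv < 0) 1 - config$tenmwt_penalty else 1
      sp <- base_speed * mult * (1 + stats::rnorm(3, 0, config$tenmwt_noise_sd))
      ten_rows[[length(ten_rows) + 1L]] <- data.frame(
        subject_id = sub$subject_id, stiffness_rel = dv, repetition = 1:3,
        distance_m = config$tenmwt_distance,
        time_s = config$tenmwt_distance / sp, device = "vspa")
    }
  }
  tenmwt <- do.call(rbind, ten_rows)

  subj_df <- data.frame(
    subject_id = vapply(subjects, `[[`, character(1), "subject_id"),
    body_mass_kg = vapply(subjects, `[[`, numeric(1), "body_mass"),
    self_selected_speed_mps = vapply(subjects, `[[`, numeric(1),
                                     "self_selected_speed"),
    resting_rate_w = vapply(subjects, `[[`, numeric(1), "resting_rate"),
    met_baseline_w = vapply(subjects, function(s)
      s$body_mass * (config$wkg_coefs[1] + s$random_intercepts$metabolic_wkg),
      numeric(1)))

  files <- c(subjects = file.path(out_dir, "subjects.csv"),
             preference_log = file.path(out_dir, "preference_log.csv"),
             breaths = file.path(out_dir, "breaths.csv"),
             trial_schedule = file.path(out_dir, "trial_schedule.csv"),
             tenmwt = file.path(out_dir, "tenmwt.csv"),
             ground_truth = file.path(out_dir, "ground_truth.json"))
  utils::write.csv(subj_df, files[["subjects"]], row.names = FALSE)
  utils::write.csv(pref_log, files[["preference_log"]], row.names = FALSE)
  utils::write.csv(do.call(rbind, breath_rows), files[["breaths"]], row.names = FALSE)
  utils::write.csv(do.call(rbind, sched_rows), files[["trial_schedule"]], row.names = FALSE)
  utils::write.csv(tenmwt, files[["tenmwt"]], row.names = FALSE)

  truth <- list(
    tau = config$tau,
    planted_vertex = config$planted_vertex,
    tenmwt_penalty = config$tenmwt_penalty,
    preferred_stiffness = lapply(subjects, function(s)
      as.list(s$preferred_stiffness_by_speed)),
    metabolic = met_truth,
    descriptor_trends = descriptor_truth(config))
  names(truth$preferred_stiffness) <- subj_df$subject_id
  jsonlite::write_json(truth, files[["ground_truth"]], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, dataframe = "rows")

  invisible(list(dir = out_dir, files = c(files, gait = list(gait_files)),
                 subjects = subjects, truth = truth, config = config))
}
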