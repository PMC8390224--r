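#' Generate synthetic study subjects
#'
#' Draws a cohort of subjects with unilateral below-knee amputation for the
#' synthetic study: body mass uniform over the configured range, a
#' self-selected treadmill speed, a quiet-standing resting rate, a preferred
#' dorsiflexion stiffness profile over relative speed, and per-subject random
#' effects used by the descriptor and metabolic generators. When
#' `u_shaped_preference` is on, the preferred-stiffness profile is quadratic
#' in relative speed with its minimum at the self-selected speed.
#'
#' @param n Number of subjects (>= 1).
#' @param seed Integer seed; draws are deterministic given the seed.
#' @param config A [synth_config()].
#' @return List of `subject_spec` objects, each a list with `subject_id`,
#'   `body_mass` (kg), `self_selected_speed` (m/s),
#'   `preferred_stiffness_by_speed` (named Nm/deg vector over relative
#'   speeds -0.3/0/+0.3), `resting_rate` (W), `random_intercepts` (list of
#'   per-model offsets) and `random_speed_slope`.
#' @examples
#' subs <- gen_subjects(7, seed = 1)
#' range(vapply(subs, `[[`, numeric(1), "body_mass"))
#' @export
gen_subjects <- function(n, seed = 1, config = synth_config()) {
  if (!is.numeric(n) || n < 1) stop("`n` must be a positive count")
  n <- as.integer(n)
  validate_synth_config(config)
  set.seed(derive_seed(seed, "subjects"))
  grids <- study_grids()
  out <- vector("list", n)
  for (i in seq_len(n)) {
    mass <- stats::runif(1, config$mass_range[1], config$mass_range[2])
    spd <- min(max(stats::rnorm(1, config$speed_mean, config$speed_sd),
                   config$speed_range[1]), config$speed_range[2])
    rest <- stats::runif(1, config$resting_range[1], config$resting_range[2])
    base <- stats::runif(1, config$pref_base_range[1], config$pref_base_range[2])
    curv <- if (config$u_shaped_preference) config$pref_curvature else 0
    pref <- base * (1 + curv * grids$speed_levels^2)
    pref <- pmin(pmax(pref, config$stiffness_bounds[1]), config$stiffness_bounds[2])
    names(pref) <- as.character(grids$speed_levels)
    out[[i]] <- structure(list(
      subject_id = sprintf("S%02d", i),
      body_mass = mass,
      self_selected_speed = spd,
      preferred_stiffness_by_speed = pref,
      resting_rate = rest,
      random_intercepts = list(
        descriptor = stats::rnorm(1, 0, config$sd_intercept),
        metabolic_wkg = stats::rnorm(1, 0, config$sd_met_wkg)),
      random_speed_slope = stats::rnorm(1, 0, config$sd_speed_slope)),
      class = "subject_spec")
  }
  out
}

#' @export
print.subject_spec <- function(x, ...) {
  cat(sprintf("<subject %s: %.1f kg, %.2f m/s, preferred %s Nm/deg>\n",
              x$subject_id, x$body_mass, x$self_selected_speed,
              paste(sprintf("%.1f", x$preferred_stiffness_by_speed),
                    collapse = "/")))
  invisible(x)
}

#' Generate long-format descriptor records with a planted trend
#'
#' Simulates subject-condition descriptor averages directly from the
#' mixed-effects family the trend analysis fits: a fixed quadratic in
#' stiffness deviation plus a fixed speed effect, a random intercept and a
#' random speed slope per subject, and i.i.d. Gaussian residual noise. This
#' is the workhorse for vertex-coverage, classification-recovery and type-I
#' error simulations, where the full waveform pipeline would add nothing but
#' runtime.
#'
#' To plant a vertex at deviation `v`, pass `beta_L = -2 * beta_Q * v`.
#'
#' @param n_subjects Number of subjects.
#' @param beta0,beta_L,beta_Q,beta_speed Fixed-effect coefficients:
#'   intercept, linear and quadratic stiffness terms (per % deviation and
#'   per (% deviation)^2), and speed term (per unit relative speed).
#' @param sd_intercept,sd_speed_slope,sd_resid Random-intercept,
#'   random-speed-slope and residual SDs.
#' @param dev_levels,speed_levels Condition grids.
#' @param seed Integer seed.
#' @return Data frame with columns `subject_id`, `speed_rel`,
#'   `stiffness_dev`, `value`.
#' @export
gen_descriptor_records <- function(n_subjects = 7,
                                   beta0 = 1, beta_L = 0, beta_Q = 0,
                                   beta_speed = 0.5,
                                   sd_intercept = 0.3, sd_speed_slope = 0.5,
                                   sd_resid = 1.5,
                                   dev_levels = study_grids()$stiffness_levels,
                                   speed_levels = study_grids()$speed_levels,
                                   seed = 1) {
  if (n_subjects < 2) stop("need at least two subjects")
  set.seed(derive_seed(seed, "descrecords"))
  u <- stats::rnorm(n_subjects, 0, sd_intercept)
  w <- stats::rnorm(n_subjects, 0, sd_speed_slope)
  grid <- expand.grid(stiffness_dev = dev_levels, speed_rel = speed_levels,
                      subject = seq_len(n_subjects))
  mu <- beta0 + beta_L * grid$stiffness_dev + beta_Q * grid$stiffness_dev^2 +
    (beta_speed + w[grid$subject]) * grid$speed_rel + u[grid$subject]
  data.frame(subject_id = sprintf("S%02d", grid$subject),
             speed_rel = grid$speed_rel,
             stiffness_dev = grid$stiffness_dev,
             value = mu + stats::rnorm(nrow(grid), 0, sd_resid))
}
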