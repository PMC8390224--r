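#' Generate a breath-by-breath metabolic block
#'
#' Simulates one consecutive metabolic block: breath times are cumulative
#' sums of truncated-normal inter-breath intervals, and breath values follow
#' the first-order relaxation model ([predict_response()]) driven by the
#' per-trial steady-state rates, plus additive Gaussian noise. With
#' `noise_sd = 0` the output equals the forward model exactly, which is what
#' noiseless round-trip tests rely on.
#'
#' Per-trial steady-state truth is built from the subject's body mass and a
#' metabolic-intensity curve over relative speed, plus the subject's
#' metabolic random effect; the quadratic stiffness effect defaults to zero
#' (stiffness changes of the studied size do not measurably move metabolic
#' rate). Generated rates are gross (resting rate included), so the
#' net-rate subtraction step is exercised downstream.
#'
#' @param subject A `subject_spec` from [gen_subjects()].
#' @param schedule A [trial_schedule()] whose `stiffness_rel` labels are %
#'   deviations from preferred.
#' @param speed_rel Relative treadmill speed of the block (-0.3, 0, +0.3).
#' @param tau Time constant (s); defaults to the configured value.
#' @param noise_sd Additive breath noise SD (W); >= 0.
#' @param breath_interval_mean Mean inter-breath interval (s).
#' @param seed Integer seed.
#' @param config A [synth_config()].
#' @return List with `series` (a [breath_series()], gross W) and `truth`
#'   (list: `x_net`, `x_gross` per trial, `tau`, `y0`, `resting_rate`).
#' @export
gen_breath_block <- function(subject, schedule, speed_rel = 0,
                             tau = NULL, noise_sd = NULL,
                             breath_interval_mean = NULL,
                             seed = 1, config = synth_config()) {
  stopifnot(inherits(subject, "subject_spec"), inherits(schedule, "trial_schedule"))
  if (is.null(tau)) tau <- config$tau
  if (is.null(noise_sd)) noise_sd <- config$breath_noise_sd
  if (is.null(breath_interval_mean)) breath_interval_mean <- config$breath_interval_mean
  if (noise_sd < 0) stop("`noise_sd` must be non-negative")
  if (tau <= 0) stop("`tau` must be positive")
  set.seed(derive_seed(seed, "breath"))

  span <- schedule$end_s[nrow(schedule)] - schedule$start_s[1L]
  n_max <- ceiling(span / config$breath_interval_min) + 2L
  iv <- stats::rnorm(n_max, breath_interval_mean, config$breath_interval_sd)
  iv <- pmax(iv, config$breath_interval_min)
  times <- schedule$start_s[1L] + cumsum(iv)
  times <- times[times <= schedule$end_s[nrow(schedule)]]

  dev <- schedule$stiffness_rel
  wkg <- config$wkg_coefs[1] + config$wkg_coefs[2] * speed_rel +
    config$wkg_coefs[3] * speed_rel^2 +
    subject$random_intercepts$metabolic_wkg +
    config$stiffness_met_effect * (dev / 100)^2
  x_net <- subject$body_mass * wkg
  x_gross <- x_net + subject$resting_rate
  y0 <- subject$resting_rate

  y <- predict_response(x_gross, schedule, tau, y0, times)
  if (noise_sd > 0) y <- y + stats::rnorm(length(y), 0, noise_sd)

  list(series = breath_series(times, y,
                              meta = list(subject_id = subject$subject_id,
                                          speed_rel = speed_rel)),
       truth = list(x_net = x_net, x_gross = x_gross, tau = tau, y0 = y0,
                    resting_rate = subject$resting_rate))
}
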