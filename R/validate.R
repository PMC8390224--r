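# Simulation experiments that characterize the estimators under the study
# conditions: metabolic round-trip and oracle agreement, delta-method CI
# coverage for the vertex, and trend-classification operating
# characteristics. These drive the package's own validation reports.

#' Metabolic estimator recovery and oracle-agreement check
#'
#' Runs the standard five-trial block (4/4/4/3/3 minutes, tau = 42 s) in two
#' regimes. Noiseless: breaths generated exactly from the first-order model
#' must be inverted exactly by the linear least-squares estimator. Noisy: at
#' the given breath noise SD, the estimate is compared on every replicate
#' against direct nonlinear least-squares minimization of the squared
#' prediction error (BFGS over the five steady states) — the two routes
#' must agree closely because the prediction is affine in the unknowns.
#'
#' @param n_seeds Number of noisy replicates.
#' @param noise_sd Breath noise SD (W).
#' @param seed Master seed.
#' @param x_true Per-trial steady-state truth (W).
#' @return List with `noiseless_max_err` (W), `noiseless_residual_rms` (W),
#'   `oracle_max_gap` (W, worst componentwise disagreement across
#'   replicates), `mean_abs_err` (W, vs truth) and `n_breaths`.
#' @export
metabolic_recovery_check <- function(n_seeds = 100, noise_sd = 20, seed = 1,
                                     x_true = c(320, 410, 360, 390, 340)) {
  sch <- trial_schedule(c(4, 4, 4, 3, 3) * 60, stiffness_rel = c(-30, 15, 0, 30, -15))
  gen_times <- function(s) {
    set.seed(s)
    tms <- cumsum(pmax(stats::rnorm(400, 3, 0.8), 1))
    tms[tms <= 1080]
  }
  tms0 <- gen_times(derive_seed(seed, "metval", 0L))
  y0 <- predict_response(x_true, sch, 42, 300, tms0)
  est0 <- estimate_steady_states(breath_series(tms0, y0), sch, tau = 42)
  noiseless_max_err <- max(abs(est0$x_hat - x_true))

  nls_oracle <- function(tms, y) {
    sse <- function(x) sum((predict_response(x, sch, 42, y[1], tms[-1],
                                             t0 = tms[1]) - y[-1])^2)
    stats::optim(rep(mean(y), 5), sse, method = "BFGS",
                 control = list(maxit = 500, reltol = 1e-12))$par
  }
  gaps <- numeric(n_seeds); errs <- numeric(n_seeds)
  for (i in seq_len(n_seeds)) {
    s <- derive_seed(seed, "metval", i)
    tms <- gen_times(s)
    set.seed(s + 1L)
    y <- predict_response(x_true, sch, 42, 300, tms) +
      stats::rnorm(length(tms), 0, noise_sd)
    est <- suppressWarnings(
      estimate_steady_states(breath_series(tms, y), sch, tau = 42))
    gaps[i] <- max(abs(est$x_hat - nls_oracle(tms, y)))
    errs[i] <- mean(abs(est$x_hat - x_true))
  }
  list(noiseless_max_err = noiseless_max_err,
       noiseless_residual_rms = est0$residual_rms,
       oracle_max_gap = max(gaps),
       mean_abs_err = mean(errs),
       n_breaths = length(tms0))
}

#' Delta-method vertex CI coverage under the study design
#'
#' Simulates datasets from the fitted model family at the study scale
#' (7 subjects, 3 speeds x 5 stiffness levels) with a planted vertex and a
#' residual SD calibrated so the quadratic term carries a Wald statistic of
#' about 5, refits the quadratic mixed model on each, and reports how often
#' the 95% delta-method interval covers the true vertex.
#'
#' @param n_rep Number of simulated datasets.
#' @param seed Master seed.
#' @param vertex Planted vertex (% deviation from preferred).
#' @param beta_Q Planted quadratic coefficient.
#' @param sd_resid Residual SD (calibrated default gives |z_Q| near 5).
#' @param n_subjects Cohort size per dataset.
#' @return List with `coverage` (fraction in \[0, 1\]), `mean_abs_z_Q`,
#'   `n_used` (converged fits) and `n_rep`.
#' @export
vertex_coverage_sim <- function(n_rep = 500, seed = 1, vertex = 5,
                                beta_Q = 0.002, sd_resid = 1.5,
                                n_subjects = 7) {
  hits <- logical(0); zs <- numeric(0)
  for (i in seq_len(n_rep)) {
    rec <- gen_descriptor_records(n_subjects, beta0 = 1,
                                  beta_L = -2 * beta_Q * vertex,
                                  beta_Q = beta_Q, beta_speed = 0.5,
                                  sd_resid = sd_resid,
                                  seed = derive_seed(seed, "cov", i))
    ft <- fit_stiffness_trend(rec)
    if (!is.finite(ft$vertex)) next
    hits <- c(hits, ft$v_lb <= vertex && vertex <= ft$v_ub)
    zs <- c(zs, abs(ft$beta[["quadratic"]]) / ft$se[["quadratic"]])
  }
  list(coverage = mean(hits), mean_abs_z_Q = mean(zs),
       n_used = length(hits), n_rep = n_rep)
}

#' Trend-classification operating characteristics
#'
#' Plants each trend category at effect sizes giving high power (Wald
#' statistics near 5-7 for the active terms) under the study design, refits
#' and classifies each replicate, and tabulates the fraction classified
#' into the planted category. The null ("none") condition doubles as the
#' type-I error check of the quadratic term.
#'
#' @param n_rep Replicates per planted condition.
#' @param seed Master seed.
#' @param sd_resid Residual SD.
#' @param n_subjects Cohort size per dataset.
#' @return List with `accuracy` (named fractions per planted condition),
#'   `type1_quadratic` (fraction of null replicates with p_Q < 0.05) and
#'   `n_rep`.
#' @export
classification_recovery_sim <- function(n_rep = 200, seed = 1,
                                        sd_resid = 1.5, n_subjects = 7) {
  conds <- list(
    none = list(beta_L = 0, beta_Q = 0, truth = "none"),
    linear = list(beta_L = 0.05, beta_Q = 0, truth = "linear"),
    quadratic_near = list(beta_L = 0, beta_Q = 0.002, truth = "quadratic_near"),
    quadratic_far_pos = list(beta_L = -2 * 0.002 * 20, beta_Q = 0.002,
                             truth = "quadratic_far"),
    quadratic_far_neg = list(beta_L = 2 * 0.002 * 20, beta_Q = 0.002,
                             truth = "quadratic_far"))
  acc <- stats::setNames(numeric(length(conds)), names(conds))
  p_q_null <- numeric(n_rep)
  for (cn in names(conds)) {
    cc <- conds[[cn]]
    good <- logical(n_rep)
    for (i in seq_len(n_rep)) {
      rec <- gen_descriptor_records(n_subjects, beta0 = 1,
                                    beta_L = cc$beta_L, beta_Q = cc$beta_Q,
                                    beta_speed = 0.5, sd_resid = sd_resid,
                                    seed = derive_seed(seed, paste0("cls", cn), i))
      ft <- fit_stiffness_trend(rec)
      good[i] <- ft$category == cc$truth
      if (cn == "none") p_q_null[i] <- ft$p_Q
    }
    acc[cn] <- mean(good)
  }
  list(accuracy = acc, type1_quadratic = mean(p_q_null < 0.05), n_rep = n_rep)
}
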