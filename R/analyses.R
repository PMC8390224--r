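#' Staged preference-versus-speed analysis
#'
#' Stage 1 fits a first-order mixed model of dial-selected preferred
#' stiffness on relative treadmill speed (random intercept per subject). If
#' and only if the linear speed term is not significant at `alpha`, stage 2
#' fits the second-order model adding the squared speed term; when the
#' fitted quadratic opens upward, the implied speed of minimum preference
#' is reported.
#'
#' @param prefs Data frame with columns `subject_id`, `speed_rel`,
#'   `preferred_stiffness` (and optionally `repetition`).
#' @param alpha Significance level for the staging rule.
#' @return Object of class `preference_speed_fit`: list with `stage1`
#'   (coefficients, p-value of the linear term), `stage2` (`NULL` when not
#'   invoked; else coefficients, quadratic-term p-value and `implied_min`),
#'   and `alpha`.
#' @export
fit_preference_vs_speed <- function(prefs, alpha = 0.05) {
  need <- c("subject_id", "speed_rel", "preferred_stiffness")
  if (!all(need %in% names(prefs)))
    stop("`prefs` must contain columns: ", paste(need, collapse = ", "))
  if (any(prefs$preferred_stiffness <= 0)) stop("preferred stiffness must be positive")
  d <- data.frame(y = prefs$preferred_stiffness, v = prefs$speed_rel,
                  subject = factor(prefs$subject_id))
  if (nlevels(d$subject) < 2L) stop("need at least 2 subjects")
  ctrl <- lme4::lmerControl(calc.derivs = FALSE, check.conv.singular = "ignore",
                            check.scaleX = "ignore")
  m1 <- suppressMessages(lme4::lmer(y ~ v + (1 | subject), data = d,
                                    REML = FALSE, control = ctrl))
  b1 <- lme4::fixef(m1)
  se1 <- sqrt(diag(as.matrix(stats::vcov(m1))))
  p_lin <- 2 * stats::pnorm(-abs(b1[["v"]] / se1[["v"]]))
  stage1 <- list(coefficients = b1, se = se1, p_linear = unname(p_lin), fit = m1)

  stage2 <- NULL
  if (p_lin >= alpha) {
    if (length(unique(d$v)) < 3L)
      stop("fewer than 3 distinct speeds: quadratic stage unidentifiable")
    m2 <- suppressMessages(lme4::lmer(y ~ v + I(v^2) + (1 | subject), data = d,
                                      REML = FALSE, control = ctrl))
    b2 <- lme4::fixef(m2)
    se2 <- sqrt(diag(as.matrix(stats::vcov(m2))))
    p_quad <- 2 * stats::pnorm(-abs(b2[["I(v^2)"]] / se2[["I(v^2)"]]))
    implied_min <- if (b2[["I(v^2)"]] > 0) -b2[["v"]] / (2 * b2[["I(v^2)"]]) else NA_real_
    stage2 <- list(coefficients = b2, se = se2, p_quadratic = unname(p_quad),
                   implied_min = unname(implied_min), fit = m2)
  }
  structure(list(stage1 = stage1, stage2 = stage2, alpha = alpha),
            class = "preference_speed_fit")
}

#' @export
print.preference_speed_fit <- function(x, ...) {
  cat(sprintf("Stage 1 (linear): slope p = %.4g\n", x$stage1$p_linear))
  if (is.null(x$stage2)) {
    cat("Stage 2 not invoked (linear term significant)\n")
  } else {
    cat(sprintf("Stage 2 (quadratic): p = %.4g", x$stage2$p_quadratic))
    if (is.finite(x$stage2$implied_min))
      cat(sprintf("; implied minimum at relative speed %.3f", x$stage2$implied_min))
    cat("\n")
  }
  invisible(x)
}

#' Body mass versus preferred stiffness regression
#'
#' Ordinary least squares of each subject's mean preferred stiffness on
#' body mass, with R-squared and the two-sided slope p-value.
#'
#' @param masses Body masses (kg), one per subject (>= 3 subjects).
#' @param mean_prefs Subject mean preferred stiffness (Nm/deg).
#' @return List with `slope`, `intercept`, `r_squared`, `p_value`, `fit`.
#' @export
mass_preference_regression <- function(masses, mean_prefs) {
  if (length(masses) != length(mean_prefs)) stop("length mismatch")
  if (length(masses) < 3L) stop("need at least 3 subjects")
  if (stats::sd(masses) == 0) stop("zero variance in body mass")
  fit <- stats::lm(mean_prefs ~ masses)
  sm <- summary(fit)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = sm$r.squared,
       p_value = sm$coefficients[2, 4],
       fit = fit)
}

#' Analyze 10-meter walk test performance across stiffness levels
#'
#' Per-trial walking speed is total distance over travel time, normalized
#' within subject to the mean daily-use-prosthesis baseline speed. Fits
#' first- and second-order mixed models of normalized speed on stiffness
#' deviation (random intercept per subject), and runs the post-hoc
#' two-sample t-test comparing subject-condition mean normalized speeds at
#' stiffness below preferred against those at or above preferred.
#'
#' @param tenmwt Data frame with columns `subject_id`, `stiffness_rel`
#'   (% deviation; `NA` allowed for baseline rows), `repetition`,
#'   `distance_m`, `time_s`, `device` (`"daily_use"` baseline rows or
#'   `"vspa"` experimental rows).
#' @return List with `records` (per-trial normalized speeds), `linear` and
#'   `quadratic` model summaries (coefficients and term p-values),
#'   `t_test` (the post-hoc comparison) and group means.
#' @export
analyze_10mwt <- function(tenmwt) {
  need <- c("subject_id", "stiffness_rel", "distance_m", "time_s", "device")
  if (!all(need %in% names(tenmwt)))
    stop("`tenmwt` must contain columns: ", paste(need, collapse = ", "))
  base <- tenmwt[tenmwt$device == "daily_use", , drop = FALSE]
  exp <- tenmwt[tenmwt$device != "daily_use", , drop = FALSE]
  if (nrow(exp) == 0L) stop("no experimental trials")
  baselines <- tapply(base$distance_m / base$time_s, base$subject_id, mean)
  missing <- setdiff(unique(exp$subject_id), names(baselines))
  if (length(missing) > 0L)
    stop("missing daily-use baseline for subject(s): ",
         paste(missing, collapse = ", "))
  exp$speed_norm <- (exp$distance_m / exp$time_s) /
    as.numeric(baselines[as.character(exp$subject_id)])

  d <- data.frame(y = exp$speed_norm, dev = exp$stiffness_rel,
                  subject = factor(exp$subject_id))
  ctrl <- lme4::lmerControl(calc.derivs = FALSE, check.conv.singular = "ignore",
                            check.scaleX = "ignore")
  wald <- function(m, term) {
    b <- lme4::fixef(m)
    se <- tryCatch(sqrt(diag(as.matrix(stats::vcov(m)))),
                   error = function(e) NULL, warning = function(w) NULL)
    p <- if (is.null(se) || !is.finite(se[[term]]) || se[[term]] == 0)
      NA_real_ else 2 * stats::pnorm(-abs(b[[term]] / se[[term]]))
    list(coefficients = b, p = p)
  }
  m1 <- suppressMessages(lme4::lmer(y ~ dev + (1 | subject), data = d,
                                    REML = FALSE, control = ctrl))
  m2 <- suppressMessages(lme4::lmer(y ~ dev + I(dev^2) + (1 | subject), data = d,
                                    REML = FALSE, control = ctrl))
  lin <- wald(m1, "dev")
  quad <- wald(m2, "I(dev^2)")

  cond_means <- stats::aggregate(y ~ subject + dev, data = d, FUN = mean)
  below <- cond_means$y[cond_means$dev < 0]
  atabove <- cond_means$y[cond_means$dev >= 0]
  # degenerate (zero within-group variance) data make the t statistic
  # ill-defined: equal means carry no evidence, distinct means are exact
  tt <- tryCatch(stats::t.test(below, atabove), error = function(e)
    list(p.value = if (abs(mean(below) - mean(atabove)) < 1e-12) 1 else 0,
         statistic = NA_real_,
         method = "degenerate two-sample comparison (zero variance)"))
  list(records = exp,
       linear = list(coefficients = lin$coefficients, p_linear = lin$p),
       quadratic = list(coefficients = quad$coefficients, p_quadratic = quad$p),
       t_test = tt,
       mean_below = mean(below), mean_at_above = mean(atabove))
}

#' Preference- and baseline-normalization of raw conditions
#'
#' Converts absolute stiffness to percent deviation from the subject's
#' preferred stiffness (`100 * (raw/preferred - 1)`), optionally computes
#' the weight-normalized alternative (`raw / body_mass`, Nm/deg/kg), and
#' normalizes metabolic rates to a subject baseline (`raw / baseline`).
#'
#' @param raw_stiffness Absolute stiffness values (Nm/deg).
#' @param preferred Preferred stiffness (Nm/deg, > 0); recycled.
#' @param raw_metabolic,baseline Optional metabolic rates (W) and baseline
#'   (W, > 0) for the metabolic ratio.
#' @param body_mass Optional body mass (kg) for weight-normalized stiffness.
#' @return List with `stiffness_dev` (%), and where inputs were supplied
#'   `stiffness_per_kg` and `metabolic_ratio`.
#' @export
normalize_conditions <- function(raw_stiffness, preferred,
                                 raw_metabolic = NULL, baseline = NULL,
                                 body_mass = NULL) {
  if (any(preferred <= 0)) stop("`preferred` must be positive")
  out <- list(stiffness_dev = 100 * (raw_stiffness / preferred - 1))
  if (!is.null(body_mass)) {
    if (any(body_mass <= 0)) stop("`body_mass` must be positive")
    out$stiffness_per_kg <- raw_stiffness / body_mass
  }
  if (!is.null(raw_metabolic)) {
    if (is.null(baseline) || any(baseline <= 0))
      stop("metabolic normalization requires a positive `baseline`")
    out$metabolic_ratio <- raw_metabolic / baseline
  }
  out
}

#' Fit stiffness trends for every descriptor (plus the metabolic ratio)
#'
#' Batch driver over a long descriptor table: one quadratic mixed-effects
#' trend per descriptor name, each summarized into one row. When a
#' steady-state table and subject baselines are supplied, the normalized
#' metabolic ratio is appended as an additional response
#' (`net_metabolic_ratio`).
#'
#' @param descriptors Data frame (`subject_id`, `speed_rel`,
#'   `stiffness_rel`, `descriptor_name`, `value`).
#' @param steady_states Optional data frame (`subject_id`, `speed_rel`,
#'   `stiffness_rel`, `x_hat_w`).
#' @param met_baselines Optional named vector of per-subject baseline net
#'   metabolic rates (W) for the ratio.
#' @param alpha,m_tests,near_threshold_pct Passed to
#'   [fit_stiffness_trend()].
#' @return Data frame with one row per response: coefficients, term
#'   p-values, vertex and CI, category, Bonferroni stars, convergence flag.
#' @export
fit_trend_table <- function(descriptors, steady_states = NULL,
                            met_baselines = NULL,
                            alpha = 0.05, m_tests = 25,
                            near_threshold_pct = 10) {
  responses <- split(descriptors, descriptors$descriptor_name)
  if (!is.null(steady_states)) {
    if (is.null(met_baselines)) stop("metabolic trend requires `met_baselines`")
    ss <- steady_states
    ss$value <- ss$x_hat_w / as.numeric(met_baselines[as.character(ss$subject_id)])
    ss$descriptor_name <- "net_metabolic_ratio"
    responses$net_metabolic_ratio <- ss
  }
  rows <- lapply(names(responses), function(nm) {
    r <- responses[[nm]]
    r$stiffness_dev <- r$stiffness_rel
    ft <- tryCatch(
      fit_stiffness_trend(r, response = "value", alpha = alpha,
                          m_tests = m_tests,
                          near_threshold_pct = near_threshold_pct),
      error = function(e) NULL)
    if (is.null(ft)) {
      # degenerate response (e.g. exactly constant): report a no-trend row
      # rather than aborting the batch over the remaining descriptors
      return(data.frame(descriptor_name = nm, beta_intercept = NA_real_,
                        beta_linear = NA_real_, beta_quadratic = NA_real_,
                        beta_speed = NA_real_, p_L = NA_real_, p_Q = NA_real_,
                        vertex = NA_real_, v_lb = NA_real_, v_ub = NA_real_,
                        category = "none", bonferroni_star_L = FALSE,
                        bonferroni_star_Q = FALSE, converged = FALSE,
                        n_obs = nrow(r)))
    }
    data.frame(descriptor_name = nm,
               beta_intercept = ft$beta[["intercept"]],
               beta_linear = ft$beta[["linear"]],
               beta_quadratic = ft$beta[["quadratic"]],
               beta_speed = ft$beta[["speed"]],
               p_L = ft$p_L, p_Q = ft$p_Q,
               vertex = ft$vertex, v_lb = ft$v_lb, v_ub = ft$v_ub,
               category = ft$category,
               bonferroni_star_L = ft$bonferroni_star_L,
               bonferroni_star_Q = ft$bonferroni_star_Q,
               converged = ft$converged, n_obs = ft$n_obs)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
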