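#' Fit a preference-normalized quadratic stiffness trend
#'
#' The core trend model of the package: a linear mixed-effects model of a
#' descriptor (or metabolic ratio, or normalized walking speed) against
#' preference-normalized stiffness,
#' \deqn{y = \beta_0 + \beta_L d + \beta_Q d^2 + \beta_S v + u_i + w_i v + e}
#' where `d` is stiffness deviation from preferred (%), `v` relative
#' treadmill speed, `u_i` a random intercept and `w_i` a random speed slope
#' per subject (independent random effects). Estimation is by maximum
#' likelihood; the linear and quadratic stiffness coefficients get Wald
#' z-tests, and their covariance block feeds the delta-method confidence
#' interval on the vertex location \eqn{-\beta_L / (2\beta_Q)}
#' ([vertex_ci()]). The fitted trend is classified into one of four
#' categories ([classify_trend()]): no trend, linear, quadratic with vertex
#' far from preferred, quadratic with vertex near preferred.
#'
#' If the full model fails to converge, the model is refit with a random
#' intercept only and flagged `converged = FALSE`.
#'
#' @param records Data frame with columns `subject_id`, `speed_rel`,
#'   `stiffness_dev` (% deviation from preferred) and the response column.
#' @param response Name of the response column (default `"value"`).
#' @param alpha Significance level for term tests and classification.
#' @param m_tests Number of descriptors tested in the family (Bonferroni
#'   starring; default 25).
#' @param near_threshold_pct Half-width (%) of the "near preferred" vertex
#'   band (default 10).
#' @param level Confidence level for the vertex interval.
#' @return An object of class `stiffness_trend` with components `beta`
#'   (named fixed effects), `p_L`, `p_Q`, `p_speed`, `cov_LQ` (2x2), `vertex`,
#'   `v_lb`, `v_ub`, `category`, `bonferroni_star_L`, `bonferroni_star_Q`,
#'   `converged`, `n_obs`, `n_subjects`, `response`, and the underlying
#'   `lme4` fit in `$fit`.
#' @seealso [vertex_ci()], [classify_trend()], [gen_descriptor_records()]
#' @export
fit_stiffness_trend <- function(records, response = "value",
                                alpha = 0.05, m_tests = 25,
                                near_threshold_pct = 10, level = 0.95) {
  need <- c("subject_id", "speed_rel", "stiffness_dev", response)
  if (!all(need %in% names(records)))
    stop("`records` must contain columns: ", paste(need, collapse = ", "))
  d <- data.frame(y = records[[response]],
                  dev = records$stiffness_dev,
                  dev2 = records$stiffness_dev^2,
                  speed = records$speed_rel,
                  subject = factor(records$subject_id))
  if (any(!is.finite(d$dev))) stop("non-finite stiffness deviations")
  if (nlevels(d$subject) < 2L) stop("need at least 2 subjects")
  if (length(unique(d$dev)) < 3L)
    stop("need at least 3 distinct stiffness levels (quadratic unidentifiable)")
  if (stats::sd(d$y) == 0) stop("all-constant response")

  ctrl <- lme4::lmerControl(calc.derivs = FALSE,
                            check.conv.singular = "ignore",
                            check.scaleX = "ignore")
  converged <- TRUE
  fit <- tryCatch(
    suppressWarnings(suppressMessages(lme4::lmer(
      y ~ dev + dev2 + speed + (1 | subject) + (0 + speed | subject),
      data = d, REML = FALSE, control = ctrl))),
    error = function(e) NULL)
  if (!is.null(fit) && !is.null(fit@optinfo$conv$opt) && fit@optinfo$conv$opt != 0)
    fit <- NULL
  if (is.null(fit)) {
    converged <- FALSE
    fit <- suppressMessages(lme4::lmer(
      y ~ dev + dev2 + speed + (1 | subject),
      data = d, REML = FALSE, control = ctrl))
  }

  beta <- lme4::fixef(fit)
  V <- as.matrix(stats::vcov(fit))
  se <- sqrt(diag(V))
  z <- beta / se
  p <- 2 * stats::pnorm(-abs(z))
  cov_LQ <- V[c("dev", "dev2"), c("dev", "dev2")]

  vx <- c(vertex = NA_real_, lb = NA_real_, ub = NA_real_)
  if (is.finite(beta[["dev2"]]) && beta[["dev2"]] != 0)
    vx <- vertex_ci(beta[["dev"]], beta[["dev2"]], cov_LQ, level = level)

  obj <- structure(list(
    beta = c(intercept = unname(beta[["(Intercept)"]]),
             linear = unname(beta[["dev"]]),
             quadratic = unname(beta[["dev2"]]),
             speed = unname(beta[["speed"]])),
    se = c(intercept = se[["(Intercept)"]], linear = se[["dev"]],
           quadratic = se[["dev2"]], speed = se[["speed"]]),
    p_L = unname(p[["dev"]]), p_Q = unname(p[["dev2"]]),
    p_speed = unname(p[["speed"]]),
    cov_LQ = cov_LQ,
    vertex = unname(vx[1]), v_lb = unname(vx[2]), v_ub = unname(vx[3]),
    alpha = alpha, m_tests = m_tests, near_threshold_pct = near_threshold_pct,
    bonferroni_star_L = unname(p[["dev"]]) < alpha / m_tests,
    bonferroni_star_Q = unname(p[["dev2"]]) < alpha / m_tests,
    converged = converged,
    n_obs = nrow(d), n_subjects = nlevels(d$subject),
    response = response, fit = fit, data = d),
    class = "stiffness_trend")
  obj$category <- classify_trend(obj, alpha = alpha,
                                 near_threshold_pct = near_threshold_pct)
  obj
}

#' Delta-method confidence interval for a quadratic vertex
#'
#' The vertex of \eqn{y = \beta_0 + \beta_L d + \beta_Q d^2} sits at
#' \eqn{-\beta_L/(2\beta_Q)}. First-order (delta-method) propagation of the
#' coefficient covariance through this ratio uses the gradient
#' \eqn{g = (-1/(2\beta_Q),\; \beta_L/(2\beta_Q^2))}, giving
#' \eqn{\mathrm{var} = g^\top C g} and normal-quantile bounds
#' `vertex ± z * sqrt(var)`.
#'
#' @param beta_L,beta_Q Linear and quadratic coefficients (`beta_Q != 0`).
#' @param cov_LQ 2x2 covariance matrix of `(beta_L, beta_Q)` (symmetric
#'   positive semidefinite).
#' @param level Confidence level (default 0.95).
#' @return Named numeric vector `c(vertex, lb, ub)`.
#' @examples
#' vertex_ci(-2, 0.1, matrix(0, 2, 2))  # vertex 10, zero-width interval
#' @export
vertex_ci <- function(beta_L, beta_Q, cov_LQ, level = 0.95) {
  if (!is.finite(beta_Q) || beta_Q == 0) stop("vertex undefined: `beta_Q` is zero")
  cov_LQ <- as.matrix(cov_LQ)
  if (!isTRUE(all.equal(cov_LQ, t(cov_LQ), tolerance = 1e-8)))
    stop("`cov_LQ` must be symmetric")
  vertex <- -beta_L / (2 * beta_Q)
  g <- c(-1 / (2 * beta_Q), beta_L / (2 * beta_Q^2))
  v <- drop(t(g) %*% cov_LQ %*% g)
  if (v < -1e-12) stop("negative variance: `cov_LQ` is not positive semidefinite")
  v <- max(v, 0)
  zq <- stats::qnorm(1 - (1 - level) / 2)
  c(vertex = vertex, lb = vertex - zq * sqrt(v), ub = vertex + zq * sqrt(v))
}

#' Classify a fitted stiffness trend
#'
#' Applies the four-category taxonomy: if the quadratic term is significant
#' at `alpha`, the trend is `"quadratic_near"` when the vertex lies within
#' `near_threshold_pct` of the preferred stiffness (|vertex| <= threshold,
#' in % deviation) and `"quadratic_far"` otherwise; else if the linear term
#' is significant, `"linear"`; else `"none"`. Classification uses the raw
#' `alpha`; Bonferroni-corrected significance flags (`alpha / m_tests`) are
#' carried separately on the fit object, mirroring the dual reporting
#' convention for descriptor tables.
#'
#' @param fit A converged `stiffness_trend` (or a list with `p_L`, `p_Q`,
#'   `vertex`, `converged`).
#' @param alpha Significance level (default 0.05).
#' @param near_threshold_pct "Near preferred" half-width in % (default 10).
#' @return One of `"none"`, `"linear"`, `"quadratic_far"`,
#'   `"quadratic_near"`.
#' @export
classify_trend <- function(fit, alpha = 0.05, near_threshold_pct = 10) {
  if (is.list(fit) && !is.null(fit$converged) && !fit$converged &&
      !inherits(fit, "stiffness_trend"))
    stop("cannot classify an unconverged fit")
  p_L <- fit$p_L; p_Q <- fit$p_Q; vertex <- fit$vertex
  if (!is.finite(p_L) || !is.finite(p_Q)) stop("fit lacks term p-values")
  if (p_Q < alpha) {
    if (is.finite(vertex) && abs(vertex) <= near_threshold_pct) "quadratic_near"
    else "quadratic_far"
  } else if (p_L < alpha) "linear" else "none"
}

#' @export
print.stiffness_trend <- function(x, ...) {
  cat(sprintf("Quadratic stiffness trend for '%s' (%d obs, %d subjects%s)\n",
              x$response, x$n_obs, x$n_subjects,
              if (x$converged) "" else "; fallback: random intercept only"))
  cat(sprintf("  beta_L = %.4g (p = %.3g%s), beta_Q = %.4g (p = %.3g%s)\n",
              x$beta[["linear"]], x$p_L, if (x$bonferroni_star_L) " *" else "",
              x$beta[["quadratic"]], x$p_Q, if (x$bonferroni_star_Q) " *" else ""))
  if (is.finite(x$vertex))
    cat(sprintf("  vertex at %.2f%% deviation from preferred [%.2f, %.2f]\n",
                x$vertex, x$v_lb, x$v_ub))
  cat(sprintf("  category: %s\n", x$category))
  invisible(x)
}

#' @export
summary.stiffness_trend <- function(object, ...) {
  tab <- data.frame(estimate = object$beta, se = object$se,
                    z = object$beta / object$se,
                    p = 2 * stats::pnorm(-abs(object$beta / object$se)))
  structure(list(coefficients = tab, vertex = object$vertex,
                 v_lb = object$v_lb, v_ub = object$v_ub,
                 category = object$category, converged = object$converged,
                 response = object$response),
            class = "summary.stiffness_trend")
}

#' @export
print.summary.stiffness_trend <- function(x, ...) {
  cat(sprintf("Stiffness trend summary ('%s')\n", x$response))
  print(round(x$coefficients, 6))
  if (is.finite(x$vertex))
    cat(sprintf("vertex: %.2f%% [%.2f, %.2f] (delta method, 95%%)\n",
                x$vertex, x$v_lb, x$v_ub))
  cat("category:", x$category, "\n")
  invisible(x)
}

#' @export
coef.stiffness_trend <- function(object, ...) object$beta

#' @export
vcov.stiffness_trend <- function(object, ...) as.matrix(stats::vcov(object$fit))

#' Population-level prediction from a fitted stiffness trend
#'
#' Evaluates the fixed-effects surface at new stiffness deviations and
#' relative speeds (random effects set to zero).
#'
#' @param object A `stiffness_trend`.
#' @param newdata Data frame with `stiffness_dev` and optionally
#'   `speed_rel` (default 0).
#' @param ... Unused.
#' @return Numeric vector of predicted responses.
#' @export
predict.stiffness_trend <- function(object, newdata = NULL, ...) {
  if (is.null(newdata))
    newdata <- data.frame(stiffness_dev = object$data$dev,
                          speed_rel = object$data$speed)
  if (is.null(newdata$speed_rel)) newdata$speed_rel <- 0
  b <- object$beta
  b[["intercept"]] + b[["linear"]] * newdata$stiffness_dev +
    b[["quadratic"]] * newdata$stiffness_dev^2 + b[["speed"]] * newdata$speed_rel
}

#' @export
residuals.stiffness_trend <- function(object, ...) stats::residuals(object$fit)

#' Plot a fitted stiffness trend
#'
#' Subject-condition responses against stiffness deviation with the fitted
#' fixed-effects parabola (at mean speed); when the quadratic term is
#' significant the vertex and its delta-method interval are marked.
#'
#' @param x A `stiffness_trend`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.stiffness_trend <- function(x, ...) {
  d <- x$data
  graphics::plot(d$dev, d$y, xlab = "stiffness deviation from preferred (%)",
                 ylab = x$response, ...)
  dv <- seq(min(d$dev), max(d$dev), length.out = 100)
  graphics::lines(dv, predict(x, data.frame(stiffness_dev = dv,
                                            speed_rel = mean(d$speed))))
  if (is.finite(x$vertex) && x$p_Q < x$alpha) {
    graphics::abline(v = x$vertex, lty = 2)
    graphics::abline(v = c(x$v_lb, x$v_ub), lty = 3, col = "grey50")
  }
  invisible(x)
}

#' Simulate response vectors from a fitted stiffness trend
#'
#' Draws new response vectors from the fitted mixed model (new random
#' effects and residuals at the original design points), delegating to
#' [lme4::simulate.merMod()].
#'
#' @param object A `stiffness_trend`.
#' @param nsim Number of simulated response vectors.
#' @param seed Optional seed.
#' @param ... Passed to the `lme4` simulate method.
#' @return Data frame of simulated responses, one column per simulation.
#' @export
simulate.stiffness_trend <- function(object, nsim = 1, seed = NULL, ...) {
  stats::simulate(object$fit, nsim = nsim, seed = seed,
                  use.u = FALSE, ...)
}
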