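test_that("exact quadratic data are recovered to numerical precision", {
  grid <- expand.grid(stiffness_dev = c(-30, -15, 0, 15, 30),
                      speed_rel = c(-0.3, 0, 0.3), subject = 1:5)
  u <- c(-0.4, 0.1, 0.3, -0.2, 0.2)
  rec <- data.frame(subject_id = sprintf("S%02d", grid$subject),
                    speed_rel = grid$speed_rel,
                    stiffness_dev = grid$stiffness_dev,
                    value = 5 + 0.01 * grid$stiffness_dev^2 + u[grid$subject])
  ft <- fit_stiffness_trend(rec)
  expect_equal(ft$beta[["quadratic"]], 0.01, tolerance = 1e-6)
  expect_equal(ft$beta[["linear"]], 0, tolerance = 1e-8)
  expect_lt(ft$p_Q, 1e-12)
  expect_equal(ft$category, "quadratic_near")
})

test_that("trend fitting validates its inputs", {
  rec <- gen_descriptor_records(7, beta_Q = 0.002, seed = 1)
  expect_error(fit_stiffness_trend(rec[rec$subject_id == "S01", ]),
               "2 subjects")
  expect_error(fit_stiffness_trend(rec[rec$stiffness_dev %in% c(0, 15), ]),
               "3 distinct")
  rec2 <- rec; rec2$value <- 1
  expect_error(fit_stiffness_trend(rec2), "constant")
})

test_that("vertex CI follows the delta-method closed form", {
  expect_equal(unname(vertex_ci(0, 1, diag(2))[1]), 0)
  v <- vertex_ci(-2, 0.1, matrix(0, 2, 2))
  expect_equal(unname(v), c(10, 10, 10))
  # hand-computed propagation for a correlated covariance
  C <- matrix(c(0.04, 0.002, 0.002, 0.0009), 2)
  bL <- -1.2; bQ <- 0.05
  g <- c(-1 / (2 * bQ), bL / (2 * bQ^2))
  want <- -bL / (2 * bQ) + c(0, -1, 1) * qnorm(0.975) * sqrt(drop(t(g) %*% C %*% g))
  expect_equal(unname(vertex_ci(bL, bQ, C)), want[c(1, 2, 3)])
  expect_error(vertex_ci(1, 0, diag(2)), "zero")
  expect_error(vertex_ci(1, 1, matrix(c(1, 2, 2, -8), 2)), "positive semidefinite")
})

test_that("delta-method bounds agree with a parametric bootstrap", {
  # fit one strong-curvature dataset, then Monte-Carlo the vertex ratio
  rec <- gen_descriptor_records(7, beta_L = -2 * 0.002 * 5, beta_Q = 0.002,
                                sd_resid = 1.0, seed = 42)
  ft <- fit_stiffness_trend(rec)
  expect_gt(abs(ft$beta[["quadratic"]]) / ft$se[["quadratic"]], 4)
  set.seed(99)
  ch <- chol(ft$cov_LQ)
  draws <- matrix(rnorm(2 * 10000), ncol = 2) %*% ch
  bL <- ft$beta[["linear"]] + draws[, 1]
  bQ <- ft$beta[["quadratic"]] + draws[, 2]
  boot <- -bL / (2 * bQ)
  bq <- quantile(boot, c(0.025, 0.975))
  half_delta <- (ft$v_ub - ft$v_lb) / 2
  half_boot <- (bq[2] - bq[1]) / 2
  expect_lt(abs(half_delta - half_boot) / half_boot, 0.05)
  expect_lt(abs(ft$vertex - median(boot)) / half_boot, 0.1)
})

test_that("trend classification applies the four-category rule", {
  mk <- function(p_L, p_Q, vertex)
    list(p_L = p_L, p_Q = p_Q, vertex = vertex, converged = TRUE)
  expect_equal(classify_trend(mk(0.5, 0.5, 3)), "none")
  expect_equal(classify_trend(mk(0.0009, 0.5, 3)), "linear")
  # vertex within 10% of preferred: the near-preferred category
  expect_equal(classify_trend(mk(0.2, 0.0009, 7.02)), "quadratic_near")
  expect_equal(classify_trend(mk(0.2, 0.01, -18.0)), "quadratic_far")
  expect_equal(classify_trend(mk(0.001, 0.01, -18.0)), "quadratic_far")
  expect_error(classify_trend(list(p_L = 0.1, p_Q = 0.1, vertex = 1,
                                   converged = FALSE)),
               "unconverged")
})

test_that("shifting and scaling responses transform the fit predictably", {
  rec <- gen_descriptor_records(7, beta_L = -0.06, beta_Q = 0.002,
                                sd_resid = 1, seed = 7)
  f0 <- fit_stiffness_trend(rec)
  rec_shift <- rec; rec_shift$value <- rec$value + 100
  fs <- fit_stiffness_trend(rec_shift)
  expect_equal(fs$beta[["intercept"]], f0$beta[["intercept"]] + 100,
               tolerance = 1e-4)
  expect_equal(fs$beta[c("linear", "quadratic")],
               f0$beta[c("linear", "quadratic")], tolerance = 1e-4)
  rec_scale <- rec; rec_scale$value <- rec$value * 3
  fc <- fit_stiffness_trend(rec_scale)
  expect_equal(fc$beta[["quadratic"]], 3 * f0$beta[["quadratic"]],
               tolerance = 1e-4)
  expect_equal(fc$vertex, f0$vertex, tolerance = 1e-4)
  expect_equal(fc$p_Q, f0$p_Q, tolerance = 1e-4)
})

test_that("model object supports the standard methods", {
  rec <- gen_descriptor_records(7, beta_L = -0.02, beta_Q = 0.002,
                                beta_speed = 0.5, sd_resid = 1, seed = 3)
  ft <- fit_stiffness_trend(rec)
  expect_s3_class(ft, "stiffness_trend")
  expect_named(coef(ft), c("intercept", "linear", "quadratic", "speed"))
  expect_output(print(ft), "vertex")
  expect_output(print(summary(ft)), "category")
  pr <- predict(ft, data.frame(stiffness_dev = c(0, 10), speed_rel = 0))
  expect_equal(pr[1], ft$beta[["intercept"]])
  expect_equal(length(residuals(ft)), nrow(rec))
  sim <- simulate(ft, nsim = 2, seed = 1)
  expect_equal(dim(sim), c(nrow(rec), 2))
  pdf(NULL); on.exit(dev.off())
  expect_silent(plot(ft))
})
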