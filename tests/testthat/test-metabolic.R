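test_that("net rate subtraction is exact and linear", {
  s <- breath_series(c(1, 2), c(500, 520))
  expect_equal(net_rate(s, 100)$rates, c(400, 420))
  expect_equal(net_rate(s, 0)$rates, s$rates)
  set.seed(4)
  r <- breath_series(sort(runif(50, 0, 100)), rnorm(50, 400, 30))
  expect_equal(mean(net_rate(r, 37.5)$rates), mean(r$rates) - 37.5,
               tolerance = 1e-12)
})

test_that("gas-to-power conversion is the configured linear map", {
  expect_equal(gas_to_power(0, 0), 0)
  expect_equal(gas_to_power(1, 0), 16.58 * 1000 / 60)
  set.seed(5)
  vo2 <- runif(20, 0, 4); vco2 <- runif(20, 0, 4)
  expect_equal(gas_to_power(2 * vo2, 2 * vco2), 2 * gas_to_power(vo2, vco2),
               tolerance = 1e-12)
  expect_error(gas_to_power(-1, 0), "non-negative")
})

test_that("predict_response matches the closed-form first-order solution", {
  sch <- trial_schedule(300)
  # equilibrium and frozen-dynamics limits
  expect_equal(predict_response(300, sch, 42, 300, c(10, 100, 250)),
               rep(300, 3))
  expect_equal(predict_response(400, sch, 1e12, 300, c(10, 100, 250)),
               rep(300, 3), tolerance = 1e-9)
  # one time constant into a step: y0 + (1 - e^-1) * step
  expect_equal(predict_response(400, sch, 42, 300, 42),
               300 + 100 * (1 - exp(-1)), tolerance = 1e-12)
  # continuity across a trial boundary with piecewise-constant input
  sch2 <- trial_schedule(c(100, 100), stiffness_rel = c(0, 15))
  y_end1 <- 300 + (250 - 300) * exp(-100 / 42)
  expect_equal(predict_response(c(300, 350), sch2, 42, 250, c(100, 150)),
               c(y_end1, 350 + (y_end1 - 350) * exp(-50 / 42)),
               tolerance = 1e-12)
  expect_error(predict_response(300, sch, -1, 300, 10), "positive")
  expect_error(predict_response(300, sch, 42, 300, 400), "span")
})

test_that("prediction is affine in the steady-state vector", {
  sch <- block_schedule()
  set.seed(11)
  tms <- cumsum(pmax(rnorm(200, 3, 0.8), 1))
  tms <- tms[tms <= 1080]
  for (i in 1:5) {
    x1 <- runif(5, 200, 500); x2 <- runif(5, 200, 500); a <- runif(1)
    lhs <- predict_response(a * x1 + (1 - a) * x2, sch, 42, 300, tms)
    rhs <- a * predict_response(x1, sch, 42, 300, tms) +
      (1 - a) * predict_response(x2, sch, 42, 300, tms)
    expect_equal(lhs, rhs, tolerance = 1e-10)
  }
})

test_that("noiseless round trip recovers steady states exactly", {
  sch <- block_schedule()
  x <- c(300, 400, 350, 380, 320)
  set.seed(2)
  tms <- cumsum(pmax(rnorm(400, 3, 0.8), 1))
  tms <- tms[tms <= 1080]
  y <- predict_response(x, sch, 42, 300, tms)
  for (pol in c("first_breath", "free")) {
    est <- estimate_steady_states(breath_series(tms, y), sch, tau = 42,
                                  y0_policy = pol)
    expect_lt(max(abs(est$x_hat - x)), 1e-6)
    expect_lt(est$residual_rms, 1e-6)
  }
})

test_that("constant series at equilibrium yields constant estimates", {
  sch <- trial_schedule(c(120, 120, 120), stiffness_rel = c(0, 15, -15))
  tms <- seq(2, 360, by = 3)
  est <- estimate_steady_states(breath_series(tms, rep(250, length(tms))), sch)
  expect_equal(est$x_hat, rep(250, 3), tolerance = 1e-9)
})

test_that("estimator rejects unidentifiable or invalid inputs", {
  sch <- trial_schedule(c(120, 120))
  expect_error(estimate_steady_states(breath_series(c(5, 10, 15), c(1, 2, 3)),
                                      sch),
               "fewer than 2 breaths")
  expect_error(trial_schedule(numeric(0)), "empty")
  expect_error(trial_schedule(c(60, -30)), "positive")
  expect_error(estimate_steady_states(breath_series(seq(5, 230, 3),
                                                    rnorm(76, 300, 5)),
                                      sch, tau = -5),
               "positive")
})

test_that("negative steady-state estimates are flagged, not clipped", {
  sch <- trial_schedule(c(60, 60), stiffness_rel = c(0, 15))
  tms <- seq(1, 120, by = 2)
  # force a sharp downward ramp: least squares must chase it below zero
  y <- 50 - 2 * tms
  expect_warning(est <- estimate_steady_states(breath_series(tms, y), sch),
                 "negative")
  expect_true(any(est$negative))
  expect_true(any(est$x_hat < 0))
})

test_that("linear-algebra estimate matches direct nonlinear least squares", {
  # oracle: numerical minimization of squared prediction error in x
  sch <- block_schedule()
  x_true <- c(320, 410, 360, 390, 340)
  nls_oracle <- function(tms, y) {
    sse <- function(x) sum((predict_response(x, sch, 42, y[1], tms[-1],
                                             t0 = tms[1]) - y[-1])^2)
    stats::optim(rep(mean(y), 5), sse, method = "BFGS",
                 control = list(maxit = 500, reltol = 1e-14))$par
  }
  for (sd in 1:10) {
    set.seed(sd)
    tms <- cumsum(pmax(rnorm(400, 3, 0.8), 1)); tms <- tms[tms <= 1080]
    y <- predict_response(x_true, sch, 42, 300, tms) + rnorm(length(tms), 0, 20)
    est <- suppressWarnings(
      estimate_steady_states(breath_series(tms, y), sch, tau = 42))
    expect_lt(max(abs(est$x_hat - nls_oracle(tms, y))), 0.5)
  }
})

test_that("more breaths never hurt average recovery accuracy", {
  sch <- trial_schedule(rep(60, 5), stiffness_rel = c(0, 15, -15, 30, -30))
  x <- c(300, 380, 340, 360, 310)
  mae <- function(n_per_min) {
    errs <- vapply(1:100, function(sd) {
      set.seed(sd + 300)
      tms <- seq(1, 300 - 1, length.out = n_per_min * 5)
      y <- predict_response(x, sch, 42, 280, tms) + rnorm(length(tms), 0, 20)
      est <- suppressWarnings(
        estimate_steady_states(breath_series(tms, y), sch))
      mean(abs(est$x_hat - x))
    }, numeric(1))
    mean(errs)
  }
  expect_lte(mae(40), mae(20))
})

test_that("time-constant profiling recovers the generating tau", {
  sch <- block_schedule()
  x <- c(300, 400, 350, 380, 320)
  set.seed(3)
  tms <- cumsum(pmax(rnorm(400, 3, 0.8), 1)); tms <- tms[tms <= 1080]
  y <- predict_response(x, sch, 42, 300, tms)
  pr <- estimate_tau(breath_series(tms, y), sch, tau_grid = seq(20, 80, 2))
  expect_equal(pr$tau_best, 42)
  expect_equal(estimate_tau(breath_series(tms, y), sch, tau_grid = 37)$tau_best, 37)
  expect_error(estimate_tau(breath_series(tms, y), sch, tau_grid = numeric(0)),
               "empty")
})

test_that("device stiffness range ratio matches the printed bounds", {
  r <- device_stiffness_range()
  expect_equal(round(r$range_ratio, 1), 5.9)
  expect_error(device_stiffness_range(5, 4), "invalid")
})
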