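# Initialization, curve fitting, fallback integration and measure_peak.

test_that("guess_initial recovers location/spread on a noiseless gaussian", {
  t <- seq(0, 60, by = 1)
  p <- shape_params("gaussian", 100, 31.3, 4)
  g <- guess_initial(make_eic(t, model_eval(p, t)), "gaussian")
  expect_lt(abs(g$mu - 31.3), 1)            # within one scan interval
  expect_lt(abs(g$sigma - 4) / 4, 0.15)
  expect_lt(abs(g$amplitude - 100) / 100, 0.1)
})

test_that("guess_initial contracts: no signal, argmax, short input", {
  expect_error(guess_initial(make_eic(1:10, rep(0, 10))), "no signal")
  expect_error(guess_initial(make_eic(1:4, c(0, 1, 1, 0))), "fewer than 5")
  t <- seq(0, 100, by = 1)
  y <- model_eval(shape_params("gaussian", 50, 30, 3), t) +
    model_eval(shape_params("gaussian", 80, 70, 3), t)
  expect_lt(abs(guess_initial(make_eic(t, y))$mu - 70), 1)
})

test_that("fit_curve recovers a noiseless EMG: apex within 0.1 s, area within 1%", {
  t <- seq(0, 59, length.out = 60)
  true <- shape_params("emg", 1000, 25, 3, tau = 2.5)
  fit <- fit_curve(make_eic(t, model_eval(true, t)), "emg")
  expect_true(fit$converged)
  m <- peak_metrics(fit)
  true_apex <- stats::optimize(function(x) model_eval(true, x), c(20, 40),
                               maximum = TRUE, tol = 1e-10)$maximum
  expect_lt(abs(m$apex_rt - true_apex), 0.1)
  true_area <- stats::integrate(function(x) model_eval(true, x),
                                -100, 250, rel.tol = 1e-10)$value
  got_area <- model_area(fit$params, -100, 250)
  expect_lt(abs(got_area - true_area) / true_area, 0.01)
})

test_that("fit_curve on gaussian + 2% noise converges with small residual", {
  t <- seq(0, 80, by = 1)
  p <- shape_params("gaussian", 500, 40, 5)
  y0 <- model_eval(p, t)
  withr::with_seed(11, y <- pmax(y0 + rnorm(length(t), 0, 0.02 * 500), 0))
  fit <- fit_curve(make_eic(t, y), "gaussian")
  expect_true(fit$converged)
  expect_lt(fit$residual_rel_rmse, 0.05)
})

test_that("fit_curve never crashes on pure noise", {
  withr::with_seed(5, y <- abs(rnorm(50, 10, 3)))
  fit <- fit_curve(make_eic(seq_len(50), y), "emg")
  expect_s3_class(fit, "FitResult")
  expect_true(!fit$converged || fit$residual_rel_rmse > 0.05)
  expect_error(fit_curve(make_eic(1:3, c(0, 1, 0)), "gaussian"),
               "fewer than 5")
})

test_that("fallback_area: printed-geometry fixtures are exact", {
  # triangle (0,0),(1,1),(2,0): area 1
  tri <- fallback_area(make_eic(c(0, 1, 2), c(0, 1, 0)), 0, 2)
  expect_equal(tri$area, 1.0)
  expect_equal(tri$apex_rt, 1)
  expect_equal(tri$apex_height, 1)
  # rectangle height 3 width 4 on a fine grid, zero edges
  t <- seq(0, 6, by = 0.01)
  y <- ifelse(t >= 1 & t <= 5, 3, 0)
  rect <- fallback_area(make_eic(t, y), 0, 6)
  expect_equal(rect$area, 3 * 4, tolerance = 0.01 * 3)  # grid discretization
  # invariant to zero-intensity points outside the window
  t2 <- c(-5, -4, t, 10, 11)
  y2 <- c(0, 0, y, 0, 0)
  rect2 <- fallback_area(make_eic(t2, y2), 0, 6)
  expect_equal(rect2$area, rect$area)
  # no points in window -> not-found, no exception
  expect_false(fallback_area(make_eic(c(1, 2), c(1, 1)), 5, 6)$found)
})

test_that("fallback integrates a noisy EMG within 10% of truth at SNR 50", {
  t <- seq(0, 79, by = 1)
  true <- shape_params("emg", 1000, 35, 3, tau = 3)
  withr::with_seed(21,
    y <- pmax(model_eval(true, t) + rnorm(length(t), 0, 20), 0))
  fb <- fallback_area(make_eic(t, y), 0, 79)
  true_area <- stats::integrate(function(x) model_eval(true, x), -100, 300,
                                rel.tol = 1e-10)$value
  expect_lt(abs(fb$area - true_area) / true_area, 0.10)
})

test_that("measure_peak accepts a clean EMG via the model route", {
  t <- seq(0, 99, by = 1)
  true <- shape_params("emg", 2000, 50, 3, tau = 2, baseline = 10)
  withr::with_seed(3,
    y <- pmax(model_eval(true, t) + rnorm(length(t), 0, 40), 0))
  roi <- make_roi(rtMin = 30, rtMax = 75, rt = 50)
  pm <- measure_peak(make_eic(t, y), roi)
  expect_true(pm$found)
  expect_false(pm$fallback_used)
  true_area <- stats::integrate(function(x)
    model_eval(true, x) - 10, -100, 300, rel.tol = 1e-10)$value
  expect_lt(abs(pm$area - true_area) / true_area, 0.05)
  expect_true(pm$rt_min_obs < pm$apex_rt && pm$apex_rt < pm$rt_max_obs)
})

test_that("measure_peak falls back on a shouldered bimodal signal", {
  t <- seq(0, 99, by = 1)
  y <- model_eval(shape_params("gaussian", 1000, 40, 3), t) +
    model_eval(shape_params("gaussian", 900, 55, 3), t)
  roi <- make_roi(rtMin = 25, rtMax = 75)
  pm <- measure_peak(make_eic(t, y), roi,
                     fit_config(max_residual = 0.02))
  expect_true(pm$found)
  expect_true(pm$fallback_used)
  # trapezoid oracle over the window (edge intensities ~0)
  sel <- t >= 25 & t <= 75
  oracle <- sum((y[sel][-1] + y[sel][-sum(sel)]) / 2 * diff(t[sel]))
  expect_lt(abs(pm$area - oracle) / oracle, 0.02)
})

test_that("measure_peak reports not-found on blank noise-only windows", {
  withr::with_seed(9, y <- abs(rnorm(60, 5, 2)))
  pm <- measure_peak(make_eic(seq_len(60), y), make_roi(rtMin = 10, rtMax = 50))
  expect_false(pm$found)
  expect_true(is.na(pm$area) && is.na(pm$apex_rt))
  blank <- measure_peak(make_eic(numeric(0), numeric(0)),
                        make_roi(rtMin = 0, rtMax = 1))
  expect_false(blank$found)
})

test_that("measure_peak never raises on generator-producible EICs (fuzz)", {
  for (s in 1:15) {
    withr::with_seed(s, {
      n <- sample(10:80, 1)
      t <- seq(0, n - 1)
      kind <- sample(3, 1)
      y <- switch(kind,
        pmax(rnorm(n, 50, 20), 0),                      # noise only
        rep(0, n),                                      # blank
        {                                               # peak + noise
          tau <- runif(1, 0, 4)
          p <- if (tau > 0.01)
            shape_params("emg", runif(1, 10, 1e5), runif(1, 5, n - 5),
                         runif(1, 0.5, 8), tau = tau)
          else shape_params("gaussian", runif(1, 10, 1e5),
                            runif(1, 5, n - 5), runif(1, 0.5, 8))
          pmax(model_eval(p, t) + rnorm(n, 0, 30), 0)
        })
      expect_no_error(measure_peak(make_eic(t, y),
                                   make_roi(rtMin = 0, rtMax = n - 1)))
    })
  }
})
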