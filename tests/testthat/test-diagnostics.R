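test_that("shrinkage line matches closed forms", {
  # univariate y = x + e with Var(x) = 1, Var(e) = 1: slope = 1/2
  line <- least_squares_effect_line(1, cov_xy = 1, var_y = 2)
  expect_equal(line$slope, 0.5)
  expect_equal(line$slope * 2, 1.0)  # at y - mean = 2, yhat - mean = 1
  # noise-free: identity line; zero coefficients: predict the mean
  expect_equal(least_squares_effect_line(1, 1, 1)$slope, 1)
  expect_equal(least_squares_effect_line(c(0, 0), c(1, 2), 3)$slope, 0)
  expect_error(least_squares_effect_line(1, 1, var_y = 0), "positive")
})

test_that("plug-in shrinkage slope is consistent on large samples", {
  set.seed(20)
  n <- 20000
  x <- rnorm(n)
  y <- x + rnorm(n)
  slope_hat <- least_squares_effect_line(1, cov_xy = cov(x, y),
                                         var_y = var(y))$slope
  expect_lt(abs(slope_hat - 0.5), 0.05)
  # score-space version on a fitted model: slope equals explained variance
  # fraction of the first ncomp components
  sim <- simulate_dataset(small_truth(), n = 200, n_test = 2, seed = 21)
  fit <- fit_pcr(sim$x_cal, sim$y_cal, ncomp = 2)
  sl <- least_squares_effect_line(fit, sim$y_cal)
  yc <- sim$y_cal - fit$y_mean
  expect_equal(sl$slope, sum(fit$g_hat[1:2]^2) / sum(yc^2), tolerance = 1e-10)
  expect_lte(sl$slope, 1 + 1e-10)
  expect_gt(sl$slope, 0)
})

test_that("loess smoother is exact on polynomials and matches a direct local solve", {
  x <- seq(0, 1, length.out = 50)
  fit_lin <- loess_fit(x, 2 * x, span = 0.5, degree = 2)
  expect_lt(max(abs(fit_lin$fitted - 2 * fit_lin$eval_points)), 1e-8)
  fit_const <- loess_fit(x, rep(3, 50), span = 0.4, degree = 2)
  expect_lt(max(abs(fit_const$fitted - 3)), 1e-8)

  # independent oracle: tricube-weighted quadratic over the q nearest points
  set.seed(22)
  xs <- sort(runif(40))
  ys <- sin(6 * xs) + rnorm(40, 0, 0.1)
  sf <- loess_fit(xs, ys, span = 0.5, degree = 2)
  x0 <- sf$eval_points[17]
  q <- floor(0.5 * 40)
  d <- abs(xs - x0)
  idx <- order(d)[1:q]
  wts <- (1 - (d[idx] / max(d[idx]))^3)^3
  co <- coef(lm(ys[idx] ~ xs[idx] + I(xs[idx]^2), weights = wts))
  expect_equal(sf$fitted[17], unname(sum(co * c(1, x0, x0^2))), tolerance = 1e-10)

  expect_error(loess_fit(1:3, 1:3, degree = 2), "too few")
})

test_that("loess respects the inclusion mask yet evaluates everywhere", {
  set.seed(23)
  x <- seq(0, 1, length.out = 60)
  y <- 2 * x
  y[c(10, 30)] <- 50  # gross outliers
  inc <- rep(TRUE, 60)
  inc[c(10, 30)] <- FALSE
  sf <- loess_fit(x, y, span = 0.5, degree = 2, included = inc)
  expect_length(sf$fitted, 60)
  # excluded outliers get fitted values from the clean tendency
  expect_lt(max(abs(sf$fitted - 2 * sf$eval_points)), 1e-6)
})

test_that("agreement report recovers identity data and flags degenerate abscissae", {
  set.seed(24)
  est <- rnorm(100)
  rep_id <- agreement_report(est, est)
  expect_equal(rep_id$mean_diff, 0)
  expect_equal(rep_id$slope, 1, tolerance = 1e-6)
  # additive noise leaves the observed-on-estimated slope near one
  est2 <- rnorm(400)
  obs2 <- est2 + rnorm(400, 0, 0.5 * sd(est2))
  expect_lt(abs(agreement_report(est2, obs2)$slope - 1), 0.1)
  # constant abscissa: slope not available, no error
  rep_flat <- agreement_report(rep(1, 50), rnorm(50))
  expect_true(is.na(rep_flat$slope))
  expect_error(agreement_report(1:5, 1:4), "equal length")
})

test_that("binned observed squared errors track the error formula", {
  sim <- simulate_dataset(nir_truth(), n = 100, n_test = 423, seed = 1)
  model <- fit_pcr(sim$x_cal, sim$y_cal, ncomp = 5)
  model <- suppressWarnings(calibrate_uncertainty(model, sim$x_cal, sim$y_cal))
  tab <- prediction_uncertainty(model, sim$x_test)
  observed <- (tab$y_hat - sim$y_test)^2
  bins <- cut(rank(tab$expected_squared_error), 5, labels = FALSE)
  for (b in 1:5) {
    sel <- bins == b
    se <- sd(observed[sel]) / sqrt(sum(sel))
    expect_lt(abs(mean(observed[sel]) - mean(tab$expected_squared_error[sel])),
              3 * se)
  }
})

test_that("estimated bias recovers the true conditional bias with unit slope", {
  hits <- 0L
  for (seed in 1:10) {
    sim <- simulate_dataset(nir_truth(), n = 100, n_test = 423, seed = seed)
    model <- fit_pcr(sim$x_cal, sim$y_cal, ncomp = 5)
    model <- suppressWarnings(calibrate_uncertainty(model, sim$x_cal, sim$y_cal))
    b_est <- estimated_bias(project(model, sim$x_test), model)
    b_true <- true_test_bias(sim, 5)
    slope <- agreement_report(b_est, b_true)$slope
    if (!is.na(slope) && slope >= 0.8 && slope <= 1.2) hits <- hits + 1L
  }
  expect_gte(hits, 8L)
})
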