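test_that("noise variance estimate is exact on noise-free data and concentrates otherwise", {
  # noise-free data whose signal rank (3) is below the capped request
  truth <- small_truth(g = c(5, 4, 3, 0), sigma2_y = 0)
  sim <- simulate_dataset(truth, n = 40, n_test = 2, seed = 1)
  expect_lt(suppressWarnings(estimate_sigma2(sim$x_cal, sim$y_cal, a_noise = 10)),
            1e-10)
  # full-rank spectra (spectral noise inflates rank past a_noise):
  # MSEC at 50 components concentrates around the true variance
  tr <- simulation_truth(generate_loadings(60, 5, smoothness = 3, seed = 2),
                         score_sd = 2 * 0.7^(0:4), g_true = c(5, 4, 3, 2, 1),
                         g0_true = 3, sigma2_y = 0.25, sigma2_x = 1e-4)
  simn <- simulate_dataset(tr, n = 200, n_test = 1, seed = 6)
  est <- estimate_sigma2(simn$x_cal, simn$y_cal, a_noise = 50)
  expect_lt(abs(est - 0.25), 0.25 * 0.25)
  # requested components must leave residual degrees of freedom
  expect_error(estimate_sigma2(sim$x_cal, sim$y_cal, a_noise = 39),
               "degrees of freedom")
  # over-rank requests are capped with a warning
  expect_warning(estimate_sigma2(sim$x_cal, sim$y_cal, a_noise = 20), "capped")
})

test_that("significance mask flags exactly the informative score directions", {
  set.seed(10)
  x <- matrix(rnorm(30 * 10), 30, 10)
  base <- fit_pcr(x, rnorm(30), ncomp = 2)
  y <- 5 * base$scores[, 2]
  fit <- fit_pcr(x, y, ncomp = 2)
  mask <- significant_components(fit, y, alpha = 0.01, m_max = 6)
  expect_true(mask[2])
  expect_false(any(mask[-2]))
  # alpha = 1 flags every tested component, none beyond m_max
  m_all <- significant_components(fit, y + rnorm(30, 0, 0.1), alpha = 1, m_max = 4)
  expect_true(all(m_all[1:4]))
  expect_false(any(m_all[5:fit$m]))
})

test_that("under a null response the mask false-positive rate matches alpha", {
  set.seed(11)
  x <- matrix(rnorm(100 * 20), 100, 20)
  flags <- vapply(1:200, function(r) {
    y <- rnorm(100)
    fit <- fit_pcr(x, y, ncomp = 1)
    sum(significant_components(fit, y, alpha = 0.01, m_max = 15))
  }, numeric(1))
  # expected count 15 * 0.01 = 0.15 per replicate
  expect_lte(mean(flags), 0.5)
})

test_that("variance contribution follows the leverage formula and grows with rank", {
  expect_equal(variance_contribution(rep(0, 5), 3, sigma2 = 1, n = 100), 0.01)
  expect_equal(variance_contribution(c(0.1, 0.2, 0.5), 2, sigma2 = 1, n = 100),
               0.01 + 0.05, tolerance = 1e-12)
  u <- rnorm(8)
  v <- vapply(1:8, function(a) variance_contribution(u, a, 0.3, 50), numeric(1))
  expect_true(all(diff(v) >= 0))
  expect_error(variance_contribution(u, 9, 0.3, 50), "invalid rank")
})

test_that("bias contribution sums significance-gated coefficients beyond the model rank", {
  model <- structure(list(ncomp = 2L, m = 6L, n = 20L,
                          g_hat = c(9, 9, 2, 1, 3, 3),
                          significance_mask = c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE),
                          m_max_bias = 4L),
                     class = "pcr_model")
  u <- c(0.3, -0.2, 0.5, 0.1, 2, 2)
  expect_equal(bias_contribution(u, model), -(0.5 * 2 + 0.1 * 1))
  model$significance_mask[4] <- FALSE
  expect_equal(bias_contribution(u, model), -1.0)
  expect_equal(bias_contribution(u, model, ncomp = 4), 0)  # empty range
  model$significance_mask <- NULL
  expect_error(bias_contribution(u, model), "calibrate_uncertainty")
})

test_that("the error breakdown assembles its terms and decomposes exactly", {
  model <- structure(list(ncomp = 2L, m = 6L, n = 100L, sigma2_hat = 1,
                          g_hat = c(9, 9, 2, 1, 3, 3),
                          significance_mask = rep(c(TRUE, FALSE), c(4, 2)),
                          m_max_bias = 4L),
                     class = "pcr_model")
  u <- c(0.1, 0.2, 0.5, 0.1, 0, 0)
  bd <- expected_squared_error(u, model)
  expect_equal(bd$variance_term, 0.06, tolerance = 1e-12)
  expect_equal(bd$bias_signed, -1.1, tolerance = 1e-12)
  expect_equal(bd$total, 1 + 0.06 + 1.21, tolerance = 1e-10)
  # centroid sample: sigma2 * (1 + 1/n), zero bias
  bd0 <- expected_squared_error(rep(0, 6), model)
  expect_equal(bd0$total, 1.01, tolerance = 1e-12)
  model$sigma2_hat <- NULL
  expect_error(expected_squared_error(u, model), "sigma2_hat")
})

test_that("decomposition identity holds on many random breakdowns", {
  truth <- nir_truth()
  sim <- simulate_dataset(truth, n = 100, n_test = 5, seed = 12)
  model <- fit_pcr(sim$x_cal, sim$y_cal, ncomp = 5)
  model <- suppressWarnings(calibrate_uncertainty(model, sim$x_cal, sim$y_cal))
  set.seed(13)
  for (i in 1:1000) {
    u <- rnorm(model$m, 0, 0.3)
    bd <- expected_squared_error(u, model)
    expect_lt(abs(bd$total - (bd$sigma2 + bd$variance_term + bd$bias_signed^2)),
              1e-10)
    expect_gte(bd$variance_term, bd$sigma2 / model$n)
  }
})

test_that("full-rank PCR error with empty bias range reduces to the OLS formula", {
  set.seed(14)
  n <- 30
  x <- matrix(rnorm(n * 5), n, 5)
  y <- rnorm(n)
  fit <- fit_pcr(x, y, ncomp = 5)
  expect_equal(fit$m, 5)
  fit$sigma2_hat <- 0.7
  fit$significance_mask <- rep(TRUE, 5)
  fit$m_max_bias <- 5L
  xc_cal <- sweep(x, 2, fit$x_mean)
  for (i in 1:5) {
    xnew <- rnorm(5)
    u <- project(fit, xnew)
    pcr_val <- expected_squared_error(u, fit)$total
    ols_val <- ols_expected_squared_error(xnew - fit$x_mean, xc_cal,
                                          sigma2 = 0.7, n = n)
    expect_equal(pcr_val, ols_val, tolerance = 1e-8)
  }
  # centroid value and linear scaling in sigma2
  expect_equal(ols_expected_squared_error(rep(0, 5), xc_cal, 1, n), 1 + 1 / n)
  z <- rnorm(5)
  expect_equal(ols_expected_squared_error(z, xc_cal, 2, n),
               2 * ols_expected_squared_error(z, xc_cal, 1, n), tolerance = 1e-10)
  # collinear spectra are rejected with advice
  sing <- cbind(xc_cal, xc_cal[, 1])
  expect_error(ols_expected_squared_error(rep(0, 6), sing, 1, n), "PCR")
})

test_that("identical predictions can carry different uncertainties", {
  truth <- nir_truth()
  sim <- simulate_dataset(truth, n = 100, n_test = 5, seed = 15)
  model <- fit_pcr(sim$x_cal, sim$y_cal, ncomp = 5)
  model <- suppressWarnings(calibrate_uncertainty(model, sim$x_cal, sim$y_cal))
  g <- model$g_hat
  u1 <- c(0.1, rep(0, model$m - 1))
  w <- c(0, g[3], -g[2], rep(0, model$m - 3))    # orthogonal to g over 1..ncomp
  w <- w / sqrt(sum(w^2)) * 2
  u2 <- u1 + w
  p1 <- model$y_mean + sum(u1[1:5] * g[1:5])
  p2 <- model$y_mean + sum(u2[1:5] * g[1:5])
  expect_lt(abs(p1 - p2), 1e-12)
  t1 <- expected_squared_error(u1, model)$total
  t2 <- expected_squared_error(u2, model)$total
  expect_gte(t2 / t1, 1.5)
})

test_that("average estimated squared bias falls as rank grows through the signal", {
  sim <- simulate_dataset(nir_truth(tail_signal = FALSE), n = 100, n_test = 423,
                          seed = 16)
  model <- fit_pcr(sim$x_cal, sim$y_cal, ncomp = 5)
  model <- suppressWarnings(calibrate_uncertainty(model, sim$x_cal, sim$y_cal))
  u_test <- project(model, sim$x_test)
  avg_bias2 <- vapply(1:5, function(a)
    mean(estimated_bias(u_test, model, ncomp = a)^2), numeric(1))
  expect_true(all(diff(avg_bias2) <= 1e-12))
})
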