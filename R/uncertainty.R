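#' Estimate the random-error variance from a high-rank fit
#'
#' Fits a PCR model with enough components that the residuals are expected
#' to carry no systematic analyte information and returns its MSEC
#' (component-based denominator). The default `a_noise = 50` is a deliberate
#' overshoot for typical NIR calibrations; when the data have lower rank the
#' request is capped at `rank - 1` with a warning.
#'
#' @param x,y Calibration spectra and reference values.
#' @param a_noise Requested number of components (default 50). Must leave
#'   positive residual degrees of freedom: `n - a_noise - 1 > 0`.
#' @return Scalar estimate of `sigma^2`, reference units squared.
#' @export
estimate_sigma2 <- function(x, y, a_noise = 50) {
  x <- as_matrix(x, "x")
  n <- nrow(x)
  if (n - a_noise - 1 <= 0) abort(sprintf(
    "a_noise = %d leaves no residual degrees of freedom with n = %d", a_noise, n))
  fit <- fit_pcr(x, y, ncomp = 1)
  a <- a_noise
  if (a > fit$m - 1) {
    a <- fit$m - 1
    warning(sprintf(
      "a_noise = %d exceeds retained rank %d; capped at %d", a_noise, fit$m, a))
  }
  if (a < 1) abort("retained rank too low to estimate the noise variance")
  msec(fit, x, y, ncomp = a, denominator = "ncomp")
}

#' Significance mask for score-space coefficients
#'
#' For each component up to `m_max`, regresses the centered reference values
#' on that score column alone (by orthonormality the slope equals the fitted
#' coefficient `g_m`) and flags the component when the two-sided t-test of
#' zero slope (residual degrees of freedom `n - 2`) rejects at level
#' `alpha`. Components beyond `m_max` are never flagged. The mask gates
#' which coefficients enter the omitted-component bias estimate — it does
#' not affect prediction.
#'
#' @param model A [fit_pcr()] model.
#' @param y The calibration reference values the model was fitted on.
#' @param alpha Two-sided significance level (default 0.01).
#' @param m_max Highest component tested (default 15; capped at the model
#'   rank with a warning).
#' @return Logical vector of length `model$m`.
#' @export
significant_components <- function(model, y, alpha = 0.01, m_max = 15) {
  stopifnot(inherits(model, "pcr_model"))
  n <- model$n
  if (n < 4) abort("need at least 4 samples for the slope t-test")
  if (m_max > model$m) {
    m_max <- model$m
    warning(sprintf("m_max exceeds retained rank; capped at %d", m_max))
  }
  yc <- y - model$y_mean
  ss_tot <- sum(yc^2)
  mask <- logical(model$m)
  if (ss_tot == 0) return(mask)  # all-zero (constant) y: nothing to flag
  for (mm in seq_len(m_max)) {
    g <- sum(model$scores[, mm] * yc)   # univariate slope, = g_hat for the fitted y
    ss_res <- max(ss_tot - g^2, 0)
    if (ss_res == 0) {           # perfect univariate fit, t -> infinity
      mask[mm] <- g != 0
    } else {
      tval <- g / sqrt(ss_res / (n - 2))
      mask[mm] <- 2 * pt(-abs(tval), df = n - 2) < alpha
    }
  }
  mask
}

#' Attach uncertainty parameters to a PCR model
#'
#' Convenience wrapper that estimates the noise variance
#' ([estimate_sigma2()]), computes the significance mask
#' ([significant_components()]), and stores both together with the bias
#' range on the model, after which [expected_squared_error()] and
#' [prediction_uncertainty()] can be used.
#'
#' @param model A [fit_pcr()] model.
#' @param x,y The calibration data the model was fitted on.
#' @param a_noise Components for the noise estimate (default 50, capped).
#' @param alpha Significance level for the coefficient mask (default 0.01).
#' @param m_max_bias Highest component entering the bias sum (default 15,
#'   capped at the model rank).
#' @return The model with `sigma2_hat`, `significance_mask` and
#'   `m_max_bias` filled in.
#' @export
calibrate_uncertainty <- function(model, x, y, a_noise = 50, alpha = 0.01,
                                  m_max_bias = 15) {
  stopifnot(inherits(model, "pcr_model"))
  model$sigma2_hat <- estimate_sigma2(x, y, a_noise = a_noise)
  if (m_max_bias > model$m) m_max_bias <- model$m
  model$significance_mask <- significant_components(model, y, alpha = alpha,
                                                    m_max = m_max_bias)
  model$m_max_bias <- as.integer(m_max_bias)
  model
}

#' Estimation-variance contribution at a score position
#'
#' `sigma2 / n + sigma2 * sum_{a <= ncomp} u_a^2`: the variance of the
#' fitted predictor at score position `u`, i.e. the noise variance times the
#' score-space leverage. Grows with distance from the calibration centroid
#' and with the number of components.
#'
#' @param u Score vector.
#' @param ncomp Components used in the prediction model.
#' @param sigma2 Random-error variance (positive).
#' @param n Calibration size.
#' @return Scalar, reference units squared.
#' @export
variance_contribution <- function(u, ncomp, sigma2, n) {
  if (ncomp < 1 || ncomp > length(u))
    abort(sprintf("'ncomp' = %d outside 1..%d (invalid rank)", ncomp, length(u)))
  if (sigma2 <= 0) abort("'sigma2' must be positive")
  sigma2 / n + sigma2 * sum(u[seq_len(ncomp)]^2)
}

#' Signed omitted-component bias at a score position
#'
#' `-sum u_m g_m` over the components beyond the prediction rank, up to
#' `m_max_bias`, restricted to components whose coefficient passed the
#' significance test. The value is signed (the squared bias enters the total
#' expected squared error); it is zero when the prediction rank already
#' covers the whole bias range.
#'
#' @param u Score vector.
#' @param model A [calibrate_uncertainty()]-prepared model (needs
#'   `significance_mask` and `m_max_bias`).
#' @param ncomp Prediction rank (default: the model's `ncomp`).
#' @return Scalar signed bias, reference units.
#' @export
bias_contribution <- function(u, model, ncomp = model$ncomp) {
  stopifnot(inherits(model, "pcr_model"))
  if (is.null(model$significance_mask) || is.null(model$m_max_bias))
    abort("model carries no significance mask; run calibrate_uncertainty() (or significant_components()) first")
  hi <- min(model$m_max_bias, model$m)
  if (ncomp >= hi) return(0)
  idx <- (ncomp + 1):hi
  idx <- idx[model$significance_mask[idx]]
  if (!length(idx)) return(0)
  -sum(u[idx] * model$g_hat[idx])
}

#' Sample-specific expected squared prediction error
#'
#' Assembles the full decomposition at score position `u`:
#' `total = sigma2 + (sigma2/n + sigma2 * sum u_a^2) + bias^2`, with the
#' signed omitted-component bias reported separately. The decomposition
#' identity holds exactly by construction.
#'
#' @param u Score vector (length `model$m`).
#' @param model A [calibrate_uncertainty()]-prepared model (needs
#'   `sigma2_hat`, `significance_mask`, `m_max_bias`).
#' @param ncomp Prediction rank (default: the model's `ncomp`).
#' @return An object of class `error_breakdown`: list with `sigma2`,
#'   `variance_term`, `bias_signed`, `total` (reference units squared;
#'   `bias_signed` in reference units).
#' @export
expected_squared_error <- function(u, model, ncomp = model$ncomp) {
  stopifnot(inherits(model, "pcr_model"))
  if (is.null(model$sigma2_hat))
    abort("model carries no sigma2_hat; run calibrate_uncertainty() first")
  v <- variance_contribution(u, ncomp, model$sigma2_hat, model$n)
  b <- bias_contribution(u, model, ncomp)
  structure(list(sigma2 = model$sigma2_hat, variance_term = v,
                 bias_signed = b, total = model$sigma2_hat + v + b^2),
            class = "error_breakdown")
}

#' @export
print.error_breakdown <- function(x, ...) {
  cat(sprintf(
    "Expected squared error %.4g = sigma2 %.4g + variance %.4g + bias^2 %.4g (bias %+.4g)\n",
    x$total, x$sigma2, x$variance_term, x$bias_signed^2, x$bias_signed))
  invisible(x)
}

#' Per-sample uncertainty table for new spectra
#'
#' Vectorized front end over [expected_squared_error()]: projects each new
#' spectrum, predicts it, and reports the full error decomposition together
#' with the leverage and the squared spectral residual (the two
#' representativeness diagnostics).
#'
#' @param model A [calibrate_uncertainty()]-prepared model.
#' @param x_new Spectra matrix (rows = samples) or a single spectrum.
#' @param ncomp Prediction rank (default: the model's `ncomp`).
#' @return A `data.frame` with columns `y_hat`, `sigma2`, `variance_term`,
#'   `bias_signed`, `expected_squared_error`, `leverage`,
#'   `spectral_residual`.
#' @export
prediction_uncertainty <- function(model, x_new, ncomp = model$ncomp) {
  stopifnot(inherits(model, "pcr_model"))
  u <- project(model, x_new)
  if (!is.matrix(u)) u <- matrix(u, nrow = 1)
  bd <- lapply(seq_len(nrow(u)), function(i)
    expected_squared_error(u[i, ], model, ncomp = ncomp))
  data.frame(
    y_hat = drop(model$y_mean +
                   u[, seq_len(ncomp), drop = FALSE] %*% model$g_hat[seq_len(ncomp)]),
    sigma2 = vapply(bd, `[[`, numeric(1), "sigma2"),
    variance_term = vapply(bd, `[[`, numeric(1), "variance_term"),
    bias_signed = vapply(bd, `[[`, numeric(1), "bias_signed"),
    expected_squared_error = vapply(bd, `[[`, numeric(1), "total"),
    leverage = leverage(model, u = u, ncomp = ncomp),
    spectral_residual = spectral_residual(model, x_new, ncomp = ncomp))
}

#' Expected squared prediction error for full-rank least squares
#'
#' The classical sample-specific formula
#' `sigma2 * (1 + 1/n + x' (X'X)^-1 x)` for an ordinary least-squares
#' calibration on full-column-rank predictors. Requires the centered
#' calibration matrix and a sample centered by the same means. For
#' collinear spectra (singular `X'X`) this is unusable — that is precisely
#' what the PCR decomposition is for — and a rank error says so.
#'
#' @param x Centered spectrum of the sample to predict (length `k`).
#' @param x_cal Centered calibration matrix, full column rank, `k < n`.
#' @param sigma2 Random-error variance.
#' @param n Calibration size (default `nrow(x_cal)`).
#' @return Scalar expected squared error.
#' @export
ols_expected_squared_error <- function(x, x_cal, sigma2, n = nrow(x_cal)) {
  x_cal <- as_matrix(x_cal, "x_cal")
  if (length(x) != ncol(x_cal)) abort("'x' length must match ncol(x_cal)")
  xtx <- crossprod(x_cal)
  sol <- tryCatch(solve(xtx, x), error = function(e) NULL)
  if (is.null(sol) || !all(is.finite(sol)))
    abort("X'X is singular (collinear spectra); use the PCR error decomposition instead")
  sigma2 * (1 + 1 / n + drop(crossprod(x, sol)))
}
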