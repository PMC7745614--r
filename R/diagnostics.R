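#' Least-squares-effect shrinkage line
#'
#' Even with exactly known model parameters, the conditional expectation of
#' a linear predictor given the true reference value is shrunk toward the
#' mean: `E(yhat | y) = slope * y` in centered coordinates, with
#' `slope = b' cov_xy / var_y`. Low reference values are overestimated and
#' high values underestimated whenever the slope is below one. This function
#' computes that line; for a fitted PCR model the coefficients and
#' covariances are taken in score space with plug-in sample estimates from
#' the calibration set.
#'
#' @param b Coefficient vector, or a [fit_pcr()] model (then supply `y`).
#' @param cov_xy Covariances between each predictor and `y` (same length as
#'   `b`); ignored for a model.
#' @param var_y Variance of `y` (positive); ignored for a model.
#' @param ... Passed between methods.
#' @return An object of class `shrinkage_line` with element `slope`; the
#'   line passes through the mean point, i.e. `yhat - mean = slope * (y -
#'   mean)`.
#' @examples
#' # univariate y = x + e with Var(x) = Var(e) = 1: slope = 1/2
#' least_squares_effect_line(1, cov_xy = 1, var_y = 2)$slope
#' @export
least_squares_effect_line <- function(b, ...) UseMethod("least_squares_effect_line")

#' @rdname least_squares_effect_line
#' @export
least_squares_effect_line.default <- function(b, cov_xy, var_y, ...) {
  if (var_y <= 0) abort("'var_y' must be positive")
  if (length(b) != length(cov_xy)) abort("'b' and 'cov_xy' must have equal length")
  structure(list(slope = sum(b * cov_xy) / var_y), class = "shrinkage_line")
}

#' @rdname least_squares_effect_line
#' @param y Calibration reference values (model method only).
#' @param ncomp Prediction rank (model method only).
#' @export
least_squares_effect_line.pcr_model <- function(b, y, ncomp = b$ncomp, ...) {
  model <- b
  yc <- y - model$y_mean
  a <- seq_len(ncomp)
  # sample covariances in score space: cov(u_a, y) = g_a / (n - 1)
  least_squares_effect_line(model$g_hat[a],
                            cov_xy = model$g_hat[a] / (model$n - 1),
                            var_y = sum(yc^2) / (model$n - 1))
}

#' @export
print.shrinkage_line <- function(x, ...) {
  cat(sprintf("Least-squares-effect line: yhat - mean = %.4g * (y - mean)\n", x$slope))
  invisible(x)
}

#' Loess tendency smoother
#'
#' Locally weighted polynomial regression (tricube weights, no robustness
#' iterations) for reading the average tendency out of a scatter. The fit
#' uses only the points marked in `included`, with the neighbourhood size
#' `floor(span * n_included)`; fitted values are returned at *all* input
#' abscissae, included or not.
#'
#' @param x,y Numeric vectors of equal length.
#' @param span Neighbourhood fraction in (0, 1] (default 0.5).
#' @param degree Local polynomial degree (default 2).
#' @param included Optional logical mask of points used in fitting
#'   (default: all).
#' @return An object of class `smoother_fit`: `eval_points` (sorted
#'   ascending), `fitted` (aligned with `eval_points`), `span`, `degree`,
#'   `included_mask` (aligned with `eval_points`), and `order` (the
#'   permutation mapping input order to `eval_points`).
#' @export
loess_fit <- function(x, y, span = 0.5, degree = 2, included = NULL) {
  if (length(x) != length(y)) abort("'x' and 'y' must have equal length")
  if (span <= 0 || span > 1) abort("'span' must be in (0, 1]")
  if (is.null(included)) included <- rep(TRUE, length(x))
  n_inc <- sum(included)
  if (n_inc < degree + 2) abort("too few included points for the local fit")
  if (floor(span * n_inc) < degree + 1)
    abort("span * n_included too small for the polynomial degree")
  dat <- data.frame(ab = x[included], ord_ = y[included])
  fit <- loess(ord_ ~ ab, data = dat, span = span, degree = degree,
               family = "gaussian",
               control = loess.control(surface = "direct"))
  ord <- order(x)
  fitted_all <- predict(fit, newdata = data.frame(ab = x[ord]))
  structure(list(eval_points = x[ord], fitted = as.numeric(fitted_all),
                 span = span, degree = degree,
                 included_mask = included[ord], order = ord),
            class = "smoother_fit")
}

#' Agreement between estimated and observed error quantities
#'
#' The validation protocol for a sample-specific error (or bias) estimate:
#' given the estimated values and the observed counterparts on a prediction
#' set, report the mean difference `observed - estimated`, the variance of
#' each vector, the Loess tendency of observed on estimated, and a single
#' summary slope — the straight-line fit to the Loess curve over the central
#' 90% of the estimated values (edges excluded to avoid end-effect
#' leverage). A slope near one means the estimate tracks the observed
#' tendency one-to-one.
#'
#' @param estimated Estimated per-sample values (abscissa).
#' @param observed Observed per-sample values (ordinate).
#' @param span,degree Loess parameters (defaults 0.5 and 2).
#' @param included Optional logical mask of samples used in the Loess fit.
#' @return An object of class `agreement_report`: `mean_diff`,
#'   `var_estimated`, `var_observed`, `loess` (a `smoother_fit`), `slope`
#'   (`NA` when the abscissa is degenerate), and `n`.
#' @export
agreement_report <- function(estimated, observed, span = 0.5, degree = 2,
                             included = NULL) {
  if (length(estimated) != length(observed))
    abort("'estimated' and 'observed' must have equal length")
  n <- length(estimated)
  if (n < 10) abort("need at least 10 samples for an agreement report")
  if (sd(estimated) < 1e-12) {
    return(structure(list(mean_diff = mean(observed - estimated),
                          var_estimated = var(estimated),
                          var_observed = var(observed),
                          loess = NULL, slope = NA_real_, n = n),
                     class = "agreement_report"))
  }
  lo <- loess_fit(estimated, observed, span = span, degree = degree,
                  included = included)
  qs <- quantile(lo$eval_points, c(0.05, 0.95), names = FALSE)
  sel <- lo$eval_points >= qs[1] & lo$eval_points <= qs[2]
  slope <- unname(coef(lm(lo$fitted[sel] ~ lo$eval_points[sel]))[2])
  structure(list(mean_diff = mean(observed - estimated),
                 var_estimated = var(estimated),
                 var_observed = var(observed),
                 loess = lo, slope = slope, n = n),
            class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  cat(sprintf("Agreement over %d samples: mean(obs - est) = %+.4g\n", x$n, x$mean_diff))
  cat(sprintf("  var(estimated) = %.4g, var(observed) = %.4g, tendency slope = %s\n",
              x$var_estimated, x$var_observed,
              if (is.na(x$slope)) "n/a (degenerate abscissa)" else sprintf("%.3f", x$slope)))
  invisible(x)
}
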