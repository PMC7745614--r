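#' Mean squared error of calibration (MSEC)
#'
#' Sum of squared fitted residuals divided by the residual degrees of
#' freedom. For PCR the default denominator is `n - ncomp - 1` (the number
#' of fitted score coefficients plus the mean); `denominator = "nvar"`
#' selects the classical full-rank convention `n - k - 1`, feasible only
#' when the channel count is small relative to `n`.
#'
#' @param model A [fit_pcr()] model.
#' @param x,y The calibration data the model was fitted on.
#' @param ncomp Components to evaluate at (default: the model's `ncomp`).
#' @param denominator `"ncomp"` (default) or `"nvar"`.
#' @return Scalar MSEC, reference units squared.
#' @export
msec <- function(model, x, y, ncomp = model$ncomp,
                 denominator = c("ncomp", "nvar")) {
  stopifnot(inherits(model, "pcr_model"))
  denominator <- match.arg(denominator)
  n <- model$n
  dof <- if (denominator == "ncomp") n - ncomp - 1 else n - model$k - 1
  if (dof <= 0) abort(sprintf(
    "nonpositive residual degrees of freedom (%d) for MSEC", dof))
  resid <- y - predict(model, x, ncomp = ncomp)
  sum(resid^2) / dof
}

#' Leave-one-out cross-validation error curve
#'
#' For each left-out sample the centering, the singular value decomposition,
#' and the score coefficients are refitted from scratch on the remaining
#' `n - 1` samples — no shortcut formulae — and the left-out sample is
#' predicted at every requested rank. The MSECV denominator is `n` (no
#' degrees-of-freedom correction). The corresponding MSEC values are
#' reported alongside, and MSEP when a test set is supplied.
#'
#' @param x Calibration spectra matrix.
#' @param y Calibration reference values.
#' @param ncomp_values Integer vector of ranks to evaluate;
#'   `max(ncomp_values) <= min(n - 2, k)`.
#' @param x_test,y_test Optional independent test set for an MSEP column.
#' @param denominator MSEC denominator convention, see [msec()].
#' @return A `data.frame` of class `validation_curves` with columns
#'   `component`, `msec`, `msecv` (and `msep` if a test set was given).
#' @export
loocv_curve <- function(x, y, ncomp_values = 1:10,
                        x_test = NULL, y_test = NULL,
                        denominator = c("ncomp", "nvar")) {
  denominator <- match.arg(denominator)
  x <- as_matrix(x, "x")
  n <- nrow(x)
  ncomp_values <- sort(unique(as.integer(ncomp_values)))
  a_max <- max(ncomp_values)
  if (a_max > min(n - 2, ncol(x))) abort(sprintf(
    "max ncomp (%d) too large for %d samples and %d channels", a_max, n, ncol(x)))
  sqerr <- matrix(NA_real_, n, length(ncomp_values))
  for (i in seq_len(n)) {
    fit <- fit_pcr(x[-i, , drop = FALSE], y[-i], ncomp = 1)
    if (a_max > fit$m) abort(sprintf(
      "rank %d of a leave-one-out fold is below max ncomp %d", fit$m, a_max))
    u <- project(fit, x[i, ])
    cum <- fit$y_mean + cumsum(u * fit$g_hat)
    sqerr[i, ] <- (cum[ncomp_values] - y[i])^2
  }
  full <- fit_pcr(x, y, ncomp = 1)
  out <- data.frame(
    component = ncomp_values,
    msec = vapply(ncomp_values, function(a)
      msec(full, x, y, ncomp = a, denominator = denominator), numeric(1)),
    msecv = colMeans(sqerr))
  if (!is.null(x_test)) {
    if (is.null(y_test)) abort("'y_test' required when 'x_test' is given")
    out$msep <- vapply(ncomp_values, function(a)
      msep(full, x_test, y_test, ncomp = a), numeric(1))
  }
  class(out) <- c("validation_curves", "data.frame")
  out
}

#' Mean squared error of prediction (MSEP)
#'
#' Mean of squared prediction errors over an independent test set
#' (denominator: the number of test samples).
#'
#' @param model A [fit_pcr()] model.
#' @param x_test,y_test Independent test spectra and reference values.
#' @param ncomp Components to use (default: the model's `ncomp`).
#' @return Scalar MSEP, reference units squared.
#' @export
msep <- function(model, x_test, y_test, ncomp = model$ncomp) {
  stopifnot(inherits(model, "pcr_model"))
  x_test <- as_matrix(x_test, "x_test")
  if (nrow(x_test) < 1) abort("empty test set")
  if (length(y_test) != nrow(x_test))
    abort("'y_test' must have one value per row of 'x_test'")
  mean((predict(model, x_test, ncomp = ncomp) - y_test)^2)
}
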