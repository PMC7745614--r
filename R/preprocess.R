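#' Savitzky-Golay derivative filtering of spectra
#'
#' Applies a Savitzky-Golay moving-window polynomial derivative filter to
#' each spectrum (row), the standard pre-treatment for removing baseline and
#' scatter effects from NIR absorbance spectra. Only the valid interior
#' region is returned — `window - 1` channels are dropped, half at each
#' edge — so every retained channel is governed by the same centered filter
#' and no edge values are extrapolated. The wavelength axis (taken from the
#' `"wavelengths"` attribute, if present) is trimmed to match so calibration
#' and prediction sets stay aligned.
#'
#' The derivative is per unit channel *index*; for an evenly spaced axis the
#' physical spacing only rescales the spectra by a constant, which the
#' regression absorbs.
#'
#' @param x Spectra matrix (rows = samples) or a single spectrum vector.
#' @param window Odd window length (default 21).
#' @param polyorder Polynomial order of the local fit (default 2).
#' @param deriv Derivative order, `deriv <= polyorder` (default 2).
#' @return Matrix of derivative spectra with `ncol(x) - window + 1` columns
#'   and a trimmed `"wavelengths"` attribute.
#' @examples
#' x <- matrix(seq(0, 29)^2, nrow = 1)   # quadratic ramp
#' savgol_derivative(x)                  # exactly 2 everywhere
#' @export
savgol_derivative <- function(x, window = 21, polyorder = 2, deriv = 2) {
  vec_in <- is.vector(x) && is.numeric(x)
  x <- as_matrix(x, "x")
  check_finite(x, "x")
  k <- ncol(x)
  if (window %% 2 != 1) abort("'window' must be odd (invalid parameter)")
  if (!(deriv <= polyorder && polyorder < window))
    abort("need deriv <= polyorder < window (invalid parameter)")
  if (k < window) abort(sprintf(
    "too few channels: %d columns but window = %d", k, window))
  # Center row of the sgolay projection matrix = the symmetric FIR filter
  # for the requested derivative, already scaled per unit channel step.
  co <- signal::sgolay(p = polyorder, n = window, m = deriv)
  filt <- co[(window + 1) / 2, ]
  h <- (window - 1) / 2
  cols <- (h + 1):(k - h)
  out <- t(apply(x, 1, function(row)
    vapply(cols, function(i) sum(filt * row[(i - h):(i + h)]), numeric(1))))
  if (nrow(x) == 1) out <- matrix(out, nrow = 1)
  wl <- attr(x, "wavelengths")
  if (!is.null(wl)) attr(out, "wavelengths") <- wl[cols]
  if (vec_in) drop(out) else out
}

#' Column mean-centering with reusable means
#'
#' Centers spectra (or any numeric matrix) column-wise. In calibration mode
#' (`means = NULL`) the column means are computed and returned; in
#' prediction mode the supplied calibration means are subtracted instead, so
#' new samples are centered *according to the calibration set*.
#'
#' @param x Numeric matrix, rows = samples.
#' @param means Optional length-`ncol(x)` vector of means to apply.
#' @return List with `values` (centered matrix, attributes preserved) and
#'   `means` (the vector used).
#' @export
center_columns <- function(x, means = NULL) {
  x <- as_matrix(x, "x")
  check_finite(x, "x")
  if (is.null(means)) {
    means <- colMeans(x)
  } else if (length(means) != ncol(x)) {
    abort(sprintf("'means' has length %d but x has %d columns (invalid dimension)",
                  length(means), ncol(x)))
  }
  out <- sweep(x, 2, means, "-")
  attr(out, "wavelengths") <- attr(x, "wavelengths")
  list(values = out, means = as.numeric(means))
}
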