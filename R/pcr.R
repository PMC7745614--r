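#' Fit a principal component regression model
#'
#' Centers the spectra and the reference values by their calibration means,
#' takes the singular value decomposition of the centered spectra
#' `X = U S P'`, and regresses the centered reference values on the
#' orthonormal score columns. Because the scores are orthonormal the
#' least-squares coefficients are simply `g_m = u_m' y`; they are estimated
#' for *all* retained components, not just the `ncomp` used for prediction,
#' because the omitted-component bias formula needs coefficients beyond the
#' prediction rank.
#'
#' Rank is truncated at singular values below `1e-10` times the largest.
#' Loading signs follow a fixed convention — the largest-magnitude element
#' of each loading column is made positive (ties broken at the lowest
#' channel index) — so refits are bitwise reproducible.
#'
#' @param x Calibration spectra, `n x k` numeric matrix (rows = samples).
#' @param y Numeric reference values, length `n`.
#' @param ncomp Number of components `A` used for prediction,
#'   `1 <= ncomp <=` retained rank.
#' @return An object of class `pcr_model` with elements `x_mean`, `y_mean`,
#'   `loadings` (`k x m`), `singular_values`, `scores` (`n x m`,
#'   orthonormal), `g_hat`, `ncomp`, `n`, `k`, `m`, and placeholders
#'   `sigma2_hat`, `significance_mask`, `m_max_bias` filled by
#'   [calibrate_uncertainty()].
#' @seealso [project()], [predict.pcr_model()], [loocv_curve()],
#'   [calibrate_uncertainty()]
#' @export
fit_pcr <- function(x, y, ncomp) {
  x <- as_matrix(x, "x")
  check_finite(x, "x")
  check_finite(y, "y")
  n <- nrow(x)
  k <- ncol(x)
  if (length(y) != n) abort("'y' must have one value per row of 'x'")
  if (n < 2) abort("need at least 2 calibration samples")
  x_mean <- colMeans(x)
  y_mean <- mean(y)
  xc <- sweep(x, 2, x_mean, "-")
  sv <- svd(xc)
  m <- sum(sv$d > 1e-10 * sv$d[1])
  if (m < 1) abort("centered spectra have rank 0")
  if (ncomp < 1 || ncomp > m)
    abort(sprintf("'ncomp' = %d outside the retained rank 1..%d", ncomp, m))
  p <- sv$v[, seq_len(m), drop = FALSE]
  u <- sv$u[, seq_len(m), drop = FALSE]
  flip <- apply(p, 2, function(col) col[which.max(abs(col))] < 0)
  p[, flip] <- -p[, flip, drop = FALSE]
  u[, flip] <- -u[, flip, drop = FALSE]
  g_hat <- drop(crossprod(u, y - y_mean))
  structure(list(x_mean = x_mean, y_mean = y_mean,
                 loadings = p, singular_values = sv$d[seq_len(m)],
                 scores = u, g_hat = g_hat,
                 ncomp = as.integer(ncomp), n = n, k = k, m = m,
                 wavelengths = attr(x, "wavelengths"),
                 sigma2_hat = NULL, significance_mask = NULL,
                 m_max_bias = NULL),
            class = "pcr_model")
}

#' Project new spectra into the calibration score space
#'
#' Centers each new spectrum by the calibration means and projects it onto
#' `P S^-1`, giving its coordinates `u` in the orthonormal score basis of
#' the calibration SVD. A calibration row projects back onto its own score
#' row.
#'
#' @param model A [fit_pcr()] model.
#' @param x_new A length-`k` spectrum or an `n x k` matrix of spectra.
#' @return A score vector (for a single spectrum) or matrix with one row per
#'   sample and `model$m` columns.
#' @export
project <- function(model, x_new) {
  stopifnot(inherits(model, "pcr_model"))
  vec_in <- is.vector(x_new) && is.numeric(x_new)
  x_new <- as_matrix(x_new, "x_new")
  if (ncol(x_new) != model$k)
    abort(sprintf("'x_new' has %d channels; model expects %d (invalid dimension)",
                  ncol(x_new), model$k))
  xc <- sweep(x_new, 2, model$x_mean, "-")
  u <- sweep(xc %*% model$loadings, 2, model$singular_values, "/")
  if (vec_in) drop(u) else u
}

#' Predict reference values for new spectra
#'
#' `yhat = y_mean + sum_{a <= ncomp} u_a g_a`: the calibration mean of the
#' reference values plus the truncated score expansion.
#'
#' @param object A [fit_pcr()] model.
#' @param x_new Spectrum vector or spectra matrix.
#' @param ncomp Components to use (default: the model's `ncomp`).
#' @param ... Unused.
#' @return Numeric vector of predictions.
#' @export
predict.pcr_model <- function(object, x_new, ncomp = object$ncomp, ...) {
  if (ncomp < 1 || ncomp > object$m)
    abort(sprintf("'ncomp' = %d outside 1..%d", ncomp, object$m))
  u <- project(object, x_new)
  u <- if (is.matrix(u)) u[, seq_len(ncomp), drop = FALSE] else
    matrix(u[seq_len(ncomp)], nrow = 1)
  drop(object$y_mean + u %*% object$g_hat[seq_len(ncomp)])
}

#' Squared spectral reconstruction residual
#'
#' Squared norm of a centered spectrum minus its rank-`ncomp`
#' reconstruction `sum_{a <= ncomp} u_a s_a p_a`. Large values flag samples
#' whose spectra are not well described by the calibration subspace — a
#' representativeness diagnostic used together with [leverage()].
#'
#' @param model A [fit_pcr()] model.
#' @param x_new Spectrum vector or spectra matrix.
#' @param ncomp Reconstruction rank (default: the model's `ncomp`).
#' @return Nonnegative residual(s), squared spectral units.
#' @export
spectral_residual <- function(model, x_new, ncomp = model$ncomp) {
  stopifnot(inherits(model, "pcr_model"))
  if (ncomp < 1 || ncomp > model$m)
    abort(sprintf("'ncomp' = %d outside 1..%d", ncomp, model$m))
  vec_in <- is.vector(x_new) && is.numeric(x_new)
  x_new <- as_matrix(x_new, "x_new")
  xc <- sweep(x_new, 2, model$x_mean, "-")
  u <- project(model, x_new)
  if (!is.matrix(u)) u <- matrix(u, nrow = 1)
  a <- seq_len(ncomp)
  recon <- sweep(u[, a, drop = FALSE], 2, model$singular_values[a], "*") %*%
    t(model$loadings[, a, drop = FALSE])
  res <- rowSums((xc - recon)^2)
  if (vec_in) unname(res[1]) else unname(res)
}

#' Score-space leverage of new samples
#'
#' `1/n + sum_{a <= ncomp} u_a^2`: the hat-matrix diagonal of the
#' score-space regression, measuring distance from the calibration centroid
#' within the model space. Scaled by the noise variance it *is* the
#' estimation-variance term of the error decomposition.
#'
#' @param model A [fit_pcr()] model.
#' @param x_new Spectrum vector or spectra matrix (alternatively supply
#'   precomputed scores via `u`).
#' @param ncomp Components to use (default: the model's `ncomp`).
#' @param u Optional precomputed score vector/matrix, bypassing projection.
#' @return Numeric leverage value(s).
#' @export
leverage <- function(model, x_new = NULL, ncomp = model$ncomp, u = NULL) {
  stopifnot(inherits(model, "pcr_model"))
  if (is.null(u)) u <- project(model, x_new)
  if (!is.matrix(u)) u <- matrix(u, nrow = 1)
  drop(1 / model$n + rowSums(u[, seq_len(ncomp), drop = FALSE]^2))
}

#' @export
print.pcr_model <- function(x, ...) {
  cat(sprintf("PCR model: %d samples x %d channels, rank %d, using %d component%s\n",
              x$n, x$k, x$m, x$ncomp, if (x$ncomp > 1) "s" else ""))
  if (!is.null(x$sigma2_hat))
    cat(sprintf("  sigma2_hat = %.4g; %d significant component(s) in bias range <= %d\n",
                x$sigma2_hat, sum(x$significance_mask), x$m_max_bias))
  invisible(x)
}
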