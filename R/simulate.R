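#' Smooth orthonormal spectral loadings
#'
#' Generates a `k x m` orthonormal matrix whose columns are smooth functions
#' of channel index, emulating the broad-band loadings typical of NIR
#' spectra. Each column starts as a sum of random Gaussian bumps; the set is
#' then orthonormalized by QR and sign-fixed so that the largest-magnitude
#' element of every column is positive (ties broken at the lowest channel).
#'
#' @param k Number of spectral channels.
#' @param m Number of components, `1 <= m <= k`.
#' @param smoothness Bump width in channel units; larger values give smoother
#'   loadings. Must be positive.
#' @param seed Integer seed; the result is deterministic given `seed`.
#' @return A `k x m` matrix with orthonormal columns.
#' @examples
#' P <- generate_loadings(85, 15, smoothness = 5, seed = 1)
#' max(abs(crossprod(P) - diag(15)))  # ~1e-16
#' @export
generate_loadings <- function(k, m, smoothness = 5, seed = 1) {
  if (m < 1 || m > k) abort("'m' must satisfy 1 <= m <= k (invalid dimension)")
  if (smoothness <= 0) abort("'smoothness' must be positive")
  with_seed(seed, {
    t_idx <- seq_len(k)
    n_bumps <- 8L
    raw <- vapply(seq_len(m), function(j) {
      centers <- runif(n_bumps, 1, k)
      amps <- rnorm(n_bumps)
      widths <- smoothness * runif(n_bumps, 0.6, 1.6)
      bumps <- vapply(seq_len(n_bumps), function(b)
        amps[b] * exp(-((t_idx - centers[b])^2) / (2 * widths[b]^2)),
        numeric(k))
      rowSums(matrix(bumps, nrow = k))
    }, numeric(k))
    raw <- matrix(raw, nrow = k)
    qrd <- qr(raw)
    if (qrd$rank < m) abort("degenerate bump draw; loadings rank-deficient")
    fix_column_signs(qr.Q(qrd))
  })
}

# Sign convention shared with fit_pcr: largest-|.| element of each column
# positive; which.max takes the first (lowest-index) maximum on ties.
fix_column_signs <- function(p) {
  flip <- apply(p, 2, function(col) col[which.max(abs(col))] < 0)
  p[, flip] <- -p[, flip, drop = FALSE]
  p
}

#' Ground truth for a synthetic calibration scenario
#'
#' Bundles the generative parameters of the bilinear spectra model: smooth
#' orthonormal channel loadings, latent score standard deviations, and the
#' score-space regression law `y = g0 + u g + e` with `Var(e) = sigma2_y`.
#' Coefficients `g_true` are expressed in the orthonormal score basis of the
#' calibration set (the basis a singular value decomposition of the centered
#' calibration spectra recovers when `sigma2_x = 0`).
#'
#' @param loadings `k x m` orthonormal matrix of channel loadings.
#' @param score_sd Strictly decreasing positive vector of latent score
#'   standard deviations (one per component); the ordering guarantees the
#'   SVD recovers components in generative order.
#' @param g_true Length-`m` score-space regression coefficients
#'   (reference units per orthonormal score unit).
#' @param g0_true Scalar offset (reference units).
#' @param sigma2_y Positive variance of the random error on `y`.
#' @param sigma2_x Nonnegative per-channel spectral noise variance. Zero (the
#'   default) keeps the error formula's errorless-spectra assumption exact.
#' @param seed Integer recorded for provenance (the seed used to build
#'   `loadings`).
#' @return An object of class `simulation_truth`.
#' @export
simulation_truth <- function(loadings, score_sd, g_true, g0_true = 0,
                             sigma2_y = 0.25, sigma2_x = 0, seed = NA_integer_) {
  loadings <- as_matrix(loadings, "loadings")
  m <- ncol(loadings)
  if (max(abs(crossprod(loadings) - diag(m))) > 1e-10)
    abort("'loadings' columns must be orthonormal (to 1e-10)")
  if (length(score_sd) != m || any(score_sd <= 0) || any(diff(score_sd) >= 0))
    abort("'score_sd' must be positive and strictly decreasing, one per component")
  if (length(g_true) != m) abort("'g_true' must have one coefficient per component")
  if (sigma2_y < 0) abort("'sigma2_y' must be nonnegative")
  if (sigma2_x < 0) abort("'sigma2_x' must be nonnegative")
  structure(list(loadings = loadings, score_sd = as.numeric(score_sd),
                 g_true = as.numeric(g_true), g0_true = g0_true,
                 sigma2_y = sigma2_y, sigma2_x = sigma2_x, seed = seed),
            class = "simulation_truth")
}

#' Standard NIR-like simulation scenario
#'
#' The package's reference scenario: 85 channels (860-1028 nm at 2 nm),
#' 15 latent components with geometrically decaying score scale, five
#' dominant analyte components, and (optionally) three minor informative
#' components beyond the usual model rank. The minor components are what
#' creates a nonzero omitted-component bias in a five-component model; they
#' are sized to be reliably detectable by the univariate significance test
#' at `alpha = 0.01` with 100 calibration samples.
#'
#' @param k Channel count.
#' @param m Component count (at least 5; at least 8 with `tail_signal`).
#' @param tail_signal If `TRUE` (default) components 6-8 carry minor signal
#'   (coefficients 6.5, 6, 5.5); if `FALSE` only components 1-5 are
#'   informative ("strong-signal" scenario).
#' @param sigma2_y Random-error variance of the reference values.
#' @param sigma2_x Spectral noise variance (default 0).
#' @param seed Seed for the loading shapes.
#' @return A [simulation_truth()] object.
#' @export
nir_truth <- function(k = 85, m = 15, tail_signal = TRUE,
                      sigma2_y = 0.25, sigma2_x = 0, seed = 1) {
  if (m < (if (tail_signal) 8 else 5)) abort("'m' too small for this scenario")
  g <- numeric(m)
  g[1:5] <- c(9, 8, 7, 6, 5)
  if (tail_signal) g[6:8] <- c(6.5, 6, 5.5)
  simulation_truth(loadings = generate_loadings(k, m, smoothness = 5, seed = seed),
                   score_sd = 1.5 * 0.78^(seq_len(m) - 1),
                   g_true = g, g0_true = 12,
                   sigma2_y = sigma2_y, sigma2_x = sigma2_x, seed = seed)
}

#' Simulate calibration and test spectra with known truth
#'
#' Draws latent calibration scores with standard deviations
#' `truth$score_sd`, centers and exactly orthogonalizes them (QR), and
#' rescales the orthonormal columns to singular values
#' `score_sd * sqrt(n - 1)` before mapping through the loadings. With
#' `sigma2_x = 0` the centered calibration spectra then have exactly the SVD
#' `X = U S P'` with `P = truth$loadings`, so the generative score basis and
#' the fitted basis coincide (up to the shared sign convention) and
#' `truth$g_true` is directly comparable with fitted coefficients.
#' Reference values follow `y = g0 + u g + e` in that orthonormal basis.
#'
#' Draw order under the single seed is fixed and documented: calibration
#' scores, calibration y-noise, test scores, test y-noise, then (only when
#' `sigma2_x > 0`) spectral noise — so switching spectral noise on never
#' shifts the other streams.
#'
#' @param truth A [simulation_truth()] object.
#' @param n Calibration size, at least `m + 2`.
#' @param n_test Test-set size, at least 1.
#' @param seed Integer seed; datasets are bitwise reproducible.
#' @return An object of class `pcr_simulation`: `x_cal`, `y_cal`, `x_test`,
#'   `y_test` (matrices carry a `"wavelengths"` attribute), `truth`, and
#'   `true_test_scores` — the noise-free test scores expressed in the
#'   calibration SVD basis (the `u` of the error formula).
#' @export
simulate_dataset <- function(truth, n = 100, n_test = 423, seed = 1) {
  stopifnot(inherits(truth, "simulation_truth"))
  m <- length(truth$score_sd)
  k <- nrow(truth$loadings)
  if (n <= m + 1) abort(sprintf(
    "calibration size n = %d too small for %d components (rank deficiency); need n >= m + 2", n, m))
  if (n_test < 1) abort("'n_test' must be at least 1")
  with_seed(seed, {
    t_cal <- sweep(matrix(rnorm(n * m), n, m), 2, truth$score_sd, "*")
    e_cal <- rnorm(n, 0, sqrt(truth$sigma2_y))
    t_test <- sweep(matrix(rnorm(n_test * m), n_test, m), 2, truth$score_sd, "*")
    e_test <- rnorm(n_test, 0, sqrt(truth$sigma2_y))

    # Exact orthogonal calibration scores in the generative basis.
    t_cal <- scale(t_cal, scale = FALSE)
    qrd <- qr(t_cal)
    if (qrd$rank < m) abort("degenerate score draw (rank deficiency)")
    u_cal <- qr.Q(qrd)
    sing <- truth$score_sd * sqrt(n - 1)
    x_cal <- u_cal %*% (sing * t(truth$loadings))
    x_test <- t_test %*% t(truth$loadings)
    u_test <- sweep(t_test, 2, sing, "/")

    y_cal <- truth$g0_true + drop(u_cal %*% truth$g_true) + e_cal
    y_test <- truth$g0_true + drop(u_test %*% truth$g_true) + e_test

    if (truth$sigma2_x > 0) {
      x_cal <- x_cal + matrix(rnorm(n * k, 0, sqrt(truth$sigma2_x)), n, k)
      x_test <- x_test + matrix(rnorm(n_test * k, 0, sqrt(truth$sigma2_x)), n_test, k)
    }
    wl <- default_wavelengths(k)
    attr(x_cal, "wavelengths") <- wl
    attr(x_test, "wavelengths") <- wl
    structure(list(x_cal = x_cal, y_cal = y_cal,
                   x_test = x_test, y_test = y_test,
                   truth = truth, true_test_scores = u_test, seed = seed),
              class = "pcr_simulation")
  })
}

#' Monte-Carlo oracle for the expected squared prediction error
#'
#' Brute-force estimate of `E(yhat - y)^2` for a new sample at score
#' position `u`, conditioning on a fixed calibration spectra matrix. Each
#' replicate redraws the calibration reference values from the generative
#' law `y = g0 + U g + e`, refits the `ncomp`-component score regression
#' (mean plus orthonormal-score coefficients), predicts the sample at `u`,
#' redraws that sample's own reference value, and accumulates the squared
#' error. This estimates, independently of any formula, the quantity the
#' analytical error decomposition claims to compute.
#'
#' @param truth A [simulation_truth()] object (supplies `g_true`, `g0_true`,
#'   `sigma2_y` in the calibration SVD basis; requires `sigma2_x = 0`
#'   semantics, i.e. `x_cal` built from the same truth without spectral
#'   noise).
#' @param x_cal Fixed calibration spectra (`n x k`), held constant across
#'   replicates.
#' @param u Score vector of the sample to predict (length = retained rank).
#' @param ncomp Components used in the prediction model.
#' @param reps Number of Monte-Carlo replicates, at least 100.
#' @param seed Integer seed.
#' @return List with `estimate` (mean squared error over replicates), `se`
#'   (its Monte-Carlo standard error), and `reps`.
#' @export
monte_carlo_expected_error <- function(truth, x_cal, u, ncomp,
                                       reps = 5000, seed = 1) {
  stopifnot(inherits(truth, "simulation_truth"))
  if (reps < 100) abort("'reps' must be at least 100")
  x_cal <- as_matrix(x_cal, "x_cal")
  n <- nrow(x_cal)
  xc <- scale(x_cal, scale = FALSE)
  sv <- svd(xc)
  m <- sum(sv$d > 1e-10 * sv$d[1])
  if (ncomp > m) abort(sprintf("'ncomp' = %d exceeds the rank (%d) of 'x_cal'", ncomp, m))
  if (length(u) != m) abort(sprintf("'u' must have length %d (retained rank)", m))
  p <- sv$v[, seq_len(m), drop = FALSE]
  flip <- apply(p, 2, function(col) col[which.max(abs(col))] < 0)
  uu <- sv$u[, seq_len(m), drop = FALSE]
  uu[, flip] <- -uu[, flip, drop = FALSE]
  g <- truth$g_true
  if (length(g) != m) abort("truth dimension does not match the rank of 'x_cal'")
  sdy <- sqrt(truth$sigma2_y)
  a <- seq_len(ncomp)
  with_seed(seed, {
    e_cal <- matrix(rnorm(reps * n, 0, sdy), reps, n)
    e_new <- rnorm(reps, 0, sdy)
    # ghat_r = g + U' e_r ; ybar_r = g0 + mean(e_r)  (U columns are centered)
    ghat_dev <- e_cal %*% uu[, a, drop = FALSE]       # reps x ncomp
    yhat <- truth$g0_true + rowMeans(e_cal) +
      drop(ghat_dev %*% u[a]) + sum(u[a] * g[a])
    y_new <- truth$g0_true + sum(u * g) + e_new
    sq <- (yhat - y_new)^2
    list(estimate = mean(sq), se = stats::sd(sq) / sqrt(reps), reps = reps)
  })
}

#' @export
print.simulation_truth <- function(x, ...) {
  cat(sprintf("Simulation truth: %d channels, %d components, %d informative\n",
              nrow(x$loadings), length(x$score_sd), sum(x$g_true != 0)))
  cat(sprintf("  sigma2_y = %g, sigma2_x = %g, g0 = %g\n",
              x$sigma2_y, x$sigma2_x, x$g0_true))
  invisible(x)
}

#' @export
print.pcr_simulation <- function(x, ...) {
  cat(sprintf("Synthetic spectra: %d calibration / %d test samples, %d channels\n",
              nrow(x$x_cal), nrow(x$x_test), ncol(x$x_cal)))
  invisible(x)
}
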