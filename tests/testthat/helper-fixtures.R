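# Shared fixtures, built in code at test time.

# Small low-rank scenario for fast exact checks.
small_truth <- function(k = 20, m = 4, g = c(5, 4, 3, 2), sigma2_y = 1,
                        sigma2_x = 0, seed = 2) {
  simulation_truth(loadings = generate_loadings(k, m, smoothness = 3, seed = seed),
                   score_sd = 2 * 0.7^(seq_len(m) - 1),
                   g_true = g, g0_true = 3,
                   sigma2_y = sigma2_y, sigma2_x = sigma2_x, seed = seed)
}

# A fitted model whose error-formula inputs are the *true* generative
# parameters: coefficients, noise variance, an all-pass significance mask.
# Used to compare the analytical decomposition against the Monte-Carlo
# oracle without estimation noise.
true_parameter_model <- function(sim, ncomp) {
  model <- fit_pcr(sim$x_cal, sim$y_cal, ncomp = ncomp)
  model$g_hat <- sim$truth$g_true
  model$sigma2_hat <- sim$truth$sigma2_y
  model$significance_mask <- rep(TRUE, model$m)
  model$m_max_bias <- model$m
  model
}

# True conditional omitted-component bias of each test sample, from the
# generative coefficients (the quantity the estimated bias targets).
true_test_bias <- function(sim, ncomp) {
  m <- length(sim$truth$g_true)
  drop(-sim$true_test_scores[, (ncomp + 1):m, drop = FALSE] %*%
         sim$truth$g_true[(ncomp + 1):m])
}

# Estimated signed bias for every row of a score matrix.
estimated_bias <- function(u_mat, model, ncomp = model$ncomp) {
  vapply(seq_len(nrow(u_mat)), function(i)
    bias_contribution(u_mat[i, ], model, ncomp = ncomp), numeric(1))
}

# Self-cleaning temporary directory for CLI tests.
withr_local_tempdir <- function(env = parent.frame()) {
  d <- tempfile("pcruq")
  dir.create(d)
  withr::defer(unlink(d, recursive = TRUE), envir = env)
  d
}
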