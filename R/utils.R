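# Internal helpers shared across modules.

# Stop with a consistent error class so callers (and the CLI) can map
# validation failures to exit status 2.
abort <- function(msg, class = "pcruq_error") {
  stop(structure(class = c(class, "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

check_finite <- function(x, name) {
  if (!all(is.finite(x))) abort(sprintf("'%s' contains non-finite values", name))
  invisible(x)
}

as_matrix <- function(x, name = deparse(substitute(x))) {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (is.vector(x) && is.numeric(x)) x <- matrix(x, nrow = 1)
  if (!is.matrix(x) || !is.numeric(x)) abort(sprintf("'%s' must be a numeric matrix", name))
  x
}

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# RNG stream (the global .Random.seed is saved and restored).
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Default wavelength axis for simulated spectra: NIR channels at 2 nm.
default_wavelengths <- function(k) seq(860, by = 2, length.out = k)

wavelengths_of <- function(x, k = ncol(x)) {
  wl <- attr(x, "wavelengths")
  if (is.null(wl)) default_wavelengths(k) else wl
}
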