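# CSV and JSON serialization for the command-line pipeline.
# CSV dialect: comma separator, "." decimal, header row; spectra files carry
# wavelength labels as column names, reference files a single "y" column.

#' Read a spectra matrix from CSV
#'
#' Expects the package CSV dialect: one row per sample, a header row of
#' wavelength labels, comma-separated, `.` decimal.
#'
#' @param path File path.
#' @return Numeric matrix with a `"wavelengths"` attribute parsed from the
#'   header (sequential indices when the header is not numeric).
#' @export
read_spectra_csv <- function(path) {
  if (!file.exists(path)) abort(sprintf("input file '%s' not found", path))
  df <- read.csv(path, check.names = FALSE)
  x <- as.matrix(df)
  storage.mode(x) <- "double"
  wl <- suppressWarnings(as.numeric(colnames(x)))
  attr(x, "wavelengths") <- if (anyNA(wl)) seq_len(ncol(x)) else wl
  dimnames(x) <- NULL
  check_finite(x, path)
  x
}

#' Write a spectra matrix to CSV
#'
#' @param x Numeric matrix (optionally with a `"wavelengths"` attribute used
#'   for the header).
#' @param path Output file path.
#' @export
write_spectra_csv <- function(x, path) {
  wl <- wavelengths_of(x)
  df <- as.data.frame(x)
  names(df) <- format(wl, trim = TRUE)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a reference-value vector from CSV
#' @param path File path (single-column CSV with header).
#' @return Numeric vector.
#' @export
read_reference_csv <- function(path) {
  if (!file.exists(path)) abort(sprintf("input file '%s' not found", path))
  df <- read.csv(path)
  y <- as.numeric(df[[1]])
  check_finite(y, path)
  y
}

#' Write a reference-value vector to CSV
#' @param y Numeric vector.
#' @param path Output file path.
#' @export
write_reference_csv <- function(y, path) {
  write.csv(data.frame(y = y), path, row.names = FALSE)
  invisible(path)
}

#' Serialize a fitted PCR model to JSON
#'
#' All model fields, matrices as nested arrays; round-trips through
#' [read_model_json()].
#'
#' @param model A [fit_pcr()] (optionally
#'   [calibrate_uncertainty()]-prepared) model.
#' @param path Output file path.
#' @export
write_model_json <- function(model, path) {
  stopifnot(inherits(model, "pcr_model"))
  jsonlite::write_json(unclass(model), path, auto_unbox = TRUE, digits = NA,
                       null = "null", matrix = "rowmajor")
  invisible(path)
}

#' Read a PCR model back from JSON
#' @param path File written by [write_model_json()].
#' @return A `pcr_model` object.
#' @export
read_model_json <- function(path) {
  if (!file.exists(path)) abort(sprintf("input file '%s' not found", path))
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (f in c("loadings", "scores")) obj[[f]] <- as.matrix(obj[[f]])
  for (f in c("ncomp", "n", "k", "m", "m_max_bias"))
    if (!is.null(obj[[f]])) obj[[f]] <- as.integer(obj[[f]])
  if (!is.null(obj$significance_mask))
    obj$significance_mask <- as.logical(obj$significance_mask)
  structure(obj, class = "pcr_model")
}

# Truth serialization for the simulate subcommand.
write_truth_json <- function(truth, path) {
  jsonlite::write_json(unclass(truth), path, auto_unbox = TRUE, digits = NA,
                       null = "null", matrix = "rowmajor")
  invisible(path)
}
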