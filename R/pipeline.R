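#' Run the derivative synchronous pipeline on one EEM
#'
#' Convenience chain: synchronous extraction at `delta_lambda` followed by the
#' Savitzky-Golay first derivative. These defaults are the production
#' settings of the assay (offset 50 nm, 9-point cubic derivative).
#'
#' @param x An [eem].
#' @param delta_lambda Scan offset (nm), default 50.
#' @param window_points,poly_order Derivative filter settings (defaults 9, 3).
#' @return A `deriv_spectrum`.
#' @export
derivative_pipeline <- function(x, delta_lambda = 50, window_points = 9,
                                poly_order = 3) {
  savgol_first_derivative(extract_synchronous(x, delta_lambda),
                          window_points = window_points,
                          poly_order = poly_order)
}

#' Measure the derivative amplitude of an EEM at a readout wavelength
#'
#' @param x An [eem] (optionally blank-subtracted beforehand).
#' @param wavelength Readout wavelength (nm).
#' @inheritParams derivative_pipeline
#' @return Signed amplitude (intensity / nm).
#' @export
measure_amplitude <- function(x, wavelength, delta_lambda = 50,
                              window_points = 9, poly_order = 3) {
  amplitude_at(derivative_pipeline(x, delta_lambda, window_points,
                                   poly_order), wavelength)
}

#' Calibrate from a simulated (or measured) series
#'
#' Measures the derivative amplitude of every EEM in a calibration series at
#' the analytical wavelength and fits the calibration line.
#'
#' @param series Tibble with columns `concentration` and list-column `eem`
#'   (as returned by [make_calibration_series()]).
#' @param wavelength Analytical readout wavelength (nm).
#' @param analyte Analyte label.
#' @param blank Optional blank [eem] subtracted from every series member
#'   before measurement.
#' @inheritParams derivative_pipeline
#' @return A `fluor_calibration`.
#' @export
calibrate_series <- function(series, wavelength, analyte = "A", blank = NULL,
                             delta_lambda = 50, window_points = 9,
                             poly_order = 3) {
  amps <- purrr::map_dbl(series$eem, function(e) {
    if (!is.null(blank)) e <- e - blank
    measure_amplitude(e, wavelength, delta_lambda, window_points, poly_order)
  })
  fit_calibration(
    tibble::tibble(concentration = series$concentration, amplitude = amps),
    concentration, amplitude, analyte = analyte, wavelength = wavelength)
}

#' Quantify an EEM against a persisted calibration
#'
#' Runs the full readout (synchronous extraction, derivative, amplitude at
#' the calibration's wavelength) and inverts the calibration line.
#'
#' @param x An [eem].
#' @param model A `fluor_calibration` with a stored wavelength.
#' @param blank Optional blank [eem] subtracted before measurement.
#' @inheritParams derivative_pipeline
#' @return A one-row tibble: `amplitude`, `concentration` (ng/mL), `flag`.
#' @export
quantify_eem <- function(x, model, blank = NULL, delta_lambda = 50,
                         window_points = 9, poly_order = 3) {
  stopifnot(inherits(model, "fluor_calibration"))
  if (is.na(model$wavelength)) {
    stop("The calibration carries no readout wavelength.", call. = FALSE)
  }
  if (!is.null(blank)) x <- x - blank
  amp <- measure_amplitude(x, model$wavelength, delta_lambda, window_points,
                           poly_order)
  predict_concentration(model, amp)
}
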