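#' Fit a linear calibration of derivative amplitude vs concentration
#'
#' Ordinary least squares of the signed first-derivative amplitude at the
#' analytical wavelength against concentration. The residual standard
#' deviation uses the regression definition `sqrt(SSE / (n - 2))`, and the
#' detection / quantification limits follow the ICH Q2 formulas
#' (see [lod_loq()]). The valid range is the span of the input
#' concentrations. Weighted regression is deliberately not offered: dilute
#' fluorescence calibrations of this kind are homoscedastic enough for plain
#' OLS.
#'
#' @param data Data frame with the calibration points.
#' @param concentration,amplitude Column names (tidy-eval) holding
#'   concentrations (ng/mL) and signed amplitudes (intensity / nm).
#' @param analyte Analyte label stored in the model.
#' @param wavelength Analytical readout wavelength (nm), stored for
#'   provenance and used by [quantify_eem()].
#' @param lod_k,loq_k ICH multipliers (defaults 3.3 and 10).
#' @return An object of class `fluor_calibration`.
#' @examples
#' d <- tibble::tibble(conc = c(0, 1, 2), amp = c(0.762, 0.773, 0.784))
#' fit_calibration(d, conc, amp, analyte = "HL", wavelength = 419)
#' @export
fit_calibration <- function(data, concentration, amplitude, analyte = "A",
                            wavelength = NA_real_, lod_k = 3.3, loq_k = 10) {
  conc <- dplyr::pull(data, {{ concentration }})
  amp <- dplyr::pull(data, {{ amplitude }})
  if (length(conc) != length(amp)) {
    stop("Concentration and amplitude vectors differ in length.",
         call. = FALSE)
  }
  if (length(unique(conc)) < 3L) {
    stop("Calibration needs at least 3 distinct concentration levels.",
         call. = FALSE)
  }
  fit <- stats::lm(amp ~ conc)
  slope <- unname(stats::coef(fit)[2])
  intercept <- unname(stats::coef(fit)[1])
  n <- length(conc)
  sse <- sum(stats::residuals(fit)^2)
  sst <- sum((amp - mean(amp))^2)
  residual_sd <- sqrt(sse / (n - 2))
  r_squared <- if (sst > 0) 1 - sse / sst else 1
  limits <- lod_loq(residual_sd, slope, lod_k = lod_k, loq_k = loq_k)
  structure(
    list(analyte = analyte, wavelength = wavelength,
         slope = slope, intercept = intercept,
         r_squared = r_squared, residual_sd = residual_sd,
         lod = limits$lod, loq = limits$loq,
         range = c(min(conc), max(conc)), n_points = n,
         data = tibble::tibble(concentration = conc, amplitude = amp),
         fit = fit),
    class = "fluor_calibration")
}

#' ICH Q2 detection and quantification limits
#'
#' `LOD = 3.3 * sigma / |S|` and `LOQ = 10 * sigma / |S|`, where `sigma` is
#' the residual standard deviation of the calibration regression and `S` its
#' slope. The multipliers are configurable but fixed at the ICH values by
#' default; their ratio LOQ/LOD = 10/3.3 is a structural property of the
#' formulas.
#'
#' @param residual_sd Residual SD of the regression (>= 0).
#' @param slope Calibration slope (non-zero).
#' @param lod_k,loq_k Multipliers (defaults 3.3, 10).
#' @return A tibble with columns `lod` and `loq` (ng/mL).
#' @export
lod_loq <- function(residual_sd, slope, lod_k = 3.3, loq_k = 10) {
  if (any(slope == 0)) stop("`slope` must be non-zero.", call. = FALSE)
  if (any(residual_sd < 0)) stop("`residual_sd` must be >= 0.", call. = FALSE)
  tibble::tibble(lod = lod_k * residual_sd / abs(slope),
                 loq = loq_k * residual_sd / abs(slope))
}

#' Invert a calibration line
#'
#' `c = (amplitude - intercept) / slope`, flagged `"below_loq"` when the
#' estimate falls under the quantification limit, `"out_of_range"` when it
#' falls outside the calibrated span, `"ok"` otherwise. Negative estimates are
#' returned as-is (flagged), never truncated.
#'
#' @param model A `fluor_calibration`.
#' @param amplitude Signed derivative amplitude(s), intensity / nm.
#' @return A tibble with columns `amplitude`, `concentration`, `flag`.
#' @export
predict_concentration <- function(model, amplitude) {
  stopifnot(inherits(model, "fluor_calibration"))
  conc <- (amplitude - model$intercept) / model$slope
  flag <- dplyr::case_when(
    conc < model$loq ~ "below_loq",
    conc < model$range[1] | conc > model$range[2] ~ "out_of_range",
    TRUE ~ "ok")
  tibble::tibble(amplitude = amplitude, concentration = conc, flag = flag)
}

#' Percent recovery
#'
#' `100 * found / added`, the accuracy metric of assay validation, rounded to
#' two decimals in rendered tables (round-half-even).
#'
#' @param found,added Found and added concentrations (ng/mL); `added > 0`.
#' @return Percent recovery (vectorised).
#' @examples
#' percent_recovery(74.29, 75) # 99.05...
#' @export
percent_recovery <- function(found, added) {
  if (any(added <= 0)) stop("`added` must be positive.", call. = FALSE)
  100 * found / added
}

#' Percent relative standard deviation
#'
#' `100 * sd(x) / mean(x)` with the sample (n - 1) standard deviation; the
#' precision metric of assay validation.
#'
#' @param values At least two numeric values with non-zero mean.
#' @return Percent RSD.
#' @export
rsd <- function(values) {
  if (length(values) < 2L) stop("`rsd()` needs at least 2 values.",
                                call. = FALSE)
  m <- mean(values)
  if (m == 0) stop("`rsd()` is undefined for zero-mean data.", call. = FALSE)
  100 * stats::sd(values) / m
}

#' @export
print.fluor_calibration <- function(x, ...) {
  cat(sprintf(
    paste0("<fluor_calibration> %s @ %g nm\n",
           "  amplitude = %.6g + %.6g * c   (c in ng/mL, n = %d)\n",
           "  r^2 = %.6f | residual SD = %.4g\n",
           "  LOD = %.3g ng/mL | LOQ = %.3g ng/mL | range %g-%g ng/mL\n"),
    x$analyte, x$wavelength, x$intercept, x$slope, x$n_points,
    x$r_squared, x$residual_sd, x$lod, x$loq, x$range[1], x$range[2]))
  invisible(x)
}

#' Tidy a calibration model
#'
#' @param x A `fluor_calibration`.
#' @param ... Unused.
#' @return One row per coefficient with estimate and standard error.
#' @export
tidy.fluor_calibration <- function(x, ...) {
  # suppressWarnings: summary.lm warns on an exactly collinear (perfect) fit
  se <- if (is.null(x$fit)) c(NA_real_, NA_real_) else
    unname(suppressWarnings(summary(x$fit))$coefficients[, "Std. Error"])
  tibble::tibble(term = c("intercept", "slope"),
                 estimate = c(x$intercept, x$slope),
                 std.error = se)
}

#' One-row summary of a calibration model
#'
#' @param x A `fluor_calibration`.
#' @param ... Unused.
#' @return A one-row tibble with the figures of merit.
#' @export
glance.fluor_calibration <- function(x, ...) {
  tibble::tibble(analyte = x$analyte, wavelength = x$wavelength,
                 slope = x$slope, intercept = x$intercept,
                 r_squared = x$r_squared, residual_sd = x$residual_sd,
                 lod = x$lod, loq = x$loq,
                 range_low = x$range[1], range_high = x$range[2],
                 n_points = x$n_points)
}

#' @export
autoplot.fluor_calibration <- function(object, ...) {
  ggplot2::ggplot(object$data,
                  ggplot2::aes(x = .data$concentration,
                               y = .data$amplitude)) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(slope = object$slope,
                         intercept = object$intercept, colour = "steelblue") +
    ggplot2::labs(
      x = "concentration (ng/mL)", y = "derivative amplitude (a.u. / nm)",
      subtitle = sprintf("%s @ %g nm | r² = %.4f", object$analyte,
                         object$wavelength, object$r_squared))
}

#' Persist / restore a calibration as JSON
#'
#' @param model A `fluor_calibration`.
#' @param path File path.
#' @return `read_calibration_json()` returns a `fluor_calibration` (without
#'   the underlying `lm` object); `write_calibration_json()` returns `path`
#'   invisibly.
#' @export
write_calibration_json <- function(model, path) {
  stopifnot(inherits(model, "fluor_calibration"))
  doc <- list(
    analyte = model$analyte, wavelength = model$wavelength,
    slope = model$slope, intercept = model$intercept,
    r_squared = model$r_squared, residual_sd = model$residual_sd,
    lod = model$lod, loq = model$loq, range = model$range,
    n_points = model$n_points,
    data = model$data)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_calibration_json
#' @export
read_calibration_json <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(
    list(analyte = doc$analyte, wavelength = doc$wavelength,
         slope = doc$slope, intercept = doc$intercept,
         r_squared = doc$r_squared, residual_sd = doc$residual_sd,
         lod = doc$lod, loq = doc$loq, range = doc$range,
         n_points = doc$n_points,
         data = tibble::as_tibble(doc$data), fit = NULL),
    class = "fluor_calibration")
}
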