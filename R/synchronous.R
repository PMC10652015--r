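#' Extract a synchronous spectrum from an excitation-emission matrix
#'
#' Emulates a synchronous scan in which both monochromators move together at a
#' fixed offset `delta_lambda` = lambda_em - lambda_ex. The spectrum is indexed
#' by the emission wavelength, so `S(lambda_em) = EEM(lambda_em - delta_lambda,
#' lambda_em)`, with linear interpolation along the excitation axis when the
#' diagonal falls between excitation grid points. The result is restricted to
#' emission wavelengths whose paired excitation wavelength lies inside the EEM.
#'
#' @param x An [eem].
#' @param delta_lambda Scan offset in nm (> 0). Default 50, the production
#'   offset for the harmaline/harmine assay.
#' @return A tibble of class `sync_spectrum` with columns `wavelength_nm`
#'   (emission axis) and `intensity`, and attribute `delta_lambda`.
#' @examples
#' e <- eem(wl_grid(240, 340), wl_grid(290, 420), matrix(1, 101, 131))
#' extract_synchronous(e, 50)
#' @export
extract_synchronous <- function(x, delta_lambda = 50) {
  stopifnot(inherits(x, "eem"))
  if (!is.numeric(delta_lambda) || length(delta_lambda) != 1L ||
      !is.finite(delta_lambda) || delta_lambda <= 0) {
    stop("`delta_lambda` must be a single positive number (nm).", call. = FALSE)
  }
  ex_target <- x$em_nm - delta_lambda
  ok <- ex_target >= min(x$ex_nm) & ex_target <= max(x$ex_nm)
  if (sum(ok) < 9L) {
    stop(sprintf(
      paste0("The synchronous diagonal (delta_lambda = %g nm) intersects the ",
             "EEM at only %d emission points; at least 9 are required."),
      delta_lambda, sum(ok)), call. = FALSE)
  }
  em <- x$em_nm[ok]
  xt <- ex_target[ok]
  j <- which(ok)
  # linear interpolation along the excitation axis, vectorised over columns
  i <- findInterval(xt, x$ex_nm, rightmost.closed = TRUE)
  i <- pmin(i, length(x$ex_nm) - 1L)
  w <- (xt - x$ex_nm[i]) / (x$ex_nm[i + 1L] - x$ex_nm[i])
  lo <- x$intensity[cbind(i, j)]
  hi <- x$intensity[cbind(i + 1L, j)]
  new_sync_spectrum(em, (1 - w) * lo + w * hi, delta_lambda)
}

new_sync_spectrum <- function(wavelength_nm, intensity, delta_lambda) {
  out <- tibble::tibble(wavelength_nm = wavelength_nm, intensity = intensity)
  attr(out, "delta_lambda") <- delta_lambda
  class(out) <- c("sync_spectrum", class(out))
  out
}

#' Offset of a synchronous spectrum
#'
#' @param spec A `sync_spectrum`.
#' @return The scan offset delta lambda in nm.
#' @export
delta_lambda <- function(spec) attr(spec, "delta_lambda")

#' @export
autoplot.sync_spectrum <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$wavelength_nm,
                                       y = .data$intensity)) +
    ggplot2::geom_line() +
    ggplot2::labs(
      x = "emission wavelength (nm)", y = "intensity (a.u.)",
      subtitle = sprintf("synchronous spectrum, Δλ = %g nm",
                         attr(object, "delta_lambda") %||% NA_real_))
}
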