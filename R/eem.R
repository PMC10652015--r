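#' Build a wavelength grid
#'
#' A wavelength grid is a strictly increasing numeric vector
#' `start + k * step`, in nanometres. All spectra and
#' excitation-emission matrices in synchrofluor live on such grids.
#'
#' @param start,stop Grid limits in nm (`start < stop`).
#' @param step Grid spacing in nm (default 1).
#' @return Numeric vector of wavelengths.
#' @examples
#' wl_grid(290, 300)
#' @export
wl_grid <- function(start, stop, step = 1) {
  stopifnot(is.numeric(start), is.numeric(stop), is.numeric(step))
  if (step <= 0) stop("`step` must be positive.", call. = FALSE)
  if (start >= stop) stop("`start` must be smaller than `stop`.", call. = FALSE)
  seq(start, stop, by = step)
}

#' Default instrument grids
#'
#' Defaults chosen so that a synchronous scan at any offset in the screened
#' 20-80 nm range covers the full emission window: emission 290-600 nm,
#' excitation 240-560 nm, both at 1 nm spacing.
#'
#' @return Numeric vector of wavelengths (nm).
#' @export
default_em_grid <- function() wl_grid(290, 600, 1)

#' @rdname default_em_grid
#' @export
default_ex_grid <- function() wl_grid(240, 560, 1)

check_grid <- function(x, what = "grid") {
  if (!is.numeric(x) || length(x) < 2L || anyNA(x) || any(diff(x) <= 0)) {
    stop("`", what, "` must be a strictly increasing numeric wavelength vector.",
         call. = FALSE)
  }
  invisible(x)
}

#' Excitation-emission matrix
#'
#' Container for 2-D fluorescence intensity over an excitation x emission
#' wavelength grid. Intensities are in arbitrary fluorescence units and are
#' stored as a dense matrix with one row per excitation wavelength and one
#' column per emission wavelength.
#'
#' @param ex_nm Excitation wavelength grid (nm), strictly increasing.
#' @param em_nm Emission wavelength grid (nm), strictly increasing.
#' @param intensity Numeric matrix, `length(ex_nm)` x `length(em_nm)`, finite.
#' @return An object of class `eem`.
#' @examples
#' e <- eem(wl_grid(250, 260), wl_grid(300, 320),
#'          matrix(1, 11, 21))
#' @export
eem <- function(ex_nm, em_nm, intensity) {
  check_grid(ex_nm, "ex_nm")
  check_grid(em_nm, "em_nm")
  if (!is.matrix(intensity) || !is.numeric(intensity)) {
    stop("`intensity` must be a numeric matrix.", call. = FALSE)
  }
  if (nrow(intensity) != length(ex_nm) || ncol(intensity) != length(em_nm)) {
    stop(sprintf("`intensity` must be %d x %d (got %d x %d).",
                 length(ex_nm), length(em_nm),
                 nrow(intensity), ncol(intensity)), call. = FALSE)
  }
  if (!all(is.finite(intensity))) {
    stop("`intensity` must be finite everywhere.", call. = FALSE)
  }
  structure(
    list(ex_nm = as.numeric(ex_nm), em_nm = as.numeric(em_nm),
         intensity = intensity),
    class = "eem"
  )
}

#' @export
print.eem <- function(x, ...) {
  cat(sprintf(
    "<eem> %d x %d | ex %g-%g nm | em %g-%g nm | max intensity %.4g\n",
    length(x$ex_nm), length(x$em_nm),
    min(x$ex_nm), max(x$ex_nm), min(x$em_nm), max(x$em_nm),
    max(x$intensity)))
  invisible(x)
}

#' @importFrom tibble as_tibble
#' @export
as_tibble.eem <- function(x, ...) {
  tibble::tibble(
    ex_nm = rep(x$ex_nm, times = length(x$em_nm)),
    em_nm = rep(x$em_nm, each = length(x$ex_nm)),
    intensity = as.vector(x$intensity)
  )
}

#' @export
`+.eem` <- function(e1, e2) {
  if (!identical(e1$ex_nm, e2$ex_nm) || !identical(e1$em_nm, e2$em_nm)) {
    stop("Cannot add eems on different grids.", call. = FALSE)
  }
  eem(e1$ex_nm, e1$em_nm, e1$intensity + e2$intensity)
}

#' @export
`-.eem` <- function(e1, e2) {
  if (!identical(e1$ex_nm, e2$ex_nm) || !identical(e1$em_nm, e2$em_nm)) {
    stop("Cannot subtract eems on different grids.", call. = FALSE)
  }
  eem(e1$ex_nm, e1$em_nm, e1$intensity - e2$intensity)
}

#' Plot an excitation-emission matrix
#'
#' @param object An [eem].
#' @param ... Unused.
#' @return A ggplot object (filled raster, emission on x).
#' @export
autoplot.eem <- function(object, ...) {
  df <- as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$em_nm, y = .data$ex_nm,
                                   fill = .data$intensity)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "intensity") +
    ggplot2::labs(x = "emission wavelength (nm)",
                  y = "excitation wavelength (nm)")
}
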