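#' Select interference-free analytical wavelengths for a fluorophore pair
#'
#' Implements the zero-crossing technique operationally: each analyte is read
#' at a wavelength where the other component's first-derivative signal
#' vanishes, chosen to maximise the analyte's own derivative amplitude.
#'
#' Candidate wavelengths for analyte A are the interpolated zero crossings of
#' B's derivative plus any grid region where B's derivative is identically
#' zero (disjoint support); among these, the one maximising `|dA|` wins. With
#' `tolerance > 0` the readout may move up to `tolerance` nm away from a
#' crossing in search of a larger analyte amplitude, trading exact
#' interference cancellation for sensitivity; the default (`tolerance = 0`)
#' pins the readout to the crossing so the interferent's interpolated
#' amplitude there is exactly zero. If one spectrum has no usable crossing,
#' the readout falls back to the grid wavelength minimising the
#' interferent-to-analyte amplitude ratio and the result is flagged.
#'
#' Both the crossing noise guard and the zero threshold scale with the
#' spectrum's own maximum amplitude, so the selection is invariant under joint
#' rescaling of the two spectra.
#'
#' @param dspec_a,dspec_b `deriv_spectrum` objects on the same grid (analytes
#'   A and B).
#' @param tolerance Search half-width around each crossing, nm (default 0).
#' @param min_flank_frac Crossings of the interferent whose flanking extrema
#'   are both below this fraction of its maximum amplitude are ignored
#'   (default 0.01).
#' @return A one-row tibble of class `analytical_wavelengths` with columns
#'   `lambda_a`, `lambda_b` (nm) and logical `fallback_a`, `fallback_b`.
#' @export
select_analytical_wavelengths <- function(dspec_a, dspec_b, tolerance = 0,
                                          min_flank_frac = 0.01) {
  if (!isTRUE(all.equal(dspec_a$wavelength_nm, dspec_b$wavelength_nm))) {
    stop("The two derivative spectra must share the same wavelength grid.",
         call. = FALSE)
  }
  a <- pick_readout(dspec_a, dspec_b, tolerance, min_flank_frac)
  b <- pick_readout(dspec_b, dspec_a, tolerance, min_flank_frac)
  out <- tibble::tibble(lambda_a = a$lambda, lambda_b = b$lambda,
                        fallback_a = a$fallback, fallback_b = b$fallback)
  class(out) <- c("analytical_wavelengths", class(out))
  out
}

# readout for `analyte` against `interferent`
pick_readout <- function(analyte, interferent, tolerance, min_flank_frac) {
  wl <- analyte$wavelength_nm
  d_int <- interferent$d_intensity
  max_int <- max(abs(d_int))
  cross <- find_zero_crossings(interferent,
                               min_flank = min_flank_frac * max_int)
  # machine-zero regions of the interferent count as interference-free
  zero_grid <- wl[abs(d_int) <= 1e-12 * max(max_int, .Machine$double.xmin)]
  cand <- c(cross, zero_grid)
  if (!length(cand)) {
    eps <- 1e-12 * max(abs(analyte$d_intensity))
    ratio <- abs(d_int) / (abs(analyte$d_intensity) + eps)
    return(list(lambda = wl[which.min(ratio)], fallback = TRUE))
  }
  if (tolerance > 0) {
    best <- vapply(cand, function(x) {
      o <- stats::optimize(
        function(l) -abs(amplitude_at(analyte, l)),
        lower = max(min(wl), x - tolerance),
        upper = min(max(wl), x + tolerance))
      c(o$minimum, -o$objective)
    }, numeric(2))
    list(lambda = best[1, which.max(best[2, ])], fallback = FALSE)
  } else {
    amp <- abs(amplitude_at(analyte, cand))
    list(lambda = cand[which.max(amp)], fallback = FALSE)
  }
}

#' Resolution score of a wavelength pair
#'
#' Quantifies how cleanly two derivative spectra are resolved at the chosen
#' readouts: for each readout the analyte's derivative amplitude is divided by
#' the interferent's amplitude there (plus a guard term), and the score is the
#' minimum of the two ratios. Higher is better. The guard term is
#' `eps_rel * max(max|dA|, max|dB|)`: tying it to the joint amplitude scale
#' keeps the score finite at exact crossings, makes it invariant under joint
#' rescaling of both spectra, and lets the relative intensity of the two
#' components enter - a readout on a component that is weak relative to its
#' partner scores lower, which is what penalises scan offsets that excite one
#' component at the expense of the other.
#'
#' @param dspec_a,dspec_b `deriv_spectrum` objects on the same grid.
#' @param wavelengths An `analytical_wavelengths` row (or list with
#'   `lambda_a`, `lambda_b`).
#' @param eps_rel Relative guard, default 1e-3.
#' @return A single dimensionless score.
#' @export
resolution_score <- function(dspec_a, dspec_b, wavelengths, eps_rel = 1e-3) {
  la <- wavelengths$lambda_a
  lb <- wavelengths$lambda_b
  max_a <- max(abs(dspec_a$d_intensity))
  max_b <- max(abs(dspec_b$d_intensity))
  guard <- eps_rel * max(max_a, max_b)
  s_a <- abs(amplitude_at(dspec_a, la)) /
    (abs(amplitude_at(dspec_b, la)) + guard)
  s_b <- abs(amplitude_at(dspec_b, lb)) /
    (abs(amplitude_at(dspec_a, lb)) + guard)
  # an identically-zero spectrum has no readout of its own to score
  if (max_a == 0 && max_b == 0) return(0)
  if (max_b == 0) return(s_a)
  if (max_a == 0) return(s_b)
  min(s_a, s_b)
}
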