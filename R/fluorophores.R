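#' Parametric fluorophore model
#'
#' Describes one analyte in one state (free or cyclodextrin-complexed) as a
#' Gaussian excitation band times a sum of Gaussian emission bands:
#' `I(ex, em) = c * rf * G(ex; ex_center, ex_width) *
#' sum_b a_b * G(em; center_b, width_b)`, strictly linear in the
#' concentration `c` (ng/mL).
#'
#' @param name Analyte label.
#' @param ex_center,ex_width Excitation band centre and Gaussian width (nm).
#' @param emission_bands Data frame with columns `center`, `width` (nm) and
#'   `rel_amplitude` (> 0), one row per emission band.
#' @param response_factor Peak intensity per ng/mL (arbitrary fluorescence
#'   units); encodes quantum yield and instrumental response.
#' @param complexed Logical: is this the cyclodextrin inclusion complex?
#' @return An object of class `fluorophore_model`.
#' @export
fluorophore_model <- function(name, ex_center, ex_width, emission_bands,
                              response_factor = 1, complexed = FALSE) {
  emission_bands <- tibble::as_tibble(emission_bands)
  stopifnot(all(c("center", "width", "rel_amplitude") %in%
                  names(emission_bands)))
  if (ex_width <= 0 || any(emission_bands$width <= 0) ||
      any(emission_bands$rel_amplitude <= 0) || response_factor <= 0) {
    stop("Widths, relative amplitudes and the response factor must be positive.",
         call. = FALSE)
  }
  structure(
    list(name = name, ex_center = ex_center, ex_width = ex_width,
         emission_bands = emission_bands,
         response_factor = response_factor, complexed = complexed),
    class = "fluorophore_model"
  )
}

#' @export
print.fluorophore_model <- function(x, ...) {
  cat(sprintf("<fluorophore_model> %s (%s) | ex %g/%g nm | rf %g\n",
              x$name, if (x$complexed) "complexed" else "free",
              x$ex_center, x$ex_width, x$response_factor))
  print(x$emission_bands)
  invisible(x)
}

gaussian_band <- function(x, center, width) {
  exp(-0.5 * ((x - center) / width)^2)
}

# emission profile of a model at unit concentration (no excitation factor)
emission_profile <- function(model, em_nm) {
  b <- model$emission_bands
  rowSums(vapply(seq_len(nrow(b)), function(k) {
    b$rel_amplitude[k] * gaussian_band(em_nm, b$center[k], b$width[k])
  }, numeric(length(em_nm))))
}

#' Default harmaline/harmine-like fluorophore models
#'
#' Four models of the two beta-carboline analytes: the free forms excited at
#' 285 nm, whose emission bands peak inside 300-400 nm and overlap almost
#' completely (the unresolvable case), and the cyclodextrin inclusion
#' complexes, whose emission maxima sit at 400 nm (harmaline-like, "HL") and
#' 455 nm (harmine-like, "HM").
#'
#' The complexed band parameters are a frozen numerical calibration of the
#' simulator: widths, secondary-band positions and the HM/HL response ratio
#' were fitted once so that the full pipeline (synchronous extraction at
#' delta lambda = 50 nm, 9-point cubic Savitzky-Golay first derivative,
#' zero-crossing wavelength selection) reads out at 419 nm (HL) and 456 nm
#' (HM) and so that the 20-80 nm offset screen peaks at 50 nm. Each complexed
#' model carries a weak secondary emission band (a red vibronic shoulder for
#' HL, a blue shoulder of the uncomplexed-like emission for HM); these
#' secondary bands are what give each component's derivative a zero crossing
#' inside the partner's band, which the zero-crossing technique requires.
#'
#' @return Named list with elements `hl_free`, `hm_free`, `hl_complexed`,
#'   `hm_complexed`, each a [fluorophore_model].
#' @export
default_models <- function() {
  list(
    hl_free = fluorophore_model(
      "HL", 285, 45,
      tibble::tibble(center = 360, width = 32, rel_amplitude = 1),
      response_factor = 1, complexed = FALSE),
    hm_free = fluorophore_model(
      "HM", 285, 45,
      tibble::tibble(center = 372, width = 30, rel_amplitude = 1),
      response_factor = 1.5, complexed = FALSE),
    hl_complexed = fluorophore_model(
      "HL", 285, 65.6,
      tibble::tibble(center = c(400, 481.5), width = c(23.2, 12.2),
                     rel_amplitude = c(1, 0.44)),
      response_factor = 1, complexed = TRUE),
    hm_complexed = fluorophore_model(
      "HM", 285, 65.6,
      tibble::tibble(center = c(455, 392.9), width = c(15.3, 14.7),
                     rel_amplitude = c(1, 0.29)),
      response_factor = 2.68, complexed = TRUE)
  )
}

#' Overlap coefficient of two emission profiles
#'
#' Normalised inner product of the two models' emission profiles on a grid
#' (1 for identical shapes, 0 for disjoint bands). The free forms of the
#' default pair overlap above 0.8, which is what makes them unresolvable
#' without complexation.
#'
#' @param model_a,model_b [fluorophore_model]s.
#' @param em_nm Emission grid (default [default_em_grid()]).
#' @return Overlap coefficient in `[0, 1]`.
#' @export
overlap_coefficient <- function(model_a, model_b, em_nm = default_em_grid()) {
  pa <- emission_profile(model_a, em_nm)
  pb <- emission_profile(model_b, em_nm)
  sum(pa * pb) / sqrt(sum(pa^2) * sum(pb^2))
}

#' Spectral proxy for a bench perturbation
#'
#' Robustness factors of the wet method (buffer pH, reagent volumes) are
#' represented by their effect on the spectra: a rigid shift of all emission
#' band centres and a relative change of the response factor.
#'
#' @param band_shift Emission band centre shift in nm (|shift| <= 5).
#' @param intensity_scale_delta Relative response change (|delta| <= 0.1).
#' @return An object of class `perturbation`.
#' @export
perturbation <- function(band_shift = 0, intensity_scale_delta = 0) {
  if (abs(band_shift) > 5) {
    stop("|band_shift| must be <= 5 nm.", call. = FALSE)
  }
  if (abs(intensity_scale_delta) > 0.1) {
    stop("|intensity_scale_delta| must be <= 0.1.", call. = FALSE)
  }
  structure(list(band_shift = band_shift,
                 intensity_scale_delta = intensity_scale_delta),
            class = "perturbation")
}

#' Apply a perturbation to a fluorophore model
#'
#' Returns a copy of the model with every emission band centre shifted by
#' `band_shift` and the response factor scaled by
#' `1 + intensity_scale_delta`.
#'
#' @param model A [fluorophore_model].
#' @param p A [perturbation].
#' @return A perturbed [fluorophore_model].
#' @export
apply_perturbation <- function(model, p) {
  stopifnot(inherits(model, "fluorophore_model"), inherits(p, "perturbation"))
  model$emission_bands$center <- model$emission_bands$center + p$band_shift
  model$response_factor <- model$response_factor *
    (1 + p$intensity_scale_delta)
  model
}
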