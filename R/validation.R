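#' Select production wavelengths from a model pair
#'
#' Simulates noise-free single-component EEMs for the two (complexed) models,
#' runs the derivative synchronous pipeline and applies
#' [select_analytical_wavelengths()]. With the packaged [default_models()]
#' this returns 419 nm (HL) and 456 nm (HM).
#'
#' @param models List with elements `hl` and `hm` ([fluorophore_model]s).
#' @param delta_lambda Scan offset (nm), default 50.
#' @param concentration Reference concentration used for the pure spectra
#'   (irrelevant to the result, which is scale-invariant).
#' @inheritParams derivative_pipeline
#' @param ... Passed to [select_analytical_wavelengths()].
#' @return An `analytical_wavelengths` row.
#' @export
select_default_wavelengths <- function(models, delta_lambda = 50,
                                       concentration = 100,
                                       window_points = 9, poly_order = 3,
                                       ...) {
  da <- derivative_pipeline(
    simulate_eem(list(component(models$hl, concentration))),
    delta_lambda, window_points, poly_order)
  db <- derivative_pipeline(
    simulate_eem(list(component(models$hm, concentration))),
    delta_lambda, window_points, poly_order)
  select_analytical_wavelengths(da, db, ...)
}

#' Build the two calibrations of the assay
#'
#' Simulates a calibration series per analyte and fits both lines at the
#' chosen analytical wavelengths.
#'
#' @inheritParams select_default_wavelengths
#' @param wavelengths An `analytical_wavelengths` row (default: selected from
#'   the models).
#' @param concentrations Calibration levels (ng/mL).
#' @param noise A [noise_model] or `NULL` for noise-free calibration.
#' @return Named list of `fluor_calibration` objects (`hl`, `hm`).
#' @export
build_calibrations <- function(models, wavelengths = NULL,
                               concentrations = c(10, 25, 50, 75, 100, 150,
                                                  200),
                               noise = NULL, delta_lambda = 50,
                               window_points = 9, poly_order = 3) {
  if (is.null(wavelengths)) {
    wavelengths <- select_default_wavelengths(
      models, delta_lambda, window_points = window_points,
      poly_order = poly_order)
  }
  fit1 <- function(model, wl, label, offset) {
    calibrate_series(
      make_calibration_series(model, concentrations,
                              noise = reseed(noise, if (is.null(noise)) 0 else
                                noise$seed + offset)),
      wavelength = wl, analyte = label, delta_lambda = delta_lambda,
      window_points = window_points, poly_order = poly_order)
  }
  list(hl = fit1(models$hl, wavelengths$lambda_a, "HL", 0),
       hm = fit1(models$hm, wavelengths$lambda_b, "HM", 1000))
}

det_seed <- function(base, session, level_idx, rep) {
  (base + 97L * session + 13L * level_idx + rep) %% .Machine$integer.max
}

# one determination: mixture of both analytes at `level`, quantified at both
# wavelengths against the given calibrations
run_determination <- function(models, calibrations, level, noise,
                              delta_lambda, window_points, poly_order) {
  e <- simulate_eem(list(component(models$hl, level),
                         component(models$hm, level)), noise = noise)
  d <- derivative_pipeline(e, delta_lambda, window_points, poly_order)
  found_hl <- predict_concentration(
    calibrations$hl, amplitude_at(d, calibrations$hl$wavelength))$concentration
  found_hm <- predict_concentration(
    calibrations$hm, amplitude_at(d, calibrations$hm$wavelength))$concentration
  tibble::tibble(analyte = c("HL", "HM"), found = c(found_hl, found_hm),
                 recovery = percent_recovery(c(found_hl, found_hm), level))
}

#' Accuracy and precision study
#'
#' ICH-style design: `reps` replicates at each level, repeated over
#' `sessions` sessions. Each determination is a two-analyte mixture with both
#' components at the level concentration. The session effect (day-to-day
#' instrument drift) is a small seeded response-scale jitter applied to
#' sessions after the first. Accuracy is the mean percent recovery over the
#' first session's `reps * length(levels)` determinations per analyte;
#' repeatability RSD comes from the same block; intermediate-precision RSD
#' pools the within-session variance with the (non-negative) between-session
#' variance component over all sessions.
#'
#' @inheritParams build_calibrations
#' @param calibrations Named list of `fluor_calibration`s (`hl`, `hm`).
#' @param levels Study levels in ng/mL (default 10, 50, 100).
#' @param reps Replicates per level per session (default 3).
#' @param sessions Number of sessions (default 3).
#' @param noise A [noise_model] or `NULL`.
#' @param session_sd SD of the relative between-session response jitter
#'   (default 0.003); 0 disables the session effect.
#' @param seed Base seed for determination-level noise (default: the noise
#'   model's seed).
#' @return An object of class `accuracy_precision_study`: list with
#'   `determinations` (tibble) and `summary` (one row per analyte).
#' @export
accuracy_precision_study <- function(models, calibrations,
                                     levels = c(10, 50, 100), reps = 3,
                                     sessions = 3,
                                     noise = noise_model(),
                                     session_sd = 0.003, seed = NULL) {
  rng_low <- min(calibrations$hl$range[1], calibrations$hm$range[1])
  rng_high <- max(calibrations$hl$range[2], calibrations$hm$range[2])
  if (any(levels < rng_low | levels > rng_high)) {
    stop("Study levels must lie inside the calibration range.", call. = FALSE)
  }
  if (is.null(seed)) seed <- if (is.null(noise)) 1L else noise$seed
  session_scale <- withr::with_seed(seed, {
    c(1, 1 + pmax(pmin(stats::rnorm(max(sessions - 1, 0), 0, session_sd),
                       0.05), -0.05))
  })
  det <- purrr::pmap_dfr(
    expand.grid(rep = seq_len(reps), level_idx = seq_along(levels),
                session = seq_len(sessions)),
    function(rep, level_idx, session) {
      sc <- session_scale[session]
      m <- list(
        hl = apply_perturbation(models$hl,
                                perturbation(intensity_scale_delta = sc - 1)),
        hm = apply_perturbation(models$hm,
                                perturbation(intensity_scale_delta = sc - 1)))
      run_determination(
        m, calibrations, levels[level_idx],
        noise = reseed(noise, det_seed(seed, session, level_idx, rep)),
        delta_lambda = 50, window_points = 9, poly_order = 3) |>
        dplyr::mutate(session = session, level = levels[level_idx],
                      rep = rep, .before = 1)
    })
  summarise_one <- function(d) {
    s1 <- d$recovery[d$session == 1]
    grand <- mean(d$recovery)
    within <- stats::aggregate(recovery ~ session, data = d, FUN = stats::var)
    n_per <- nrow(d) / length(unique(d$session))
    s_w2 <- mean(within$recovery)
    means <- stats::aggregate(recovery ~ session, data = d, FUN = mean)
    s_b2 <- if (nrow(means) > 1) {
      max(0, stats::var(means$recovery) - s_w2 / n_per)
    } else 0
    tibble::tibble(
      accuracy = mean(s1),
      repeatability_rsd = rsd(s1),
      intermediate_precision_rsd = 100 * sqrt(s_w2 + s_b2) / grand)
  }
  summary <- det |>
    dplyr::group_by(.data$analyte) |>
    dplyr::group_modify(~ summarise_one(.x)) |>
    dplyr::ungroup()
  structure(list(determinations = det, summary = summary,
                 levels = levels, reps = reps, sessions = sessions,
                 session_sd = session_sd, seed = seed),
            class = "accuracy_precision_study")
}

#' Default robustness design
#'
#' Spectral proxies for the bench perturbations examined in robustness
#' testing: a buffered pH step of +/- 0.5 is modelled as a +/- 0.1 nm rigid
#' emission band shift (near the buffered optimum the complexed bands move
#' very little), and the two reagent-volume factors as +/- 1.5% and +/- 1%
#' response-scale changes.
#'
#' @return Tibble with columns `label`, `band_shift`,
#'   `intensity_scale_delta`.
#' @export
default_robustness_design <- function() {
  tibble::tibble(
    label = c("Buffer pH (+/- 0.5)", "Buffer volume (+/- 0.25 mL)",
              "HP-b-CD volume (+/- 0.1 mL)"),
    band_shift = c(0.1, 0, 0),
    intensity_scale_delta = c(0, 0.015, 0.01))
}

#' Robustness study
#'
#' For every perturbation (applied with both signs) the accuracy design is
#' re-simulated with perturbed models while quantification still uses the
#' unperturbed calibrations - that mismatch is what makes it a robustness
#' test. An identity perturbation with the same seed reproduces the
#' first-session accuracy figures exactly.
#'
#' @inheritParams accuracy_precision_study
#' @param design Perturbation design (default
#'   [default_robustness_design()]); labels must be unique.
#' @return An object of class `robustness_study`: `determinations` plus a
#'   `summary` tibble (label, sign, analyte, mean recovery, RSD).
#' @export
robustness_study <- function(models, calibrations,
                             design = default_robustness_design(),
                             levels = c(10, 50, 100), reps = 3,
                             noise = noise_model(), seed = NULL) {
  design <- tibble::as_tibble(design)
  if (anyDuplicated(design$label)) {
    stop("Perturbation labels must be unique.", call. = FALSE)
  }
  if (is.null(seed)) seed <- if (is.null(noise)) 1L else noise$seed
  one_side <- function(label, shift, delta, sgn) {
    p <- perturbation(band_shift = sgn * shift,
                      intensity_scale_delta = sgn * delta)
    m <- list(hl = apply_perturbation(models$hl, p),
              hm = apply_perturbation(models$hm, p))
    purrr::pmap_dfr(
      expand.grid(rep = seq_len(reps), level_idx = seq_along(levels)),
      function(rep, level_idx) {
        run_determination(
          m, calibrations, levels[level_idx],
          noise = reseed(noise, det_seed(seed, 1L, level_idx, rep)),
          delta_lambda = 50, window_points = 9, poly_order = 3) |>
          dplyr::mutate(label = label, sign = sgn,
                        level = levels[level_idx], rep = rep, .before = 1)
      })
  }
  det <- purrr::pmap_dfr(design, function(label, band_shift,
                                          intensity_scale_delta) {
    dplyr::bind_rows(one_side(label, band_shift, intensity_scale_delta, 1),
                     one_side(label, band_shift, intensity_scale_delta, -1))
  })
  summary <- det |>
    dplyr::group_by(.data$label, .data$sign, .data$analyte) |>
    dplyr::summarise(recovery_mean = mean(.data$recovery),
                     recovery_rsd = rsd(.data$recovery), .groups = "drop")
  structure(list(determinations = det, summary = summary, design = design,
                 seed = seed),
            class = "robustness_study")
}

#' Specificity / spiked-recovery study
#'
#' Simulates two-analyte mixtures (optionally on a matrix background with a
#' parallel blank, which is subtracted before measurement, mirroring blank
#' correction of spiked plasma), quantifies each analyte at its analytical
#' wavelength, and reports found concentrations, percent recovery, and
#' per-analyte mean and RSD.
#'
#' @inheritParams accuracy_precision_study
#' @param design Added-concentration pairs (columns `c_hl`, `c_hm`); default
#'   [default_mixture_design()].
#' @param background A [matrix_background]; when not `"none"` a blank with
#'   the same background is simulated and subtracted.
#' @return An object of class `specificity_study`: `results` (added, found,
#'   recovery per analyte) and `summary` (mean, RSD per analyte).
#' @export
specificity_study <- function(models, calibrations,
                              design = default_mixture_design(),
                              background = matrix_background("none"),
                              noise = noise_model(), seed = NULL) {
  if (is.null(seed)) seed <- if (is.null(noise)) 1L else noise$seed
  mixtures <- make_mixture_set(design, models, background = background,
                               noise = reseed(noise, seed))
  blank <- if (background$kind != "none") {
    simulate_eem(list(), background = background,
                 noise = reseed(noise, seed + 5000L))
  }
  results <- purrr::pmap_dfr(
    list(mixtures$c_hl, mixtures$c_hm, mixtures$eem),
    function(a, b, e) {
      if (!is.null(blank)) e <- e - blank
      d <- derivative_pipeline(e)
      tibble::tibble(
        analyte = c("HL", "HM"), added = c(a, b),
        found = c(
          predict_concentration(
            calibrations$hl,
            amplitude_at(d, calibrations$hl$wavelength))$concentration,
          predict_concentration(
            calibrations$hm,
            amplitude_at(d, calibrations$hm$wavelength))$concentration)) |>
        dplyr::mutate(recovery = percent_recovery(.data$found, .data$added))
    })
  summary <- results |>
    dplyr::group_by(.data$analyte) |>
    dplyr::summarise(recovery_mean = mean(.data$recovery),
                     recovery_rsd = rsd(.data$recovery), .groups = "drop")
  structure(list(results = results, summary = summary,
                 background = background$kind, seed = seed),
            class = "specificity_study")
}

#' Screen the synchronous scan offset
#'
#' Runs the full selection pipeline on the pure complexed pair for every
#' candidate offset and scores each with [resolution_score()]. With the
#' packaged default models the 20-80 nm screen peaks at 50 nm.
#'
#' @inheritParams select_default_wavelengths
#' @param candidates Offsets to examine in nm (default `seq(20, 80, 10)`).
#' @param eps_rel Guard fraction for [resolution_score()].
#' @return An object of class `delta_lambda_screen`: `best` (nm) and `table`
#'   (offset, selected wavelengths, score).
#' @export
delta_lambda_screen <- function(models, candidates = seq(20, 80, by = 10),
                                concentration = 100, window_points = 9,
                                poly_order = 3, eps_rel = 1e-3) {
  if (!length(candidates)) {
    stop("`candidates` must contain at least one offset.", call. = FALSE)
  }
  ea <- simulate_eem(list(component(models$hl, concentration)))
  eb <- simulate_eem(list(component(models$hm, concentration)))
  tab <- purrr::map_dfr(as.numeric(candidates), function(dl) {
    da <- derivative_pipeline(ea, dl, window_points, poly_order)
    db <- derivative_pipeline(eb, dl, window_points, poly_order)
    wl <- select_analytical_wavelengths(da, db)
    tibble::tibble(delta_lambda = dl,
                   lambda_a = wl$lambda_a, lambda_b = wl$lambda_b,
                   score = resolution_score(da, db, wl, eps_rel = eps_rel))
  })
  structure(list(best = tab$delta_lambda[which.max(tab$score)], table = tab),
            class = "delta_lambda_screen")
}

#' @export
print.delta_lambda_screen <- function(x, ...) {
  cat(sprintf("<delta_lambda_screen> best offset: %g nm\n", x$best))
  print(x$table)
  invisible(x)
}

#' @export
autoplot.delta_lambda_screen <- function(object, ...) {
  ggplot2::ggplot(object$table,
                  ggplot2::aes(x = .data$delta_lambda, y = .data$score)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = object$best, linetype = 2,
                        colour = "steelblue") +
    ggplot2::labs(x = "scan offset Δλ (nm)", y = "resolution score")
}
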