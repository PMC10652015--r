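#' Assay run configuration
#'
#' Bundles the tunable settings of the pipeline. The defaults are the
#' production settings of the harmaline/harmine assay: scan offset 50 nm,
#' 9-point cubic first derivative, automatic zero-crossing wavelength
#' selection, the seven-level 10-200 ng/mL calibration design, and the
#' default noise model. All randomness flows from the single `seed`.
#'
#' @param delta_lambda Scan offset (nm).
#' @param window_points,poly_order Derivative filter settings.
#' @param wavelengths `NULL` for automatic selection, or a list/row with
#'   `lambda_a`, `lambda_b` in nm.
#' @param concentrations Calibration levels (ng/mL).
#' @param levels Accuracy-study levels (ng/mL).
#' @param additive_sd,proportional_sd Noise settings (see [noise_model()]).
#' @param seed Master seed.
#' @param ex_start,ex_stop,em_start,em_stop,step Grid settings (nm).
#' @return An object of class `run_config`.
#' @export
run_config <- function(delta_lambda = 50, window_points = 9, poly_order = 3,
                       wavelengths = NULL,
                       concentrations = c(10, 25, 50, 75, 100, 150, 200),
                       levels = c(10, 50, 100),
                       additive_sd = 0.002, proportional_sd = 0.0005,
                       seed = 1L,
                       ex_start = 240, ex_stop = 560,
                       em_start = 290, em_stop = 600, step = 1) {
  structure(
    list(delta_lambda = delta_lambda, window_points = window_points,
         poly_order = poly_order, wavelengths = wavelengths,
         concentrations = concentrations, levels = levels,
         additive_sd = additive_sd, proportional_sd = proportional_sd,
         seed = as.integer(seed),
         ex_start = ex_start, ex_stop = ex_stop,
         em_start = em_start, em_stop = em_stop, step = step),
    class = "run_config")
}

#' Read a run configuration from YAML
#'
#' Unknown keys are rejected so typos fail loudly; missing keys fall back to
#' the defaults of [run_config()].
#'
#' @param path YAML file path.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("No such file: ", path, call. = FALSE)
  vals <- yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()
  known <- names(formals(run_config))
  bad <- setdiff(names(vals), known)
  if (length(bad)) {
    stop("Unknown config keys: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  do.call(run_config, vals)
}

config_noise <- function(cfg) {
  noise_model(cfg$additive_sd, cfg$proportional_sd, cfg$seed)
}

config_grids <- function(cfg) {
  list(ex = wl_grid(cfg$ex_start, cfg$ex_stop, cfg$step),
       em = wl_grid(cfg$em_start, cfg$em_stop, cfg$step))
}
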