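# synchrofluor

Derivative synchronous spectrofluorometry for pairs of strongly overlapping
fluorophores, built around the harmaline/harmine (HL/HM) β-carboline assay:
two analytes whose free emission bands coincide in 300–400 nm are shifted
apart by hydroxypropyl-β-cyclodextrin complexation (maxima at 400 and
455 nm), resolved by a synchronous scan at a fixed offset, and quantified by
first-derivative zero-crossing readouts. The package is for analytical
chemists and method developers who want the complete numerical side of such
an assay — simulation, spectral processing, calibration and ICH Q2-style
validation — as reusable, testable code.

## Method

For an excitation–emission matrix `EEM(λ_ex, λ_em)`, the synchronous
spectrum at offset Δλ is the diagonal cut

    S(λ) = EEM(λ − Δλ, λ),      Δλ = λ_em − λ_ex  (50 nm in production)

followed by a 9-point Savitzky–Golay first derivative `D(λ) = dS/dλ`
(cubic, one-sided fits at the edges, units intensity/nm). Analyte A is read
at a wavelength where the interferent B's derivative crosses zero — for the
default models 419 nm (HL) and 456 nm (HM) — so the signed amplitude
`D(λ_A)` is linear in A alone. Calibration is OLS over 10–200 ng/mL,

    D(λ_A) = S·c + b,   LOD = 3.3 σ/|S|,   LOQ = 10 σ/|S|,

with σ the regression residual SD, and validation reports %R = 100·found/added
and %RSD per ICH Q2. A screening utility scans Δλ over 20–80 nm and scores
each candidate by the worst-case analyte/interferent amplitude ratio at the
selected readouts; the default models peak at Δλ = 50 nm.

Everything runs on simulated data: parametric Gaussian band models (free and
complexed states), matrix backgrounds (plasma blank, seed extract) and a
seeded, fully reproducible noise model.

## Worked example

```r
library(synchrofluor)

m <- default_models()
pair <- list(hl = m$hl_complexed, hm = m$hm_complexed)

# interference-free readouts from the pure complexed spectra
select_default_wavelengths(pair)
#> # A tibble: 1 × 4
#>   lambda_a lambda_b fallback_a fallback_b
#>      <dbl>    <dbl> <lgl>      <lgl>
#> 1     419.     456. FALSE      FALSE

delta_lambda_screen(pair)$best
#> [1] 50

# seeded seven-level calibration, 10-200 ng/mL
cal <- build_calibrations(pair, noise = noise_model(seed = 1))
glance(cal$hl)
#> # A tibble: 1 × 11
#>   analyte wavelength   slope intercept r_squared residual_sd   lod   loq
#>   <chr>        <dbl>   <dbl>     <dbl>     <dbl>       <dbl> <dbl> <dbl>
#> 1 HL            419. -0.0172  -0.00284     1.000      0.0111  2.12  6.43
#> ...

# quantify an "unknown" two-analyte sample
unknown <- simulate_eem(list(component(pair$hl, 120), component(pair$hm, 45)),
                        noise = noise_model(seed = 99))
quantify_eem(unknown, cal$hl)
#> # A tibble: 1 × 3
#>   amplitude concentration flag
#>       <dbl>         <dbl> <chr>
#> 1     -2.07          120. ok
quantify_eem(unknown, cal$hm)
#> 1    -0.714          44.9 ok
```

The true values were 120 and 45 ng/mL; both come back within the assay's
~1% precision despite the heavy band overlap, because each readout sits on
the other component's derivative zero crossing. `validation_report()` runs
the full suite (linearity, accuracy/precision, robustness, specificity on
the synthetic-mixture and spiked-plasma designs) and
`write_validation_report()` renders it as JSON and Markdown tables. A thin
command-line front end with `simulate`, `screen`, `calibrate`, `quantify`
and `validate` subcommands ships at `inst/cli/synchrofluor.R`.

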