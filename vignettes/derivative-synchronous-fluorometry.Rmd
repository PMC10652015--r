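---
title: "Derivative synchronous fluorometry: model, numerics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Derivative synchronous fluorometry: model, numerics and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(synchrofluor)
```

## The analytical problem

Harmaline (HL) and harmine (HM) are closely related β-carboline alkaloids
with strong native fluorescence. Excited at 285 nm, their free forms emit
almost on top of each other in the 300–400 nm window, so neither can be
quantified in the presence of the other by a conventional emission scan.
Complexation with hydroxypropyl-β-cyclodextrin (HP-β-CD) shields the excited
states inside the hydrophobic cavity and shifts the emission maxima apart —
to about 400 nm for the HL complex and 455 nm for the HM complex — but a
substantial overlap remains.

The assay this package implements resolves the residual overlap numerically,
in two steps:

1. **Synchronous scanning.** Both monochromators move together at a fixed
   offset Δλ = λ~em~ − λ~ex~. The recorded signal
   `S(λ) = EEM(λ − Δλ, λ)` is a diagonal cut through the
   excitation–emission matrix (EEM); because it multiplies the excitation
   and emission profiles, synchronous bands are narrower than either.
2. **First-derivative zero-crossing readout.** The synchronous spectrum is
   differentiated with a 9-point Savitzky–Golay filter. Each analyte is then
   read at a wavelength where the *other* component's derivative crosses
   zero: 419 nm for HL and 456 nm for HM at the production offset
   Δλ = 50 nm. At such a wavelength the interferent contributes nothing to
   the signed derivative amplitude, so the reading is linear in the analyte
   alone.

Calibration is ordinary least squares of the signed amplitude against
concentration over 10–200 ng/mL, with ICH Q2 detection and quantification
limits, and the validation module reruns the full ICH battery (accuracy,
precision, robustness, specificity, offset screening) on simulated data.

## The simulator

Nothing in the quantitative pipeline depends on instrument data: the
`simulate` functions generate EEMs from parametric band models,

$$I(\lambda_{ex}, \lambda_{em}) \;=\; \sum_i c_i\, r_i\,
  G(\lambda_{ex};\, \mu^{ex}_i, w^{ex}_i)
  \sum_b a_{ib}\, G(\lambda_{em};\, \mu_{ib}, w_{ib})
  \;+\; B(\lambda_{ex}, \lambda_{em}) \;+\; \varepsilon,$$

where `G` is a unit-height Gaussian, `c_i` the concentration in ng/mL,
`r_i` a response factor (intensity per ng/mL), `B` an optional broad matrix
background (plasma blank or seed extract) and ε the noise term. Gaussian
band shapes were chosen for transparency; log-normal (asymmetric) bands
would be a straightforward extension but add parameters the available
evidence cannot constrain.

### The default models and how they were fixed

The free forms are single bands at 360 and 372 nm (widths 32 and 30 nm)
excited at 285 nm: their emission overlap coefficient exceeds 0.97, which is
the point — they document the unresolvable case, and all quantitative
workflows use the complexed models, mirroring the role of HP-β-CD in the
bench method.

The complexed models each carry a main band plus a weak secondary band:

| model | excitation | emission bands (centre nm, width nm, rel. amp.) | r |
|---|---|---|---|
| HL complex | 285 / 65.6 | (400, 23.2, 1) + (481.5, 12.2, 0.44) | 1 |
| HM complex | 285 / 65.6 | (455, 15.3, 1) + (392.9, 14.7, 0.29) | 2.68 |

The secondary bands (a red vibronic shoulder for HL, a residual blue
shoulder for HM) are essential, not cosmetic: a single-Gaussian synchronous
band has exactly one derivative zero crossing — at its own centre — which
would force each analyte to be read at the partner's band maximum. The
shoulders give each derivative an additional crossing *inside* the partner's
band, which is the geometry the zero-crossing technique actually uses.

These parameters are a **frozen numerical calibration** of the simulator:
widths, shoulder positions/amplitudes and the HM/HL response ratio were
fitted once (Nelder–Mead on the selection residuals) so that the full
pipeline returns readouts at 419 and 456 nm and the 20–80 nm offset screen
peaks at 50 nm, and they have not been revisited since. The emission maxima
(400/455 nm), the excitation wavelength (285 nm), the linear range and the
readout/offset targets are the method's stated operating points; everything
else is the package's own choice. Consequence for interpretation: tests
that recover 419/456/50 from these models demonstrate the *internal
consistency* of the pipeline, not an independent prediction about the
instrument.

### Grids

Default grids are 1 nm steps, emission 290–600 nm, excitation 240–560 nm.
The excitation span is deliberately wide: reading HM at 456 nm with
Δλ = 50 nm means exciting at 406 nm, and screening offsets down to 20 nm
across the full emission window needs excitation up to 560 nm. A grid
truncated at the excitation band (say 240–340 nm) would silently cut the
synchronous spectrum off at λ~em~ = 390 nm and make the published readouts
unreachable.

### Noise

Per-pixel noise is `I*(1 + N(0, p)) + N(0, a)` with defaults `p = 5e-4`,
`a = 2e-3` intensity units. Two calibration constraints fixed these, once:

* the repeatability RSD of a nine-determination accuracy study (3 levels ×
  3 replicates at 10/50/100 ng/mL, quantified through a freshly fitted
  seven-level calibration) averages ≈ 0.8%, the magnitude the bench method
  reports for the same design;
* the noise floor must be proportional-dominant. A purely additive model
  tuned to the same figure at 50 ng/mL puts ≈ 4% RSD on the 10 ng/mL level,
  which is not how fluorometer noise behaves and would break the ICH-style
  precision band at the low level.

All randomness flows from the `noise_model()` seed through R's default
Mersenne–Twister generator, applied via `withr::with_seed()` so global RNG
state is never touched; per-level and per-study seeds are derived
arithmetically from the base seed, and every simulated object is
bit-reproducible.

What the generator does **not** emulate: Rayleigh/Raman scatter ridges,
inner-filter attenuation at high absorbance, photobleaching, band
asymmetry, pH-dependent band structure (robustness proxies are rigid shifts
and scale changes, see below) and between-sample matrix variability beyond a
fixed analytic background. A pass on simulated data therefore certifies the
numerical method — extraction, differentiation, selection, calibration,
inversion — under idealised spectra; it does not certify performance on a
real instrument.

## Numerical choices in the pipeline

**Synchronous extraction** interpolates linearly along the excitation axis
when λ~em~ − Δλ falls between grid points (error O(step²)); the result is
restricted to emission wavelengths whose diagonal partner lies inside the
EEM, and fewer than 9 such points is an error rather than a silent short
spectrum. Spectra are indexed by the *emission* wavelength: the HM readout
at 456 nm coincides with its stated emission maximum at 455 nm, which fixes
the axis convention.

**Derivative.** The Savitzky–Golay filter uses a 9-point window. The
polynomial order defaults to 3, not the more customary 2: for a first
derivative over a symmetric window the quadratic and cubic weights differ,
and on a 25 nm-wide Gaussian band sampled at 1 nm the quadratic filter
leaves a measured ~0.7% peak bias while the cubic is exact to ~2 × 10⁻⁵.
Order 2 remains available (`poly_order = 2`). Edge points come from
one-sided polynomial fits over the first/last window (the filter matrix's
boundary rows), never from truncation — a linear ramp differentiates
exactly at every point including the ends. Amplitudes are scaled by the
grid step, so units are intensity per nm, and they are **signed**:
calibration uses the signed value (readouts on a falling flank give
negative slopes), never the absolute value.

**Zero crossings** are located by linear interpolation between bracketing
grid points of opposite sign. At the interpolated crossing the linearly
interpolated derivative of that component is *exactly* zero, and every
operation upstream (extraction, filtering, interpolation) is linear in the
EEM — so a mixture read exactly at an interferent crossing carries zero
interferent contribution to machine precision. This is why
`select_analytical_wavelengths()` defaults to `tolerance = 0` (readout
pinned to the crossing): a nonzero tolerance lets the readout drift toward
a larger analyte amplitude but trades away the exact cancellation. A
relative flank guard (1% of the interferent's maximum amplitude) discards
crossings produced by numerical ripple, and regions where the interferent
is identically zero (disjoint bands) count as interference-free, so a
non-overlapping pair resolves to each analyte's global amplitude maximum.
If an interferent has no usable crossing at all, the selector falls back to
the grid wavelength minimising the interferent-to-analyte amplitude ratio
and flags it — flagged wavelengths do not carry the exactness guarantee.

**Resolution score.** For the offset screen each candidate Δλ is scored by
`min` over the two readouts of `|analyte| / (|interferent| + ε)` with
`ε = 10⁻³ · max(max|dA|, max|dB|)`. Tying ε to the *joint* amplitude scale
keeps the score finite at exact crossings and invariant under joint
rescaling, while letting the relative intensity of the two components
enter. That last property is what produces an interior optimum: small
offsets favour the blue-emitting HL complex, large offsets the red-emitting
HM complex, and the minimum of the two one-sided scores peaks where the
pair is balanced — at 50 nm for the default models, with the 419/456 nm
readouts stable across the 30–70 nm range of the screen.

**Calibration.** Plain OLS (`stats::lm`); weighting is deliberately
omitted — the assay's dilute range shows no documented heteroscedasticity.
σ is the regression residual SD with the n−2 denominator (ICH permits
either this or a blank-based SD; the regression definition is the one the
printed limits are consistent with), and LOD/LOQ are 3.3σ/|S| and 10σ/|S|,
multipliers configurable. Their ratio 10/3.3 is structural. Inverse
prediction returns negative estimates as-is with a flag (`below_loq`,
`out_of_range`, `ok`) rather than truncating. Report tables round to two
decimals (round-half-even); comparisons against published worked examples
use ±0.01 to absorb the mixed rounding/truncation in the printed tables.

## Validation studies

* **Accuracy/precision**: 3 replicates × {10, 50, 100} ng/mL × 3 sessions;
  each determination is a two-analyte mixture so cross-interference is
  exercised. The between-session effect is a seeded response-scale jitter
  (SD 0.3%) on sessions after the first — a minimal model of day-to-day
  drift. Accuracy and repeatability come from session 1's nine
  determinations; intermediate precision pools the within-session variance
  with the non-negative between-session variance component.
* **Robustness** re-simulates the accuracy design with perturbed models
  while quantifying against the *unperturbed* calibration — the mismatch is
  the test. Bench factors map to spectral proxies: pH ± 0.5 → ± 0.1 nm
  rigid band shift (near the buffered optimum the complexed bands move very
  little; the zero-crossing geometry makes recovery sensitive to shifts, at
  roughly 12% per nm on the HM readout, which is exactly why robustness is
  worth testing), buffer volume ± 0.25 mL → ± 1.5% response, HP-β-CD
  volume ± 0.1 mL → ± 1% response.
* **Specificity** runs the two published added-concentration designs —
  (75, 25), (100, 100), (25, 75) ng/mL synthetic mixtures and (67, 200),
  (120, 120), (200, 67) ng/mL spiked plasma. Plasma simulations add the
  analytic plasma background and subtract a simulated parallel blank before
  measurement, mirroring blank correction at the bench. Noise-free,
  every recovery is 100% to ~10⁻¹³ — the operational form of the
  "no interference" claim.

Problem sizes were chosen to keep every study cheap while preserving the
published designs: single EEMs are 321 × 311 points, a full validation
report simulates on the order of 150 EEMs and runs in seconds.

## Known limitations

* The nine-determination RSD is itself a noisy estimator (few degrees of
  freedom), and the seven-point calibration's residual SD (5 df) is
  heavy-tailed; occasional seeds push the simulated repeatability RSD past
  2% or the LOD a factor of 2 from its typical value. The packaged default
  seed meets all bands with margin, but single-seed precision figures
  should be read as draws, not properties.
* Simulator parameters were tuned to reproduce the method's stated
  operating points, so agreement with those points validates the pipeline's
  internal consistency only (see above).
* Instrument-bound figures (absolute slopes/intercepts, the printed LODs,
  real-sample concentrations) are not reproducible from a simulator and are
  not targeted; the package asserts structure (linearity, limit ratios,
  recovery bands) instead.
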