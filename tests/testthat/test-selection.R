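test_that("disjoint-support pairs resolve to each analyte's global maximum", {
  em <- wl_grid(300, 600)
  # bands compactly supported (set tails to exact zero)
  ya <- gauss(em, 360, 10); ya[abs(em - 360) > 60] <- 0
  yb <- gauss(em, 520, 10); yb[abs(em - 520) > 60] <- 0
  da <- savgol_first_derivative(synchrofluor:::new_sync_spectrum(em, ya, 50))
  db <- savgol_first_derivative(synchrofluor:::new_sync_spectrum(em, yb, 50))
  wl <- select_analytical_wavelengths(da, db)
  expect_false(wl$fallback_a || wl$fallback_b)
  expect_equal(wl$lambda_a,
               da$wavelength_nm[which.max(abs(da$d_intensity))],
               tolerance = 1e-6)
  expect_equal(wl$lambda_b,
               db$wavelength_nm[which.max(abs(db$d_intensity))],
               tolerance = 1e-6)
})

test_that("default complexed models read out at 419 and 456 nm", {
  pair <- default_complexed_pair()
  wl <- select_default_wavelengths(pair)
  expect_lt(abs(wl$lambda_a - 419), 2)
  expect_lt(abs(wl$lambda_b - 456), 2)
})

test_that("selection is invariant under joint rescaling of both spectra", {
  pair <- default_complexed_pair()
  da <- derivative_pipeline(simulate_eem(list(component(pair$hl, 80))))
  db <- derivative_pipeline(simulate_eem(list(component(pair$hm, 80))))
  scale_spec <- function(d, k) {
    d$d_intensity <- d$d_intensity * k
    d
  }
  wl1 <- select_analytical_wavelengths(da, db)
  wl2 <- select_analytical_wavelengths(scale_spec(da, 137.5),
                                       scale_spec(db, 137.5))
  expect_equal(wl1$lambda_a, wl2$lambda_a, tolerance = 1e-12)
  expect_equal(wl1$lambda_b, wl2$lambda_b, tolerance = 1e-12)
})

test_that("selection agrees with a brute-force crossing/amplitude search", {
  for (seed in c(3, 17)) {
    sa <- three_band_spectrum(seed)
    sb <- three_band_spectrum(seed + 100)
    da <- savgol_first_derivative(sa)
    db <- savgol_first_derivative(sb)
    wl <- select_analytical_wavelengths(da, db, min_flank_frac = 0)
    # oracle: scan every crossing of the interferent plus every grid point
    # where the interferent has decayed to relative machine zero, then
    # evaluate |analyte| at each candidate
    candidates <- function(analyte, interferent) {
      c(brute_crossings(interferent$wavelength_nm, interferent$d_intensity),
        interferent$wavelength_nm[abs(interferent$d_intensity) <=
                                    1e-12 * max(abs(interferent$d_intensity))])
    }
    ca <- candidates(da, db)
    amps <- abs(approx(da$wavelength_nm, da$d_intensity, xout = ca)$y)
    expect_equal(wl$lambda_a, ca[which.max(amps)], tolerance = 1e-10)
    cb <- candidates(db, da)
    amps_b <- abs(approx(db$wavelength_nm, db$d_intensity, xout = cb)$y)
    expect_equal(wl$lambda_b, cb[which.max(amps_b)], tolerance = 1e-10)
  }
})

test_that("selection falls back to a ratio minimum when no crossing exists", {
  em <- wl_grid(300, 400)
  # monotone interferent derivative (no crossing, nowhere exactly zero)
  da <- savgol_first_derivative(
    synchrofluor:::new_sync_spectrum(em, gauss(em, 350, 15), 50))
  db <- savgol_first_derivative(
    synchrofluor:::new_sync_spectrum(em, exp(em / 200), 50))
  wl <- select_analytical_wavelengths(da, db)
  expect_true(wl$fallback_a)
  expect_true(wl$lambda_a >= 300 && wl$lambda_a <= 400)
})

test_that("resolution score behaves at its limits and ranks offsets correctly", {
  em <- wl_grid(300, 400)
  da <- savgol_first_derivative(
    synchrofluor:::new_sync_spectrum(em, gauss(em, 350, 15), 50))
  zero <- da; zero$d_intensity <- rep(0, length(em))
  wl <- tibble::tibble(lambda_a = 335, lambda_b = 335)
  # interferent identically zero: score = |analyte| / guard, large but finite
  s <- resolution_score(da, zero, wl, eps_rel = 1e-3)
  expect_true(is.finite(s))
  expect_equal(s, abs(amplitude_at(da, 335)) /
                 (1e-3 * max(abs(da$d_intensity))), tolerance = 1e-12)
  # identical spectra score ~ 1
  expect_equal(resolution_score(da, da, wl), 1, tolerance = 2e-3)

  # ranking across offsets equals elementwise recomputation
  pair <- default_complexed_pair()
  sc <- delta_lambda_screen(pair, candidates = c(30, 50, 70))
  redo <- vapply(c(30, 50, 70), function(dl) {
    da <- derivative_pipeline(simulate_eem(list(component(pair$hl, 100))), dl)
    db <- derivative_pipeline(simulate_eem(list(component(pair$hm, 100))), dl)
    resolution_score(da, db, select_analytical_wavelengths(da, db))
  }, numeric(1))
  expect_equal(sc$table$score, redo, tolerance = 1e-12)
  expect_equal(order(sc$table$score), order(redo))
})
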