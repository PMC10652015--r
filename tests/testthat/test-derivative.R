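test_that("derivative of constant and affine spectra is exact, edges included", {
  em <- wl_grid(300, 400)
  const <- synchrofluor:::new_sync_spectrum(em, rep(2.5, length(em)), 50)
  d0 <- savgol_first_derivative(const)
  expect_true(all(abs(d0$d_intensity) < 1e-12))
  ramp <- synchrofluor:::new_sync_spectrum(em, 3 + 0.7 * em, 50)
  d1 <- savgol_first_derivative(ramp)
  expect_equal(d1$d_intensity, rep(0.7, length(em)), tolerance = 1e-10)
  # step scaling: same ramp sampled at 0.5 nm still has slope 0.7 per nm
  em2 <- wl_grid(300, 400, 0.5)
  ramp2 <- synchrofluor:::new_sync_spectrum(em2, 3 + 0.7 * em2, 50)
  expect_equal(savgol_first_derivative(ramp2)$d_intensity,
               rep(0.7, length(em2)), tolerance = 1e-10)
})

test_that("9-point derivative of a sampled Gaussian matches the analytic derivative", {
  em <- wl_grid(300, 600)
  spec <- synchrofluor:::new_sync_spectrum(em, gauss(em, 455, 25), 50)
  d <- savgol_first_derivative(spec, window_points = 9, poly_order = 3)
  analytic <- -(em - 455) / 25^2 * gauss(em, 455, 25)
  expect_lt(max(abs(d$d_intensity - analytic)) / max(abs(analytic)), 1e-3)
  # the quadratic filter is available but visibly more biased
  d2 <- savgol_first_derivative(spec, window_points = 9, poly_order = 2)
  expect_gt(max(abs(d2$d_intensity - analytic)) / max(abs(analytic)), 1e-3)
})

test_that("derivative and extraction commute with scaling and addition", {
  e1 <- gauss_eem(em_center = 410, em_width = 22)
  e2 <- gauss_eem(em_center = 470, em_width = 15)
  d_sum <- savgol_first_derivative(extract_synchronous(e1 + e2, 50))
  d1 <- savgol_first_derivative(extract_synchronous(e1, 50))
  d2 <- savgol_first_derivative(extract_synchronous(e2, 50))
  expect_equal(d_sum$d_intensity, d1$d_intensity + d2$d_intensity,
               tolerance = 1e-12)
})

test_that("derivative input contracts are enforced", {
  em <- wl_grid(300, 320)
  s <- synchrofluor:::new_sync_spectrum(em, gauss(em, 310, 5), 50)
  expect_error(savgol_first_derivative(s, window_points = 8), "odd")
  expect_error(savgol_first_derivative(s, window_points = 9, poly_order = 9),
               "poly_order")
  short <- synchrofluor:::new_sync_spectrum(em[1:5], rep(1, 5), 50)
  expect_error(savgol_first_derivative(short), "shorter")
  uneven <- synchrofluor:::new_sync_spectrum(c(300, 301, 303, 304, 305, 306,
                                               307, 308, 309, 310),
                                             rnorm(10), 50)
  expect_error(savgol_first_derivative(uneven), "equally spaced")
})

test_that("amplitude readout interpolates linearly and respects the grid span", {
  em <- wl_grid(300, 310)
  d <- structure(tibble::tibble(wavelength_nm = em,
                                d_intensity = c(2, 4, 1, 0, 5, 2, 3, 1, 0, 2, 4)),
                 class = c("deriv_spectrum", class(tibble::tibble())))
  expect_identical(amplitude_at(d, 301), 4)      # on-grid: stored value
  expect_identical(amplitude_at(d, 300.5), 3)    # midway between 2 and 4
  expect_error(amplitude_at(d, 299.9), "outside")
  expect_error(amplitude_at(d, 310.1), "outside")
})

test_that("amplitude at the inflection point matches the closed form", {
  em <- wl_grid(300, 600)
  spec <- synchrofluor:::new_sync_spectrum(em, gauss(em, 455, 25), 50)
  d <- savgol_first_derivative(spec)
  # inflection at 455 - 25 nm: derivative extremum -(x-c)/w^2 * G(x) = exp(-1/2)/25
  expect_equal(amplitude_at(d, 430), exp(-0.5) / 25, tolerance = 1e-3)
})

test_that("zero crossings match an exhaustive sign-change scan", {
  em <- wl_grid(300, 400)
  up <- synchrofluor:::new_sync_spectrum(em, 1 + 0.01 * em, 50)
  d_up <- savgol_first_derivative(up)
  expect_length(find_zero_crossings(d_up), 0)

  spec <- synchrofluor:::new_sync_spectrum(em, gauss(em, 350, 12), 50)
  d <- savgol_first_derivative(spec)
  cr <- find_zero_crossings(d)
  expect_length(cr, 1)
  expect_lt(abs(cr - 350), 0.5)  # band centre +/- half a step

  for (seed in c(11, 42, 99)) {
    s3 <- three_band_spectrum(seed)
    d3 <- savgol_first_derivative(s3)
    expect_equal(find_zero_crossings(d3),
                 brute_crossings(d3$wavelength_nm, d3$d_intensity),
                 tolerance = 1e-12)
  }
})

test_that("the flank guard suppresses low-amplitude crossings only", {
  em <- wl_grid(300, 500)
  # strong band + tiny ripple band
  y <- gauss(em, 350, 12) + 0.001 * gauss(em, 460, 8)
  d <- savgol_first_derivative(synchrofluor:::new_sync_spectrum(em, y, 50))
  all_cr <- find_zero_crossings(d)
  expect_length(all_cr, 3)  # main peak, valley, ripple peak
  guarded <- find_zero_crossings(d, min_flank = 0.05 * max(abs(d$d_intensity)))
  # the ripple-peak crossing has two weak flanks and is suppressed; the
  # valley crossing keeps its strong left flank and survives
  expect_length(guarded, 2)
  expect_lt(abs(guarded[1] - 350), 0.5)
  expect_false(any(abs(guarded - 460) < 2))
})
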