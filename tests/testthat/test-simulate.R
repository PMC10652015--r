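test_that("default models reproduce the stated emission maxima and overlap", {
  m <- default_models()
  em <- default_em_grid()
  # complexed emission maxima at 400 (HL) and 455 nm (HM) for 285 nm excitation
  row_at_285 <- function(model) {
    e <- simulate_eem(list(component(model, 100)))
    e$intensity[match(285, e$ex_nm), ]
  }
  expect_equal(em[which.max(row_at_285(m$hl_complexed))], 400)
  expect_equal(em[which.max(row_at_285(m$hm_complexed))], 455)
  # free forms: heavy overlap inside 300-400 nm
  expect_gt(overlap_coefficient(m$hl_free, m$hm_free), 0.8)
  expect_lt(abs(m$hl_free$emission_bands$center -
                  m$hm_free$emission_bands$center), 15)
  expect_true(all(dplyr::between(m$hl_free$emission_bands$center, 300, 400)))
  expect_true(all(dplyr::between(m$hm_free$emission_bands$center, 300, 400)))
})

test_that("simulation is linear in concentration and matches the band formula", {
  m <- default_models()$hl_complexed
  zero <- simulate_eem(list(component(m, 0)))
  expect_true(all(zero$intensity == 0))
  e1 <- simulate_eem(list(component(m, 50)))
  e2 <- simulate_eem(list(component(m, 100)))
  expect_equal(e2$intensity, 2 * e1$intensity, tolerance = 1e-12)
  # pointwise oracle at random grid points
  withr::with_seed(5, {
    i <- sample(length(e1$ex_nm), 10)
    j <- sample(length(e1$em_nm), 10)
  })
  b <- m$emission_bands
  oracle <- 50 * m$response_factor *
    gauss(e1$ex_nm[i], m$ex_center, m$ex_width) *
    (b$rel_amplitude[1] * gauss(e1$em_nm[j], b$center[1], b$width[1]) +
       b$rel_amplitude[2] * gauss(e1$em_nm[j], b$center[2], b$width[2]))
  expect_equal(e1$intensity[cbind(i, j)], oracle, tolerance = 1e-12)
  expect_error(component(m, -5), "non-negative")
})

test_that("noise is reproducible from the seed alone", {
  m <- default_models()$hm_complexed
  nz <- noise_model(seed = 77)
  a <- simulate_eem(list(component(m, 40)), noise = nz)
  b <- simulate_eem(list(component(m, 40)), noise = nz)
  expect_identical(a$intensity, b$intensity)
  c <- simulate_eem(list(component(m, 40)), noise = noise_model(seed = 78))
  expect_false(identical(a$intensity, c$intensity))
  # the global RNG stream is untouched
  withr::with_seed(1, before <- rnorm(1))
  set.seed(1)
  invisible(simulate_eem(list(component(m, 40)), noise = nz))
  expect_identical(rnorm(1), before)
})

test_that("calibration series covers the linear range with derived seeds", {
  m <- default_models()$hl_complexed
  ser <- make_calibration_series(m)
  expect_equal(ser$concentration, c(10, 25, 50, 75, 100, 150, 200))
  expect_equal(nrow(ser), 7)
  noisy1 <- make_calibration_series(m, noise = noise_model(seed = 9))
  noisy2 <- make_calibration_series(m, noise = noise_model(seed = 9))
  expect_identical(purrr::map(noisy1$eem, "intensity"),
                   purrr::map(noisy2$eem, "intensity"))
  expect_error(make_calibration_series(m, concentrations = numeric(0)),
               "non-empty")
})

test_that("mixtures are additive and backgrounds separable (noise off)", {
  pair <- default_complexed_pair()
  mix <- make_mixture_set(tibble::tibble(c_hl = 75, c_hm = 25), pair)$eem[[1]]
  single_hl <- simulate_eem(list(component(pair$hl, 75)))
  single_hm <- simulate_eem(list(component(pair$hm, 25)))
  expect_equal(mix$intensity, single_hl$intensity + single_hm$intensity,
               tolerance = 1e-12)
  bg <- matrix_background("plasma_blank")
  with_bg <- simulate_eem(list(component(pair$hl, 75)), background = bg)
  blank <- simulate_eem(list(), background = bg)
  expect_equal((with_bg - blank)$intensity, single_hl$intensity,
               tolerance = 1e-12)
  expect_true(all(blank$intensity >= 0))
  # published designs
  expect_equal(default_mixture_design()$c_hl, c(75, 100, 25))
  expect_equal(default_mixture_design()$c_hm, c(25, 100, 75))
  expect_equal(default_plasma_design()$c_hl, c(67, 120, 200))
  expect_equal(default_plasma_design()$c_hm, c(200, 120, 67))
})

test_that("perturbations shift bands and scale response as declared", {
  m <- default_models()$hl_complexed
  expect_equal(apply_perturbation(m, perturbation(0, 0)), m)
  shifted <- apply_perturbation(m, perturbation(band_shift = 1))
  expect_equal(shifted$emission_bands$center, m$emission_bands$center + 1)
  scaled <- apply_perturbation(m, perturbation(intensity_scale_delta = 0.05))
  e0 <- simulate_eem(list(component(m, 100)))
  e1 <- simulate_eem(list(component(scaled, 100)))
  expect_equal(max(e1$intensity) / max(e0$intensity), 1.05, tolerance = 1e-12)
  expect_error(perturbation(band_shift = 6), "band_shift")
  expect_error(perturbation(intensity_scale_delta = 0.2), "intensity_scale")
})
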