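pair <- default_complexed_pair()
cal0 <- build_calibrations(pair, noise = NULL)

test_that("noise-free accuracy study recovers 100% exactly", {
  ap <- accuracy_precision_study(pair, cal0, noise = NULL, session_sd = 0,
                                 seed = 1)
  expect_true(all(abs(ap$determinations$recovery - 100) < 1e-9))
  expect_true(all(abs(ap$summary$accuracy - 100) < 1e-9))
  expect_true(all(ap$summary$repeatability_rsd < 1e-9))
  expect_true(all(ap$summary$intermediate_precision_rsd < 1e-9))
})

test_that("the study design yields nine determinations per analyte and session", {
  ap <- accuracy_precision_study(pair, cal0, noise = noise_model(seed = 4))
  det <- ap$determinations
  expect_equal(nrow(det), 3 * 3 * 3 * 2)  # sessions x levels x reps x analytes
  counts <- table(det$analyte, det$session)
  expect_true(all(counts == 9))
  expect_error(
    accuracy_precision_study(pair, cal0, levels = c(10, 500),
                             noise = NULL, seed = 1),
    "calibration range")
})

test_that("studies are reproducible bit-for-bit under a fixed seed", {
  a <- accuracy_precision_study(pair, cal0, noise = noise_model(seed = 31))
  b <- accuracy_precision_study(pair, cal0, noise = noise_model(seed = 31))
  expect_identical(a$determinations, b$determinations)
  s1 <- specificity_study(pair, cal0, noise = noise_model(seed = 8))
  s2 <- specificity_study(pair, cal0, noise = noise_model(seed = 8))
  expect_identical(s1$results, s2$results)
})

test_that("intermediate precision dominates the pooled within-session spread", {
  for (seed in c(2, 13, 27)) {
    ap <- accuracy_precision_study(pair, cal0,
                                   noise = noise_model(seed = seed),
                                   session_sd = 0.02, seed = seed)
    det <- ap$determinations
    for (an in c("HL", "HM")) {
      d <- det[det$analyte == an, ]
      s_w <- sqrt(mean(tapply(d$recovery, d$session, var)))
      pooled_within_rsd <- 100 * s_w / mean(d$recovery)
      ip <- ap$summary$intermediate_precision_rsd[ap$summary$analyte == an]
      expect_gte(ip, pooled_within_rsd - 1e-9)
    }
  }
})

test_that("an identity perturbation reproduces the accuracy determinations", {
  rb <- robustness_study(
    pair, cal0,
    design = tibble::tibble(label = "identity", band_shift = 0,
                            intensity_scale_delta = 0),
    noise = noise_model(seed = 6), seed = 6)
  ap <- accuracy_precision_study(pair, cal0, sessions = 1,
                                 noise = noise_model(seed = 6),
                                 session_sd = 0, seed = 6)
  plus <- rb$determinations[rb$determinations$sign == 1, ]
  expect_equal(sort(plus$found), sort(ap$determinations$found),
               tolerance = 1e-12)
})

test_that("the robustness table carries two signed sub-results per factor", {
  rb <- robustness_study(pair, cal0, noise = noise_model(seed = 3), seed = 3)
  expect_equal(nrow(rb$summary), 3 * 2 * 2)  # labels x signs x analytes
  expect_setequal(unique(rb$summary$sign), c(-1, 1))
  expect_error(
    robustness_study(pair, cal0,
                     design = tibble::tibble(label = c("a", "a"),
                                             band_shift = 0,
                                             intensity_scale_delta = 0),
                     noise = NULL),
    "unique")
})

test_that("noise-free specificity recovers every mixture exactly", {
  for (design in list(default_mixture_design(), default_plasma_design())) {
    sp <- specificity_study(pair, cal0, design = design, noise = NULL)
    expect_true(all(abs(sp$results$recovery - 100) < 1e-4))
  }
  # and with a plasma background + blank subtraction
  sp_bg <- specificity_study(pair, cal0, design = default_plasma_design(),
                             background = matrix_background("plasma_blank"),
                             noise = NULL)
  expect_true(all(abs(sp_bg$results$recovery - 100) < 1e-4))
})

test_that("offset screening returns its table consistently", {
  single <- delta_lambda_screen(pair, candidates = 45)
  expect_equal(single$best, 45)
  expect_error(delta_lambda_screen(pair, candidates = numeric(0)),
               "at least one")
  sc <- delta_lambda_screen(pair)
  expect_equal(sc$table$delta_lambda, seq(20, 80, 10))
  expect_equal(sc$best, sc$table$delta_lambda[which.max(sc$table$score)])
})

test_that("the full validation report is deterministic and renders", {
  rep1 <- validation_report(pair, noise = noise_model(seed = 5))
  rep2 <- validation_report(pair, noise = noise_model(seed = 5))
  expect_identical(rep1$accuracy$summary, rep2$accuracy$summary)
  expect_identical(rep1$plasma$results, rep2$plasma$results)
  json <- withr::local_tempfile(fileext = ".json")
  md <- withr::local_tempfile(fileext = ".md")
  write_validation_report(rep1, json_path = json, md_path = md)
  parsed <- jsonlite::read_json(json, simplifyVector = TRUE)
  expect_equal(parsed$best_delta_lambda, 50)
  expect_true(any(grepl("## Linearity", readLines(md))))
})
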