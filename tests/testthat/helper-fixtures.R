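# shared fixtures: analytic bands and small EEMs built in code

gauss <- function(x, center, width) exp(-0.5 * ((x - center) / width)^2)

# separable Gaussian EEM: G(ex) * G(em)
gauss_eem <- function(ex = wl_grid(240, 340), em = wl_grid(300, 600),
                      ex_center = 285, ex_width = 20,
                      em_center = 455, em_width = 25) {
  eem(ex, em, outer(gauss(ex, ex_center, ex_width),
                    gauss(em, em_center, em_width)))
}

constant_eem <- function(value = 1, ex = wl_grid(240, 340),
                         em = wl_grid(290, 420)) {
  eem(ex, em, matrix(value, length(ex), length(em)))
}

# spectrum with three Gaussian bands and a seeded jitter, used as a
# "realistic" multi-crossing fixture
three_band_spectrum <- function(seed, em = wl_grid(300, 560)) {
  withr::with_seed(seed, {
    centers <- sort(runif(3, 330, 520))
    widths <- runif(3, 10, 25)
    amps <- runif(3, 0.4, 1) * sample(c(-1, 1), 3, replace = TRUE)
    y <- amps[1] * gauss(em, centers[1], widths[1]) +
      amps[2] * gauss(em, centers[2], widths[2]) +
      amps[3] * gauss(em, centers[3], widths[3])
    synchrofluor:::new_sync_spectrum(em, y, 50)
  })
}

default_complexed_pair <- function() {
  m <- default_models()
  list(hl = m$hl_complexed, hm = m$hm_complexed)
}

# independent brute-force sign-change scan (same linear interpolation rule,
# written independently of find_zero_crossings)
brute_crossings <- function(wl, d) {
  out <- numeric(0)
  for (i in seq_len(length(d) - 1L)) {
    if (d[i] * d[i + 1L] < 0) {
      out <- c(out, wl[i] - d[i] * (wl[i + 1L] - wl[i]) / (d[i + 1L] - d[i]))
    }
  }
  out
}
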