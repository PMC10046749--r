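test_that("the Morse wavelet peaks at (beta/gamma)^(1/gamma)", {
  params <- morse_params(gamma = 3, beta = 20)
  w <- seq(0.01, 6, by = 1e-4)
  shape <- w^params$beta * exp(-w^params$gamma)
  expect_equal(w[which.max(shape)], (20 / 3)^(1 / 3), tolerance = 1e-3)

  # every bank row peaks at its nominal frequency, at unit height
  bank <- morse_filterbank(params, 512, 100)
  omega <- 2 * pi * (0:(bank$nfft - 1)) / bank$nfft
  for (s in c(1, 10, 25, length(bank$grid$scales))) {
    expect_equal(max(bank$bank[s, ]), 1)
    peak_hz <- omega[which.max(bank$bank[s, ])] * 100 / (2 * pi)
    df <- 100 / bank$nfft
    expect_lt(abs(peak_hz - bank$grid$freqs[s]), df)
  }
})

test_that("the scale grid is geometric and consistent with F = Fc*fs/a", {
  params <- morse_params(voices_per_octave = 12, freq_min = 0.4, freq_max = 8)
  bank <- morse_filterbank(params, 500, 100)
  grid <- bank$grid
  # F * a = Fc * fs to machine precision, for every scale
  expect_equal(grid$freqs * grid$scales,
               rep(grid$center_freq * grid$fs, length(grid$scales)),
               tolerance = 1e-12)
  expect_true(all(diff(grid$scales) > 0))
  expect_true(all(diff(grid$freqs) < 0))
  expect_equal(grid$freqs[1], 8)
  # doubling the voice density doubles (+-1) the number of scales
  n12 <- length(grid$scales)
  n24 <- length(morse_filterbank(morse_params(voices_per_octave = 24),
                                 500, 100)$grid$scales)
  expect_lte(abs(n24 - 2 * n12), 1)

  expect_equal(scale_to_freq(grid$center_freq * 100, grid$center_freq, 100), 1)
  expect_equal(scale_to_freq(5, 0.1, 100), 2 * scale_to_freq(10, 0.1, 100))
  expect_equal(scale_to_freq(10, Fc = 0.1, fs = 100), 1)
  expect_error(scale_to_freq(-1, 0.1, 100), "positive")

  expect_error(morse_filterbank(params, 100, 100), "at least")
  expect_error(morse_filterbank(morse_params(freq_max = 60), 500, 100),
               "fs/2")
})

test_that("pure tones produce ridges at the nearest grid frequency", {
  params <- morse_params()
  fs <- 100
  n <- 1000
  bank <- morse_filterbank(params, n, fs)
  tt <- (0:(n - 1)) / fs
  for (f in c(0.8, 1.2, 2.5)) {
    scal <- cwt_morse(sin(2 * pi * f * tt), bank)
    rf <- ridge_frequency(scal)
    # within one voice spacing of the true tone frequency
    expect_lt(abs(log2(rf / f)), 1 / params$voices_per_octave)
  }
})

test_that("the CWT is linear and rejects bad input", {
  bank <- morse_filterbank(morse_params(), 500, 100)
  x <- rnorm(500)
  s1 <- cwt_morse(x, bank)
  s2 <- cwt_morse(2 * x, bank)
  expect_equal(s2$magnitude, 2 * s1$magnitude, tolerance = 1e-12)
  expect_true(all(s1$magnitude >= 0))
  expect_equal(dim(s1$magnitude),
               c(length(bank$grid$scales), 500L))

  z <- cwt_morse(numeric(500), bank)
  expect_true(all(z$magnitude == 0))
  expect_error(cwt_morse(c(rnorm(499), NA), bank), "non-finite")
  expect_error(cwt_morse(rnorm(400), bank), "does not match")
})

test_that("rendering gives a normalized fixed-size RGB image", {
  bank <- morse_filterbank(morse_params(), 500, 100)
  x <- sin(2 * pi * 1.2 * (0:499) / 100) + rnorm(500, 0, 0.1)
  scal <- cwt_morse(x, bank)
  img <- render_scalogram(scal)
  expect_equal(dim(img), c(224L, 224L, 3L))
  expect_true(all(img >= 0 & img <= 1))

  img32 <- render_scalogram(scal, size = 32)
  expect_equal(dim(img32), c(32L, 32L, 3L))

  # per-image normalization: amplitude-scaled copies render identically
  scal2 <- cwt_morse(5 * x, bank)
  expect_identical(render_scalogram(scal2, size = 32), img32)

  expect_warning(flat <- render_scalogram(matrix(1, 4, 6), size = 16),
                 "constant")
  # uniform at the colormap origin: constant within each channel
  for (k in 1:3) expect_equal(length(unique(as.vector(flat[, , k]))), 1L)
  gray <- render_scalogram(scal, size = 16, grayscale = TRUE)
  expect_identical(gray[, , 1], gray[, , 3])
  expect_error(render_scalogram(matrix(numeric(0), 0, 0)), "non-empty")
})

test_that("scalogram images survive a PNG round trip", {
  bank <- morse_filterbank(morse_params(), 300, 100)
  img <- render_scalogram(cwt_morse(rnorm(300), bank), size = 32)
  path <- file.path(withr::local_tempdir(), "scal.png")
  write_scalogram_png(img, path)
  back <- read_scalogram_png(path)
  expect_equal(dim(back), dim(img))
  expect_lt(max(abs(back - img)), 1 / 255)  # 8-bit quantization only
})

test_that("stressed segments ridge at higher frequency than non-stressed", {
  cfg <- quiet_generator_config(duration_s = 20, seed = 21)
  bank <- morse_filterbank(morse_params(), 500, 100)
  ridge_of <- function(cond) {
    rec <- generate_recording(cfg, "S01", cond)
    cl <- preprocess_recording(rec)
    segs <- segment_signal(cl, 5)
    median(vapply(segs, function(s) ridge_frequency(cwt_morse(s$samples, bank)),
                  numeric(1)))
  }
  r_stress <- ridge_of("stressed")
  r_rest <- ridge_of("non_stressed")
  expect_gt(r_stress, r_rest)
  expect_equal(r_rest, cfg$hr_nonstressed / 60, tolerance = 0.15)
  expect_equal(r_stress, cfg$hr_stressed / 60, tolerance = 0.15)
})
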