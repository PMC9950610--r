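test_that("linear_spectrum isolates a tone and satisfies Parseval", {
  x <- make_sine(1000, 1.5)
  sp <- linear_spectrum(x, 0)
  i <- which.max(sp$amplitude)
  expect_equal(sp$freqs_hz[i], 1000)
  far <- abs(sp$freqs_hz - 1000) > 50
  expect_gte(sp$amplitude[i], 100 * max(sp$amplitude[far]))
  # zero signal
  z <- linear_spectrum(audio_signal(rep(0, 100), 1000), 0)
  expect_true(all(z$amplitude == 0))
  # Parseval with two-sided accounting
  y <- audio_signal(stats::rnorm(4096), 8000)
  sy <- linear_spectrum(y, 0)
  n <- 4096
  twosided <- sy$amplitude[1]^2 + sy$amplitude[n / 2 + 1]^2 +
    2 * sum(sy$amplitude[2:(n / 2)]^2)
  expect_equal(twosided / n, sum(y$samples^2), tolerance = 1e-9)
})

test_that("phase_randomize preserves the tapered amplitude spectrum and energy exactly", {
  x <- gen_white_noise(1.5, 24000, seed = 3)
  xt <- cosine_taper(x, 0.3)
  pr <- phase_randomize(x, seed = 9, taper_s = 0.3)
  a0 <- linear_spectrum(xt, 0)$amplitude
  a1 <- linear_spectrum(pr, 0)$amplitude
  expect_lt(max(abs(a1 - a0)) / max(a0), 1e-9)
  expect_equal(sum(pr$samples^2), sum(xt$samples^2), tolerance = 1e-9)
  # deterministic per seed, decorrelated across seeds
  expect_identical(phase_randomize(x, 9, 0.3)$samples, pr$samples)
  other <- phase_randomize(x, 10, 0.3)
  expect_lt(abs(stats::cor(pr$samples, other$samples)), 0.2)
})

test_that("envelope extraction recovers tone level, compression power law, and AM rate", {
  fb <- fb_fast()
  ctr <- fb$center_freqs_hz[18]
  for (A in c(0.25, 1)) {
    tone <- make_sine(ctr, 1.5, amp = A)
    env <- extract_envelopes(analyze_subbands(tone, fb))
    interior <- env$values[18, 100:500]
    expect_lt(max(abs(interior - A^0.3)) / A^0.3, 0.05)
  }
  # scaling the waveform by c scales the compressed envelope by c^0.3
  x <- gen_am_noise(500, 2000, 10, 1, 1.5, 24000, seed = 4)
  e1 <- extract_envelopes(analyze_subbands(x, fb))
  x3 <- audio_signal(3 * x$samples, 24000)
  e3 <- extract_envelopes(analyze_subbands(x3, fb))
  # tolerance reflects the power law's unbounded slope at envelope zeros
  # (depth-1 AM touches zero, where roundoff is amplified by ^0.3)
  expect_equal(e3$values, 3^0.3 * e1$values, tolerance = 1e-4)
  expect_true(all(e1$values >= 0))
  # silence
  e0 <- extract_envelopes(analyze_subbands(audio_signal(rep(0, 36000), 24000), fb))
  expect_true(all(e0$values == 0))
  expect_equal(ncol(e0$values), 600)  # 1.5 s at 400 Hz
  # 10 Hz AM appears as the dominant envelope component
  k <- which.min(abs(fb$center_freqs_hz - 1000))
  expect_equal(row_peak_hz(e1$values[k, ]), 10, tolerance = 1e-9)
})

test_that("the 2D envelope spectrum counts, concentrates, and shift-invariates correctly", {
  fb <- fb_fast()
  x <- gen_am_noise(500, 2000, 10, 1, 1.5, 24000, seed = 4)
  e <- extract_envelopes(analyze_subbands(x, fb))
  es <- envelope_spectrum_2d(e)
  expect_equal(es$n_unique, 32 * 600 / 2)
  expect_true(all(es$amplitude_2d >= 0))
  # constant matrix: all energy at the (0, 0) coefficient
  ec <- e; ec$values <- matrix(0.5, 32, 600)
  esc <- envelope_spectrum_2d(ec)
  expect_equal(esc$amplitude_2d[1, 1], 0.5 * 32 * 600)
  expect_lt(max(esc$amplitude_2d[-1]), 1e-9)
  # circular time shift leaves the amplitude spectrum unchanged
  eshift <- e; eshift$values <- e$values[, c(101:600, 1:100)]
  expect_equal(envelope_spectrum_2d(eshift)$amplitude_2d, es$amplitude_2d,
               tolerance = 1e-9)
})

test_that("imposing an envelope spectrum is exact, real, and an identity when matched", {
  fb <- fb_fast()
  x <- gen_am_noise(500, 2000, 10, 1, 1.5, 24000, seed = 4)
  e <- extract_envelopes(analyze_subbands(x, fb))
  target <- envelope_spectrum_2d(e)$amplitude_2d
  # matched source: identity
  same <- impose_envelope_spectrum(target, e)
  expect_lt(max(abs(same$values - e$values)), 1e-9 * max(e$values))
  # cross source: real output, target amplitude achieved pre-rectification
  y <- gen_white_noise(1.5, 24000, seed = 5)
  ey <- extract_envelopes(analyze_subbands(y, fb))
  imp <- impose_envelope_spectrum(target, ey)
  expect_lt(attr(imp, "max_imaginary"), 1e-9 * max(target))
  got <- Mod(stats::fft(attr(imp, "pre_rectification")))
  expect_lt(max(abs(got - target)), 1e-9 * max(target))
  expect_true(all(imp$values >= 0))
  expect_error(impose_envelope_spectrum(target[, 1:10], ey), "shape")
})

test_that("compression inversion and upsampling undo the envelope front end", {
  fb <- fb_fast()
  # constant row: pointwise power inversion
  e <- structure(list(values = matrix(0.5, 32, 600), env_rate_hz = 400,
                      compression_exponent = 0.3, duration_s = 1.5),
                 class = "envelope_matrix")
  up <- invert_compression_and_upsample(e, 24000)
  expect_equal(ncol(up), 36000)
  expect_lt(max(abs(up - 0.5^(1 / 0.3))), 1e-6)
  e$values[] <- 0
  expect_true(all(invert_compression_and_upsample(e, 24000) == 0))
  # smooth 5 Hz modulator survives the full round trip within 5%
  fs <- 24000
  t <- (0:35999) / fs
  modw <- audio_signal(gen_am_noise(800, 900, 0, 0, 1.5, fs, seed = 5)$samples *
                       (1 + 0.8 * sin(2 * pi * 5 * t)), fs)
  sb <- analyze_subbands(modw, fb)
  env <- extract_envelopes(sb)
  rec <- invert_compression_and_upsample(env, fs)
  k <- which.max(rowSums(sb$subbands^2))
  ref <- soundtexture:::hilbert_envelope(sb$subbands[k, ])
  expect_lt(sqrt(sum((rec[k, ] - ref)^2) / sum(ref^2)), 0.05)
})

test_that("two_stage_spectra serializes to identical bytes after a reload", {
  cfg <- cfg_fast()
  x <- preprocess(gen_am_noise(500, 2000, 10, 1, 2, 24000, seed = 6), cfg)
  ts <- two_stage_spectra(x, cfg)
  expect_equal(dim(ts$env_amplitude_2d), c(32, 600))
  expect_equal(ts$n_unique_env_points, 9600)
  d <- withr::local_tempdir()
  p1 <- file.path(d, "a"); p2 <- file.path(d, "b")
  write_two_stage_spectra(ts, p1)
  write_two_stage_spectra(read_two_stage_spectra(p1), p2)
  for (suffix in c("_linear_amplitude.txt", "_env_amplitude_2d.txt",
                   "_env_phase_2d.txt", ".json")) {
    expect_identical(readBin(paste0(p1, suffix), "raw", 1e7),
                     readBin(paste0(p2, suffix), "raw", 1e7))
  }
  # envelope matrix container round trip
  fb <- fb_fast()
  e <- extract_envelopes(analyze_subbands(x, fb))
  write_envelope_matrix(e, file.path(d, "env"))
  e2 <- read_envelope_matrix(file.path(d, "env"))
  expect_equal(e2$values, e$values)
  expect_equal(e2$compression_exponent, e$compression_exponent)
})
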