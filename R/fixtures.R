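#' Seeded Gaussian white noise fixture
#'
#' A stand-in for the unmodulated end of the natural-texture continuum:
#' spectrally flat, no envelope modulation structure.  RMS-normalized to
#' the pipeline's default level.
#'
#' @param duration_s Positive duration, s.
#' @param sample_rate_hz Sample rate, Hz (default 48000).
#' @param seed Integer RNG seed.
#' @param target_rms RMS normalization level (default 0.1).
#' @return A mono `audio_signal`.
#' @export
gen_white_noise <- function(duration_s, sample_rate_hz = 48000, seed = 0,
                            target_rms = 0.1) {
  if (duration_s <= 0) stop("duration must be positive")
  n <- round(duration_s * sample_rate_hz)
  s <- with_seed(seed, stats::rnorm(n))
  rms_normalize(audio_signal(s, sample_rate_hz), target_rms)
}

# Brick-wall band-pass of a vector in the frequency domain.
brickwall_bandpass <- function(v, fs, f_lo, f_hi) {
  n <- length(v)
  X <- stats::fft(v)
  f <- (0:(n - 1)) * fs / n
  f <- pmin(f, fs - f)
  X[f < f_lo | f > f_hi] <- 0
  Re(stats::fft(X, inverse = TRUE)) / n
}

#' Sinusoidally amplitude-modulated band-pass noise fixture
#'
#' Band-limited Gaussian noise multiplied by
#' `1 + mod_depth * cos(2 pi mod_hz t)` — the canonical repetitive texture
#' (sirens, sleigh bells, writing) whose envelope modulation spectrum has a
#' known discrete peak at `mod_hz`.
#'
#' @param carrier_lo_hz,carrier_hi_hz Carrier band edges, Hz, inside
#'   (0, Nyquist).
#' @param mod_hz Modulation rate, Hz; must be below half the 400 Hz
#'   envelope rate.
#' @param mod_depth Modulation depth in \[0, 1\]; 0 reduces to plain
#'   band-pass noise.
#' @param duration_s Positive duration, s.
#' @param sample_rate_hz Sample rate, Hz.
#' @param seed Integer RNG seed.
#' @param target_rms RMS normalization level.
#' @return A mono `audio_signal`.
#' @export
gen_am_noise <- function(carrier_lo_hz, carrier_hi_hz, mod_hz, mod_depth,
                         duration_s, sample_rate_hz = 48000, seed = 0,
                         target_rms = 0.1) {
  if (carrier_lo_hz <= 0 || carrier_hi_hz >= sample_rate_hz / 2 ||
      carrier_lo_hz >= carrier_hi_hz)
    stop("carrier band must lie inside (0, Nyquist)")
  if (mod_hz < 0 || mod_hz >= 200) stop("mod_hz must lie in [0, 200) (half the envelope rate)")
  if (mod_depth < 0 || mod_depth > 1) stop("mod_depth must lie in [0, 1]")
  if (duration_s <= 0) stop("duration must be positive")
  n <- round(duration_s * sample_rate_hz)
  carrier <- with_seed(seed, stats::rnorm(n))
  carrier <- brickwall_bandpass(carrier, sample_rate_hz, carrier_lo_hz, carrier_hi_hz)
  t <- (seq_len(n) - 1) / sample_rate_hz
  s <- carrier * (1 + mod_depth * cos(2 * pi * mod_hz * t))
  rms_normalize(audio_signal(s, sample_rate_hz), target_rms)
}

#' Click-train fixture
#'
#' Unit impulses at (optionally jittered) regular intervals, spectrally
#' safeguarded by a brick-wall low-pass just below Nyquist — a broadband
#' repetitive texture in the style of crackling.
#'
#' @param rate_hz Positive click rate, Hz.
#' @param jitter_s Uniform timing jitter half-width, s (0 = periodic).
#' @param duration_s Positive duration, s.
#' @param sample_rate_hz Sample rate, Hz.
#' @param seed Integer RNG seed (used only when `jitter_s > 0`).
#' @return A mono `audio_signal`.
#' @export
gen_click_train <- function(rate_hz, jitter_s = 0, duration_s = 3,
                            sample_rate_hz = 48000, seed = 0) {
  if (rate_hz <= 0) stop("click rate must be positive")
  if (duration_s <= 0) stop("duration must be positive")
  n <- round(duration_s * sample_rate_hz)
  n_clicks <- floor(duration_s * rate_hz)
  times <- (seq_len(n_clicks) - 1) / rate_hz
  if (jitter_s > 0)
    times <- times + with_seed(seed, stats::runif(n_clicks, -jitter_s, jitter_s))
  idx <- round(times * sample_rate_hz) + 1
  idx <- idx[idx >= 1 & idx <= n]
  s <- numeric(n)
  s[idx] <- 1
  s <- brickwall_bandpass(s, sample_rate_hz, 0, 0.95 * sample_rate_hz / 2)
  audio_signal(s, sample_rate_hz)
}

#' Multiband texture fixture with channel-dependent modulation
#'
#' Sums independent AM band-pass noises, one per spec, so different
#' cochlear channels carry different modulation rates — exercising the
#' joint time-by-channel structure of the 2D envelope spectrum.  Component
#' `i` uses seed `seed + i - 1`, so a single-spec call reproduces
#' [gen_am_noise()] exactly.
#'
#' @param band_specs List of lists/vectors with named fields `lo`, `hi`
#'   (carrier band, Hz), `mod_hz`, `depth`.  Bands must be disjoint.
#' @param duration_s Positive duration, s.
#' @param sample_rate_hz Sample rate, Hz.
#' @param seed Integer RNG base seed.
#' @return A mono `audio_signal` (sum of components, not renormalized).
#' @export
gen_multiband_texture <- function(band_specs, duration_s, sample_rate_hz = 48000,
                                  seed = 0) {
  if (!length(band_specs)) stop("need at least one band spec")
  bands <- t(vapply(band_specs, function(b) c(b[["lo"]], b[["hi"]]), numeric(2)))
  o <- order(bands[, 1])
  if (any(bands[o, 2][-nrow(bands)] > bands[o, 1][-1]))
    stop("carrier bands must be disjoint")
  n <- round(duration_s * sample_rate_hz)
  s <- numeric(n)
  for (i in seq_along(band_specs)) {
    b <- band_specs[[i]]
    comp <- gen_am_noise(b[["lo"]], b[["hi"]], b[["mod_hz"]], b[["depth"]],
                         duration_s, sample_rate_hz, seed = seed + i - 1)
    s <- s + comp$samples
  }
  audio_signal(s, sample_rate_hz)
}
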