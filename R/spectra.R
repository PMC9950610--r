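#' One-sided amplitude and phase spectrum of a waveform
#'
#' First stage of the two-stage representation: the discrete Fourier
#' amplitude spectrum of the cosine-tapered waveform (temporal-frequency
#' axis).
#'
#' @param x A mono `audio_signal`.
#' @param taper_s Edge taper in seconds applied before the transform
#'   (see [cosine_taper()]); 0 disables tapering.
#' @return List with `amplitude` and `phase` (length `floor(n/2) + 1`),
#'   `freqs_hz`, `n`, `sample_rate_hz`.
#' @export
linear_spectrum <- function(x, taper_s = 0) {
  assert_mono(x)
  xt <- cosine_taper(x, taper_s)
  n <- n_samples(xt)
  X <- stats::fft(xt$samples)
  nb <- n %/% 2L
  one <- X[1:(nb + 1L)]
  list(amplitude = Mod(one), phase = Arg(one),
       freqs_hz = (0:nb) * x$sample_rate_hz / n,
       n = n, sample_rate_hz = x$sample_rate_hz)
}

# Rebuild a full Hermitian DFT vector from one-sided modulus and phase and
# invert it to a real signal of length n.
inverse_from_onesided <- function(amplitude, phase, n) {
  nb <- n %/% 2L
  one <- amplitude * exp(1i * phase)
  full <- if (n %% 2L == 0L) c(one, Conj(one[nb:2])) else c(one, Conj(one[(nb + 1L):2]))
  Re(stats::fft(full, inverse = TRUE)) / n
}

#' Phase-randomized (PR) surrogate of a sound
#'
#' Keeps the amplitude spectrum of the tapered waveform exactly and replaces
#' every interior phase by an independent draw uniform on (-pi, pi] — the
#' phase spectrum of a white noise.  DC and Nyquist coefficients are kept as
#' in the input (they are real), and conjugate symmetry is enforced so the
#' output is exactly real.  Deterministic for a fixed `seed`; the caller's
#' RNG state is left untouched.
#'
#' @param x A mono `audio_signal`.
#' @param seed Integer RNG seed.
#' @param taper_s Edge taper in seconds applied before the transform.
#' @return A mono `audio_signal` of the same length and rate.
#' @export
phase_randomize <- function(x, seed = 0, taper_s = 0) {
  assert_mono(x)
  xt <- cosine_taper(x, taper_s)
  n <- n_samples(xt)
  X <- stats::fft(xt$samples)
  nb <- n %/% 2L
  one <- X[1:(nb + 1L)]
  ph <- Arg(one)
  # interior bins exclude DC and (for even n) the Nyquist bin
  hi <- if (n %% 2L == 0L) nb else nb + 1L
  if (hi >= 2L) {
    rnd <- with_seed(seed, stats::runif(hi - 1L, -pi, pi))
    ph[2:hi] <- rnd
  }
  audio_signal(inverse_from_onesided(Mod(one), ph, n), x$sample_rate_hz)
}

# Magnitude of the analytic signal (Hilbert envelope), FFT method.
hilbert_envelope <- function(v) {
  n <- length(v)
  V <- stats::fft(v)
  h <- numeric(n)
  if (n %% 2L == 0L) {
    h[1] <- 1; h[n %/% 2 + 1] <- 1; h[2:(n %/% 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) %/% 2)] <- 2
  }
  Mod(stats::fft(V * h, inverse = TRUE) / n)
}

# Band-limited resampling of a vector to an arbitrary length by Fourier
# truncation / zero-padding (brick-wall anti-aliasing, amplitude preserved).
fft_resample_to <- function(v, n_out) {
  n <- length(v)
  if (n_out == n) return(v)
  V <- stats::fft(v)
  out <- complex(n_out)
  half <- min(n, n_out) %/% 2L
  out[1] <- V[1]
  if (half >= 2L) {
    out[2:half] <- V[2:half]
    out[n_out - (2:half) + 2L] <- V[n - (2:half) + 2L]
  }
  if (min(n, n_out) %% 2L == 0L) {
    # shared Nyquist-edge bin must stay real for a real result
    out[half + 1L] <- Re(V[half + 1L])
  } else if (half + 1L <= n_out - half) {
    out[half + 1L] <- V[half + 1L]
    if (n_out - half + 1L <= n_out && half >= 1L && n_out > 2L * half)
      out[n_out - half + 1L] <- V[n - half + 1L]
  }
  Re(stats::fft(out, inverse = TRUE)) / n
}

#' Extract the compressed subband envelope matrix
#'
#' Second-stage front end: for each subband, the Hilbert envelope is taken,
#' downsampled (band-limited) to `env_rate_hz`, floored at zero, and
#' compressed by `value^compression` — a power-law nonlinearity emulating
#' cochlear transduction.
#'
#' @param s A `subband_set` from [analyze_subbands()].
#' @param env_rate_hz Envelope sample rate, Hz (default 400).
#' @param compression Compression exponent (default 0.3).
#' @return An object of class `envelope_matrix`: list with `values`
#'   (channels x time, nonnegative), `env_rate_hz`, `compression_exponent`,
#'   `duration_s`.
#' @export
extract_envelopes <- function(s, env_rate_hz = 400, compression = 0.3) {
  if (!inherits(s, "subband_set")) stop("expected a `subband_set`")
  if (env_rate_hz >= s$sample_rate_hz) stop("envelope rate must be below the audio rate")
  if (compression <= 0) stop("compression exponent must be positive")
  n <- ncol(s$subbands)
  dur <- n / s$sample_rate_hz
  n_env <- round(dur * env_rate_hz)
  vals <- matrix(0, nrow(s$subbands), n_env)
  for (k in seq_len(nrow(s$subbands))) {
    env <- hilbert_envelope(s$subbands[k, ])
    ds <- fft_resample_to(env, n_env)
    vals[k, ] <- pmax(ds, 0)^compression
  }
  structure(list(values = vals, env_rate_hz = env_rate_hz,
                 compression_exponent = compression, duration_s = dur),
            class = "envelope_matrix")
}

#' @export
print.envelope_matrix <- function(x, ...) {
  cat(sprintf("<envelope_matrix> %d channels x %d frames @ %g Hz, exponent %g\n",
              nrow(x$values), ncol(x$values), x$env_rate_hz, x$compression_exponent))
  invisible(x)
}

#' 2D amplitude and phase spectrum of an envelope matrix
#'
#' Second stage of the representation: the joint discrete Fourier transform
#' over the time axis (modulation frequency, Ft) and the channel axis
#' (frequency-of-modulation-frequency, Ffreq) of the compressed envelope
#' matrix.
#'
#' @param e An `envelope_matrix`.
#' @return List with `amplitude_2d` and `phase_2d` (channels x frames),
#'   `env_rate_hz`, `n_unique` — the number of non-redundant amplitude
#'   points for a real-valued matrix, `n_channels * n_frames / 2`.
#' @export
envelope_spectrum_2d <- function(e) {
  if (!inherits(e, "envelope_matrix")) stop("expected an `envelope_matrix`")
  F2 <- stats::fft(e$values)
  list(amplitude_2d = Mod(F2), phase_2d = Arg(F2),
       env_rate_hz = e$env_rate_hz,
       n_unique = nrow(e$values) * ncol(e$values) / 2)
}

#' Impose a target 2D envelope amplitude spectrum
#'
#' Combines a target 2D amplitude spectrum (typically the original sound's)
#' with the 2D phase spectrum of `phase_source` (typically the PR sound's
#' envelopes) and inverts.  Because both factors carry the Hermitian
#' symmetry of real matrices, the inverse is real up to numerical noise;
#' the tiny imaginary residue is discarded and negative values — which have
#' no physical meaning as energies — are floored at zero.
#'
#' @param target_amplitude_2d Nonnegative matrix, same shape as the
#'   phase source's values.
#' @param phase_source An `envelope_matrix` supplying the 2D phase.
#' @return An `envelope_matrix` with the imposed spectrum.  Attributes
#'   `max_imaginary` (largest |imaginary| of the inverse transform) and
#'   `pre_rectification` (the real part before flooring) are attached for
#'   diagnostics.
#' @export
impose_envelope_spectrum <- function(target_amplitude_2d, phase_source) {
  if (!inherits(phase_source, "envelope_matrix"))
    stop("`phase_source` must be an `envelope_matrix`")
  if (!all(dim(target_amplitude_2d) == dim(phase_source$values)))
    stop("target amplitude shape does not match the phase source")
  P <- Arg(stats::fft(phase_source$values))
  Z <- target_amplitude_2d * exp(1i * P)
  w <- stats::fft(Z, inverse = TRUE) / length(Z)
  out <- phase_source
  out$values <- pmax(Re(w), 0)
  attr(out, "max_imaginary") <- max(abs(Im(w)))
  attr(out, "pre_rectification") <- Re(w)
  out
}

#' Undo envelope compression and return to the audio rate
#'
#' Per channel: raise to `1/compression` (defined because envelope values
#' are nonnegative), band-limited upsample to the audio rate, floor at zero.
#'
#' @param e An `envelope_matrix`.
#' @param audio_rate_hz Target audio sample rate, Hz.
#' @return A channels x `round(duration_s * audio_rate_hz)` matrix of
#'   nonnegative envelopes at the audio rate.
#' @export
invert_compression_and_upsample <- function(e, audio_rate_hz) {
  if (!inherits(e, "envelope_matrix")) stop("expected an `envelope_matrix`")
  n_out <- round(e$duration_s * audio_rate_hz)
  out <- matrix(0, nrow(e$values), n_out)
  for (k in seq_len(nrow(e$values))) {
    v <- e$values[k, ]^(1 / e$compression_exponent)
    out[k, ] <- pmax(fft_resample_to(v, n_out), 0)
  }
  out
}

#' Compute the full two-stage spectral representation of a sound
#'
#' Convenience wrapper producing the pair of spectra that defines a texture
#' under this model: the 1D amplitude (+ phase) spectrum of the tapered
#' waveform and the 2D amplitude (+ phase) spectrum of its compressed
#' cochlear envelope matrix.
#'
#' @param x A mono `audio_signal` at the configured rate.
#' @param cfg A [synthesis_config()]; its taper, filterbank and envelope
#'   parameters are used.
#' @return An object of class `two_stage_spectra`: list with
#'   `linear_amplitude`, `linear_phase`, `freqs_hz`, `env_amplitude_2d`,
#'   `env_phase_2d`, `env_rate_hz`, `compression_exponent`, `duration_s`,
#'   `sample_rate_hz`, `n_unique_env_points`.
#' @export
two_stage_spectra <- function(x, cfg = synthesis_config()) {
  assert_mono(x)
  ls <- linear_spectrum(x, cfg$taper_s)
  fb <- design_filterbank(x$sample_rate_hz, n_samples(x), cfg$n_bandpass,
                          cfg$f_lo_hz, cfg$f_hi_hz)
  env <- extract_envelopes(analyze_subbands(cosine_taper(x, cfg$taper_s), fb),
                           cfg$env_rate_hz, cfg$compression_exponent)
  es <- envelope_spectrum_2d(env)
  structure(list(
    linear_amplitude = ls$amplitude, linear_phase = ls$phase,
    freqs_hz = ls$freqs_hz,
    env_amplitude_2d = es$amplitude_2d, env_phase_2d = es$phase_2d,
    env_rate_hz = env$env_rate_hz,
    compression_exponent = env$compression_exponent,
    duration_s = duration_s(x), sample_rate_hz = x$sample_rate_hz,
    n_unique_env_points = es$n_unique
  ), class = "two_stage_spectra")
}

#' @export
print.two_stage_spectra <- function(x, ...) {
  cat(sprintf(paste0("<two_stage_spectra> %.3g s @ %g Hz; 1D bins: %d; ",
                     "2D grid: %d x %d (%g unique points)\n"),
              x$duration_s, x$sample_rate_hz, length(x$linear_amplitude),
              nrow(x$env_amplitude_2d), ncol(x$env_amplitude_2d),
              x$n_unique_env_points))
  invisible(x)
}
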