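#' ERB-spaced band powers of a sound
#'
#' Integrates the power spectrum over `n_bands` contiguous bands whose
#' edges are equally spaced on the ERB-number axis between `f_lo` and
#' `f_hi` — the auditory analogue of a 1/3-octave band analysis.
#'
#' @param x A mono `audio_signal`.
#' @param n_bands Number of bands (default 30).
#' @param f_lo,f_hi Analysis range, Hz.
#' @return Numeric vector of band powers (linear units).
#' @export
erb_band_powers <- function(x, n_bands = 30, f_lo = 20, f_hi = 10000) {
  assert_mono(x)
  sp <- linear_spectrum(x, 0)
  edges <- erb_number_inverse(seq(erb_number(f_lo), erb_number(f_hi),
                                  length.out = n_bands + 1))
  band <- findInterval(sp$freqs_hz, edges, rightmost.closed = TRUE)
  pw <- numeric(n_bands)
  inb <- band >= 1 & band <= n_bands
  agg <- tapply(sp$amplitude[inb]^2, band[inb], sum)
  pw[as.integer(names(agg))] <- agg
  pw
}

#' Worst-case band-power difference between two sounds, in dB
#'
#' The maximum absolute difference of ERB-spaced band powers,
#' `max_b |10 log10(P_a(b) / P_b(b))|` — the objective check that a
#' synthesized sound preserved the first-stage (linear) spectrum.  Bands
#' more than 90 dB below the strongest band in either signal are excluded:
#' for band-limited material such bands hold only numerical leakage and
#' their power ratios are meaningless.
#'
#' @param a,b Mono `audio_signal`s of equal length and rate.
#' @param n_bands Number of ERB-spaced bands.
#' @param normalize If `TRUE`, each signal's band powers are divided by
#'   their total first, so the comparison is between band-power
#'   *profiles* (spectral shapes) and insensitive to overall level — e.g.
#'   to the energy removed by edge tapering.  Default `FALSE` compares
#'   absolute powers (so `b = 2 a` gives 20 log10(2) in every band).
#' @return Nonnegative scalar in dB (0 iff band powers are identical).
#' @export
linear_spectrum_error_db <- function(a, b, n_bands = 30, normalize = FALSE) {
  assert_mono(a); assert_mono(b)
  if (n_samples(a) != n_samples(b) || a$sample_rate_hz != b$sample_rate_hz)
    stop("signals must have equal length and sample rate")
  pa <- erb_band_powers(a, n_bands)
  pb <- erb_band_powers(b, n_bands)
  if (normalize) { pa <- pa / sum(pa); pb <- pb / sum(pb) }
  keep <- pa > 1e-9 * max(pa) & pb > 1e-9 * max(pb)
  if (!any(keep)) stop("no band carries energy in both signals")
  max(abs(10 * log10(pa[keep] / pb[keep])))
}

#' Relative error between two sounds' 2D envelope spectra
#'
#' `||A - B||_F / ||A||_F` where A and B are the 2D envelope amplitude
#' spectra of `a` and `b` under `cfg` — the objective check that a
#' synthesized sound preserved the second-stage spectrum.  Both signals
#' are tapered and analyzed identically.
#'
#' @param a,b Mono `audio_signal`s of equal length and rate.
#' @param cfg A `synthesis_config` supplying taper, filterbank and
#'   envelope parameters.
#' @return Nonnegative dimensionless scalar (0 iff spectra are identical).
#' @export
env_spectrum_error <- function(a, b, cfg = synthesis_config()) {
  assert_mono(a); assert_mono(b)
  if (n_samples(a) != n_samples(b) || a$sample_rate_hz != b$sample_rate_hz)
    stop("signals must have equal length and sample rate")
  A <- two_stage_spectra(a, cfg)$env_amplitude_2d
  B <- two_stage_spectra(b, cfg)$env_amplitude_2d
  sqrt(sum((A - B)^2)) / sqrt(sum(A^2))
}

#' Channel-averaged envelope modulation spectrum
#'
#' Extracts the compressed envelope matrix and averages the one-sided
#' amplitude spectra of the individual channel envelopes (DC removed per
#' channel before the transform).  Averaging amplitude spectra — rather
#' than transforming the channel-averaged envelope — keeps a modulation
#' peak visible even when its phase differs across channels.
#'
#' @param x A mono `audio_signal`.
#' @param cfg A `synthesis_config`.
#' @return List with `freqs_hz` (modulation frequencies, one-sided) and
#'   `amplitude` (averaged amplitude, same length); the DC bin is zero.
#' @export
modulation_spectrum <- function(x, cfg = synthesis_config()) {
  assert_mono(x)
  fb <- design_filterbank(x$sample_rate_hz, n_samples(x), cfg$n_bandpass,
                          cfg$f_lo_hz, cfg$f_hi_hz)
  env <- extract_envelopes(analyze_subbands(cosine_taper(x, cfg$taper_s), fb),
                           cfg$env_rate_hz, cfg$compression_exponent)
  n_env <- ncol(env$values)
  nb <- n_env %/% 2L
  acc <- numeric(nb + 1L)
  for (k in seq_len(nrow(env$values))) {
    v <- env$values[k, ] - mean(env$values[k, ])
    acc <- acc + Mod(stats::fft(v)[1:(nb + 1L)])
  }
  list(freqs_hz = (0:nb) * cfg$env_rate_hz / n_env,
       amplitude = acc / nrow(env$values))
}

#' Dominant modulation frequency of a modulation spectrum
#'
#' Location of the largest amplitude at or above `min_hz`.  The default
#' floor of 2 Hz excludes the low-frequency skirt that any finite tapered
#' segment carries: components slower than a few cycles per segment are
#' dominated by the segment window and by slow envelope drift rather than
#' by the texture's modulation structure.
#'
#' @param ms A modulation spectrum from [modulation_spectrum()].
#' @param min_hz Lowest modulation frequency considered (default 2).
#' @return The dominant modulation frequency in Hz.
#' @export
dominant_modulation_hz <- function(ms, min_hz = 2) {
  ok <- ms$freqs_hz >= min_hz
  if (!any(ok)) stop("no modulation bins at or above min_hz")
  ms$freqs_hz[ok][which.max(ms$amplitude[ok])]
}

#' Analysis-synthesis round-trip SNR through the filterbank
#'
#' Band-limits `x` to the filterbank's passband (brick wall), runs it
#' through analysis and synthesis, and reports
#' `10 log10(||x_bl||^2 / ||x_bl - x_hat||^2)`.
#'
#' @param x A mono, non-zero `audio_signal` matching the bank's rate and
#'   design length.
#' @param fb An `erb_filterbank`.
#' @return SNR in dB (`Inf` for an exact round trip).
#' @export
round_trip_snr_db <- function(x, fb) {
  assert_mono(x)
  if (all(x$samples == 0)) stop("round-trip SNR is undefined for a zero signal")
  n <- n_samples(x)
  X <- stats::fft(x$samples)
  freqs_full <- (0:(n - 1)) * x$sample_rate_hz / n
  freqs_full <- pmin(freqs_full, x$sample_rate_hz - freqs_full)  # fold
  X[freqs_full < fb$f_lo_hz | freqs_full > fb$f_hi_hz] <- 0
  x_bl <- audio_signal(Re(stats::fft(X, inverse = TRUE)) / n, x$sample_rate_hz)
  if (all(x_bl$samples == 0)) stop("signal has no energy inside the filterbank passband")
  xh <- synthesize_from_subbands(analyze_subbands(x_bl, fb))
  err <- sum((x_bl$samples - xh$samples)^2)
  if (err == 0) return(Inf)
  10 * log10(sum(x_bl$samples^2) / err)
}

#' Short-time Fourier spectrogram on a log-frequency grid
#'
#' Hann-windowed STFT magnitude, averaged onto a logarithmic frequency axis
#' for display (the rendering style used to compare original and
#' synthesized textures).
#'
#' @param x A mono `audio_signal`.
#' @param window_s Window length in seconds (default 0.025).
#' @param hop_s Hop in seconds (default 0.010); must satisfy
#'   `0 < hop_s < window_s`.
#' @param f_lo,f_hi Display frequency range, Hz.
#' @param n_freq Number of log-spaced display bins.
#' @return An object of class `texture_spectrogram`: list with `magnitude`
#'   (time x frequency), `times_s`, `freqs_hz`.
#' @export
spectrogram <- function(x, window_s = 0.025, hop_s = 0.010,
                        f_lo = 20, f_hi = 10000, n_freq = 128) {
  assert_mono(x)
  if (!(hop_s > 0 && window_s > hop_s)) stop("require window_s > hop_s > 0")
  fs <- x$sample_rate_hz
  w <- round(window_s * fs); h <- round(hop_s * fs)
  if (w > n_samples(x)) stop("window longer than the signal")
  win <- 0.5 * (1 - cos(2 * pi * (seq_len(w) - 1) / (w - 1)))
  starts <- seq(1, n_samples(x) - w + 1, by = h)
  nbin <- w %/% 2L
  freqs_fft <- (0:nbin) * fs / w
  S <- matrix(0, length(starts), nbin + 1L)
  for (i in seq_along(starts)) {
    seg <- x$samples[starts[i] + seq_len(w) - 1] * win
    S[i, ] <- Mod(stats::fft(seg)[1:(nbin + 1L)])
  }
  edges <- exp(seq(log(f_lo), log(f_hi), length.out = n_freq + 1))
  bin <- findInterval(freqs_fft, edges, rightmost.closed = TRUE)
  M <- matrix(0, length(starts), n_freq)
  for (b in seq_len(n_freq)) {
    cols <- which(bin == b)
    if (length(cols)) M[, b] <- rowMeans(S[, cols, drop = FALSE])
    else {
      # display bin narrower than an FFT bin: interpolate at its center
      fc <- sqrt(edges[b] * edges[b + 1])
      j <- findInterval(fc, freqs_fft)
      M[, b] <- S[, min(j, nbin + 1L)]
    }
  }
  structure(list(magnitude = M,
                 times_s = (starts - 1 + w / 2) / fs,
                 freqs_hz = sqrt(edges[-1] * edges[-(n_freq + 1)])),
            class = "texture_spectrogram")
}

#' Render a spectrogram to a PNG file
#'
#' @param sg A `texture_spectrogram`.
#' @param path Output PNG path.
#' @param dynamic_range_db Floor of the dB color scale below the maximum.
#' @return `path`, invisibly.
#' @export
plot_spectrogram <- function(sg, path, dynamic_range_db = 60) {
  if (!inherits(sg, "texture_spectrogram")) stop("expected a `texture_spectrogram`")
  db <- 20 * log10(pmax(sg$magnitude, .Machine$double.eps))
  db <- pmax(db, max(db) - dynamic_range_db)
  grDevices::png(path, width = 900, height = 500)
  on.exit(grDevices::dev.off())
  graphics::image(sg$times_s, seq_along(sg$freqs_hz), db,
                  col = grDevices::hcl.colors(256, "Inferno"),
                  xlab = "Time (s)", ylab = "Frequency (Hz)", yaxt = "n",
                  useRaster = TRUE)
  at <- pretty(seq_along(sg$freqs_hz), 6)
  at <- at[at >= 1 & at <= length(sg$freqs_hz)]
  graphics::axis(2, at = at, labels = signif(sg$freqs_hz[at], 3))
  invisible(path)
}

#' Compute the standard metric set for an (original, synthetic) pair
#'
#' @param a,b Mono `audio_signal`s of equal duration and rate.
#' @param cfg A `synthesis_config`.
#' @return A data frame with columns `metric` and `value`, rows
#'   `linear_spectrum_error_db`, `env_spectrum_error`, `round_trip_snr_db`
#'   (the latter measured on `a` through the configured filterbank).
#' @export
metric_table <- function(a, b, cfg = synthesis_config()) {
  fb <- design_filterbank(a$sample_rate_hz, n_samples(a), cfg$n_bandpass,
                          cfg$f_lo_hz, cfg$f_hi_hz)
  data.frame(
    metric = c("linear_spectrum_error_db", "env_spectrum_error",
               "round_trip_snr_db"),
    value = c(linear_spectrum_error_db(a, b),
              env_spectrum_error(a, b, cfg),
              round_trip_snr_db(a, fb)),
    stringsAsFactors = FALSE)
}
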