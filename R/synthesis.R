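#' Synthesis configuration
#'
#' Bundles every tunable parameter of the analysis/synthesis pipeline.
#' Defaults are the model's study conditions: 48 kHz audio, 3 s segments
#' with 600 ms edge tapers, a 32-channel ERB filterbank spanning
#' 20--10000 Hz, envelopes at 400 Hz compressed with exponent 0.3.
#' `target_rms` fixes the loudness normalization of every preprocessed
#' sound; `envelope_floor_eps` guards the division that extracts the
#' fine structure of silent channels; `n_outer_iterations = 1` performs the
#' single-pass synthesis, larger values alternate re-imposition of the
#' linear spectrum with envelope-spectrum imposition.
#'
#' @param sample_rate_hz Working audio rate, Hz.
#' @param segment_s Synthesis segment duration, s.
#' @param taper_s Raised-cosine edge taper, s.
#' @param n_bandpass Number of band-pass cochlear channels.
#' @param f_lo_hz,f_hi_hz Filterbank passband edges, Hz.
#' @param env_rate_hz Envelope sample rate, Hz.
#' @param compression_exponent Envelope compression power.
#' @param target_rms RMS amplitude every input is normalized to.
#' @param seed Integer RNG seed for the random phases.
#' @param n_outer_iterations Number of outer synthesis passes (>= 1).
#' @param envelope_floor_eps Floor applied to envelopes before division.
#' @return A validated list of class `synthesis_config`.
#' @export
synthesis_config <- function(sample_rate_hz = 48000, segment_s = 3,
                             taper_s = 0.6, n_bandpass = 30,
                             f_lo_hz = 20, f_hi_hz = 10000,
                             env_rate_hz = 400, compression_exponent = 0.3,
                             target_rms = 0.1, seed = 0L,
                             n_outer_iterations = 1L,
                             envelope_floor_eps = 1e-8) {
  cfg <- list(sample_rate_hz = sample_rate_hz, segment_s = segment_s,
              taper_s = taper_s, n_bandpass = as.integer(n_bandpass),
              f_lo_hz = f_lo_hz, f_hi_hz = f_hi_hz,
              env_rate_hz = env_rate_hz,
              compression_exponent = compression_exponent,
              target_rms = target_rms, seed = as.integer(seed),
              n_outer_iterations = as.integer(n_outer_iterations),
              envelope_floor_eps = envelope_floor_eps)
  if (2 * cfg$taper_s >= cfg$segment_s) stop("require 2 * taper_s < segment_s")
  if (cfg$f_lo_hz <= 0 || cfg$f_lo_hz >= cfg$f_hi_hz) stop("require 0 < f_lo < f_hi")
  if (cfg$f_hi_hz >= cfg$sample_rate_hz / 2) stop("require f_hi below Nyquist")
  if (cfg$compression_exponent <= 0) stop("compression exponent must be positive")
  if (cfg$n_outer_iterations < 1) stop("n_outer_iterations must be >= 1")
  if (cfg$env_rate_hz <= 0 || cfg$env_rate_hz >= cfg$sample_rate_hz)
    stop("envelope rate must be positive and below the audio rate")
  structure(cfg, class = "synthesis_config")
}

#' Read a synthesis configuration from a JSON file
#'
#' The file holds any subset of [synthesis_config()]'s fields; unspecified
#' fields keep their defaults.  `overrides` (e.g. command-line values) win
#' over file values.
#'
#' @param path Path to a JSON object file, or `NULL` for pure defaults.
#' @param overrides Named list of fields overriding the file.
#' @return A `synthesis_config`.
#' @export
read_config <- function(path = NULL, overrides = list()) {
  vals <- list()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    vals <- jsonlite::fromJSON(path, simplifyVector = TRUE)
    unknown <- setdiff(names(vals), names(formals(synthesis_config)))
    if (length(unknown))
      stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  }
  vals[names(overrides)] <- overrides
  do.call(synthesis_config, vals)
}

#' @export
print.synthesis_config <- function(x, ...) {
  cat("<synthesis_config>\n")
  for (nm in names(unclass(x))) cat(sprintf("  %-22s %g\n", nm, x[[nm]]))
  invisible(x)
}

#' Standard stimulus preprocessing
#'
#' Mono mixdown, resampling to the working rate, RMS normalization and
#' truncation to the synthesis segment length, in that order.
#'
#' @param x An `audio_signal` of at least `cfg$segment_s` seconds.
#' @param cfg A `synthesis_config`.
#' @return A mono `audio_signal` of exactly `cfg$segment_s` seconds at
#'   `cfg$sample_rate_hz`, RMS `cfg$target_rms`.
#' @export
preprocess <- function(x, cfg = synthesis_config()) {
  assert_audio(x)
  y <- to_mono(x)
  y <- resample_audio(y, cfg$sample_rate_hz)
  if (duration_s(y) < cfg$segment_s)
    stop(sprintf("input is %.3f s; at least %g s required", duration_s(y), cfg$segment_s))
  y <- extract_segment(y, 0, cfg$segment_s)
  rms_normalize(y, cfg$target_rms)
}

#' Synthesize the PR (phase-randomized) sound
#'
#' Produces a noise preserving only the first-stage (1D linear amplitude)
#' spectrum of the preprocessed original; all phase structure is replaced
#' by white-noise phases.
#'
#' @param x An `audio_signal` (any rate/channels; preprocessed internally).
#' @param cfg A `synthesis_config`; `cfg$seed` fixes the random phases.
#' @return A mono `audio_signal` of `cfg$segment_s` seconds.
#' @export
synthesize_pr <- function(x, cfg = synthesis_config()) {
  orig <- preprocess(x, cfg)
  phase_randomize(orig, cfg$seed, cfg$taper_s)
}

#' Synthesize the le-PR sound (two-stage spectra preserved)
#'
#' Full pipeline: (1) a PR sound supplies white-noise phase structure;
#' (2) both the tapered original and the PR sound are split into 32
#' cochlear subbands and their compressed 400 Hz envelope matrices are
#' extracted; (3) the 2D amplitude spectrum is taken from the original's
#' envelopes and the 2D phase from the PR's; (4) their combination is
#' inverse-transformed into new subband envelopes; (5) each PR subband is
#' demodulated to its fine structure (division by its own Hilbert
#' envelope, floored at `cfg$envelope_floor_eps`), remodulated by the new
#' envelope at the audio rate, refiltered by its channel gain, and the
#' channels are summed.  With `cfg$n_outer_iterations > 1`, the original's
#' linear spectrum is re-imposed on the result and steps (2)--(5) repeat
#' with the result as the new phase source.
#'
#' @param x An `audio_signal` (preprocessed internally).
#' @param cfg A `synthesis_config`.
#' @param phase_source Optional mono `audio_signal` (already at the
#'   preprocessed length and rate) used in place of the internally
#'   generated PR sound as the phase carrier.  It is edge-tapered exactly
#'   like the original before analysis, so passing the original itself
#'   makes the envelope imposition an identity and the pipeline must
#'   reproduce the tapered original up to the envelope round-trip error —
#'   a diagnostic hook.
#' @return A mono `audio_signal` of `cfg$segment_s` seconds.
#' @export
synthesize_lepr <- function(x, cfg = synthesis_config(), phase_source = NULL) {
  orig <- preprocess(x, cfg)
  ot <- cosine_taper(orig, cfg$taper_s)
  n <- n_samples(orig)
  fb <- design_filterbank(cfg$sample_rate_hz, n, cfg$n_bandpass,
                          cfg$f_lo_hz, cfg$f_hi_hz)
  ref_amp <- linear_spectrum(orig, cfg$taper_s)$amplitude

  env_o <- extract_envelopes(analyze_subbands(ot, fb),
                             cfg$env_rate_hz, cfg$compression_exponent)
  target_amp2 <- Mod(stats::fft(env_o$values))

  carrier <- if (is.null(phase_source)) {
    phase_randomize(orig, cfg$seed, cfg$taper_s)
  } else {
    assert_mono(phase_source)
    if (n_samples(phase_source) != n) stop("phase source length mismatch")
    cosine_taper(phase_source, cfg$taper_s)
  }

  y <- NULL
  for (iter in seq_len(cfg$n_outer_iterations)) {
    sub_p <- analyze_subbands(carrier, fb)
    env_p <- extract_envelopes(sub_p, cfg$env_rate_hz, cfg$compression_exponent)
    imposed <- impose_envelope_spectrum(target_amp2, env_p)
    new_env <- invert_compression_and_upsample(imposed, cfg$sample_rate_hz)

    new_sub <- sub_p
    for (k in seq_len(nrow(sub_p$subbands))) {
      env_k <- hilbert_envelope(sub_p$subbands[k, ])
      fine <- sub_p$subbands[k, ] / pmax(env_k, cfg$envelope_floor_eps)
      new_sub$subbands[k, ] <- fine * new_env[k, ]
    }
    y <- synthesize_from_subbands(new_sub)
    if (iter < cfg$n_outer_iterations) {
      carrier <- impose_linear_spectrum(y, ref_amp)
    }
  }
  y
}

#' Impose a reference 1D amplitude spectrum on a sound
#'
#' Replaces the one-sided amplitude spectrum of `y` by `reference_amplitude`
#' while keeping `y`'s phases; the output is exactly real.  Idempotent.
#'
#' @param y A mono `audio_signal`.
#' @param reference_amplitude Nonnegative vector of length
#'   `floor(n/2) + 1`.
#' @return A mono `audio_signal`.
#' @export
impose_linear_spectrum <- function(y, reference_amplitude) {
  assert_mono(y)
  n <- n_samples(y)
  nb <- n %/% 2L
  if (length(reference_amplitude) != nb + 1L)
    stop("reference amplitude length does not match the signal")
  ph <- Arg(stats::fft(y$samples)[1:(nb + 1L)])
  audio_signal(inverse_from_onesided(reference_amplitude, ph, n), y$sample_rate_hz)
}
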