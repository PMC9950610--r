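# Shared helpers: a reduced-rate configuration for fast unit tests (10 kHz
# passband still below Nyquist) and small deterministic signals.  Acceptance
# tests use the full study conditions instead (48 kHz, 3 s).

cfg_fast <- function(...) {
  synthesis_config(sample_rate_hz = 24000, segment_s = 1.5, taper_s = 0.3,
                   seed = 1L, ...)
}

make_sine <- function(freq_hz, duration_s = 1, sample_rate_hz = 24000, amp = 1,
                      phase = 0) {
  t <- (seq_len(round(duration_s * sample_rate_hz)) - 1) / sample_rate_hz
  audio_signal(amp * sin(2 * pi * freq_hz * t + phase), sample_rate_hz)
}

# memoized filterbank for the fast-test geometry
.fb_cache <- new.env(parent = emptyenv())
fb_fast <- function(n = 36000, fs = 24000) {
  key <- paste(fs, n)
  if (is.null(.fb_cache[[key]]))
    .fb_cache[[key]] <- design_filterbank(fs, n)
  .fb_cache[[key]]
}

snr_db <- function(ref, est) {
  10 * log10(sum(ref^2) / sum((ref - est)^2))
}

# largest nonzero-frequency peak of a single envelope row, in Hz
row_peak_hz <- function(v, env_rate_hz = 400, min_hz = 1) {
  v <- v - mean(v)
  n <- length(v)
  amp <- Mod(stats::fft(v)[1:(n %/% 2 + 1)])
  fr <- (0:(n %/% 2)) * env_rate_hz / n
  ok <- fr >= min_hz
  fr[ok][which.max(amp[ok])]
}
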