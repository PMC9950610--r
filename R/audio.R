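#' Construct an audio signal
#'
#' The basic container consumed and produced by every stage of the pipeline:
#' a sampled waveform (dimensionless amplitude, nominal range \[-1, 1\]) plus
#' its sample rate.  Multi-channel audio is held as a samples-by-channels
#' matrix; most operations require mono (see [to_mono()]).
#'
#' @param samples Numeric vector (mono) or matrix with one column per
#'   channel.  All values must be finite.
#' @param sample_rate_hz Positive sample rate in Hz (default 48000, the rate
#'   the synthesis pipeline works at).
#' @return An object of class `audio_signal` with elements `samples` and
#'   `sample_rate_hz`.
#' @examples
#' x <- audio_signal(sin(2 * pi * 440 * (0:999) / 8000), 8000)
#' duration_s(x)
#' @export
audio_signal <- function(samples, sample_rate_hz = 48000) {
  if (!is.numeric(samples) && !is.matrix(samples))
    stop("`samples` must be a numeric vector or matrix")
  if (!is.numeric(sample_rate_hz) || length(sample_rate_hz) != 1 ||
      !is.finite(sample_rate_hz) || sample_rate_hz <= 0)
    stop("`sample_rate_hz` must be a positive number")
  if (NROW(samples) < 1) stop("signal must contain at least one sample")
  if (!all(is.finite(samples))) stop("all samples must be finite")
  structure(list(samples = samples, sample_rate_hz = as.numeric(sample_rate_hz)),
            class = "audio_signal")
}

#' @export
print.audio_signal <- function(x, ...) {
  cat(sprintf("<audio_signal> %d samples x %d channel(s) @ %g Hz (%.3f s)\n",
              n_samples(x), n_channels(x), x$sample_rate_hz, duration_s(x)))
  invisible(x)
}

#' Number of samples per channel
#' @param x An `audio_signal`.
#' @return Integer sample count.
#' @export
n_samples <- function(x) NROW(x$samples)

#' Number of channels
#' @param x An `audio_signal`.
#' @return Integer channel count (1 for mono).
#' @export
n_channels <- function(x) if (is.matrix(x$samples)) ncol(x$samples) else 1L

#' Duration in seconds
#' @param x An `audio_signal`.
#' @return Duration = samples / rate.
#' @export
duration_s <- function(x) n_samples(x) / x$sample_rate_hz

assert_audio <- function(x) {
  if (!inherits(x, "audio_signal")) stop("expected an `audio_signal` object")
  invisible(x)
}

assert_mono <- function(x) {
  assert_audio(x)
  if (n_channels(x) != 1L) stop("expected a mono signal; call to_mono() first")
  invisible(x)
}

#' Mix down to mono
#'
#' Averages channels arithmetically; mono input is returned unchanged.
#'
#' @param x An `audio_signal` with one or more channels.
#' @return A mono `audio_signal`.
#' @export
to_mono <- function(x) {
  assert_audio(x)
  if (n_channels(x) == 1L) {
    if (is.matrix(x$samples)) x$samples <- drop(x$samples)
    return(x)
  }
  audio_signal(rowMeans(x$samples), x$sample_rate_hz)
}

#' Band-limited resampling
#'
#' Polyphase FIR resampling to a new rate.  The output length is
#' `round(n * target_hz / sample_rate_hz)`; equal rates are a no-op
#' returning the input unchanged.
#'
#' @param x A mono or multi-channel `audio_signal`.
#' @param target_hz Positive target sample rate in Hz.
#' @return An `audio_signal` at `target_hz`.
#' @export
resample_audio <- function(x, target_hz) {
  assert_audio(x)
  if (!is.numeric(target_hz) || length(target_hz) != 1 || target_hz <= 0)
    stop("`target_hz` must be a positive number")
  if (target_hz == x$sample_rate_hz) return(x)
  pq <- rational_ratio(target_hz, x$sample_rate_hz)
  n_out <- round(n_samples(x) * target_hz / x$sample_rate_hz)
  res1 <- function(v) {
    y <- signal::resample(as.numeric(v), pq[1], pq[2])
    if (length(y) >= n_out) y[seq_len(n_out)] else c(y, numeric(n_out - length(y)))
  }
  s <- if (is.matrix(x$samples)) apply(x$samples, 2, res1) else res1(x$samples)
  audio_signal(s, target_hz)
}

# Smallest integer p/q with p/q == a/b, tolerating non-integer rates
rational_ratio <- function(a, b) {
  scale <- 1
  while (scale <= 1e6 &&
         (abs(a * scale - round(a * scale)) > 1e-9 ||
          abs(b * scale - round(b * scale)) > 1e-9)) scale <- scale * 10
  p <- round(a * scale); q <- round(b * scale)
  g <- gcd_int(p, q)
  c(p / g, q / g)
}

gcd_int <- function(a, b) { while (b != 0) { t <- b; b <- a %% b; a <- t }; a }

#' Normalize to a fixed RMS amplitude
#'
#' @param x An `audio_signal`, not identically zero.
#' @param target_rms Positive target root-mean-square amplitude.
#' @return A rescaled `audio_signal` whose RMS equals `target_rms`.
#' @export
rms_normalize <- function(x, target_rms = 0.1) {
  assert_audio(x)
  if (!is.numeric(target_rms) || target_rms <= 0)
    stop("`target_rms` must be positive")
  r <- sqrt(mean(x$samples^2))
  if (r == 0) stop("cannot RMS-normalize an all-zero signal")
  audio_signal(x$samples * (target_rms / r), x$sample_rate_hz)
}

#' Raised-cosine taper of the signal edges
#'
#' Multiplies the first and last `ramp_s` seconds by half-Hann ramps rising
#' 0 to 1 and falling 1 to 0 (a Tukey-style taper); the interior is left
#' untouched and the end samples are exactly zero.  Used before any spectral
#' calculation to suppress boundary artifacts.
#'
#' @param x A mono `audio_signal`.
#' @param ramp_s Ramp duration in seconds; `2 * ramp_s` must not exceed the
#'   signal duration.  Zero is a no-op.
#' @return The tapered `audio_signal`.
#' @export
cosine_taper <- function(x, ramp_s) {
  assert_mono(x)
  if (!is.numeric(ramp_s) || length(ramp_s) != 1 || ramp_s < 0)
    stop("`ramp_s` must be a nonnegative number")
  n <- n_samples(x)
  n_ramp <- round(ramp_s * x$sample_rate_hz)
  if (n_ramp == 0) return(x)
  if (2 * n_ramp > n) stop("taper ramps longer than half the signal")
  w <- 0.5 * (1 - cos(pi * (seq_len(n_ramp) - 1) / n_ramp))
  s <- x$samples
  s[seq_len(n_ramp)] <- s[seq_len(n_ramp)] * w
  s[n - seq_len(n_ramp) + 1] <- s[n - seq_len(n_ramp) + 1] * w
  audio_signal(s, x$sample_rate_hz)
}

#' Extract a contiguous excerpt
#'
#' @param x An `audio_signal`.
#' @param start_s Nonnegative start time in seconds.
#' @param duration_s Positive excerpt duration in seconds;
#'   `start_s + duration_s` must fit inside the signal.
#' @return The excerpt as an `audio_signal` (sample-accurate boundaries).
#' @export
extract_segment <- function(x, start_s, duration_s) {
  assert_audio(x)
  if (start_s < 0) stop("`start_s` must be nonnegative")
  if (duration_s <= 0) stop("`duration_s` must be positive")
  i0 <- round(start_s * x$sample_rate_hz)
  len <- round(duration_s * x$sample_rate_hz)
  if (i0 + len > n_samples(x)) stop("requested segment extends past the end of the signal")
  idx <- i0 + seq_len(len)
  s <- if (is.matrix(x$samples)) x$samples[idx, , drop = FALSE] else x$samples[idx]
  audio_signal(s, x$sample_rate_hz)
}

# Run expr with a fixed RNG seed, restoring the caller's RNG state after.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
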