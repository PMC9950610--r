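#' ERB-number of a frequency
#'
#' Maps frequency in Hz onto the ERB-N (equivalent rectangular bandwidth)
#' scale of Glasberg and Moore:
#' `erb_number(f) = 21.4 * log10(4.37 * f / 1000 + 1)`.
#' Equal steps on this axis correspond to equal numbers of auditory-filter
#' bandwidths.
#'
#' @param f_hz Nonnegative frequency (vectorized), Hz.
#' @return ERB-number (dimensionless), 0 at 0 Hz, monotonically increasing.
#' @seealso [erb_number_inverse()]
#' @export
erb_number <- function(f_hz) {
  if (any(f_hz < 0)) stop("frequency must be nonnegative")
  21.4 * log10(4.37 * f_hz / 1000 + 1)
}

#' Frequency at an ERB-number
#'
#' Exact functional inverse of [erb_number()].
#'
#' @param e Nonnegative ERB-number (vectorized).
#' @return Frequency in Hz.
#' @export
erb_number_inverse <- function(e) {
  if (any(e < 0)) stop("ERB-number must be nonnegative")
  (10^(e / 21.4) - 1) * 1000 / 4.37
}

#' Design the 32-channel cochlear filterbank
#'
#' Builds zero-phase frequency-domain gain curves for one low-pass channel,
#' `n_bandpass` band-pass channels with center frequencies equally spaced on
#' the ERB-number axis between `f_lo` and `f_hi`, and one high-pass channel.
#' Each band-pass gain is a half-cosine on the ERB axis spanning its two
#' neighboring centers, so that squared gains sum to exactly 1 at every
#' frequency (the low- and high-pass channels complete the sum below the
#' lowest and above the highest band-pass center).  This perfect-
#' reconstruction property is what lets the synthesis stage recover a
#' waveform from modified subbands.
#'
#' Filters are designed for one exact signal length; analysis multiplies the
#' signal's full-length spectrum by each gain curve (zero phase, no group
#' delay).
#'
#' @param sample_rate_hz Audio sample rate, Hz.
#' @param n_samples Length (in samples) of the signals this bank will filter.
#' @param n_bandpass Number of band-pass channels (default 30, for 32 total).
#' @param f_lo,f_hi Passband edge frequencies, Hz (defaults 20 and 10000);
#'   `f_hi` must lie below the Nyquist frequency.
#' @return An object of class `erb_filterbank` with elements
#'   `sample_rate_hz`, `n_samples`, `n_fft_bins`, `center_freqs_hz` (length
#'   32, ascending: low-pass center, 30 band-pass centers, high-pass
#'   center), `gains` (32 x n_fft_bins, values in \[0, 1\]), `f_lo_hz`,
#'   `f_hi_hz`.
#' @export
design_filterbank <- function(sample_rate_hz, n_samples, n_bandpass = 30,
                              f_lo = 20, f_hi = 10000) {
  if (f_lo <= 0 || f_lo >= f_hi) stop("require 0 < f_lo < f_hi")
  if (f_hi >= sample_rate_hz / 2) stop("f_hi must be below the Nyquist frequency")
  if (n_bandpass < 1) stop("need at least one band-pass channel")
  n <- as.integer(n_samples)
  nb <- n %/% 2L
  freqs <- (0:nb) * sample_rate_hz / n
  e_f <- erb_number(freqs)

  # n_bandpass + 2 anchor points on the ERB axis; interior ones are the
  # band-pass centers, the extremes anchor the low/high-pass transitions.
  cuts <- seq(erb_number(f_lo), erb_number(f_hi), length.out = n_bandpass + 2)
  n_ch <- n_bandpass + 2L
  gains <- matrix(0, n_ch, nb + 1L)

  for (j in seq_len(n_bandpass)) {
    lo <- cuts[j]; hi <- cuts[j + 2]; ctr <- cuts[j + 1]
    inb <- e_f > lo & e_f < hi
    gains[j + 1L, inb] <- cos((e_f[inb] - ctr) / (hi - lo) * pi)
  }
  # Low-pass: unity below the first anchor, half-cosine rolloff to the first
  # band-pass center; complements the first band-pass so squared sums are 1.
  d1 <- cuts[2] - cuts[1]
  gains[1L, e_f <= cuts[1]] <- 1
  tr <- e_f > cuts[1] & e_f < cuts[2]
  gains[1L, tr] <- cos((e_f[tr] - cuts[1]) / d1 * pi / 2)
  # High-pass: mirror image at the top.
  dK <- cuts[n_ch] - cuts[n_ch - 1L]
  gains[n_ch, e_f >= cuts[n_ch]] <- 1
  tr <- e_f > cuts[n_ch - 1L] & e_f < cuts[n_ch]
  gains[n_ch, tr] <- cos((cuts[n_ch] - e_f[tr]) / dK * pi / 2)

  structure(list(
    sample_rate_hz = sample_rate_hz,
    n_samples = n,
    n_fft_bins = nb + 1L,
    center_freqs_hz = erb_number_inverse(cuts),
    gains = gains,
    f_lo_hz = f_lo,
    f_hi_hz = f_hi
  ), class = "erb_filterbank")
}

#' @export
print.erb_filterbank <- function(x, ...) {
  cat(sprintf("<erb_filterbank> %d channels, %g-%g Hz @ %g Hz, design length %d\n",
              nrow(x$gains), x$f_lo_hz, x$f_hi_hz, x$sample_rate_hz, x$n_samples))
  invisible(x)
}

# Mirror a one-sided gain curve onto the full DFT grid of length n.
full_gain <- function(g_onesided, n) {
  nb <- n %/% 2L
  if (n %% 2L == 0L) c(g_onesided, rev(g_onesided[2:nb]))
  else c(g_onesided, rev(g_onesided[2:(nb + 1L)]))
}

#' Split a sound into cochlear subbands
#'
#' Multiplies the signal's DFT by each channel's zero-phase gain curve and
#' inverts, yielding 32 real band-limited signals at the audio rate.
#'
#' @param x A mono `audio_signal` whose rate and length match the bank's
#'   design.
#' @param fb An `erb_filterbank` from [design_filterbank()].
#' @return An object of class `subband_set`: list with `subbands`
#'   (channels x samples matrix), `sample_rate_hz`, `filterbank`.
#' @export
analyze_subbands <- function(x, fb) {
  assert_mono(x)
  if (!inherits(fb, "erb_filterbank")) stop("`fb` must be an erb_filterbank")
  if (x$sample_rate_hz != fb$sample_rate_hz)
    stop("sample rate of signal does not match filterbank design")
  n <- n_samples(x)
  if (n != fb$n_samples)
    stop("signal length does not match filterbank design length")
  X <- stats::fft(x$samples)
  n_ch <- nrow(fb$gains)
  sub <- matrix(0, n_ch, n)
  for (k in seq_len(n_ch)) {
    gf <- full_gain(fb$gains[k, ], n)
    sub[k, ] <- Re(stats::fft(X * gf, inverse = TRUE)) / n
  }
  structure(list(subbands = sub, sample_rate_hz = x$sample_rate_hz,
                 filterbank = fb), class = "subband_set")
}

#' @export
print.subband_set <- function(x, ...) {
  cat(sprintf("<subband_set> %d channels x %d samples @ %g Hz\n",
              nrow(x$subbands), ncol(x$subbands), x$sample_rate_hz))
  invisible(x)
}

#' Recombine subbands into a waveform
#'
#' The dual of [analyze_subbands()] under the squared-sum-to-one design:
#' each subband is refiltered by its own channel gain (removing any
#' out-of-band components introduced by envelope manipulation) and the
#' channels are summed.
#'
#' @param s A `subband_set` (possibly with modified subbands).
#' @return A mono `audio_signal`.
#' @export
synthesize_from_subbands <- function(s) {
  if (!inherits(s, "subband_set")) stop("expected a `subband_set`")
  fb <- s$filterbank
  n <- ncol(s$subbands)
  if (n != fb$n_samples) stop("subband length does not match filterbank design length")
  acc <- complex(n)
  for (k in seq_len(nrow(s$subbands))) {
    gf <- full_gain(fb$gains[k, ], n)
    acc <- acc + stats::fft(s$subbands[k, ]) * gf
  }
  audio_signal(Re(stats::fft(acc, inverse = TRUE)) / n, s$sample_rate_hz)
}

#' Export a filterbank as plain tabular text
#'
#' Writes a TSV whose first column is frequency in Hz and remaining 32
#' columns are the channel gains, preceded by comment header lines carrying
#' the design parameters; [read_filterbank_tsv()] restores it.
#'
#' @param fb An `erb_filterbank`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_filterbank_tsv <- function(fb, path) {
  if (!inherits(fb, "erb_filterbank")) stop("expected an `erb_filterbank`")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# sample_rate_hz\t%.17g", fb$sample_rate_hz), con)
  writeLines(sprintf("# n_samples\t%d", fb$n_samples), con)
  writeLines(sprintf("# f_lo_hz\t%.17g", fb$f_lo_hz), con)
  writeLines(sprintf("# f_hi_hz\t%.17g", fb$f_hi_hz), con)
  writeLines(paste0("# center_freqs_hz\t",
                    paste(sprintf("%.17g", fb$center_freqs_hz), collapse = "\t")), con)
  freqs <- (seq_len(fb$n_fft_bins) - 1) * fb$sample_rate_hz / fb$n_samples
  utils::write.table(
    cbind(freq_hz = freqs, t(fb$gains)), con,
    sep = "\t", row.names = FALSE,
    col.names = c("freq_hz", paste0("ch", seq_len(nrow(fb$gains)))))
  invisible(path)
}

#' Import a filterbank written by [write_filterbank_tsv()]
#'
#' @param path Path to the TSV export.
#' @return An `erb_filterbank`.
#' @export
read_filterbank_tsv <- function(path) {
  hdr <- readLines(path, n = 5)
  meta <- lapply(strsplit(sub("^# ", "", hdr), "\t"), function(p) as.numeric(p[-1]))
  names(meta) <- vapply(strsplit(sub("^# ", "", hdr), "\t"), `[`, "", 1)
  tab <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#")
  structure(list(
    sample_rate_hz = meta$sample_rate_hz,
    n_samples = as.integer(meta$n_samples),
    n_fft_bins = nrow(tab),
    center_freqs_hz = meta$center_freqs_hz,
    gains = t(as.matrix(tab[, -1])),
    f_lo_hz = meta$f_lo_hz,
    f_hi_hz = meta$f_hi_hz
  ), class = "erb_filterbank")
}
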