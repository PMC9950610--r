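#' Read a RIFF WAV file
#'
#' Supports PCM 16/24/32-bit and IEEE float 32/64-bit, including
#' WAVE_FORMAT_EXTENSIBLE headers.  Integer PCM is scaled by
#' `2^(bits - 1)` so full-scale negative maps to exactly -1.0.
#' Multi-channel data is returned as a samples-by-channels matrix for
#' [to_mono()] to handle.
#'
#' @param path Path to an existing WAV file.
#' @return An `audio_signal` with samples in \[-1, 1\].
#' @seealso [write_wav()]
#' @export
read_wav <- function(path) {
  if (!file.exists(path)) stop("WAV file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("not a RIFF WAV file: ", path)
  readBin(con, "integer", 1, 4, endian = "little")  # chunk size, unused
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop("not a RIFF WAV file: ", path)

  fmt <- NULL; data_raw <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || nchar(id) < 4) break
    sz <- readBin(con, "integer", 1, 4, endian = "little")
    if (length(sz) == 0) break
    if (identical(id, "fmt ")) {
      body <- readBin(con, "raw", sz)
      fmt <- parse_fmt_chunk(body, path)
    } else if (identical(id, "data")) {
      data_raw <- readBin(con, "raw", sz)
    } else {
      seek(con, sz, origin = "current")
    }
    if (sz %% 2 == 1) seek(con, 1, origin = "current")  # chunk padding
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt)) stop("corrupt WAV (missing fmt chunk): ", path)
  if (is.null(data_raw)) stop("corrupt WAV (missing data chunk): ", path)

  s <- decode_wav_samples(data_raw, fmt, path)
  if (fmt$channels > 1) {
    s <- matrix(s, ncol = fmt$channels, byrow = TRUE)
  }
  audio_signal(s, fmt$sample_rate)
}

parse_fmt_chunk <- function(body, path) {
  u16 <- function(i) sum(as.integer(body[i + 0:1]) * c(1, 256))
  u32 <- function(i) sum(as.integer(body[i + 0:3]) * c(1, 256, 65536, 16777216))
  tag <- u16(1)
  fmt <- list(format = tag, channels = u16(3), sample_rate = u32(5), bits = u16(15))
  if (tag == 65534) {  # WAVE_FORMAT_EXTENSIBLE: subformat GUID at offset 24
    if (length(body) < 26) stop("corrupt WAV (truncated extensible fmt): ", path)
    fmt$format <- u16(25)
  }
  if (!fmt$format %in% c(1, 3))
    stop("unsupported WAV encoding (format tag ", fmt$format, "): ", path)
  fmt
}

decode_wav_samples <- function(raw, fmt, path) {
  n_bytes <- fmt$bits %/% 8
  n_vals <- length(raw) %/% n_bytes
  if (fmt$format == 3) {
    if (!fmt$bits %in% c(32, 64)) stop("unsupported float bit depth: ", path)
    return(readBin(raw, "numeric", n_vals, n_bytes, endian = "little"))
  }
  if (fmt$bits == 16) {
    readBin(raw, "integer", n_vals, 2, signed = TRUE, endian = "little") / 32768
  } else if (fmt$bits == 24) {
    b <- matrix(as.integer(raw[seq_len(n_vals * 3)]), nrow = 3)
    v <- b[1, ] + 256 * b[2, ] + 65536 * b[3, ]
    v <- ifelse(v >= 8388608, v - 16777216, v)
    v / 8388608
  } else if (fmt$bits == 32) {
    readBin(raw, "integer", n_vals, 4, signed = TRUE, endian = "little") / 2147483648
  } else {
    stop("unsupported PCM bit depth (", fmt$bits, "): ", path)
  }
}

#' Write a RIFF WAV file
#'
#' @param x An `audio_signal` (mono vector or samples-by-channels matrix).
#' @param path Output file path.
#' @param bit_depth One of `"float32"` (default; lossless for pipeline
#'   outputs), `"pcm16"`, `"pcm24"`, `"pcm32"`.
#' @return `path`, invisibly.
#' @export
write_wav <- function(x, path, bit_depth = c("float32", "pcm16", "pcm24", "pcm32")) {
  assert_audio(x)
  bit_depth <- match.arg(bit_depth)
  ch <- n_channels(x)
  interleaved <- if (is.matrix(x$samples)) as.numeric(t(x$samples)) else x$samples
  fs <- round(x$sample_rate_hz)

  enc <- switch(bit_depth,
    float32 = list(tag = 3L, bits = 32L),
    pcm16   = list(tag = 1L, bits = 16L),
    pcm24   = list(tag = 1L, bits = 24L),
    pcm32   = list(tag = 1L, bits = 32L))
  bytes_per <- enc$bits %/% 8L
  data_bytes <- length(interleaved) * bytes_per

  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + data_bytes), con, 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, 4, endian = "little")
  writeBin(enc$tag, con, 2, endian = "little")
  writeBin(as.integer(ch), con, 2, endian = "little")
  writeBin(as.integer(fs), con, 4, endian = "little")
  writeBin(as.integer(fs * ch * bytes_per), con, 4, endian = "little")
  writeBin(as.integer(ch * bytes_per), con, 2, endian = "little")
  writeBin(enc$bits, con, 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_bytes), con, 4, endian = "little")

  if (bit_depth == "float32") {
    writeBin(interleaved, con, 4, endian = "little")
  } else {
    full <- 2^(enc$bits - 1)
    lo <- if (bit_depth == "pcm32") -(full - 1) else -full  # R has no -2^31 integer
    v <- pmin(pmax(round(interleaved * full), lo), full - 1)
    if (bit_depth == "pcm24") {
      u <- ifelse(v < 0, v + 16777216, v)
      b <- rbind(u %% 256, (u %/% 256) %% 256, u %/% 65536)
      writeBin(as.raw(as.integer(b)), con)
    } else {
      writeBin(as.integer(v), con, bytes_per, endian = "little")
    }
  }
  invisible(path)
}
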