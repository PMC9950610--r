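# Deterministic plain-text array I/O: tab-separated %.17g values, one matrix
# row per line.  %.17g round-trips doubles exactly, so save -> load -> save
# reproduces identical bytes.
write_matrix_txt <- function(m, path) {
  m <- as.matrix(m)
  lines <- apply(m, 1, function(r) paste(sprintf("%.17g", r), collapse = "\t"))
  writeLines(lines, path)
  invisible(path)
}

read_matrix_txt <- function(path) {
  lines <- readLines(path)
  do.call(rbind, lapply(strsplit(lines, "\t", fixed = TRUE), as.numeric))
}

#' Serialize a two-stage spectral representation to disk
#'
#' Writes four plain-text array files (`<prefix>_linear_amplitude.txt`,
#' `_linear_phase.txt`, `_env_amplitude_2d.txt`, `_env_phase_2d.txt`) plus a
#' JSON sidecar `<prefix>.json` holding rates, exponent, duration and
#' shapes.  The format is deterministic: saving a reloaded object
#' reproduces identical bytes.
#'
#' @param ts A `two_stage_spectra` object.
#' @param prefix Output path prefix.
#' @return `prefix`, invisibly.
#' @seealso [read_two_stage_spectra()]
#' @export
write_two_stage_spectra <- function(ts, prefix) {
  if (!inherits(ts, "two_stage_spectra")) stop("expected a `two_stage_spectra`")
  write_matrix_txt(rbind(ts$linear_amplitude), paste0(prefix, "_linear_amplitude.txt"))
  write_matrix_txt(rbind(ts$linear_phase), paste0(prefix, "_linear_phase.txt"))
  write_matrix_txt(ts$env_amplitude_2d, paste0(prefix, "_env_amplitude_2d.txt"))
  write_matrix_txt(ts$env_phase_2d, paste0(prefix, "_env_phase_2d.txt"))
  meta <- list(sample_rate_hz = ts$sample_rate_hz, duration_s = ts$duration_s,
               env_rate_hz = ts$env_rate_hz,
               compression_exponent = ts$compression_exponent,
               n_linear_bins = length(ts$linear_amplitude),
               env_shape = dim(ts$env_amplitude_2d),
               n_unique_env_points = ts$n_unique_env_points)
  jsonlite::write_json(meta, paste0(prefix, ".json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(prefix)
}

#' Load a serialized two-stage spectral representation
#'
#' @param prefix Path prefix used by [write_two_stage_spectra()].
#' @return A `two_stage_spectra` object (without `freqs_hz`-independent
#'   fields recomputed: `freqs_hz` is rebuilt from the metadata).
#' @export
read_two_stage_spectra <- function(prefix) {
  meta <- jsonlite::fromJSON(paste0(prefix, ".json"))
  amp <- drop(read_matrix_txt(paste0(prefix, "_linear_amplitude.txt")))
  n <- round(meta$sample_rate_hz * meta$duration_s)
  structure(list(
    linear_amplitude = amp,
    linear_phase = drop(read_matrix_txt(paste0(prefix, "_linear_phase.txt"))),
    freqs_hz = (seq_along(amp) - 1) * meta$sample_rate_hz / n,
    env_amplitude_2d = read_matrix_txt(paste0(prefix, "_env_amplitude_2d.txt")),
    env_phase_2d = read_matrix_txt(paste0(prefix, "_env_phase_2d.txt")),
    env_rate_hz = meta$env_rate_hz,
    compression_exponent = meta$compression_exponent,
    duration_s = meta$duration_s, sample_rate_hz = meta$sample_rate_hz,
    n_unique_env_points = meta$n_unique_env_points
  ), class = "two_stage_spectra")
}

#' Serialize an envelope matrix to disk
#'
#' Plain-text values at `<prefix>_envelopes.txt` plus a JSON sidecar of
#' rates, exponent and duration.
#'
#' @param e An `envelope_matrix`.
#' @param prefix Output path prefix.
#' @return `prefix`, invisibly.
#' @export
write_envelope_matrix <- function(e, prefix) {
  if (!inherits(e, "envelope_matrix")) stop("expected an `envelope_matrix`")
  write_matrix_txt(e$values, paste0(prefix, "_envelopes.txt"))
  jsonlite::write_json(
    list(env_rate_hz = e$env_rate_hz,
         compression_exponent = e$compression_exponent,
         duration_s = e$duration_s, shape = dim(e$values)),
    paste0(prefix, ".json"), auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(prefix)
}

#' Load a serialized envelope matrix
#'
#' @param prefix Path prefix used by [write_envelope_matrix()].
#' @return An `envelope_matrix`.
#' @export
read_envelope_matrix <- function(prefix) {
  meta <- jsonlite::fromJSON(paste0(prefix, ".json"))
  structure(list(values = read_matrix_txt(paste0(prefix, "_envelopes.txt")),
                 env_rate_hz = meta$env_rate_hz,
                 compression_exponent = meta$compression_exponent,
                 duration_s = meta$duration_s),
            class = "envelope_matrix")
}
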