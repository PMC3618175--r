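#' Read a mono PCM WAV file
#'
#' Minimal RIFF/WAVE reader for the uncompressed 16- or 24-bit PCM files the
#' pipeline itself writes. Samples are returned as doubles in `[-1, 1]`.
#'
#' @param path Path to a `.wav` file.
#' @return A `recording` object: list with `samples` (numeric vector),
#'   `sample_rate` (Hz) and `duration` (seconds).
#' @seealso [write_wav()]
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4L, useBytes = TRUE)
  if (!identical(riff, "RIFF")) abort("Not a RIFF file.")
  readBin(con, "integer", 1L, size = 4L, endian = "little")
  wave <- readChar(con, 4L, useBytes = TRUE)
  if (!identical(wave, "WAVE")) abort("Not a WAVE file.")
  sample_rate <- NULL
  bits <- NULL
  n_channels <- NULL
  samples <- NULL
  repeat {
    id <- readChar(con, 4L, useBytes = TRUE)
    if (length(id) == 0L || nchar(id) < 4L) break
    size <- readBin(con, "integer", 1L, size = 4L, endian = "little")
    if (identical(id, "fmt ")) {
      fmt <- readBin(con, "integer", 2L, size = 2L, endian = "little")
      n_channels <- fmt[2L]
      sample_rate <- readBin(con, "integer", 1L, size = 4L, endian = "little")
      readBin(con, "integer", 1L, size = 4L, endian = "little") # byte rate
      readBin(con, "integer", 1L, size = 2L, endian = "little") # block align
      bits <- readBin(con, "integer", 1L, size = 2L, endian = "little")
      if (size > 16L) readBin(con, "raw", size - 16L)
    } else if (identical(id, "data")) {
      if (is.null(bits)) abort("Malformed WAV: data before fmt chunk.")
      if (bits == 16L) {
        raw <- readBin(con, "integer", size / 2L, size = 2L,
                       endian = "little", signed = TRUE)
        samples <- raw / 32768
      } else if (bits == 24L) {
        bytes <- readBin(con, "raw", size)
        b <- matrix(as.integer(bytes), nrow = 3L)
        v <- b[1L, ] + 256L * b[2L, ] + 65536L * b[3L, ]
        v <- ifelse(v >= 8388608, v - 16777216, v)
        samples <- v / 8388608
      } else {
        abort(sprintf("Unsupported bit depth: %d.", bits))
      }
      break
    } else {
      readBin(con, "raw", size + (size %% 2L))
    }
  }
  if (is.null(samples)) abort("No data chunk found.")
  if (n_channels > 1L) {
    samples <- colMeans(matrix(samples, nrow = n_channels))
  }
  new_recording(samples, sample_rate)
}

#' Write a mono PCM 16-bit WAV file
#'
#' @param samples Numeric vector in `[-1, 1]` (clipped if outside).
#' @param sample_rate Sampling rate in Hz.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_wav <- function(samples, sample_rate, path) {
  samples <- pmin(pmax(samples, -1), 1)
  pcm <- as.integer(round(samples * 32767))
  n <- length(pcm)
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + 2L * n), con, size = 4L, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4L, endian = "little")
  writeBin(1L, con, size = 2L, endian = "little")            # PCM
  writeBin(1L, con, size = 2L, endian = "little")            # mono
  writeBin(as.integer(sample_rate), con, size = 4L, endian = "little")
  writeBin(as.integer(sample_rate * 2L), con, size = 4L, endian = "little")
  writeBin(2L, con, size = 2L, endian = "little")
  writeBin(16L, con, size = 2L, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(2L * n), con, size = 4L, endian = "little")
  writeBin(pcm, con, size = 2L, endian = "little")
  invisible(path)
}

#' Construct a recording object
#'
#' @param samples Numeric amplitude series.
#' @param sample_rate Sampling rate, Hz.
#' @param bird_id,taxon_label,locality Optional metadata strings.
#' @return A `recording` list.
#' @export
new_recording <- function(samples, sample_rate, bird_id = NA_character_,
                          taxon_label = NA_character_,
                          locality = NA_character_) {
  stopifnot_scalar_number(sample_rate, "sample_rate", positive = TRUE)
  structure(
    list(samples = as.numeric(samples), sample_rate = sample_rate,
         duration = length(samples) / sample_rate,
         bird_id = bird_id, taxon_label = taxon_label, locality = locality),
    class = "recording"
  )
}

#' @export
print.recording <- function(x, ...) {
  cat(sprintf("<recording> %.2f s @ %d Hz", x$duration,
              as.integer(x$sample_rate)))
  if (!is.na(x$bird_id)) cat(sprintf("  bird: %s", x$bird_id))
  cat("\n")
  invisible(x)
}
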