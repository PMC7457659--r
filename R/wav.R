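# Minimal RIFF/WAVE I/O: mono, 16-bit PCM (format 1) or 32-bit float
# (format 3), 16 kHz only. Chunk-based parsing; unknown chunks are skipped.

#' Read a mono 16-kHz WAV file
#'
#' Supports 16-bit PCM and 32-bit IEEE float. Stereo files and sample rates
#' other than 16 kHz are rejected (sample-rate conversion is out of scope).
#'
#' @param path WAV file path.
#' @param calibration dB SPL of a unit-RMS waveform (default 94).
#' @return an [audio_signal()].
#' @export
read_wav <- function(path, calibration = 94) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("not a RIFF file: ", path)
  readBin(con, "integer", 1, 4, endian = "little")
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop("not a WAVE file: ", path)

  fmt <- NULL
  samples <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || nchar(id) < 4) break
    size <- readBin(con, "integer", 1, 4, endian = "little")
    if (identical(id, "fmt ")) {
      raw <- readBin(con, "raw", size)
      fmt <- list(
        format = readBin(raw[1:2], "integer", 1, 2, endian = "little"),
        channels = readBin(raw[3:4], "integer", 1, 2, endian = "little"),
        rate = readBin(raw[5:8], "integer", 1, 4, endian = "little"),
        bits = readBin(raw[15:16], "integer", 1, 2, endian = "little")
      )
    } else if (identical(id, "data")) {
      if (is.null(fmt)) stop("malformed WAV: data chunk before fmt chunk")
      if (fmt$channels != 1) stop("only mono WAV files are supported")
      if (fmt$rate != 16000) stop("only 16 kHz WAV files are supported")
      if (fmt$format == 1 && fmt$bits == 16) {
        x <- readBin(con, "integer", size / 2, 2, signed = TRUE,
                     endian = "little")
        samples <- x / 32768
      } else if (fmt$format == 3 && fmt$bits == 32) {
        samples <- readBin(con, "numeric", size / 4, 4, endian = "little")
      } else {
        stop("unsupported WAV encoding (need 16-bit PCM or 32-bit float)")
      }
      break
    } else {
      readBin(con, "raw", size + size %% 2)  # skip unknown chunk (padded)
    }
  }
  if (is.null(samples)) stop("no data chunk found in ", path)
  audio_signal(samples, 16000, calibration)
}

#' Write a mono 16-kHz WAV file
#'
#' @param signal an [audio_signal()].
#' @param path output path.
#' @param format `"float"` (32-bit IEEE, default: preserves calibration
#'   headroom exactly) or `"pcm16"`.
#' @return `path`, invisibly.
#' @export
write_wav <- function(signal, path, format = c("float", "pcm16")) {
  stopifnot(inherits(signal, "audio_signal"))
  format <- match.arg(format)
  x <- signal$samples
  bytes_per <- if (format == "float") 4L else 2L
  fmt_code <- if (format == "float") 3L else 1L
  data_size <- length(x) * bytes_per
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + data_size), con, 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, 4, endian = "little")
  writeBin(fmt_code, con, 2, endian = "little")
  writeBin(1L, con, 2, endian = "little")                 # mono
  writeBin(16000L, con, 4, endian = "little")             # sample rate
  writeBin(as.integer(16000 * bytes_per), con, 4, endian = "little")
  writeBin(bytes_per, con, 2, endian = "little")          # block align
  writeBin(8L * bytes_per, con, 2, endian = "little")     # bits per sample
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_size), con, 4, endian = "little")
  if (format == "float") {
    writeBin(x, con, 4, endian = "little")
  } else {
    writeBin(as.integer(pmax(pmin(round(x * 32768), 32767), -32768)),
             con, 2, endian = "little")
  }
  invisible(path)
}
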