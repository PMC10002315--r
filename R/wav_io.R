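#' Read a mono PCM WAV file
#'
#' Minimal RIFF/WAVE reader for uncompressed PCM. Samples are returned as
#' doubles scaled to [-1, 1]. Only format tag 1 (linear PCM) is supported;
#' 16-bit is the expected quantization, 8-bit files are accepted for
#' robustness.
#'
#' @param path path to a .wav file
#' @return a list with elements `samples` (numeric vector, one channel per
#'   column if multichannel), `rate` (Hz), `bits` and `channels`
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("not a RIFF file: ", path)
  invisible(readBin(con, "integer", 1, size = 4, endian = "little"))
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop("not a WAVE file: ", path)

  fmt <- NULL
  data_raw <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || nchar(id) < 4) break
    size <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (identical(id, "fmt ")) {
      fmt_raw <- readBin(con, "raw", size)
      fmt <- list(
        format   = readBin(fmt_raw[1:2], "integer", 1, size = 2, endian = "little"),
        channels = readBin(fmt_raw[3:4], "integer", 1, size = 2, endian = "little"),
        rate     = readBin(fmt_raw[5:8], "integer", 1, size = 4, endian = "little"),
        bits     = readBin(fmt_raw[15:16], "integer", 1, size = 2, endian = "little")
      )
    } else if (identical(id, "data")) {
      data_raw <- readBin(con, "raw", size)
    } else {
      invisible(readBin(con, "raw", size + size %% 2))
    }
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt) || is.null(data_raw)) stop("incomplete WAV file: ", path)
  if (fmt$format != 1) stop("unsupported WAV format tag ", fmt$format, " (PCM only)")

  if (fmt$bits == 16) {
    x <- readBin(data_raw, "integer", length(data_raw) %/% 2, size = 2,
                 signed = TRUE, endian = "little") / 32768
  } else if (fmt$bits == 8) {
    x <- (readBin(data_raw, "integer", length(data_raw), size = 1,
                  signed = FALSE) - 128) / 128
  } else {
    stop("unsupported bit depth: ", fmt$bits)
  }
  if (fmt$channels > 1) {
    x <- matrix(x, ncol = fmt$channels, byrow = TRUE)
  }
  list(samples = x, rate = fmt$rate, bits = fmt$bits, channels = fmt$channels)
}

#' Write a mono PCM 16-bit WAV file
#'
#' @param samples numeric vector in [-1, 1]; values outside are clipped
#' @param rate sample rate in Hz
#' @param path output path
#' @return `path`, invisibly
#' @export
write_wav <- function(samples, rate, path) {
  stopifnot(is.numeric(samples), rate > 0)
  x <- pmax(-1, pmin(1, samples))
  pcm <- as.integer(round(x * 32767))
  n_bytes <- length(pcm) * 2L
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + n_bytes), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")          # PCM
  writeBin(1L, con, size = 2, endian = "little")          # mono
  writeBin(as.integer(rate), con, size = 4, endian = "little")
  writeBin(as.integer(rate * 2), con, size = 4, endian = "little")
  writeBin(2L, con, size = 2, endian = "little")          # block align
  writeBin(16L, con, size = 2, endian = "little")         # bits
  writeChar("data", con, eos = NULL)
  writeBin(n_bytes, con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}
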