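# Minimal RIFF/WAVE I/O: 16/24-bit PCM and 32-bit float, any channel count.

#' Read a WAV file
#'
#' Supports 16-bit and 24-bit PCM and 32-bit IEEE float, mono or
#' multichannel.  Samples are returned as a numeric matrix (samples x
#' channels) scaled to [-1, 1] full scale.
#'
#' @param path Path to a `.wav` file.
#' @return List with `data` (matrix, samples x channels) and `fs` (Hz).
#' @export
wav_read <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readChar(con, 4, useBytes = TRUE)
  if (hdr != "RIFF") stop("not a RIFF file: ", path)
  invisible(readBin(con, "integer", 1, 4, endian = "little"))
  if (readChar(con, 4, useBytes = TRUE) != "WAVE") stop("not a WAVE file")
  fmt <- NULL; data_raw <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || nchar(id) < 4) break
    sz <- readBin(con, "integer", 1, 4, endian = "little")
    if (id == "fmt ") {
      fmt_bytes <- readBin(con, "raw", sz)
      fmt <- list(
        audio_format = sum(as.integer(fmt_bytes[1:2]) * c(1, 256)),
        n_channels   = sum(as.integer(fmt_bytes[3:4]) * c(1, 256)),
        fs           = sum(as.integer(fmt_bytes[5:8]) * c(1, 256, 65536, 16777216)),
        bits         = sum(as.integer(fmt_bytes[15:16]) * c(1, 256)))
    } else if (id == "data") {
      data_raw <- readBin(con, "raw", sz)
    } else {
      invisible(readBin(con, "raw", sz + sz %% 2))
    }
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt) || is.null(data_raw)) stop("missing fmt/data chunk")
  nch <- fmt$n_channels
  if (fmt$audio_format == 3L && fmt$bits == 32L) {
    x <- readBin(data_raw, "double", length(data_raw) / 4, size = 4,
                 endian = "little")
  } else if (fmt$audio_format == 1L && fmt$bits == 16L) {
    x <- readBin(data_raw, "integer", length(data_raw) / 2, size = 2,
                 signed = TRUE, endian = "little") / 32768
  } else if (fmt$audio_format == 1L && fmt$bits == 24L) {
    b <- as.integer(data_raw)
    n <- length(b) / 3
    v <- b[seq(1, by = 3, length.out = n)] +
      b[seq(2, by = 3, length.out = n)] * 256L +
      b[seq(3, by = 3, length.out = n)] * 65536L
    v <- ifelse(v >= 8388608, v - 16777216, v)
    x <- v / 8388608
  } else {
    stop("unsupported WAV format (format ", fmt$audio_format,
         ", ", fmt$bits, " bits)")
  }
  list(data = matrix(x, ncol = nch, byrow = TRUE), fs = fmt$fs)
}

#' Write a WAV file
#'
#' @param data Numeric matrix (samples x channels) or vector, full-scale
#'   relative.
#' @param fs Sample rate in Hz.
#' @param path Output path.
#' @param bits One of 16 (PCM) or 32 (IEEE float).
#' @export
wav_write <- function(data, fs, path, bits = 32) {
  if (is.vector(data)) data <- matrix(data, ncol = 1)
  stopifnot(bits %in% c(16, 32))
  nch <- ncol(data)
  interleaved <- as.numeric(t(data))
  if (bits == 16) {
    fmt_code <- 1L
    pcm <- as.integer(round(pmax(-1, pmin(1, interleaved)) * 32767))
    payload_n <- length(pcm) * 2L
  } else {
    fmt_code <- 3L
    payload_n <- length(interleaved) * 4L
  }
  block_align <- nch * bits / 8
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + payload_n), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(fmt_code, con, size = 2, endian = "little")
  writeBin(as.integer(nch), con, size = 2, endian = "little")
  writeBin(as.integer(fs), con, size = 4, endian = "little")
  writeBin(as.integer(fs * block_align), con, size = 4, endian = "little")
  writeBin(as.integer(block_align), con, size = 2, endian = "little")
  writeBin(as.integer(bits), con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(payload_n), con, size = 4, endian = "little")
  if (bits == 16) {
    writeBin(pcm, con, size = 2, endian = "little")
  } else {
    writeBin(interleaved, con, size = 4, endian = "little")
  }
  invisible(path)
}
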