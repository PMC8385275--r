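# Minimal RIFF/WAVE PCM16 mono I/O. No audio package ships with the
# environment this package targets, and the format subset needed here
# (canonical 44-byte header, 16-bit little-endian mono PCM) is fixed by the
# corpus writer, so the two functions below implement exactly that subset.

#' Write a mono audio segment as a 16-bit PCM WAV file
#'
#' @param x An [audio_segment()] with samples in `[-1, 1]`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_wav <- function(x, path) {
  stopifnot(inherits(x, "audio_segment"))
  s <- pmax(-1, pmin(1, x$samples))
  pcm <- as.integer(round(s * 32767))
  n <- length(pcm)
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + 2 * n), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")          # fmt chunk size
  writeBin(1L, con, size = 2, endian = "little")           # PCM
  writeBin(1L, con, size = 2, endian = "little")           # mono
  writeBin(as.integer(x$rate), con, size = 4, endian = "little")
  writeBin(as.integer(x$rate) * 2L, con, size = 4, endian = "little")  # byte rate
  writeBin(2L, con, size = 2, endian = "little")           # block align
  writeBin(16L, con, size = 2, endian = "little")          # bits/sample
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(2 * n), con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}

#' Read a 16-bit PCM mono WAV file
#'
#' Reads the subset of WAV written by [write_wav()]: uncompressed 16-bit
#' little-endian mono PCM. Chunks other than `fmt ` and `data` are skipped.
#'
#' @param path File path.
#' @param t0 Session-start offset (s) to attach to the segment.
#' @return An [audio_segment()].
#' @export
read_wav <- function(path, t0 = 0) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4)
  if (!identical(riff, "RIFF")) stop("not a RIFF file: ", path, call. = FALSE)
  readBin(con, "integer", 1, size = 4, endian = "little")
  if (!identical(readChar(con, 4), "WAVE")) stop("not a WAVE file: ", path, call. = FALSE)
  rate <- NULL
  repeat {
    id <- readChar(con, 4)
    if (length(id) == 0 || nchar(id) < 4) stop("no data chunk in ", path, call. = FALSE)
    size <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (identical(id, "fmt ")) {
      fmt <- readBin(con, "integer", 2, size = 2, endian = "little")
      if (fmt[1] != 1L || fmt[2] != 1L) {
        stop("only uncompressed mono PCM is supported", call. = FALSE)
      }
      rate <- readBin(con, "integer", 1, size = 4, endian = "little")
      readBin(con, "integer", 1, size = 4, endian = "little")
      ba_bits <- readBin(con, "integer", 2, size = 2, endian = "little")
      if (ba_bits[2] != 16L) stop("only 16-bit PCM is supported", call. = FALSE)
      if (size > 16) readBin(con, "raw", size - 16)
    } else if (identical(id, "data")) {
      if (is.null(rate)) stop("data chunk precedes fmt chunk in ", path, call. = FALSE)
      pcm <- readBin(con, "integer", size %/% 2, size = 2, endian = "little")
      return(audio_segment(pcm / 32767, rate = rate, t0 = t0))
    } else {
      readBin(con, "raw", size + size %% 2)
    }
  }
}
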