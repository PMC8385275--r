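#' Audio segment container
#'
#' A light container for a mono waveform: samples in `[-1, 1]`, a sample rate
#' in Hz, and an offset `t0` (seconds from session start) used when windows
#' are mapped back onto the session clock.
#'
#' @param samples Numeric vector of samples; must be finite.
#' @param rate Sample rate in Hz (> 0). Default 16000.
#' @param t0 Offset of the first sample from session start, seconds.
#' @return An object of class `audio_segment`.
#' @export
audio_segment <- function(samples, rate = 16000, t0 = 0) {
  stopifnot_scalar_number(rate, "rate", positive = TRUE)
  stopifnot_scalar_number(t0, "t0")
  samples <- as.numeric(samples)
  if (length(samples) && !all(is.finite(samples))) {
    stop("all samples must be finite", call. = FALSE)
  }
  structure(list(samples = samples, rate = rate, t0 = t0),
            class = "audio_segment")
}

#' @export
print.audio_segment <- function(x, ...) {
  cat(sprintf("<audio_segment: %.3f s @ %d Hz, t0 = %.2f s, peak %.3f>\n",
              length(x$samples) / x$rate, as.integer(x$rate), x$t0,
              if (length(x$samples)) max(abs(x$samples)) else 0))
  invisible(x)
}

#' @export
length.audio_segment <- function(x) length(x$samples)

#' Duration of an audio segment in seconds
#' @param x An `audio_segment`.
#' @return Duration in seconds.
#' @export
duration <- function(x) {
  stopifnot(inherits(x, "audio_segment"))
  length(x$samples) / x$rate
}

#' Peak-normalize a waveform to at most unit amplitude
#'
#' Scales the waveform so that `max(abs(samples))` equals `peak` when the
#' input exceeds it; quieter signals are left untouched.
#'
#' @param x An `audio_segment`.
#' @param peak Target peak, default 0.99.
#' @return A peak-limited `audio_segment`.
#' @export
peak_normalize <- function(x, peak = 0.99) {
  stopifnot(inherits(x, "audio_segment"))
  m <- if (length(x$samples)) max(abs(x$samples)) else 0
  if (m > peak) x$samples <- x$samples * (peak / m)
  x
}
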