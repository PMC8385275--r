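# Frame-level acoustic front end: 25 ms / 10 ms framing, log-mel filterbank
# energies, autocorrelation pitch, and an energy + spectral-flatness voice
# activity detector with hangover smoothing. All deterministic.

frame_matrix <- function(samples, rate, frame_s, hop_s) {
  flen <- round(frame_s * rate)
  hop <- round(hop_s * rate)
  n <- length(samples)
  if (n < flen) stop("clip shorter than one frame", call. = FALSE)
  n_frames <- floor((n - flen) / hop) + 1L
  idx <- outer(seq_len(flen), (seq_len(n_frames) - 1L) * hop, `+`)
  matrix(samples[idx], nrow = flen)
}

hz_to_mel <- function(f) 2595 * log10(1 + f / 700)
mel_to_hz <- function(m) 700 * (10^(m / 2595) - 1)

mel_filterbank <- function(n_mels, n_fft, rate, fmin = 20, fmax = rate / 2) {
  mel_pts <- seq(hz_to_mel(fmin), hz_to_mel(fmax), length.out = n_mels + 2)
  bin <- floor((n_fft + 1) * mel_to_hz(mel_pts) / rate)
  fb <- matrix(0, n_mels, n_fft %/% 2 + 1)
  for (m in seq_len(n_mels)) {
    lo <- bin[m]; ce <- bin[m + 1]; hi <- bin[m + 2]
    if (ce > lo) for (k in (lo + 1):ce) fb[m, k + 1] <- (k - lo) / (ce - lo)
    if (hi > ce) for (k in (ce + 1):hi) fb[m, k + 1] <- (hi - k) / (hi - ce)
  }
  # unit-area filters: white noise then yields a flat mel spectrum
  fb / pmax(rowSums(fb), 1e-12)
}

power_spectrum <- function(fr, n_fft) {
  flen <- nrow(fr)
  w <- 0.54 - 0.46 * cos(2 * pi * (seq_len(flen) - 1) / (flen - 1))  # Hamming
  fr <- fr * w
  if (flen < n_fft) fr <- rbind(fr, matrix(0, n_fft - flen, ncol(fr)))
  sp <- stats::mvfft(fr)[seq_len(n_fft %/% 2 + 1), , drop = FALSE]
  Mod(sp)^2
}

#' Log-mel filterbank features
#'
#' Standard 25 ms / 10 ms log-mel filterbank energies, mean-normalized per
#' clip (each band has zero mean over the clip), mirroring the usual
#' front end of speaker-embedding systems.
#'
#' @param audio An [audio_segment()].
#' @param n_mels Number of mel bands (>= 1), default 40.
#' @param frame_s Frame length in seconds.
#' @param hop_s Hop length in seconds.
#' @param mean_normalize Subtract the per-band clip mean (default `TRUE`).
#' @return Matrix of `n_frames x n_mels` log energies.
#' @export
fbank_features <- function(audio, n_mels = 40, frame_s = 0.025, hop_s = 0.010,
                           mean_normalize = TRUE) {
  stopifnot(inherits(audio, "audio_segment"))
  if (n_mels < 1) stop("n_mels must be >= 1", call. = FALSE)
  fr <- frame_matrix(audio$samples, audio$rate, frame_s, hop_s)
  n_fft <- 2^ceiling(log2(nrow(fr)))
  ps <- power_spectrum(fr, n_fft)
  fb <- mel_filterbank(n_mels, n_fft, audio$rate)
  logmel <- t(log(fb %*% ps + 1e-10))
  if (mean_normalize) logmel <- sweep(logmel, 2, colMeans(logmel))
  logmel
}

#' Autocorrelation pitch tracker
#'
#' Per-frame fundamental-frequency estimates from the normalized
#' autocorrelation peak, searched in `[f_min, f_max]` Hz. Frames whose peak
#' falls below `threshold` are reported as 0 (unvoiced).
#'
#' @param audio An [audio_segment()].
#' @param frame_s,hop_s Framing parameters; must match [fbank_features()].
#' @param f_min,f_max Pitch search range in Hz, default `[60, 400]`.
#' @param threshold Minimum normalized autocorrelation for a voiced call.
#' @return List with `f0` (Hz; 0 = unvoiced) and `nacf` (peak value) per
#'   frame.
#' @export
pitch_features <- function(audio, frame_s = 0.025, hop_s = 0.010,
                           f_min = 60, f_max = 400, threshold = 0.4) {
  stopifnot(inherits(audio, "audio_segment"))
  rate <- audio$rate
  fr <- frame_matrix(audio$samples, rate, frame_s, hop_s)
  lag_min <- max(2L, floor(rate / f_max))
  lag_max <- min(nrow(fr) - 1L, ceiling(rate / f_min))
  nf <- ncol(fr)
  f0 <- numeric(nf)
  nacf <- numeric(nf)
  fr <- sweep(fr, 2, colMeans(fr))
  e0 <- colSums(fr^2)
  # FFT-based autocorrelation over all frames at once
  n_fft <- 2^ceiling(log2(2 * nrow(fr)))
  pad <- rbind(fr, matrix(0, n_fft - nrow(fr), nf))
  ac <- Re(stats::mvfft(Mod(stats::mvfft(pad))^2, inverse = TRUE)) / n_fft
  for (j in seq_len(nf)) {
    if (e0[j] <= 1e-12) next
    r <- ac[(lag_min + 1):(lag_max + 1), j] / ac[1, j]
    k <- which.max(r)
    nacf[j] <- r[k]
    if (r[k] >= threshold) f0[j] <- rate / (lag_min + k - 1)
  }
  list(f0 = f0, nacf = nacf)
}

#' Energy and spectral-flatness voice activity detection
#'
#' A frame is voiced when its log energy clears an adaptive threshold above
#' the clip's noise floor and its spectral flatness (geometric over
#' arithmetic mean of the power spectrum) is low enough to indicate
#' structured, speech-like content. A hangover keeps a frame voiced for up
#' to `hangover` frames after the raw decision drops, bridging short
#' intra-word gaps. Thresholds adapt to the clip before any gain is
#' applied, so uniformly louder clips never lose voiced frames.
#'
#' @param audio An [audio_segment()].
#' @param frame_s,hop_s Framing parameters.
#' @param energy_margin_db Required energy rise over the noise floor (dB).
#' @param flatness_max Maximum spectral flatness for a voiced frame.
#' @param hangover Frames a voiced state persists after the raw decision
#'   drops (default 3).
#' @return Logical vector, one decision per frame.
#' @export
detect_voice <- function(audio, frame_s = 0.025, hop_s = 0.010,
                         energy_margin_db = 10, flatness_max = 0.4,
                         hangover = 3) {
  stopifnot(inherits(audio, "audio_segment"))
  fr <- frame_matrix(audio$samples, audio$rate, frame_s, hop_s)
  n_fft <- 2^ceiling(log2(nrow(fr)))
  ps <- power_spectrum(fr, n_fft)
  energy <- colMeans(fr^2)
  log_e <- 10 * log10(energy + 1e-12)
  # speech band flatness (below ~4 kHz): geometric / arithmetic mean
  hi <- min(nrow(ps), ceiling(4000 / audio$rate * n_fft) + 1L)
  band <- ps[2:hi, , drop = FALSE]
  flat <- exp(colMeans(log(band + 1e-12))) / (colMeans(band) + 1e-12)
  # noise floor = 10th percentile of frame log-energies (low enough that
  # clips with near-continuous speech keep their floor in the pauses),
  # bounded below so digital silence stays unvoiced
  floor_db <- max(stats::quantile(log_e, 0.1, names = FALSE), -75)
  raw <- (log_e > floor_db + energy_margin_db) & (flat < flatness_max)
  if (hangover > 0 && any(raw)) {
    voiced <- raw
    run <- 0L
    for (j in seq_along(raw)) {
      if (raw[j]) {
        run <- 0L
      } else if (run < hangover && j > 1 && (voiced[j - 1])) {
        run <- run + 1L
        voiced[j] <- TRUE
      } else {
        run <- 0L
      }
    }
    voiced
  } else {
    raw
  }
}

#' Full frame-level feature bundle for the counting model
#'
#' Computes time-aligned filterbank, pitch, and voicing streams sharing
#' one 25 ms / 10 ms framing, the representation consumed by
#' [extract_embedding()].
#'
#' @param audio An [audio_segment()].
#' @param n_mels Number of mel bands.
#' @param frame_s,hop_s Framing parameters.
#' @return An object of class `frame_features`: list with `frame_times`
#'   (frame centers, s, offset by the segment's `t0`), `fbank`
#'   (`n_frames x n_mels`), `pitch` (Hz, 0 = unvoiced), `nacf`, and
#'   `voiced` (logical).
#' @export
frame_features <- function(audio, n_mels = 40, frame_s = 0.025, hop_s = 0.010) {
  fb <- fbank_features(audio, n_mels = n_mels, frame_s = frame_s, hop_s = hop_s)
  pf <- pitch_features(audio, frame_s = frame_s, hop_s = hop_s)
  vd <- detect_voice(audio, frame_s = frame_s, hop_s = hop_s)
  n_frames <- nrow(fb)
  pitch <- pf$f0
  pitch[!vd] <- 0  # pitch is only reported on voiced frames
  structure(list(
    frame_times = audio$t0 + frame_s / 2 + hop_s * (seq_len(n_frames) - 1L),
    fbank = fb, pitch = pitch, nacf = pf$nacf, voiced = vd,
    frame_s = frame_s, hop_s = hop_s),
    class = "frame_features")
}
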