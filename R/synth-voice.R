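#' Parameters of a synthetic speaker voice
#'
#' A speech-like voice is a harmonic glottal source at fundamental `f0`,
#' shaped by formant resonances and gated into syllables. Voices stand in
#' for corpus speakers when building labelled overlapping-speech mixtures.
#'
#' @param seed Integer; fully determines the voice realization.
#' @param f0 Fundamental frequency in Hz, within `[80, 350]`. Drawn from the
#'   seed when `NULL`.
#' @param formant_centers Strictly increasing formant frequencies (Hz);
#'   drawn from the seed when `NULL`.
#' @param syllable_rate Syllable gating rate in Hz; drawn when `NULL`.
#' @return An object of class `speaker_voice`.
#' @export
speaker_voice <- function(seed, f0 = NULL, formant_centers = NULL,
                          syllable_rate = NULL) {
  seed <- as.integer(seed)
  drawn <- with_seed(child_seed(seed, "voice"), {
    list(
      f0 = runif(1, 95, 320),
      f1 = runif(1, 350, 850),
      f2_gap = runif(1, 600, 1400),
      f3_gap = runif(1, 700, 1300),
      syllable_rate = runif(1, 3, 6)
    )
  })
  f0 <- f0 %||% drawn$f0
  if (f0 < 80 || f0 > 350) stop("f0 must lie in [80, 350] Hz", call. = FALSE)
  formant_centers <- formant_centers %||%
    cumsum(c(drawn$f1, drawn$f2_gap, drawn$f3_gap))
  if (is.unsorted(formant_centers, strictly = TRUE)) {
    stop("formant centers must be strictly increasing", call. = FALSE)
  }
  syllable_rate <- syllable_rate %||% drawn$syllable_rate
  structure(list(seed = seed, f0 = f0, formant_centers = formant_centers,
                 syllable_rate = syllable_rate),
            class = "speaker_voice")
}

# Raised-cosine syllable gate: alternating voiced nuclei and short silences,
# with ~20 ms ramps so bursts do not click.
syllable_gate <- function(n, rate, syllable_rate, seed) {
  t <- (seq_len(n) - 1) / rate
  with_seed(seed, {
    gate <- numeric(n)
    ramp <- 0.01
    pos <- 0
    while (pos < n / rate) {
      cyc <- 1 / (syllable_rate * runif(1, 0.8, 1.25))
      # brief inter-syllable dips (<= 30 ms), as in connected speech;
      # phrase-level pauses come from the burst/pause activity pattern
      on <- cyc - min(0.03, cyc * runif(1, 0.2, 0.4))
      i <- which(t >= pos & t < pos + on)
      if (length(i)) {
        tt <- t[i] - pos
        env <- pmin(1, tt / ramp) * pmin(1, (on - tt) / ramp)
        gate[i] <- pmax(0, env)
      }
      pos <- pos + cyc
    }
    gate
  })
}

#' Synthesize a speech-like signal for one voice
#'
#' Produces an amplitude-modulated harmonic signal: a glottal-like harmonic
#' stack at the voice's `f0` (with slow vibrato and jitter), spectrally
#' shaped by the voice's formant resonances, and gated at `syllable_rate`
#' with silent inter-syllable gaps. The output is deterministic given the
#' voice seed and duration, and is detectable by the package's voice
#' activity detector and pitch tracker.
#'
#' @param voice A [speaker_voice()].
#' @param dur_s Duration in seconds (> 0).
#' @param rate Sample rate in Hz.
#' @return An [audio_segment()].
#' @export
make_speaker <- function(voice, dur_s, rate = 16000) {
  stopifnot(inherits(voice, "speaker_voice"))
  stopifnot_scalar_number(dur_s, "dur_s", positive = TRUE)
  n <- max(1L, round(dur_s * rate))
  t <- (seq_len(n) - 1) / rate

  sig <- with_seed(child_seed(voice$seed, "speaker"), {
    # slow vibrato + drift keeps the pitch track alive without leaving
    # the voice's neighbourhood (+-2.5%)
    vib <- 1 + 0.02 * sin(2 * pi * runif(1, 4, 7) * t + runif(1, 0, 2 * pi)) +
      0.005 * sin(2 * pi * runif(1, 0.3, 0.8) * t)
    phase0 <- 2 * pi * cumsum(voice$f0 * vib) / rate
    nh <- max(3L, floor(4000 / voice$f0))
    # formant envelope evaluated at the mean harmonic frequencies
    hfreq <- voice$f0 * seq_len(nh)
    fenv <- rowSums(vapply(voice$formant_centers, function(fc) {
      bw <- 0.06 * fc + 50
      1 / (1 + ((hfreq - fc) / bw)^2)
    }, numeric(nh)))
    amp <- (1 / seq_len(nh)^0.5) * (0.15 + fenv)
    s <- numeric(n)
    for (k in seq_len(nh)) s <- s + amp[k] * sin(k * phase0)
    s
  })
  gate <- syllable_gate(n, rate, voice$syllable_rate,
                        child_seed(voice$seed, "gate"))
  sig <- sig * gate
  m <- max(abs(sig))
  if (m > 0) sig <- sig * (0.7 / m)
  audio_segment(sig, rate = rate)
}

#' Synthesize background noise of a given category
#'
#' Three non-speech categories mirror typical everyday interference:
#' `"things"` (tonal beeps and clicks, e.g. dialtones and machines),
#' `"natural"` (filtered broadband noise with slow envelopes, e.g. wind),
#' and `"music"` (sustained chord-like harmonic stacks without the pitch
#' modulation characteristic of speech).
#'
#' @param kind One of `"things"`, `"natural"`, `"music"`.
#' @param dur_s Duration in seconds (> 0).
#' @param seed Integer seed; the waveform is a pure function of
#'   `(kind, dur_s, seed)`.
#' @param rate Sample rate in Hz.
#' @return An [audio_segment()].
#' @export
make_noise <- function(kind, dur_s, seed, rate = 16000) {
  kind <- match.arg(kind, c("things", "natural", "music"))
  stopifnot_scalar_number(dur_s, "dur_s", positive = TRUE)
  n <- max(1L, round(dur_s * rate))
  t <- (seq_len(n) - 1) / rate
  sig <- with_seed(child_seed(seed, paste0("noise-", kind)), {
    switch(kind,
      things = {
        s <- numeric(n)
        pos <- 0
        while (pos < dur_s) {
          beep_len <- runif(1, 0.08, 0.5)
          f <- runif(1, 300, 3000)
          i <- which(t >= pos & t < pos + beep_len)
          if (length(i)) s[i] <- s[i] + sin(2 * pi * f * t[i])
          pos <- pos + beep_len + runif(1, 0.05, 0.6)
        }
        # sparse clicks
        ck <- sample.int(n, size = max(1L, n %/% 4000))
        s[ck] <- s[ck] + runif(length(ck), -1, 1) * 2
        s
      },
      natural = {
        w <- rnorm(n)
        # gentle low-pass (moving average) + slow random amplitude envelope
        s <- stats::filter(w, rep(1 / 4, 4), sides = 2)
        s[is.na(s)] <- 0
        env_t <- seq(0, dur_s, by = 0.25)
        env <- stats::approx(env_t, runif(length(env_t), 0.3, 1), xout = t,
                             rule = 2)$y
        as.numeric(s) * env
      },
      music = {
        root <- runif(1, 100, 240)
        chord <- root * c(1, 2^(4 / 12), 2^(7 / 12))
        s <- numeric(n)
        for (f in chord) {
          for (k in 1:5) {
            s <- s + (1 / k) * sin(2 * pi * k * f * t + runif(1, 0, 2 * pi))
          }
        }
        s
      }
    )
  })
  m <- max(abs(sig))
  if (m > 0) sig <- sig * (0.7 / m)
  audio_segment(sig, rate = rate)
}

#' Generate a synthetic room impulse response
#'
#' Exponentially decaying Gaussian noise whose energy decays by 60 dB over
#' `rt60` seconds (so the Schroeder backward integral of the squared
#' response crosses -60 dB at `rt60`). `rt60 = 0` returns the unit impulse.
#' The nominal room size only sets the pre-delay of the reverberant tail.
#'
#' @param room One of `"small"`, `"medium"`, `"large"`.
#' @param rt60 Reverberation time in seconds (>= 0).
#' @param seed Integer seed.
#' @param rate Sample rate in Hz.
#' @return Numeric impulse-response vector with unit energy.
#' @export
make_rir <- function(room = c("small", "medium", "large"), rt60, seed,
                     rate = 16000) {
  room <- match.arg(room)
  stopifnot_scalar_number(rt60, "rt60")
  if (rt60 < 0) stop("rt60 must be >= 0", call. = FALSE)
  if (rt60 == 0) return(1)
  pre <- switch(room, small = 0.002, medium = 0.006, large = 0.012)
  n <- round((rt60 * 1.3 + pre) * rate)
  alpha <- 3 * log(10) / rt60  # 60 dB energy decay over rt60
  h <- with_seed(child_seed(seed, paste0("rir-", room)), rnorm(n))
  t <- pmax(0, (seq_len(n) - 1) / rate - pre)
  h <- h * exp(-alpha * t)
  h[seq_len(round(pre * rate))] <- 0
  h[max(1L, round(pre * rate))] <- 1.5  # direct path
  h / sqrt(sum(h^2))
}

#' Volume and speaking-rate augmentation
#'
#' Scales amplitude by `10^(volume_db / 20)` and changes tempo by
#' resampling, so a `rate_factor` of 2 halves the duration. This emulates
#' the natural variation in how loudly and how fast people speak.
#'
#' @param speech An [audio_segment()].
#' @param volume_db Gain in dB, restricted to `[-3, 3]`.
#' @param rate_factor Tempo multiplier (> 0).
#' @return The augmented [audio_segment()].
#' @export
augment <- function(speech, volume_db = 0, rate_factor = 1) {
  stopifnot(inherits(speech, "audio_segment"))
  stopifnot_scalar_number(volume_db, "volume_db")
  stopifnot_scalar_number(rate_factor, "rate_factor")
  if (volume_db < -3 || volume_db > 3) {
    stop("volume_db must lie in [-3, 3] dB", call. = FALSE)
  }
  if (rate_factor <= 0) stop("rate_factor must be > 0", call. = FALSE)
  s <- speech$samples
  if (rate_factor != 1 && length(s) > 1) {
    idx <- seq(1, length(s), by = rate_factor)
    s <- stats::approx(seq_along(s), s, xout = idx)$y
  }
  s <- s * 10^(volume_db / 20)
  audio_segment(s, rate = speech$rate, t0 = speech$t0)
}
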