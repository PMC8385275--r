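#' Specification of one synthetic overlapping-speech mixture
#'
#' Collects everything needed to synthesize a labelled mixture: the number
#' of simultaneous speakers, the signal-to-noise ratio and noise category,
#' the reverberation time, per-speaker volume/tempo augmentation ranges,
#' and a seed making the mixture fully reproducible.
#'
#' @param n_speakers Number of speakers (integer >= 0).
#' @param snr_db Speech-to-noise ratio in dB; `Inf` disables noise.
#' @param noise_kind One of `"things"`, `"natural"`, `"music"`.
#' @param rt60 Reverberation time in seconds (0 = anechoic).
#' @param volume_db Length-2 range (or scalar) of per-speaker gains in dB,
#'   within `[-3, 3]`.
#' @param rate_factor Length-2 range (or scalar) of per-speaker tempo
#'   multipliers; default `[0.9, 1.25]`.
#' @param dur_s Mixture duration in seconds (> 0).
#' @param seed Integer seed.
#' @param speaker_seeds Optional integer vector of length `n_speakers`
#'   fixing the voice of each speaker; defaults are derived from `seed`.
#'   Corpus builders use this to keep speaker identities disjoint across
#'   train/validation/test splits.
#' @return An object of class `synthesis_spec`.
#' @export
synthesis_spec <- function(n_speakers, snr_db = Inf, noise_kind = "natural",
                           rt60 = 0, volume_db = c(-3, 3),
                           rate_factor = c(0.9, 1.25), dur_s = 5, seed = 1,
                           speaker_seeds = NULL) {
  n_speakers <- as.integer(n_speakers)
  if (is.na(n_speakers) || n_speakers < 0) {
    stop("n_speakers must be a non-negative integer", call. = FALSE)
  }
  noise_kind <- match.arg(noise_kind, c("things", "natural", "music"))
  stopifnot_scalar_number(dur_s, "dur_s", positive = TRUE)
  stopifnot_scalar_number(rt60, "rt60")
  if (rt60 < 0) stop("rt60 must be >= 0", call. = FALSE)
  if (!(length(snr_db) == 1 && (is.infinite(snr_db) || is.finite(snr_db)))) {
    stop("snr_db must be a single number (possibly Inf)", call. = FALSE)
  }
  volume_db <- range(volume_db)
  if (volume_db[1] < -3 || volume_db[2] > 3) {
    stop("volume_db range must lie within [-3, 3] dB", call. = FALSE)
  }
  rate_factor <- range(rate_factor)
  if (rate_factor[1] <= 0) stop("rate_factor must be > 0", call. = FALSE)
  if (!is.null(speaker_seeds)) {
    speaker_seeds <- as.integer(speaker_seeds)
    if (length(speaker_seeds) != n_speakers) {
      stop("speaker_seeds must have length n_speakers", call. = FALSE)
    }
  }
  structure(list(n_speakers = n_speakers, snr_db = snr_db,
                 noise_kind = noise_kind, rt60 = rt60, volume_db = volume_db,
                 rate_factor = rate_factor, dur_s = dur_s,
                 seed = as.integer(seed), speaker_seeds = speaker_seeds),
            class = "synthesis_spec")
}

# Burst/pause activity pattern on the mixture timeline: speech bursts of
# 2-8 s alternating with 0.5-4 s pauses, starting with a burst so short
# clips still carry speech. Returns a two-column matrix of [start, end).
draw_activity <- function(dur_s, seed) {
  with_seed(seed, {
    iv <- NULL
    pos <- 0
    repeat {
      burst <- runif(1, 2, 8)
      iv <- rbind(iv, c(pos, min(pos + burst, dur_s)))
      pos <- pos + burst + runif(1, 0.5, 4)
      if (pos >= dur_s) break
    }
    iv
  })
}

interval_mask <- function(iv, n, rate) {
  m <- logical(n)
  for (r in seq_len(nrow(iv))) {
    i0 <- max(1L, floor(iv[r, 1] * rate) + 1L)
    i1 <- min(n, ceiling(iv[r, 2] * rate))
    if (i0 <= i1) m[i0:i1] <- TRUE
  }
  m
}

#' Synthesize a labelled overlapping-speech mixture
#'
#' Draws `n_speakers` voices, augments each with a random volume and tempo
#' from the spec's ranges, gates each onto the timeline with a burst/pause
#' activity pattern, sums the speakers, mixes background noise at the
#' requested SNR (powers measured on speech-active samples), convolves with
#' a synthetic room impulse response, and peak-normalizes. Ground-truth
#' per-5-second counts record how many speakers' activity covers at least
#' half of each window.
#'
#' @param spec A [synthesis_spec()].
#' @param rate Sample rate in Hz.
#' @return An object of class `mixture_example` with elements `audio`
#'   (the final [audio_segment()]), `true_counts` (integer per 5-s window),
#'   `spec`, `stems` (pre-reverberation speech and noise), and `activity`
#'   (per-speaker interval matrices).
#' @export
synthesize_mixture <- function(spec, rate = 16000) {
  stopifnot(inherits(spec, "synthesis_spec"))
  n <- round(spec$dur_s * rate)
  speech <- numeric(n)
  activity <- list()
  seeds <- spec$speaker_seeds %||%
    vapply(seq_len(spec$n_speakers), function(k) {
      child_seed(spec$seed, paste0("spk", k))
    }, integer(1))

  for (k in seq_len(spec$n_speakers)) {
    voice <- speaker_voice(seeds[k])
    aug <- with_seed(child_seed(spec$seed, paste0("aug", k)), {
      c(runif(1, spec$volume_db[1], spec$volume_db[2]),
        runif(1, spec$rate_factor[1], spec$rate_factor[2]))
    })
    # synthesize long enough that tempo change still covers the clip
    raw <- make_speaker(voice, spec$dur_s * aug[2] + 0.1, rate = rate)
    sig <- augment(raw, volume_db = aug[1], rate_factor = aug[2])$samples
    sig <- sig[seq_len(min(n, length(sig)))]
    if (length(sig) < n) sig <- c(sig, numeric(n - length(sig)))
    iv <- draw_activity(spec$dur_s, child_seed(spec$seed, paste0("act", k)))
    sig[!interval_mask(iv, n, rate)] <- 0
    speech <- speech + sig
    activity[[k]] <- iv
  }

  noise <- numeric(n)
  if (is.finite(spec$snr_db)) {
    nz <- make_noise(spec$noise_kind, spec$dur_s,
                     child_seed(spec$seed, "mixnoise"), rate = rate)$samples
    nz <- nz[seq_len(n)]
    act <- if (length(activity)) {
      Reduce(`|`, lapply(activity, interval_mask, n = n, rate = rate))
    } else {
      rep(FALSE, n)
    }
    if (any(act) && any(nz[act] != 0)) {
      p_speech <- mean(speech[act]^2)
      p_noise <- mean(nz[act]^2)
      scale <- sqrt(p_speech / (p_noise * 10^(spec$snr_db / 10)))
    } else {
      # no speech to reference: fix the noise at a plain ambient level
      scale <- 0.05 / max(rms(nz), 1e-12)
    }
    noise <- nz * scale
  }

  mix <- speech + noise
  if (spec$rt60 > 0) {
    room <- if (spec$rt60 < 0.25) "small" else if (spec$rt60 < 0.6) "medium" else "large"
    h <- make_rir(room, spec$rt60, child_seed(spec$seed, "rir"), rate = rate)
    mix <- fft_convolve(mix, h)[seq_len(n)]
  }
  audio <- peak_normalize(audio_segment(mix, rate = rate))

  n_windows <- floor(spec$dur_s / 5)
  true_counts <- integer(n_windows)
  for (w in seq_len(n_windows)) {
    w0 <- (w - 1) * 5
    covered <- vapply(activity, function(iv) {
      ov <- pmin(iv[, 2], w0 + 5) - pmax(iv[, 1], w0)
      sum(pmax(0, ov))
    }, numeric(1))
    true_counts[w] <- sum(covered >= 2.5)
  }

  structure(list(audio = audio, true_counts = true_counts, spec = spec,
                 stems = list(speech = speech, noise = noise),
                 activity = activity, speaker_seeds = seeds),
            class = "mixture_example")
}

fft_convolve <- function(x, h) {
  m <- length(x) + length(h) - 1L
  nf <- 2^ceiling(log2(m))
  Re(stats::fft(stats::fft(c(x, numeric(nf - length(x)))) *
                stats::fft(c(h, numeric(nf - length(h)))),
                inverse = TRUE))[seq_len(m)] / nf
}

#' Map a raw speaker count to its count class
#'
#' Classes follow perceptual binning: `C0` (no speech), `C1` (one
#' speaker), `C2` (2-5 speakers), `C3` (more than 5 speakers).
#'
#' @param count Integer vector of concurrent-speaker counts (>= 0).
#' @return Factor with levels `C0 < C1 < C2 < C3`.
#' @export
count_to_class <- function(count) {
  if (any(count < 0)) stop("counts must be >= 0", call. = FALSE)
  lab <- ifelse(count == 0, "C0",
         ifelse(count == 1, "C1",
         ifelse(count <= 5, "C2", "C3")))
  factor(lab, levels = c("C0", "C1", "C2", "C3"), ordered = TRUE)
}

#' Build a labelled synthetic mixture corpus on disk
#'
#' Generates `n_examples` mixtures, assigns them to train/validation/test
#' splits, writes each as a 16-bit PCM WAV, and returns (and writes) a
#' manifest. Voice seeds are drawn from disjoint pools per split, so test
#' speakers are never heard in training — the corpus supports
#' unseen-speaker generalization evaluation by construction.
#'
#' @param n_examples Number of mixtures (> 0).
#' @param dir Output directory (created if missing).
#' @param split_fracs Named or ordered numeric `(train, val, test)` summing
#'   to 1.
#' @param count_distribution Weights over the classes `0`, `1`, `2-5`,
#'   `>5` used when drawing each example's speaker count.
#' @param seed Integer seed for the whole corpus.
#' @param dur_s Duration of each mixture in seconds.
#' @param snr_range Range of SNRs (dB) to draw from.
#' @param rt60_range Range of reverberation times (s) to draw from.
#' @param noise_kinds Noise categories to draw from.
#' @return A tibble manifest with columns `path`, `split`, `duration_s`,
#'   `counts` (semicolon-joined per-window truth), and `spec` (JSON),
#'   also written to `manifest.csv` in `dir`.
#' @export
build_corpus <- function(n_examples, dir,
                         split_fracs = c(train = 0.8, val = 0.1, test = 0.1),
                         count_distribution = c(0.25, 0.25, 0.25, 0.25),
                         seed = 1, dur_s = 5,
                         snr_range = c(0, 20), rt60_range = c(0.1, 1),
                         noise_kinds = c("things", "natural", "music")) {
  if (n_examples <= 0) stop("n_examples must be > 0", call. = FALSE)
  if (abs(sum(split_fracs) - 1) > 1e-9) {
    stop("split fractions must sum to 1", call. = FALSE)
  }
  if (length(count_distribution) != 4 || any(count_distribution < 0) ||
      sum(count_distribution) <= 0) {
    stop("count_distribution must be 4 non-negative weights", call. = FALSE)
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  splits <- c("train", "val", "test")
  # largest-remainder apportionment of examples to splits
  raw <- n_examples * split_fracs / sum(split_fracs)
  n_split <- floor(raw)
  rem <- n_examples - sum(n_split)
  if (rem > 0) {
    ord <- order(raw - n_split, decreasing = TRUE)
    n_split[ord[seq_len(rem)]] <- n_split[ord[seq_len(rem)]] + 1L
  }
  split_of <- rep(splits, times = n_split)
  pw <- count_distribution / sum(count_distribution)

  rows <- vector("list", n_examples)
  for (i in seq_len(n_examples)) {
    ex_seed <- child_seed(seed, paste0("ex", i))
    draw <- with_seed(ex_seed, {
      cls <- sample.int(4, 1, prob = pw)
      k <- switch(cls, 0L, 1L, sample(2:5, 1), sample(6:8, 1))
      list(k = k, snr = runif(1, snr_range[1], snr_range[2]),
           rt60 = runif(1, rt60_range[1], rt60_range[2]),
           kind = sample(noise_kinds, 1),
           voice_draw = sample.int(100000L, max(1L, k)))
    })
    # disjoint voice-seed pools: train < 1e6 <= val < 2e6 <= test
    pool <- match(split_of[i], splits) - 1L
    spk_seeds <- if (draw$k > 0) draw$voice_draw[seq_len(draw$k)] + pool * 1000000L
    sp <- synthesis_spec(n_speakers = draw$k, snr_db = draw$snr,
                         noise_kind = draw$kind, rt60 = draw$rt60,
                         dur_s = dur_s, seed = ex_seed,
                         speaker_seeds = spk_seeds)
    ex <- synthesize_mixture(sp)
    path <- file.path(dir, sprintf("ex_%05d.wav", i))
    write_wav(ex$audio, path)
    sp_json <- jsonlite::toJSON(
      sp[c("n_speakers", "snr_db", "noise_kind", "rt60", "dur_s", "seed",
           "speaker_seeds")],
      auto_unbox = TRUE, digits = NA, null = "null")
    rows[[i]] <- tibble::tibble(
      path = path, split = split_of[i], duration_s = dur_s,
      counts = paste(ex$true_counts, collapse = ";"),
      spec = as.character(sp_json))
  }
  manifest <- dplyr::bind_rows(rows)
  utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  yaml::write_yaml(list(n_examples = n_examples, seed = seed, dur_s = dur_s,
                        split_fracs = as.list(split_fracs),
                        count_distribution = count_distribution,
                        snr_range = snr_range, rt60_range = rt60_range,
                        noise_kinds = noise_kinds),
                   file.path(dir, "corpus_config.yaml"))
  manifest
}

#' Parse the semicolon-joined per-window counts of a manifest row
#' @param counts Character vector as stored in the manifest.
#' @return List of integer vectors.
#' @export
parse_counts <- function(counts) {
  lapply(strsplit(as.character(counts), ";", fixed = TRUE), as.integer)
}
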