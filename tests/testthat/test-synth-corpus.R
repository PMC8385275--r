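test_that("speaker synthesis is deterministic with the contracted length", {
  v <- speaker_voice(7, f0 = 180)
  a <- make_speaker(v, 10)
  b <- make_speaker(v, 10)
  expect_audio_equal(a, b)
  expect_length(a$samples, 160000L)
  expect_lte(max(abs(a$samples)), 1)
  expect_error(make_speaker(v, 0), "dur_s")
})

test_that("generated voices carry their fundamental in the autocorrelation", {
  # oracle: dominant autocorrelation lag of the raw signal ~ rate / f0
  for (f0 in c(120, 200, 280)) {
    a <- make_speaker(speaker_voice(f0, f0 = f0), 2)
    s <- a$samples
    s <- s - mean(s)
    lags <- 40:270  # 59-400 Hz at 16 kHz
    ac <- vapply(lags, function(L) {
      sum(s[1:(length(s) - L)] * s[(L + 1):length(s)])
    }, numeric(1))
    lag_hat <- lags[which.max(ac)]
    expect_equal(16000 / lag_hat, f0, tolerance = 0.05)
  }
})

test_that("noise categories are deterministic and reject bad input", {
  for (kind in c("things", "natural", "music")) {
    a <- make_noise(kind, 3, seed = 5)
    b <- make_noise(kind, 3, seed = 5)
    expect_audio_equal(a, b)
    expect_false(isTRUE(all.equal(a$samples,
                                  make_noise(kind, 3, seed = 6)$samples)))
  }
  expect_error(make_noise("speechy", 3, seed = 1))
  expect_error(make_noise("music", 0, seed = 1), "dur_s")
})

test_that("natural noise is mostly rejected by the voice activity detector", {
  a <- make_noise("natural", 5, seed = 3)
  expect_lt(mean(detect_voice(a)), 0.2)
})

test_that("room impulse responses decay 60 dB over rt60", {
  expect_identical(make_rir("small", 0, seed = 1), 1)
  x <- sin(2 * pi * 440 * (0:999) / 16000)
  expect_equal(stats::convolve(x, rev(1), type = "open"), x)
  # Schroeder backward-integration oracle
  for (rt60 in c(0.3, 0.5, 0.8)) {
    h <- make_rir("medium", rt60, seed = 2)
    sch <- rev(cumsum(rev(h^2)))
    db <- 10 * log10(sch / sch[1])
    t60 <- (which(db <= -60)[1] - 1) / 16000
    expect_equal(t60, rt60, tolerance = 0.1 / rt60)
  }
  expect_identical(make_rir("large", 0.4, seed = 9),
                   make_rir("large", 0.4, seed = 9))
  expect_error(make_rir("small", -0.1, seed = 1), "rt60")
})

test_that("augmentation scales amplitude and tempo as specified", {
  a <- make_speaker(speaker_voice(3), 10)
  expect_audio_equal(augment(a, 0, 1), a)
  up <- augment(a, 3, 1)
  expect_equal(sqrt(mean(up$samples^2)) / sqrt(mean(a$samples^2)),
               10^(3 / 20), tolerance = 1e-3)
  fast <- augment(a, 0, 2)
  expect_equal(duration(fast), 5, tolerance = 0.01)
  expect_error(augment(a, 0, 0), "rate_factor")
  expect_error(augment(a, 5, 1), "volume_db")
})

test_that("mixtures respect superposition, SNR and labelling contracts", {
  silent <- synthesize_mixture(synthesis_spec(0, snr_db = Inf, dur_s = 10,
                                              seed = 1))
  expect_true(all(silent$audio$samples == 0))
  expect_identical(silent$true_counts, c(0L, 0L))

  two <- synthesize_mixture(synthesis_spec(2, snr_db = Inf, rt60 = 0,
                                           dur_s = 5, seed = 2))
  # anechoic, noiseless: output is the peak-normalized sum of the stems
  scale <- max(abs(two$audio$samples)) / max(abs(two$stems$speech))
  expect_equal(two$audio$samples, two$stems$speech * scale, tolerance = 1e-9)

  ex <- synthesize_mixture(synthesis_spec(3, snr_db = 10, noise_kind = "music",
                                          rt60 = 0, dur_s = 5, seed = 3))
  act <- Reduce(`|`, lapply(ex$activity, sambiance:::interval_mask,
                            n = length(ex$stems$speech), rate = 16000))
  snr <- 10 * log10(mean(ex$stems$speech[act]^2) / mean(ex$stems$noise[act]^2))
  expect_equal(snr, 10, tolerance = 0.5)
})

test_that("ground-truth counts are sound over random specs", {
  for (seed in 1:10) {
    k <- seed %% 4 * 2
    ex <- synthesize_mixture(synthesis_spec(k, snr_db = 15, rt60 = 0.2,
                                            dur_s = 15, seed = seed))
    expect_length(ex$true_counts, 3L)
    expect_true(all(ex$true_counts >= 0 & ex$true_counts <= k))
    expect_lte(max(abs(ex$audio$samples)), 1)
    # windows with no overlapping activity must be zero
    for (w in seq_along(ex$true_counts)) {
      ov <- vapply(ex$activity, function(iv) {
        any(pmin(iv[, 2], w * 5) > pmax(iv[, 1], (w - 1) * 5))
      }, logical(1))
      if (!any(ov)) expect_identical(ex$true_counts[w], 0L)
    }
    # determinism of the full synthesis
    again <- synthesize_mixture(synthesis_spec(k, snr_db = 15, rt60 = 0.2,
                                               dur_s = 15, seed = seed))
    expect_identical(again$audio$samples, ex$audio$samples)
  }
})

test_that("corpus builder apportions splits and isolates speaker seeds", {
  man <- tiny_corpus()
  expect_identical(as.integer(table(man$split)[c("train", "val", "test")]),
                   c(28L, 6L, 6L))
  specs <- lapply(man$spec, jsonlite::fromJSON)
  seeds_of <- function(split) {
    unlist(lapply(specs[man$split == split], `[[`, "speaker_seeds"))
  }
  expect_length(intersect(seeds_of("train"), seeds_of("test")), 0L)
  expect_length(intersect(seeds_of("train"), seeds_of("val")), 0L)
  expect_true(all(file.exists(man$path)))
  expect_error(build_corpus(0, tempdir()), "n_examples")
  expect_error(build_corpus(10, tempdir(), split_fracs = c(0.5, 0.2, 0.2)),
               "sum to 1")
})

test_that("a corpus drawn entirely from class 0 has all-zero truth", {
  dir <- file.path(tempdir(), "zero_corpus")
  man <- build_corpus(6, dir, count_distribution = c(1, 0, 0, 0), seed = 5)
  expect_true(all(unlist(parse_counts(man$counts)) == 0L))
})

test_that("WAV round-trips preserve the waveform to 16-bit precision", {
  a <- make_speaker(speaker_voice(21), 1.5)
  path <- tempfile(fileext = ".wav")
  write_wav(a, path)
  b <- read_wav(path)
  expect_equal(b$rate, 16000)
  expect_lt(max(abs(b$samples - a$samples)), 1 / 32767)
})
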