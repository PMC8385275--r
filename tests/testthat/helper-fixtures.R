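# Shared fixtures, built once per test run and memoized. Everything is
# generated in code under tempdir(); nothing is stored in the repository.

.fixtures <- new.env(parent = emptyenv())

# A small easy-regime corpus: enough windows of each class to train a
# model whose behaviour (determinism, scoring, error paths) can be probed
# quickly. Not meant to reach the full-size performance bars.
tiny_corpus <- function() {
  if (is.null(.fixtures$tiny_corpus)) {
    dir <- file.path(tempdir(), "tiny_corpus")
    .fixtures$tiny_corpus <- build_corpus(
      40, dir, split_fracs = c(train = 0.7, val = 0.15, test = 0.15),
      seed = 101, snr_range = c(20, 30), rt60_range = c(0, 0.2))
  }
  .fixtures$tiny_corpus
}

tiny_model <- function() {
  if (is.null(.fixtures$tiny_model)) {
    .fixtures$tiny_model <- train_counter(
      tiny_corpus(), counter_config(epochs = 3), seed = 11)
  }
  .fixtures$tiny_model
}

# A minimal counter_model shell with hand-set centroids, for scoring tests
# that need exact geometry.
stub_model <- function(centroids) {
  rownames(centroids) <- c("C0", "C1", "C2", "C3")
  structure(list(weights = NULL, centroids = centroids,
                 config = counter_config(embed_dim = ncol(centroids))),
            class = "counter_model")
}

expect_audio_equal <- function(a, b, tol = 1e-12) {
  expect_equal(a$samples, b$samples, tolerance = tol)
  expect_identical(a$rate, b$rate)
}
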