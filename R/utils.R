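#' Evaluate an expression with a temporary RNG seed
#'
#' Runs `expr` under `set.seed(seed)` and restores the caller's random-number
#' state afterwards, so seeded operations are pure functions of their seed and
#' do not disturb the global stream.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

#' Derive a child seed from a parent seed and a stream label
#'
#' Deterministically maps (seed, label) to a 31-bit integer so that distinct
#' pipeline stages draw from independent, reproducible streams.
#'
#' @param seed Integer parent seed.
#' @param label Character stream label.
#' @return A single integer in `[0, 2^31 - 1]`.
#' @keywords internal
child_seed <- function(seed, label) {
  h <- digest::digest(list(as.integer(seed), as.character(label)), algo = "xxhash32")
  bitwAnd(strtoi(substr(h, 1, 7), base = 16L), 2147483647L)
}

rms <- function(x) sqrt(mean(x^2))

`%||%` <- function(a, b) if (is.null(a)) b else a

stopifnot_scalar_number <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  }
  if (positive && x <= 0) {
    stop(sprintf("`%s` must be > 0", name), call. = FALSE)
  }
  invisible(x)
}
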