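# The Social Ambiance Measure: per-5-s window count classes are mapped to
# four ambiance levels, aggregated into daily time-budget fractions with a
# Shannon-entropy summary, and averaged into weekly per-participant vectors.

#' Map count classes (or raw counts) to ambiance levels
#'
#' Levels encode the richness of the social environment: AL-0 no speech,
#' AL-1 one speaker, AL-2 a medium group (2-5 simultaneous speakers),
#' AL-3 a large group (more than 5). The map is total and monotone
#' non-decreasing in the speaker count.
#'
#' @param count_class A factor from [count_to_class()], its character
#'   labels, or raw integer counts (which are binned first).
#' @return Integer ambiance levels 0-3.
#' @export
count_to_level <- function(count_class) {
  if (is.numeric(count_class)) count_class <- count_to_class(count_class)
  lev <- match(as.character(count_class), COUNT_CLASSES) - 1L
  if (anyNA(lev)) stop("unknown count class", call. = FALSE)
  lev
}

#' Aggregate one participant-day of window labels into a daily profile
#'
#' @param levels Integer vector of ambiance levels (0-3), one per 5-s
#'   window recorded that day.
#' @param window_s Window length in seconds (default 5).
#' @return List with `fractions` (named `AL0`..`AL3`, percent of recorded
#'   time, summing to 100), `total_recorded` (s), and `entropy` (nats).
#' @export
windows_to_daily_profile <- function(levels, window_s = 5) {
  if (length(levels) == 0) {
    stop("a daily profile needs at least one window", call. = FALSE)
  }
  if (any(!levels %in% 0:3)) stop("levels must be in 0..3", call. = FALSE)
  counts <- tabulate(levels + 1L, nbins = 4L)
  fractions <- 100 * counts / length(levels)
  names(fractions) <- paste0("AL", 0:3)
  list(fractions = fractions,
       total_recorded = window_s * length(levels),
       entropy = sam_entropy(fractions))
}

#' Shannon entropy of an ambiance-level time budget
#'
#' `-sum(p_i * log(p_i))` with `p_i = AL_i / 100` and `0 * log 0 := 0`.
#' Zero when all time sits at one level; maximal (`log(4)` in nats) when
#' time is spread evenly over the four levels.
#'
#' @param fractions Numeric vector of level percentages summing to 100.
#' @param base Logarithm base; the default `exp(1)` reports nats, use 2
#'   for bits.
#' @return Entropy (scalar).
#' @export
sam_entropy <- function(fractions, base = exp(1)) {
  if (any(fractions < 0)) stop("fractions must be non-negative", call. = FALSE)
  if (abs(sum(fractions) - 100) > 1e-6) {
    stop("fractions must sum to 100", call. = FALSE)
  }
  p <- fractions / 100
  p <- p[p > 0]
  -sum(p * log(p, base = base))
}

#' Weekly Social Ambiance Measure for one participant
#'
#' Averages daily profiles into the participant's weekly SAM vector:
#' the four level fractions and the entropy, each averaged over available
#' days with equal day weight (alternatively weighted by each day's
#' recorded time via `weight_by_time`). Missing days are simply absent
#' from the mean and reported through `days_used`.
#'
#' @param daily A list of profiles from [windows_to_daily_profile()], or a
#'   data frame with columns `AL0`..`AL3`, `entropy`, `total_recorded`.
#' @param weight_by_time Pool windows across days (time-weighted) instead
#'   of weighting days equally. Default `FALSE`.
#' @return List with `fractions` (`AL0`..`AL3`, summing to 100),
#'   `entropy`, `days_used`, and `total_recorded` (s).
#' @export
weekly_sam <- function(daily, weight_by_time = FALSE) {
  if (is.data.frame(daily)) {
    fr <- as.matrix(daily[, paste0("AL", 0:3), drop = FALSE])
    ent <- daily$entropy
    tot <- daily$total_recorded
  } else {
    if (length(daily) == 0) stop("no valid days to average", call. = FALSE)
    fr <- t(vapply(daily, function(d) d$fractions, numeric(4)))
    ent <- vapply(daily, function(d) d$entropy, numeric(1))
    tot <- vapply(daily, function(d) d$total_recorded, numeric(1))
  }
  if (nrow(fr) == 0) stop("no valid days to average", call. = FALSE)
  wts <- if (weight_by_time) tot / sum(tot) else rep(1 / nrow(fr), nrow(fr))
  fractions <- drop(wts %*% fr)
  names(fractions) <- paste0("AL", 0:3)
  list(fractions = fractions, entropy = sum(wts * ent),
       days_used = nrow(fr), total_recorded = sum(tot))
}

#' Tabulate window labels into daily and weekly SAM outputs
#'
#' Convenience aggregation over a window-label table for many
#' participant-days, producing the two tables the statistical layer
#' consumes.
#'
#' @param windows Data frame with columns `participant`, `day`, `level`.
#' @param window_s Window length in seconds.
#' @param weight_by_time Passed to [weekly_sam()].
#' @return List of tibbles `daily` (per participant-day fractions,
#'   entropy, coverage) and `weekly` (per participant SAM vector).
#' @export
sam_tables <- function(windows, window_s = 5, weight_by_time = FALSE) {
  stopifnot(all(c("participant", "day", "level") %in% names(windows)))
  daily <- windows |>
    dplyr::group_by(.data$participant, .data$day) |>
    dplyr::group_modify(function(d, key) {
      pr <- windows_to_daily_profile(d$level, window_s = window_s)
      tibble::tibble(!!!as.list(pr$fractions), entropy = pr$entropy,
                     total_recorded = pr$total_recorded)
    }) |>
    dplyr::ungroup()
  weekly <- daily |>
    dplyr::group_by(.data$participant) |>
    dplyr::group_modify(function(d, key) {
      wk <- weekly_sam(as.data.frame(d), weight_by_time = weight_by_time)
      tibble::tibble(!!!as.list(wk$fractions), entropy = wk$entropy,
                     days_used = wk$days_used,
                     total_recorded = wk$total_recorded)
    }) |>
    dplyr::ungroup()
  list(daily = daily, weekly = weekly)
}
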