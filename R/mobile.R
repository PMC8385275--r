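# Phone-call log processing: hashed caller identities, daily in/out call
# durations, and the share of recorded audio attributable to phone calls.

#' One-way hash of a phone number
#'
#' Normalizes the number to digits only and returns its MD5 hex digest, so
#' call partners can be distinguished without storing numbers. Note that
#' unsalted MD5 over the small space of phone numbers is reversible by
#' enumeration; pass `salt` for a private keyed variant when that matters.
#'
#' @param number Phone number as a string; non-digits are stripped.
#' @param salt Optional string prepended before hashing.
#' @return 32-character lowercase hex digest.
#' @export
hash_number <- function(number, salt = "") {
  if (!is.character(number) || length(number) != 1 || !nzchar(number)) {
    stop("number must be a non-empty string", call. = FALSE)
  }
  norm <- gsub("[^0-9]", "", number)
  if (!nzchar(norm)) norm <- number  # non-numeric ids are hashed verbatim
  digest::digest(paste0(salt, norm), algo = "md5", serialize = FALSE)
}

#' Daily incoming and outgoing call durations
#'
#' Sums call durations by direction and calendar day. Calls spanning
#' midnight are attributed to their start day. Records with negative
#' durations are rejected.
#'
#' @param calls Data frame with columns `participant`, `direction`
#'   (`"incoming"`/`"outgoing"`), `start` (POSIXct or ISO-8601 string),
#'   `duration_s`.
#' @return Tibble with `participant`, `day`, `incoming_s`, `outgoing_s`.
#' @export
daily_call_duration <- function(calls) {
  stopifnot(all(c("participant", "direction", "start", "duration_s")
                %in% names(calls)))
  if (any(calls$duration_s < 0)) {
    stop("call records with negative duration are invalid", call. = FALSE)
  }
  if (!inherits(calls$start, "POSIXct")) {
    calls$start <- as.POSIXct(calls$start, tz = "UTC")
  }
  calls |>
    dplyr::mutate(day = as.Date(.data$start, tz = "UTC")) |>
    dplyr::group_by(.data$participant, .data$day) |>
    dplyr::summarise(
      incoming_s = sum(.data$duration_s[.data$direction == "incoming"]),
      outgoing_s = sum(.data$duration_s[.data$direction == "outgoing"]),
      .groups = "drop")
}

# Total length of the union of half-open intervals, clipped against a
# second interval set. Both arguments are two-column matrices [start, end).
interval_intersection_length <- function(a, b) {
  if (!nrow(a) || !nrow(b)) return(0)
  total <- 0
  for (i in seq_len(nrow(a))) {
    lo <- pmax(a[i, 1], b[, 1])
    hi <- pmin(a[i, 2], b[, 2])
    total <- total + sum(pmax(0, hi - lo))
  }
  total
}

merge_intervals <- function(iv) {
  if (!nrow(iv)) return(iv)
  iv <- iv[order(iv[, 1]), , drop = FALSE]
  out <- iv[1, , drop = FALSE]
  for (i in seq_len(nrow(iv))[-1]) {
    if (iv[i, 1] <= out[nrow(out), 2]) {
      out[nrow(out), 2] <- max(out[nrow(out), 2], iv[i, 2])
    } else {
      out <- rbind(out, iv[i, ])
    }
  }
  out
}

#' Fraction of recorded time spent on phone calls
#'
#' Intersects call intervals `[start, start + duration)` with recording
#' session intervals and reports the overlap as a percentage of total
#' recorded time. Overlapping calls are merged first so the fraction is
#' invariant to splitting a call into contiguous sub-records.
#'
#' @param calls Data frame with `start` (POSIXct or ISO string) and
#'   `duration_s`.
#' @param sessions Data frame with recording `start` and `end` (POSIXct or
#'   ISO strings).
#' @return Percentage in `[0, 100]`.
#' @export
phone_fraction <- function(calls, sessions) {
  to_num <- function(x) as.numeric(as.POSIXct(x, tz = "UTC"))
  ses <- cbind(to_num(sessions$start), to_num(sessions$end))
  ses <- ses[ses[, 2] > ses[, 1], , drop = FALSE]
  if (nrow(ses)) ses <- merge_intervals(ses)
  total <- sum(ses[, 2] - ses[, 1])
  if (!length(total) || total <= 0) stop("zero recorded time", call. = FALSE)
  if (!nrow(calls)) return(0)
  cal <- merge_intervals(cbind(to_num(calls$start),
                               to_num(calls$start) + calls$duration_s))
  100 * interval_intersection_length(cal, ses) / total
}

#' Mask ambiance windows that overlap phone calls
#'
#' Optionally used before aggregation when phone-call ambiance should be
#' excluded from the in-person measure rather than merely quantified.
#'
#' @param windows Data frame with `start` (POSIXct window start) and 5-s
#'   windows assumed.
#' @param calls Data frame with `start` and `duration_s`.
#' @param window_s Window length (s).
#' @return `windows` with rows overlapping any call removed.
#' @export
mask_call_windows <- function(windows, calls, window_s = 5) {
  if (!nrow(calls) || !nrow(windows)) return(windows)
  to_num <- function(x) as.numeric(as.POSIXct(x, tz = "UTC"))
  w0 <- to_num(windows$start)
  cal <- merge_intervals(cbind(to_num(calls$start),
                               to_num(calls$start) + calls$duration_s))
  keep <- vapply(w0, function(s) {
    !any(pmin(s + window_s, cal[, 2]) > pmax(s, cal[, 1]))
  }, logical(1))
  windows[keep, , drop = FALSE]
}
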