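test_that("phone numbers hash stably to 32-hex MD5 digests", {
  expect_identical(hash_number("abc"), "900150983cd24fb0d6963f7d28e17f72")
  expect_identical(hash_number("7135550100"), hash_number("(713) 555-0100"))
  expect_false(hash_number("7135550100") == hash_number("7135550101"))
  expect_false(hash_number("7135550100") ==
                 hash_number("7135550100", salt = "pepper"))
  for (num in c("1", "15550100", "+1-800-555-0199")) {
    d <- hash_number(num)
    expect_match(d, "^[0-9a-f]{32}$")
    expect_identical(d, hash_number(num))
  }
  expect_error(hash_number(""), "non-empty")
})

test_that("daily call durations sum by direction and start day", {
  calls <- tibble::tibble(
    participant = "P01",
    direction = c("outgoing", "outgoing", "incoming"),
    start = as.POSIXct(c("2018-03-05 09:00:00", "2018-03-05 18:00:00",
                         "2018-03-06 10:00:00"), tz = "UTC"),
    duration_s = c(60, 120, 45))
  d <- daily_call_duration(calls)
  expect_identical(nrow(d), 2L)
  day1 <- d[d$day == as.Date("2018-03-05"), ]
  expect_equal(day1$outgoing_s, 180)
  expect_equal(day1$incoming_s, 0)

  # a call spanning midnight belongs to its start day
  late <- tibble::tibble(participant = "P01", direction = "incoming",
                         start = as.POSIXct("2018-03-05 23:55:00", tz = "UTC"),
                         duration_s = 900)
  dl <- daily_call_duration(late)
  expect_identical(dl$day, as.Date("2018-03-05"))
  expect_equal(dl$incoming_s, 900)

  bad <- calls; bad$duration_s[1] <- -5
  expect_error(daily_call_duration(bad), "negative")

  # randomized log vs a brute-force groupby oracle
  set.seed(41)
  rnd <- tibble::tibble(
    participant = sample(c("P01", "P02"), 200, replace = TRUE),
    direction = sample(c("incoming", "outgoing"), 200, replace = TRUE),
    start = as.POSIXct("2018-03-01", tz = "UTC") +
      runif(200, 0, 14 * 86400),
    duration_s = round(runif(200, 0, 3600)))
  d <- daily_call_duration(rnd)
  for (i in sample.int(nrow(d), 10)) {
    sel <- rnd$participant == d$participant[i] &
      as.Date(rnd$start, tz = "UTC") == d$day[i]
    expect_equal(d$incoming_s[i],
                 sum(rnd$duration_s[sel & rnd$direction == "incoming"]))
    expect_equal(d$outgoing_s[i],
                 sum(rnd$duration_s[sel & rnd$direction == "outgoing"]))
  }
})

test_that("phone fraction intersects calls with recording sessions", {
  sessions <- tibble::tibble(
    start = as.POSIXct("2018-03-05 08:00:00", tz = "UTC"),
    end = as.POSIXct("2018-03-05 18:00:00", tz = "UTC"))
  one_hour <- tibble::tibble(
    start = as.POSIXct("2018-03-05 09:00:00", tz = "UTC"), duration_s = 3600)
  expect_equal(phone_fraction(one_hour, sessions), 10)

  outside <- tibble::tibble(
    start = as.POSIXct("2018-03-05 20:00:00", tz = "UTC"), duration_s = 3600)
  expect_equal(phone_fraction(outside, sessions), 0)

  expect_error(phone_fraction(one_hour, sessions[0, ]),
               "zero recorded time")

  # invariance to splitting a call into contiguous sub-records
  split_call <- tibble::tibble(
    start = as.POSIXct("2018-03-05 09:00:00", tz = "UTC") + c(0, 1800),
    duration_s = c(1800, 1800))
  expect_equal(phone_fraction(split_call, sessions),
               phone_fraction(one_hour, sessions))

  # random interval sets vs a per-second brute-force oracle
  set.seed(17)
  origin <- as.POSIXct("2018-03-05 00:00:00", tz = "UTC")
  for (rep in 1:5) {
    ses <- tibble::tibble(start = origin + sample(0:80000, 4) ,
                          duration = sample(1000:8000, 4))
    ses$end <- ses$start + ses$duration
    cal <- tibble::tibble(start = origin + sample(0:80000, 6),
                          duration_s = sample(100:5000, 6))
    got <- phone_fraction(cal, ses[c("start", "end")])
    secs <- 0:95999  # covers the latest possible session end
    in_ses <- rep(FALSE, length(secs))
    for (i in 1:4) {
      in_ses <- in_ses | (secs >= as.numeric(ses$start[i]) - as.numeric(origin) &
                          secs < as.numeric(ses$end[i]) - as.numeric(origin))
    }
    in_cal <- rep(FALSE, length(secs))
    for (i in 1:6) {
      s0 <- as.numeric(cal$start[i]) - as.numeric(origin)
      in_cal <- in_cal | (secs >= s0 & secs < s0 + cal$duration_s[i])
    }
    oracle <- 100 * sum(in_ses & in_cal) / sum(in_ses)
    expect_equal(got, oracle, tolerance = 1e-9)
    expect_gte(got, 0); expect_lte(got, 100)
  }
})

test_that("call-overlapping windows can be masked out of the SAM", {
  windows <- tibble::tibble(
    start = as.POSIXct("2018-03-05 09:00:00", tz = "UTC") + seq(0, 55, 5),
    level = rep(1L, 12))
  calls <- tibble::tibble(
    start = as.POSIXct("2018-03-05 09:00:12", tz = "UTC"), duration_s = 10)
  kept <- mask_call_windows(windows, calls)
  # the call covers 09:00:12-09:00:22: windows starting at 10, 15, 20 s go
  expect_identical(nrow(kept), 9L)
  expect_false(any(format(kept$start, "%S") %in% c("10", "15", "20")))
})
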