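test_that("build_timeline handles empty, duplicated and shuffled input", {
  # empty observation list
  tl <- build_timeline(make_events())
  expect_s3_class(tl, "sepsis_timeline")
  expect_equal(nrow(tl$observations), 0)

  # exact duplicates collapse to one record
  obs <- tibble::tibble(time = rep("2012-10-01T09:00:00+0000", 2),
                        kind = "temperature", value = 38.6)
  tl <- build_timeline(make_events(obs = obs))
  expect_equal(nrow(tl$observations), 1)

  # shuffled input gives the same timeline as pre-sorted input (oracle:
  # sort the rows first, then build)
  set.seed(101)
  times <- t_utc("2012-10-01 08:00:00") + sort(sample.int(12 * 3600, 20))
  obs <- tibble::tibble(
    time = format(times, "%Y-%m-%dT%H:%M:%S+0000", tz = "UTC"),
    kind = sample(parameter_kinds(), 20, replace = TRUE),
    value = runif(20, 36, 39))
  ev_sorted <- make_events(obs = obs)
  shuffle <- sample.int(nrow(obs))
  ev_shuffled <- make_events(obs = obs[shuffle, ])
  expect_equal(build_timeline(ev_shuffled), build_timeline(ev_sorted))
})

test_that("build_timeline validates values, event times and structure", {
  obs <- tibble::tibble(time = "2012-10-01T09:00:00+0000",
                        kind = "temperature", value = 380)
  expect_error(build_timeline(make_events(obs = obs)), "temperature.*380")

  obs <- tibble::tibble(time = "2012-10-02T09:00:00+0000",
                        kind = "pulse", value = 80)
  expect_error(build_timeline(make_events(obs = obs)), "outside the ED stay")

  ev <- make_events()
  ev$patient_id <- c("P1", "P2")
  expect_error(build_timeline(ev), "exactly one patient")

  # simultaneous same-kind observations: last in input order wins, warns
  obs <- tibble::tibble(time = rep("2012-10-01T09:00:00+0000", 2),
                        kind = "pulse", value = c(88, 92))
  expect_warning(tl <- build_timeline(make_events(obs = obs)),
                 "simultaneous")
  expect_equal(tl$observations$value, 92)
})

test_that("snapshot_at applies staleness and half-open therapy intervals", {
  # no observations -> empty mapping, flags false
  tl <- build_timeline(make_events())
  s <- snapshot_at(tl, "2012-10-01T10:00:00+0000")
  expect_equal(nrow(s$latest), 0)
  expect_false(s$fluids_active)
  expect_false(s$oxygen_active)

  # temperature charted 3 h before `at`: present with 4 h staleness,
  # absent with 2 h
  obs <- tibble::tibble(time = "2012-10-01T09:00:00+0000",
                        kind = "temperature", value = 38.6)
  tl <- build_timeline(make_events(obs = obs))
  at <- "2012-10-01T12:00:00+0000"
  s4 <- snapshot_at(tl, at, staleness_windows(vitals_hours = 4))
  expect_equal(s4$latest$value, 38.6)
  s2 <- snapshot_at(tl, at, staleness_windows(vitals_hours = 2))
  expect_equal(nrow(s2$latest), 0)

  # oxygen interval [t0, t1): inactive exactly at t1
  therapy <- tibble::tibble(
    time = c("2012-10-01T09:00:00+0000", "2012-10-01T11:00:00+0000"),
    event_type = c("therapy_start", "therapy_end"),
    kind = "supplemental_oxygen")
  tl <- build_timeline(make_events(therapy = therapy))
  expect_true(snapshot_at(tl, "2012-10-01T10:59:59+0000")$oxygen_active)
  expect_false(snapshot_at(tl, "2012-10-01T11:00:00+0000")$oxygen_active)
  expect_true(snapshot_at(tl, "2012-10-01T09:00:00+0000")$oxygen_active)

  # outside the stay is an error
  expect_error(snapshot_at(tl, "2012-10-02T09:00:00+0000"), "outside")
})

test_that("snapshot_at is causal and monotone in the staleness windows", {
  set.seed(202)
  arrival <- t_utc("2012-10-01 08:00:00")
  times <- arrival + sort(sample.int(10 * 3600, 15))
  kinds <- sample(parameter_kinds(), 15, replace = TRUE)
  rg <- plausibility_ranges()
  obs <- tibble::tibble(
    time = format(times, "%Y-%m-%dT%H:%M:%S+0000", tz = "UTC"),
    kind = kinds,
    value = vapply(kinds, function(k) runif(1, rg[[k]][1], rg[[k]][2]),
                   numeric(1)))
  tl <- build_timeline(make_events(obs = obs))
  at <- arrival + 6 * 3600
  base <- snapshot_at(tl, at)

  # adding an observation after `at` does not change the snapshot
  later <- dplyr::bind_rows(obs, tibble::tibble(
    time = "2012-10-01T19:00:00+0000", kind = "lactate", value = 9))
  tl2 <- build_timeline(make_events(obs = later))
  s2 <- snapshot_at(tl2, at)
  expect_equal(s2$latest, base$latest)

  # enlarging every staleness window never removes an entry
  small <- snapshot_at(tl, at, staleness_windows(2, 12))
  big <- snapshot_at(tl, at, staleness_windows(8, 48))
  expect_true(all(small$latest$kind %in% big$latest$kind))
})
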