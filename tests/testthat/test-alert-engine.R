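# a timeline qualifying (2 SIRS + 1 OD) at given offsets (hours from an
# 08:00 arrival), long stay so vitals go stale between episodes
qualifying_timeline <- function(offsets_h, stay_h = 96, patient_id = "P1") {
  arrival <- t_utc("2012-10-01 08:00:00")
  obs <- dplyr::bind_rows(lapply(offsets_h, function(h) {
    tibble::tibble(
      time = format(arrival + h * 3600, "%Y-%m-%dT%H:%M:%S+0000", tz = "UTC"),
      kind = c("pulse", "respiratory_rate", "sbp"),
      value = c(120, 28, 80))
  }))
  build_timeline(make_events(
    patient_id, arrival = "2012-10-01T08:00:00+0000",
    departure = format(arrival + stay_h * 3600, "%Y-%m-%dT%H:%M:%S+0000",
                       tz = "UTC"),
    obs = obs))
}

disp <- function(patient_id, hours_after, category,
                 arrival = t_utc("2012-10-01 08:00:00")) {
  tibble::tibble(patient_id = patient_id,
                 time = arrival + hours_after * 3600,
                 category = category)
}

test_that("default suppression holds a second qualifying event for 24 h", {
  tl <- qualifying_timeline(c(0, 2))
  al <- run_screening(tl)
  expect_equal(nrow(al), 1)
  expect_equal(al$rationale, "sirs_plus_od")

  # beyond the default 24 h window the alert can fire again
  tl <- qualifying_timeline(c(0, 25))
  expect_equal(nrow(run_screening(tl)), 2)
  # at exactly 24 h the window has elapsed (fires at t >= expiry)
  tl <- qualifying_timeline(c(0, 24))
  expect_equal(nrow(run_screening(tl)), 2)
  tl <- qualifying_timeline(c(0, 23.9))
  expect_equal(nrow(run_screening(tl)), 1)
})

test_that("suspected-sepsis disposition extends suppression to 48 h", {
  d <- disp("P1", 1 / 6, "suspected_sepsis")
  # qualifying events at 0 and 47 h: suppressed
  expect_equal(nrow(run_screening(qualifying_timeline(c(0, 47)), d)), 1)
  # at 0 and 49 h: two alerts
  expect_equal(nrow(run_screening(qualifying_timeline(c(0, 49)), d)), 2)
})

test_that("not-sepsis disposition keeps the 24 h window", {
  d <- disp("P1", 1 / 6, "not_sepsis")
  expect_equal(nrow(run_screening(qualifying_timeline(c(0, 23)), d)), 1)
  expect_equal(nrow(run_screening(qualifying_timeline(c(0, 25)), d)), 2)
})

test_that("code-status disposition suppresses indefinitely", {
  d <- disp("P1", 1 / 6, "code_status_precludes")
  tl <- qualifying_timeline(c(0, 30, 60, 90))
  expect_equal(nrow(run_screening(tl, d)), 1)
})

test_that("a disposition before any alert is a validation error", {
  tl <- qualifying_timeline(5)
  d <- disp("P1", 1, "not_sepsis")  # alert only at +5 h
  expect_error(run_screening(tl, d), "before any alert")
})

test_that("suppression windows are never violated on random timelines", {
  set.seed(404)
  cfg <- engine_config()
  for (i in 1:20) {
    rt <- random_timeline(sprintf("R%02d", i))
    al <- run_screening(rt$timeline, config = cfg)
    if (nrow(al) >= 2) {
      gaps <- diff(as.numeric(al$time))
      expect_true(all(gaps >= 24 * 3600))
    }
    # every alert time coincides with an event arrival
    expect_true(all(al$time %in% rt$timeline$observations$time))
  }
})

test_that("replay is causal and prefix-consistent (streaming equivalence)", {
  set.seed(505)
  for (i in 1:10) {
    rt <- random_timeline(sprintf("S%02d", i))
    tl <- rt$timeline
    al <- run_screening(tl)
    # truncating the stream after a cut point reproduces the alert prefix
    cut <- tl$ed_arrival + sample.int(96 * 3600, 1)
    keep <- tl$observations$time <= cut
    tl_cut <- tl
    tl_cut$observations <- tl$observations[keep, ]
    al_cut <- run_screening(tl_cut)
    expect_equal(al_cut[setdiff(names(al_cut), "patient_id")],
                 al[al$time <= cut, setdiff(names(al), "patient_id")])
  }
  # removing all observations after the first alert preserves it
  tl <- qualifying_timeline(c(3, 30, 60))
  al <- run_screening(tl)
  tl_first <- tl
  tl_first$observations <-
    tl$observations[tl$observations$time <= al$time[1], ]
  expect_equal(run_screening(tl_first)$time[1], al$time[1])
})

test_that("with suppression disabled every qualifying event fires", {
  cfg0 <- engine_config(suppression_suspected_hours = 0,
                        suppression_not_sepsis_hours = 0,
                        suppression_default_hours = 0)
  set.seed(606)
  for (i in 1:10) {
    rt <- random_timeline(sprintf("Z%02d", i), n_events = 15)
    al <- run_screening(rt$timeline, config = cfg0)
    # brute-force oracle: snapshot + scalar criteria at every event time
    expected <- sum(vapply(rt$times, function(at) {
      s <- snapshot_at(rt$timeline, at)
      alert_decision(eval_sirs(s), eval_organ_dysfunction(s))$fire
    }, logical(1)))
    expect_equal(nrow(al), expected)
  }
})

test_that("patient_alert_status reduces alerts to any-fire", {
  expect_equal(
    patient_alert_status(tibble::tibble(patient_id = character(),
                                        time = t_utc(character())),
                         patient_ids = c("a", "b"))$alert,
    c(FALSE, FALSE))
  al <- run_screening(qualifying_timeline(c(0, 30, 60)))
  expect_gt(nrow(al), 1)
  st <- patient_alert_status(al, c("P1", "P2"))
  expect_equal(st$alert, c(TRUE, FALSE))
})

test_that("alert lead time is the signed first-alert-to-referral interval", {
  a <- tibble::tibble(patient_id = "P1",
                      time = t_utc("2012-10-01 08:00:00"))
  expect_equal(alert_lead_time(a, t_utc("2012-10-01 12:01:12")), 4.02)
  expect_equal(alert_lead_time(a, a$time), 0)
  expect_equal(alert_lead_time(a, t_utc("2012-10-01 07:00:00")), -1)
  expect_error(alert_lead_time(a[0, ], t_utc("2012-10-01 12:00:00")),
               "no alert")
  expect_error(alert_lead_time(a, NULL), "referral")
  # first alert is used when several fired
  a2 <- tibble::tibble(patient_id = "P1",
                       time = t_utc(c("2012-10-01 08:00:00",
                                      "2012-10-02 09:00:00")))
  expect_equal(alert_lead_time(a2, t_utc("2012-10-01 10:00:00")), 2)
})
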