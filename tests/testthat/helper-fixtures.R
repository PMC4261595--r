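# Fixture builders used across the suite. Everything is generated in code;
# times are ISO 8601 UTC strings unless stated otherwise.

t_utc <- function(x) as.POSIXct(x, tz = "UTC")

# event rows for one patient from compact arguments
make_events <- function(patient_id = "P1",
                        arrival = "2012-10-01T08:00:00+0000",
                        departure = "2012-10-01T20:00:00+0000",
                        triage_area = "critical",
                        obs = NULL,         # tibble(time, kind, value)
                        therapy = NULL,     # tibble(time, event_type, kind)
                        code_status = NULL, # tibble(time, value)
                        icu_referral = NULL,
                        label = NULL) {
  rows <- list(
    tibble::tibble(patient_id = patient_id, time = arrival,
                   event_type = "arrival", kind = NA_character_,
                   value = NA_real_, extra = triage_area),
    tibble::tibble(patient_id = patient_id, time = departure,
                   event_type = "departure", kind = NA_character_,
                   value = NA_real_, extra = NA_character_)
  )
  if (!is.null(obs)) {
    rows <- c(rows, list(tibble::tibble(
      patient_id = patient_id, time = obs$time, event_type = "obs",
      kind = obs$kind, value = obs$value, extra = NA_character_)))
  }
  if (!is.null(therapy)) {
    rows <- c(rows, list(tibble::tibble(
      patient_id = patient_id, time = therapy$time,
      event_type = therapy$event_type, kind = therapy$kind,
      value = NA_real_, extra = NA_character_)))
  }
  if (!is.null(code_status)) {
    rows <- c(rows, list(tibble::tibble(
      patient_id = patient_id, time = code_status$time,
      event_type = "code_status", kind = NA_character_,
      value = code_status$value, extra = NA_character_)))
  }
  if (!is.null(icu_referral)) {
    rows <- c(rows, list(tibble::tibble(
      patient_id = patient_id, time = icu_referral,
      event_type = "icu_referral", kind = NA_character_,
      value = NA_real_, extra = NA_character_)))
  }
  if (!is.null(label)) {
    rows <- c(rows, list(tibble::tibble(
      patient_id = patient_id, time = departure, event_type = "label",
      kind = NA_character_, value = as.numeric(label),
      extra = NA_character_)))
  }
  dplyr::bind_rows(rows)
}

# a snapshot object assembled directly (bypassing timelines) for pure
# criteria tests: values is a named vector over parameter kinds
make_snapshot <- function(values = c(), fluids = FALSE, oxygen = FALSE,
                          at = t_utc("2012-10-01 10:00:00")) {
  structure(
    list(
      at = at,
      latest = tibble::tibble(
        kind = names(values),
        value = unname(values),
        observation_time = rep(at, length(values))
      ),
      fluids_active = fluids,
      oxygen_active = oxygen
    ),
    class = "sepsis_snapshot"
  )
}

# plain-R reference predicate for the full alert rule: one row of values
# (NA = absent), straight-line logic, independent of the package internals
reference_alert <- function(temperature, pulse, respiratory_rate, wbc,
                            sbp, spo2, lactate, fluids, oxygen) {
  sirs <- 0L
  if (!is.na(temperature) && (temperature > 38 || temperature < 36)) sirs <- sirs + 1L
  if (!is.na(pulse) && pulse > 90) sirs <- sirs + 1L
  if (!is.na(respiratory_rate) && respiratory_rate > 20) sirs <- sirs + 1L
  if (!is.na(wbc) && (wbc > 12 || wbc < 4)) sirs <- sirs + 1L
  od <- 0L
  if (!is.na(sbp)) {
    if (sbp < 86) od <- od + 1L
    else if (sbp < 90 && fluids) od <- od + 1L
  }
  if (!is.na(spo2)) {
    if (spo2 < 85) od <- od + 1L
    else if (spo2 < 90 && oxygen) od <- od + 1L
  }
  if (!is.na(lactate) && lactate > 2) od <- od + 1L
  (sirs >= 2L && od >= 1L) || od >= 2L
}

# random single-patient timeline with qualifying physiology at known times;
# used by the suppression property tests
random_timeline <- function(patient_id, n_events = 30, stay_hours = 96,
                            p_qualify = 0.3) {
  arrival <- t_utc("2012-10-01 00:00:00")
  departure <- arrival + stay_hours * 3600
  times <- arrival + sort(sample.int(stay_hours * 3600 - 2, n_events))
  qualify <- stats::runif(n_events) < p_qualify
  # qualifying event: 2 SIRS + 1 OD; otherwise normal physiology
  obs <- dplyr::bind_rows(lapply(seq_len(n_events), function(i) {
    if (qualify[i]) {
      tibble::tibble(
        time = format(times[i], "%Y-%m-%dT%H:%M:%S+0000", tz = "UTC"),
        kind = c("pulse", "respiratory_rate", "sbp"),
        value = c(120, 28, 80))
    } else {
      tibble::tibble(
        time = format(times[i], "%Y-%m-%dT%H:%M:%S+0000", tz = "UTC"),
        kind = c("pulse", "respiratory_rate", "sbp"),
        value = c(70, 14, 120))
    }
  }))
  ev <- make_events(patient_id,
                    arrival = "2012-10-01T00:00:00+0000",
                    departure = format(departure, "%Y-%m-%dT%H:%M:%S+0000",
                                       tz = "UTC"),
                    obs = obs)
  list(timeline = build_timeline(ev), times = times, qualify = qualify)
}
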