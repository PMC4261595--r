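#' Physiologic parameter kinds
#'
#' The seven time-varying parameters the screening alert scans: five manually
#' charted vital signs and two stat-laboratory results.
#'
#' @return Character vector of the seven parameter kinds, in canonical order:
#'   `temperature` (degrees C), `pulse` (beats/min), `respiratory_rate`
#'   (breaths/min), `wbc` (10^3 cells/uL), `sbp` (mm Hg), `spo2`
#'   (% saturation), `lactate` (mmol/L).
#' @export
#' @examples
#' parameter_kinds()
parameter_kinds <- function() {
  c("temperature", "pulse", "respiratory_rate", "wbc", "sbp", "spo2", "lactate")
}

#' @keywords internal
#' @noRd
therapy_kinds <- function() c("iv_fluid_bolus", "supplemental_oxygen")

#' Physiologic plausibility ranges
#'
#' Inclusive value bounds per parameter kind used to reject charting errors
#' (for example a temperature of 380 entered without a decimal point).
#'
#' @return Named list mapping each parameter kind to `c(lower, upper)`.
#' @export
plausibility_ranges <- function() {
  list(
    temperature      = c(25, 45),    # degrees C
    pulse            = c(0, 300),    # beats/min
    respiratory_rate = c(0, 90),     # breaths/min
    wbc              = c(0, 200),    # 10^3 cells/uL
    sbp              = c(0, 320),    # mm Hg
    spo2             = c(0, 100),    # percent
    lactate          = c(0, 40)      # mmol/L
  )
}

#' Default staleness windows
#'
#' How long a charted value still counts as the "most recent" value when a
#' snapshot is taken. Vitals default to 4 hours (twice the slowest ED
#' charting cadence of 2 h), labs to 24 hours. Without such a bound a
#' day-old vital sign could keep satisfying an alert criterion.
#'
#' @param vitals_hours Staleness window for the five vital signs, in hours.
#' @param labs_hours Staleness window for WBC and lactate, in hours.
#' @return Named numeric vector of staleness windows in seconds, one per
#'   parameter kind.
#' @export
#' @examples
#' staleness_windows()
staleness_windows <- function(vitals_hours = 4, labs_hours = 24) {
  stopifnot(vitals_hours > 0, labs_hours > 0)
  c(
    temperature      = vitals_hours * 3600,
    pulse            = vitals_hours * 3600,
    respiratory_rate = vitals_hours * 3600,
    wbc              = labs_hours * 3600,
    sbp              = vitals_hours * 3600,
    spo2             = vitals_hours * 3600,
    lactate          = labs_hours * 3600
  )
}

#' @keywords internal
#' @noRd
new_timeline <- function(patient_id, triage_area, ed_arrival, ed_departure,
                         observations, therapies, code_status,
                         icu_referral_time = NULL, reference_label = NA) {
  structure(
    list(
      patient_id = patient_id,
      triage_area = triage_area,
      ed_arrival = ed_arrival,
      ed_departure = ed_departure,
      observations = observations,
      therapies = therapies,
      code_status = code_status,
      icu_referral_time = icu_referral_time,
      reference_label = reference_label
    ),
    class = "sepsis_timeline"
  )
}

empty_obs <- function() {
  quick_tbl(time = as.POSIXct(numeric(), origin = "1970-01-01", tz = "UTC"),
            kind = character(), value = numeric())
}

empty_therapies <- function() {
  quick_tbl(kind = character(),
            start = as.POSIXct(numeric(), origin = "1970-01-01", tz = "UTC"),
            end = as.POSIXct(numeric(), origin = "1970-01-01", tz = "UTC"))
}

empty_code_status <- function() {
  quick_tbl(time = as.POSIXct(numeric(), origin = "1970-01-01", tz = "UTC"),
            precludes_sepsis_icu_care = logical())
}

#' Build a validated patient timeline from parsed event records
#'
#' Assembles the heterogeneous event rows for one patient (observations,
#' therapy boundaries, code-status changes, arrival/departure, optional ICU
#' referral and reference label) into a sorted, validated timeline. Exactly
#' duplicated rows are dropped; when two different observations of the same
#' kind share a timestamp the last one in input order wins (with a warning),
#' mirroring a corrected chart entry.
#'
#' @param events Data frame in the event-stream dialect, with columns
#'   `patient_id`, `time`, `event_type`, `kind`, `value`, `extra`. See
#'   [read_events()] for the dialect. All rows must share one `patient_id`
#'   and include exactly one `arrival` and one `departure` row.
#' @param ranges Plausibility bounds per kind, as [plausibility_ranges()].
#' @return A `sepsis_timeline` object: a list with `patient_id`,
#'   `triage_area` (`"critical"` or `"other"`), `ed_arrival`/`ed_departure`
#'   timestamps, an `observations` tibble sorted by (time, kind), a
#'   `therapies` tibble of half-open intervals, a `code_status` tibble,
#'   optional `icu_referral_time`, and logical `reference_label`.
#' @export
#' @examples
#' ev <- tibble::tibble(
#'   patient_id = "P1",
#'   time = c("2012-10-01T08:00:00+0000", "2012-10-01T08:10:00+0000",
#'            "2012-10-01T12:00:00+0000"),
#'   event_type = c("arrival", "obs", "departure"),
#'   kind = c(NA, "temperature", NA),
#'   value = c(NA, 38.6, NA),
#'   extra = c("critical", NA, NA)
#' )
#' tl <- build_timeline(ev)
#' tl$observations
build_timeline <- function(events, ranges = plausibility_ranges()) {
  stopifnot(is.data.frame(events))
  req <- c("patient_id", "time", "event_type", "kind", "value")
  missing_cols <- setdiff(req, names(events))
  if (length(missing_cols)) {
    stop("events is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  if (!"extra" %in% names(events)) events$extra <- NA_character_

  pid <- unique(events$patient_id)
  if (length(pid) != 1L) {
    stop("build_timeline() expects records for exactly one patient, got: ",
         paste(pid, collapse = ", "))
  }

  events$time <- parse_timestamp(events$time)
  if (anyNA(events$time)) stop("unparseable timestamp for patient ", pid)
  events$value <- suppressWarnings(as.numeric(events$value))

  # drop exactly duplicated records
  events <- events[!duplicated(events[c("time", "event_type", "kind", "value", "extra")]), ,
                   drop = FALSE]

  take <- function(type) events[events$event_type == type, , drop = FALSE]

  arr <- take("arrival")
  dep <- take("departure")
  if (nrow(arr) != 1L || nrow(dep) != 1L) {
    stop("patient ", pid, " must have exactly one arrival and one departure event")
  }
  ed_arrival <- arr$time
  ed_departure <- dep$time
  if (ed_departure <= ed_arrival) {
    stop("patient ", pid, ": ED departure must be after arrival")
  }
  triage_area <- arr$extra[1L]
  if (is.na(triage_area) || !triage_area %in% c("critical", "other")) {
    stop("patient ", pid, ": arrival row must carry triage_area ",
         "('critical' or 'other') in the extra column")
  }

  obs <- take("obs")
  if (nrow(obs)) {
    bad_kind <- setdiff(unique(obs$kind), parameter_kinds())
    if (length(bad_kind)) {
      stop("patient ", pid, ": unknown observation kind(s): ",
           paste(bad_kind, collapse = ", "))
    }
    if (anyNA(obs$value) || any(!is.finite(obs$value))) {
      stop("patient ", pid, ": observation values must be finite numbers")
    }
    lo <- vapply(ranges, `[`, numeric(1), 1L)[obs$kind]
    hi <- vapply(ranges, `[`, numeric(1), 2L)[obs$kind]
    out_of_range <- obs$value < lo | obs$value > hi
    if (any(out_of_range)) {
      i <- which(out_of_range)[1L]
      stop("patient ", pid, ": implausible ", obs$kind[i], " value ",
           obs$value[i], " (allowed ", lo[i], "-", hi[i], ")")
    }
    # simultaneous same-kind observations: last in input order wins
    key <- paste(as.numeric(obs$time), obs$kind)
    if (anyDuplicated(key)) {
      warning("patient ", pid, ": simultaneous same-kind observations; ",
              "keeping the last in input order", call. = FALSE)
      obs <- obs[!duplicated(key, fromLast = TRUE), , drop = FALSE]
    }
    ord <- order(obs$time, match(obs$kind, parameter_kinds()))
    obs <- obs[ord, , drop = FALSE]
    observations <- quick_tbl(time = obs$time, kind = obs$kind, value = obs$value)
  } else {
    observations <- empty_obs()
  }

  ts <- take("therapy_start")
  te <- take("therapy_end")
  bad_tk <- setdiff(unique(c(ts$kind, te$kind)), therapy_kinds())
  if (length(bad_tk)) {
    stop("patient ", pid, ": unknown therapy kind(s): ",
         paste(bad_tk, collapse = ", "))
  }
  therapies <- empty_therapies()
  if (nrow(ts)) {
    ts <- ts[order(ts$time), , drop = FALSE]
    starts <- ts$time
    kinds <- ts$kind
    ends <- rep(as.POSIXct(NA, tz = "UTC"), nrow(ts))
    if (nrow(te)) {
      te <- te[order(te$time), , drop = FALSE]
      for (j in seq_len(nrow(te))) {
        open <- which(kinds == te$kind[j] & is.na(ends) & starts < te$time[j])
        if (!length(open)) {
          stop("patient ", pid, ": therapy_end without a matching open ",
               te$kind[j], " interval")
        }
        ends[open[1L]] <- te$time[j]
      }
    }
    if (any(!is.na(ends) & ends <= starts)) {
      stop("patient ", pid, ": therapy interval end must be after start")
    }
    therapies <- quick_tbl(kind = kinds, start = starts, end = ends)
  } else if (nrow(te)) {
    stop("patient ", pid, ": therapy_end without a matching therapy_start")
  }

  cs <- take("code_status")
  code_status <- empty_code_status()
  if (nrow(cs)) {
    cs <- cs[order(cs$time), , drop = FALSE]
    code_status <- quick_tbl(time = cs$time,
                             precludes_sepsis_icu_care = cs$value != 0)
  }

  icu <- take("icu_referral")
  icu_referral_time <- if (nrow(icu)) icu$time[1L] else NULL
  if (!is.null(icu_referral_time) && icu_referral_time < ed_arrival) {
    stop("patient ", pid, ": ICU referral before ED arrival")
  }

  lab <- take("label")
  reference_label <- if (nrow(lab)) lab$value[1L] != 0 else NA

  in_stay <- function(t) t >= ed_arrival & t <= ed_departure
  if (!all(in_stay(observations$time)) ||
      !all(in_stay(therapies$start)) ||
      !all(in_stay(therapies$end[!is.na(therapies$end)])) ||
      !all(in_stay(code_status$time))) {
    stop("patient ", pid, ": events outside the ED stay interval")
  }

  known <- c("arrival", "departure", "obs", "therapy_start", "therapy_end",
             "code_status", "icu_referral", "label")
  unknown <- setdiff(unique(events$event_type), known)
  if (length(unknown)) {
    stop("patient ", pid, ": unknown event_type(s): ",
         paste(unknown, collapse = ", "))
  }

  new_timeline(pid, triage_area, ed_arrival, ed_departure,
               observations, therapies, code_status,
               icu_referral_time, reference_label)
}

#' @export
print.sepsis_timeline <- function(x, ...) {
  cat("<sepsis_timeline> patient", x$patient_id,
      sprintf("[%s area]", x$triage_area), "\n")
  cat("  ED stay:", format_timestamp(x$ed_arrival), "to",
      format_timestamp(x$ed_departure), "\n")
  cat("  observations:", nrow(x$observations),
      " therapies:", nrow(x$therapies),
      " code-status events:", nrow(x$code_status), "\n")
  if (!is.null(x$icu_referral_time)) {
    cat("  ICU referral:", format_timestamp(x$icu_referral_time), "\n")
  }
  cat("  reference label:", x$reference_label, "\n")
  invisible(x)
}

#' Snapshot of the most recent values at a time point
#'
#' Collects, for each parameter kind, the latest observation at or before
#' `at` that is not stale (its age is strictly less than the kind's
#' staleness window), together with flags for whether an IV fluid bolus or
#' supplemental oxygen order is active at `at`. This "most recent values"
#' view is what the alert criteria are evaluated on: all criteria are judged
#' against the same aligned snapshot.
#'
#' Therapy intervals are half-open `[start, end)`; an order without a
#' recorded end is treated as active until ED departure.
#'
#' @param timeline A `sepsis_timeline` from [build_timeline()].
#' @param at Timestamp within the ED stay.
#' @param staleness Named vector of staleness windows in seconds, as
#'   [staleness_windows()].
#' @return A `sepsis_snapshot`: list with `at`, a `latest` tibble
#'   (`kind`, `value`, `observation_time`) holding only non-stale
#'   parameters, and logical `fluids_active`, `oxygen_active`.
#' @export
snapshot_at <- function(timeline, at, staleness = staleness_windows()) {
  stopifnot(inherits(timeline, "sepsis_timeline"))
  at <- parse_timestamp(at)
  if (at < timeline$ed_arrival || at > timeline$ed_departure) {
    stop("snapshot time ", format_timestamp(at),
         " is outside the ED stay of patient ", timeline$patient_id)
  }
  obs <- timeline$observations
  at_s <- as.numeric(at)

  kinds <- character()
  values <- numeric()
  times <- numeric()
  if (nrow(obs)) {
    ot <- as.numeric(obs$time)
    for (k in unique(obs$kind)) {
      sel <- obs$kind == k
      tk <- ot[sel]
      ok <- tk <= at_s & (at_s - tk) < staleness[[k]]
      if (any(ok)) {
        i <- max(which(ok))
        kinds <- c(kinds, k)
        values <- c(values, obs$value[sel][i])
        times <- c(times, tk[i])
      }
    }
  }

  active <- function(kind) {
    th <- timeline$therapies
    if (!nrow(th)) return(FALSE)
    sel <- th$kind == kind
    if (!any(sel)) return(FALSE)
    st <- as.numeric(th$start[sel])
    en <- as.numeric(th$end[sel])
    en[is.na(en)] <- as.numeric(timeline$ed_departure)
    any(st <= at_s & at_s < en)
  }

  structure(
    list(
      at = at,
      latest = quick_tbl(
        kind = kinds, value = values,
        observation_time = as.POSIXct(times, origin = "1970-01-01", tz = "UTC")
      ),
      fluids_active = active("iv_fluid_bolus"),
      oxygen_active = active("supplemental_oxygen")
    ),
    class = "sepsis_snapshot"
  )
}

#' @export
print.sepsis_snapshot <- function(x, ...) {
  cat("<sepsis_snapshot> at", format_timestamp(x$at), "\n")
  if (nrow(x$latest)) {
    for (i in seq_len(nrow(x$latest))) {
      cat(sprintf("  %-16s %g (charted %s)\n", x$latest$kind[i],
                  x$latest$value[i], format_timestamp(x$latest$observation_time[i])))
    }
  } else {
    cat("  (no usable observations)\n")
  }
  cat("  fluids_active:", x$fluids_active,
      " oxygen_active:", x$oxygen_active, "\n")
  invisible(x)
}
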