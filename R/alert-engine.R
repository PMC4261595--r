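#' Screening engine configuration
#'
#' Bundles the criterion thresholds, staleness windows and alert-suppression
#' durations used when replaying a patient timeline. After an alert fires,
#' further alerts for the same patient are suppressed: for 48 hours once a
#' clinician disposition of suspected severe sepsis / septic shock is
#' recorded, for 24 hours after a not-sepsis disposition, indefinitely when
#' the code status precludes intensive-care management of sepsis, and for a
#' default 24 hours while no disposition has been recorded. Suppression
#' windows are anchored at the alert time, and the engine never fires at a
#' time strictly before the suppression expiry.
#'
#' @param thresholds Criterion thresholds, see [criteria_thresholds()].
#' @param staleness Staleness windows in seconds, see [staleness_windows()].
#' @param suppression_suspected_hours,suppression_not_sepsis_hours,suppression_default_hours
#'   Suppression window durations in hours. Set all to 0 to disable
#'   suppression entirely (every qualifying evaluation then fires).
#' @param alpha Two-sided significance level carried into downstream
#'   diagnostic reports.
#' @return An `engine_config` list.
#' @export
#' @examples
#' engine_config()
engine_config <- function(thresholds = criteria_thresholds(),
                          staleness = staleness_windows(),
                          suppression_suspected_hours = 48,
                          suppression_not_sepsis_hours = 24,
                          suppression_default_hours = 24,
                          alpha = 0.05) {
  stopifnot(suppression_suspected_hours >= 0,
            suppression_not_sepsis_hours >= 0,
            suppression_default_hours >= 0,
            alpha > 0, alpha < 1)
  structure(
    list(
      thresholds = thresholds,
      staleness = staleness,
      suppression = c(
        suspected_sepsis = suppression_suspected_hours * 3600,
        not_sepsis = suppression_not_sepsis_hours * 3600,
        pending_disposition_default = suppression_default_hours * 3600
      ),
      alpha = alpha
    ),
    class = "engine_config"
  )
}

#' @keywords internal
#' @noRd
disposition_categories <- function() {
  c("suspected_sepsis", "not_sepsis", "code_status_precludes")
}

# Replay one timeline. Returns a list of plain vectors (time, sirs_count,
# od_count, rationale, sirs_met, od_met). Internal hot path: operates on
# numeric seconds and matrices, no tibbles.
#' @keywords internal
#' @noRd
screen_one <- function(tl, disp_time = numeric(), disp_cat = character(),
                       config = engine_config()) {
  obs <- tl$observations
  ot <- as.numeric(obs$time)
  th <- tl$therapies
  th_start <- as.numeric(th$start)
  th_end <- as.numeric(th$end)
  th_end[is.na(th_end)] <- as.numeric(tl$ed_departure)
  cs_time <- as.numeric(tl$code_status$time)

  tt <- sort(unique(c(ot, th_start, th_end, cs_time)))
  n <- length(tt)
  empty <- list(time = numeric(), sirs_count = integer(), od_count = integer(),
                rationale = character(), sirs_met = list(), od_met = list())
  if (n == 0L) {
    if (length(disp_time)) {
      stop("patient ", tl$patient_id,
           ": disposition recorded before any alert")
    }
    return(empty)
  }

  # latest non-stale value per kind at each evaluation time
  kinds <- parameter_kinds()
  vals <- matrix(NA_real_, n, 7L)
  stale <- config$staleness
  obs_kind <- obs$kind
  for (ki in seq_along(kinds)) {
    sel <- obs_kind == kinds[ki]
    if (!any(sel)) next
    tk <- ot[sel]
    vk <- obs$value[sel]
    idx <- findInterval(tt, tk)
    ok <- idx > 0L
    ok[ok] <- (tt[ok] - tk[idx[ok]]) < stale[[kinds[ki]]]
    vals[ok, ki] <- vk[idx[ok]]
  }

  flag_at <- function(kind) {
    out <- logical(n)
    sel <- th$kind == kind
    if (any(sel)) {
      for (j in which(sel)) {
        out <- out | (tt >= th_start[j] & tt < th_end[j])
      }
    }
    out
  }
  fluids <- flag_at("iv_fluid_bolus")
  oxygen <- flag_at("supplemental_oxygen")

  ev <- criteria_eval_vec(vals[, 1L], vals[, 2L], vals[, 3L], vals[, 4L],
                          vals[, 5L], vals[, 6L], vals[, 7L],
                          fluids, oxygen, config$thresholds)

  cand <- which(ev$fire)
  windows <- config$suppression

  if (length(disp_time)) {
    o <- order(disp_time)
    disp_time <- disp_time[o]
    disp_cat <- disp_cat[o]
  }
  nd <- length(disp_time)

  alert_idx <- integer()
  alert_times <- numeric()
  suppressed_until <- -Inf
  di <- 1L

  apply_disposition <- function(dt, cat) {
    # anchored at the latest alert at or before the disposition time
    if (!length(alert_times) || alert_times[1L] > dt) {
      stop("patient ", tl$patient_id,
           ": disposition recorded before any alert")
    }
    anchor <- max(alert_times[alert_times <= dt])
    suppressed_until <<- if (cat == "code_status_precludes") {
      Inf
    } else {
      anchor + windows[[cat]]
    }
  }

  for (i in cand) {
    t <- tt[i]
    while (di <= nd && disp_time[di] < t) {
      apply_disposition(disp_time[di], disp_cat[di])
      di <- di + 1L
    }
    if (t >= suppressed_until) {
      alert_idx <- c(alert_idx, i)
      alert_times <- c(alert_times, t)
      suppressed_until <- t + windows[["pending_disposition_default"]]
      if (windows[["pending_disposition_default"]] == 0) {
        suppressed_until <- -Inf
      }
    }
  }
  # validate any remaining dispositions (they anchor to the last alert)
  while (di <= nd) {
    apply_disposition(disp_time[di], disp_cat[di])
    di <- di + 1L
  }

  if (!length(alert_idx)) return(empty)
  list(
    time = tt[alert_idx],
    sirs_count = ev$sirs_count[alert_idx],
    od_count = ev$od_count[alert_idx],
    rationale = ev$rationale[alert_idx],
    sirs_met = lapply(alert_idx, function(i) colnames(ev$sirs)[ev$sirs[i, ]]),
    od_met = lapply(alert_idx, function(i) colnames(ev$od)[ev$od[i, ]])
  )
}

#' Replay patient timelines through the screening alert
#'
#' Evaluates the alert decision at every event arrival (observation,
#' therapy boundary, code-status change) of each timeline, fires alerts and
#' enforces the suppression policy described in [engine_config()]. When
#' several events share a timestamp the snapshot is evaluated once, after
#' all of them are applied. Clinician dispositions update the suppression
#' window of the most recent alert at or before the disposition time; the
#' latest disposition for an alert wins.
#'
#' @param timelines A `sepsis_timeline` or a list of them.
#' @param dispositions Optional data frame with columns `patient_id`, `time`
#'   and `category` (one of `suspected_sepsis`, `not_sepsis`,
#'   `code_status_precludes`). A disposition earlier than the patient's
#'   first alert is a validation error.
#' @param config An [engine_config()].
#' @return Tibble of fired alerts: `patient_id`, `time`, `sirs_count`,
#'   `od_count`, `rationale`, and list-columns `sirs_met`, `od_met` naming
#'   the criteria satisfied at the alert snapshot.
#' @export
#' @examples
#' ev <- tibble::tibble(
#'   patient_id = "P1",
#'   time = c("2012-10-01T08:00:00+0000", "2012-10-01T08:05:00+0000",
#'            "2012-10-01T08:05:00+0000", "2012-10-01T08:05:00+0000",
#'            "2012-10-01T14:00:00+0000"),
#'   event_type = c("arrival", "obs", "obs", "obs", "departure"),
#'   kind = c(NA, "temperature", "pulse", "sbp", NA),
#'   value = c(NA, 39.2, 121, 82, NA),
#'   extra = c("critical", NA, NA, NA, NA)
#' )
#' run_screening(build_timeline(ev))
run_screening <- function(timelines, dispositions = NULL,
                          config = engine_config()) {
  if (inherits(timelines, "sepsis_timeline")) timelines <- list(timelines)
  stopifnot(all(vapply(timelines, inherits, logical(1), "sepsis_timeline")))

  disp_by_pid <- NULL
  if (!is.null(dispositions) && nrow(dispositions)) {
    stopifnot(all(c("patient_id", "time", "category") %in% names(dispositions)))
    bad <- setdiff(unique(dispositions$category), disposition_categories())
    if (length(bad)) {
      stop("unknown disposition category: ", paste(bad, collapse = ", "))
    }
    dt <- as.numeric(parse_timestamp(dispositions$time))
    disp_by_pid <- split(
      data.frame(t = dt, cat = dispositions$category,
                 stringsAsFactors = FALSE),
      dispositions$patient_id
    )
  }

  res <- lapply(timelines, function(tl) {
    d <- disp_by_pid[[tl$patient_id]]
    if (is.null(d)) {
      screen_one(tl, config = config)
    } else {
      screen_one(tl, d$t, d$cat, config = config)
    }
  })

  nalerts <- vapply(res, function(r) length(r$time), integer(1))
  pids <- vapply(timelines, `[[`, character(1), "patient_id")
  quick_tbl(
    patient_id = rep(pids, nalerts),
    time = as.POSIXct(unlist(lapply(res, `[[`, "time")) %||% numeric(),
                      origin = "1970-01-01", tz = "UTC"),
    sirs_count = as.integer(unlist(lapply(res, `[[`, "sirs_count")) %||% integer()),
    od_count = as.integer(unlist(lapply(res, `[[`, "od_count")) %||% integer()),
    rationale = as.character(unlist(lapply(res, `[[`, "rationale")) %||% character()),
    sirs_met = do.call(c, c(lapply(res, `[[`, "sirs_met"), list(list()))),
    od_met = do.call(c, c(lapply(res, `[[`, "od_met"), list(list())))
  )
}

#' Patient-level alert positivity
#'
#' Reduces fired alerts to the patient-level screening result used in the
#' diagnostic 2x2 table: a patient screens positive when at least one alert
#' fired during the ED stay.
#'
#' @param alerts Alert tibble from [run_screening()].
#' @param patient_ids Optional character vector of all cohort patient ids;
#'   patients without alerts are then included with `alert = FALSE`.
#' @return Tibble with `patient_id` and logical `alert`.
#' @export
patient_alert_status <- function(alerts, patient_ids = NULL) {
  pos <- unique(alerts$patient_id)
  ids <- patient_ids %||% pos
  missing_pos <- setdiff(pos, ids)
  if (length(missing_pos)) {
    stop("alerts contain patient ids absent from patient_ids: ",
         paste(utils::head(missing_pos, 5), collapse = ", "))
  }
  tibble::tibble(patient_id = ids, alert = ids %in% pos)
}

#' Alert-to-ICU-referral lead time for one patient
#'
#' Hours from the first fired alert to the ICU referral; negative when the
#' referral preceded the alert (reported as-is).
#'
#' @param alerts Alert tibble (rows for one patient) from [run_screening()].
#' @param icu_referral_time Referral timestamp.
#' @return Lead time in hours (signed).
#' @export
#' @examples
#' a <- tibble::tibble(patient_id = "P1",
#'                     time = as.POSIXct("2012-10-01 08:00", tz = "UTC"))
#' alert_lead_time(a, as.POSIXct("2012-10-01 12:01:12", tz = "UTC"))
alert_lead_time <- function(alerts, icu_referral_time) {
  if (is.null(alerts) || nrow(alerts) == 0L) {
    stop("no alert fired; lead time is undefined")
  }
  if (length(unique(alerts$patient_id)) != 1L) {
    stop("alert_lead_time() expects alerts for a single patient; ",
         "use lead_times() for a cohort")
  }
  if (is.null(icu_referral_time) || length(icu_referral_time) != 1L ||
      is.na(icu_referral_time)) {
    stop("no ICU referral time; lead time is undefined")
  }
  first_alert <- min(as.numeric(parse_timestamp(alerts$time)))
  (as.numeric(parse_timestamp(icu_referral_time)) - first_alert) / 3600
}

#' Cohort alert-to-referral lead times
#'
#' Computes the signed first-alert-to-ICU-referral lead time for every
#' patient that both fired an alert and has a referral time.
#'
#' @param alerts Alert tibble from [run_screening()].
#' @param timelines List of `sepsis_timeline` objects (source of
#'   `icu_referral_time`).
#' @return Tibble with `patient_id` and `lead_time_hours`.
#' @export
lead_times <- function(alerts, timelines) {
  if (inherits(timelines, "sepsis_timeline")) timelines <- list(timelines)
  ref <- purrr::map(timelines, "icu_referral_time")
  has_ref <- !vapply(ref, is.null, logical(1))
  pids <- vapply(timelines, `[[`, character(1), "patient_id")
  ref_t <- vapply(ref[has_ref], as.numeric, numeric(1))
  ref_pid <- pids[has_ref]
  first_alert <- tapply(as.numeric(alerts$time), alerts$patient_id, min)
  common <- intersect(ref_pid, names(first_alert))
  tibble::tibble(
    patient_id = common,
    lead_time_hours =
      (ref_t[match(common, ref_pid)] - unname(first_alert[common])) / 3600
  )
}
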