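#' Event rows for one timeline
#'
#' Serializes a timeline back into the event-stream dialect: one row per
#' event with columns `patient_id`, `time` (ISO 8601 with offset),
#' `event_type`, `kind`, `value`, `extra`.
#'
#' @param timeline A `sepsis_timeline`.
#' @return Tibble of event rows.
#' @export
timeline_events <- function(timeline) {
  stopifnot(inherits(timeline, "sepsis_timeline"))
  tl <- timeline
  rows <- list(
    quick_tbl(patient_id = tl$patient_id,
              time = format_timestamp(tl$ed_arrival),
              event_type = "arrival", kind = NA_character_,
              value = NA_real_, extra = tl$triage_area)
  )
  if (nrow(tl$observations)) {
    rows <- c(rows, list(quick_tbl(
      patient_id = rep(tl$patient_id, nrow(tl$observations)),
      time = format_timestamp(tl$observations$time),
      event_type = rep("obs", nrow(tl$observations)),
      kind = tl$observations$kind, value = tl$observations$value,
      extra = rep(NA_character_, nrow(tl$observations))
    )))
  }
  if (nrow(tl$therapies)) {
    th <- tl$therapies
    rows <- c(rows, list(quick_tbl(
      patient_id = rep(tl$patient_id, nrow(th)),
      time = format_timestamp(th$start),
      event_type = rep("therapy_start", nrow(th)),
      kind = th$kind, value = rep(NA_real_, nrow(th)),
      extra = rep(NA_character_, nrow(th))
    )))
    has_end <- !is.na(th$end)
    if (any(has_end)) {
      rows <- c(rows, list(quick_tbl(
        patient_id = rep(tl$patient_id, sum(has_end)),
        time = format_timestamp(th$end[has_end]),
        event_type = rep("therapy_end", sum(has_end)),
        kind = th$kind[has_end], value = rep(NA_real_, sum(has_end)),
        extra = rep(NA_character_, sum(has_end))
      )))
    }
  }
  if (nrow(tl$code_status)) {
    cs <- tl$code_status
    rows <- c(rows, list(quick_tbl(
      patient_id = rep(tl$patient_id, nrow(cs)),
      time = format_timestamp(cs$time),
      event_type = rep("code_status", nrow(cs)), kind = rep(NA_character_, nrow(cs)),
      value = as.numeric(cs$precludes_sepsis_icu_care),
      extra = rep(NA_character_, nrow(cs))
    )))
  }
  if (!is.null(tl$icu_referral_time)) {
    rows <- c(rows, list(quick_tbl(
      patient_id = tl$patient_id,
      time = format_timestamp(tl$icu_referral_time),
      event_type = "icu_referral", kind = NA_character_,
      value = NA_real_, extra = NA_character_
    )))
  }
  if (!is.na(tl$reference_label)) {
    rows <- c(rows, list(quick_tbl(
      patient_id = tl$patient_id,
      time = format_timestamp(tl$ed_departure),
      event_type = "label", kind = NA_character_,
      value = as.numeric(tl$reference_label), extra = NA_character_
    )))
  }
  rows <- c(rows, list(quick_tbl(
    patient_id = tl$patient_id,
    time = format_timestamp(tl$ed_departure),
    event_type = "departure", kind = NA_character_,
    value = NA_real_, extra = NA_character_
  )))
  dplyr::bind_rows(rows)
}

#' Event rows for a whole cohort
#'
#' @param cohort A `synthetic_cohort` or list of `sepsis_timeline`s.
#' @return Tibble of event rows across all patients.
#' @export
cohort_events <- function(cohort) {
  tls <- if (inherits(cohort, "synthetic_cohort")) cohort$timelines else cohort
  dplyr::bind_rows(lapply(tls, timeline_events))
}

#' Write an event stream
#'
#' @param events Event-row tibble ([cohort_events()] / [timeline_events()]),
#'   a `synthetic_cohort`, or a list of timelines.
#' @param path Output file.
#' @param dialect `"csv"` (header row, UTF-8) or `"jsonl"` (one JSON object
#'   per line with the same field names).
#' @return `path`, invisibly.
#' @export
write_events <- function(events, path, dialect = c("csv", "jsonl")) {
  dialect <- match.arg(dialect)
  if (!is.data.frame(events)) events <- cohort_events(events)
  if (dialect == "csv") {
    readr::write_csv(events, path, na = "")
  } else {
    con <- file(path, open = "wt", encoding = "UTF-8")
    on.exit(close(con))
    jsonlite::stream_out(as.data.frame(events), con, na = "null",
                         verbose = FALSE)
  }
  invisible(path)
}

#' Read an event stream into patient timelines
#'
#' Parses the event-stream dialect, groups rows by patient and passes each
#' group through [build_timeline()]. Malformed rows (unknown `event_type`
#' or `kind`, unparseable values, implausible measurements, events outside
#' the ED stay) are collected into a line-numbered error report attached as
#' the `"row_errors"` attribute; if more than `max_error_rate` of rows are
#' malformed the read aborts.
#'
#' @param path Input file.
#' @param dialect `"csv"` or `"jsonl"`.
#' @param max_error_rate Abort threshold for the malformed-row fraction.
#' @return Named list of `sepsis_timeline`s (possibly empty), with
#'   attribute `row_errors` (tibble `line`, `patient_id`, `message`).
#' @export
read_events <- function(path, dialect = c("csv", "jsonl"),
                        max_error_rate = 0.1) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("no such file: ", path)
  if (dialect == "csv") {
    raw <- readr::read_csv(
      path,
      col_types = readr::cols(
        patient_id = readr::col_character(),
        time = readr::col_character(),
        event_type = readr::col_character(),
        kind = readr::col_character(),
        value = readr::col_character(),
        extra = readr::col_character()
      ),
      na = c("", "NA")
    )
    # line number in file: header is line 1
    raw$.line <- seq_len(nrow(raw)) + 1L
  } else {
    raw <- jsonlite::stream_in(file(path), verbose = FALSE)
    if (nrow(raw)) {
      for (col in c("patient_id", "time", "event_type", "kind", "value",
                    "extra")) {
        if (!col %in% names(raw)) raw[[col]] <- NA
        raw[[col]] <- as.character(raw[[col]])
      }
    }
    raw <- tibble::as_tibble(raw)
    raw$.line <- seq_len(nrow(raw))
  }
  req <- c("patient_id", "time", "event_type", "kind", "value")
  missing_cols <- setdiff(req, names(raw))
  if (length(missing_cols)) {
    stop("event stream is missing columns: ",
         paste(missing_cols, collapse = ", "))
  }
  if (nrow(raw) == 0L) {
    out <- list()
    attr(out, "row_errors") <- tibble::tibble(
      line = integer(), patient_id = character(), message = character())
    return(out)
  }

  n_rows_total <- nrow(raw)
  errors <- list()
  known_types <- c("arrival", "departure", "obs", "therapy_start",
                   "therapy_end", "code_status", "icu_referral", "label")
  bad_type <- !raw$event_type %in% known_types
  bad_kind <- raw$event_type == "obs" & !raw$kind %in% parameter_kinds()
  num_val <- suppressWarnings(as.numeric(raw$value))
  bad_value <- raw$event_type %in% c("obs", "code_status", "label") &
    is.na(num_val)
  bad <- bad_type | bad_kind | bad_value
  if (any(bad)) {
    msg <- ifelse(bad_type[bad], "unknown event_type",
                  ifelse(bad_kind[bad], "unknown observation kind",
                         "non-numeric value"))
    errors$parse <- tibble::tibble(line = raw$.line[bad],
                                   patient_id = raw$patient_id[bad],
                                   message = msg)
    raw <- raw[!bad, , drop = FALSE]
    num_val <- num_val[!bad]
  }
  raw$value <- num_val

  tls <- list()
  for (pid in unique(raw$patient_id)) {
    sub <- raw[raw$patient_id == pid, , drop = FALSE]
    tl <- tryCatch(
      build_timeline(sub[setdiff(names(sub), ".line")]),
      error = function(e) e
    )
    if (inherits(tl, "error")) {
      errors[[pid]] <- tibble::tibble(line = sub$.line[1L], patient_id = pid,
                                      message = conditionMessage(tl))
    } else {
      tls[[pid]] <- tl
    }
  }

  err <- if (length(errors)) dplyr::bind_rows(errors) else {
    tibble::tibble(line = integer(), patient_id = character(),
                   message = character())
  }
  if (nrow(err) && nrow(err) / max(n_rows_total, 1L) > max_error_rate) {
    stop("more than ", round(100 * max_error_rate),
         "% of event rows are malformed; first error (line ",
         err$line[1L], "): ", err$message[1L])
  }
  if (nrow(err)) {
    warning(nrow(err), " malformed event row(s)/patient(s) skipped; see ",
            "attr(, 'row_errors')", call. = FALSE)
  }
  attr(tls, "row_errors") <- err
  tls
}

#' Write patient labels
#'
#' @param labels Tibble with `patient_id` and logical `label`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_labels <- function(labels, path) {
  readr::write_csv(
    tibble::tibble(patient_id = labels$patient_id,
                   label = as.integer(labels$label)),
    path)
  invisible(path)
}

#' Read patient labels
#'
#' @param path CSV with columns `patient_id`, `label` (0/1 or
#'   true/false).
#' @return Tibble with `patient_id` and logical `label`.
#' @export
read_labels <- function(path) {
  x <- readr::read_csv(path, col_types = readr::cols(
    patient_id = readr::col_character(),
    label = readr::col_character()))
  tibble::tibble(patient_id = x$patient_id,
                 label = tolower(x$label) %in% c("1", "true", "yes"))
}

#' Write disposition events
#'
#' @param dispositions Tibble with `patient_id`, `time`, `category`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_dispositions <- function(dispositions, path) {
  readr::write_csv(
    tibble::tibble(patient_id = dispositions$patient_id,
                   time = format_timestamp(dispositions$time),
                   category = dispositions$category),
    path)
  invisible(path)
}

#' Read disposition events
#'
#' @param path CSV with columns `patient_id`, `time`, `category`.
#' @return Tibble with parsed times.
#' @export
read_dispositions <- function(path) {
  x <- readr::read_csv(path, col_types = readr::cols(
    patient_id = readr::col_character(),
    time = readr::col_character(),
    category = readr::col_character()))
  bad <- setdiff(unique(x$category), disposition_categories())
  if (length(bad)) {
    stop("unknown disposition category: ", paste(bad, collapse = ", "))
  }
  tibble::tibble(patient_id = x$patient_id,
                 time = parse_timestamp(x$time),
                 category = x$category)
}

#' Write fired alerts as JSON lines
#'
#' @param alerts Alert tibble from [run_screening()].
#' @param path Output path (one JSON object per alert).
#' @return `path`, invisibly.
#' @export
write_alerts <- function(alerts, path) {
  rows <- purrr::pmap(alerts, function(patient_id, time, sirs_count,
                                       od_count, rationale, sirs_met,
                                       od_met) {
    jsonlite::toJSON(list(
      patient_id = jsonlite::unbox(patient_id),
      time = jsonlite::unbox(format_timestamp(time)),
      sirs_count = jsonlite::unbox(sirs_count),
      od_count = jsonlite::unbox(od_count),
      rationale = jsonlite::unbox(rationale),
      sirs_met = sirs_met, od_met = od_met
    ))
  })
  writeLines(unlist(rows), path)
  invisible(path)
}

#' Read fired alerts from JSON lines
#'
#' @param path Alerts file written by [write_alerts()].
#' @return Alert tibble in the [run_screening()] layout.
#' @export
read_alerts <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  rows <- lapply(lines, jsonlite::fromJSON)
  quick_tbl(
    patient_id = vapply(rows, `[[`, character(1), "patient_id"),
    time = parse_timestamp(vapply(rows, `[[`, character(1), "time")),
    sirs_count = vapply(rows, `[[`, integer(1), "sirs_count"),
    od_count = vapply(rows, `[[`, integer(1), "od_count"),
    rationale = vapply(rows, `[[`, character(1), "rationale"),
    sirs_met = lapply(rows, function(r) as.character(r$sirs_met)),
    od_met = lapply(rows, function(r) as.character(r$od_met))
  )
}

#' @keywords internal
#' @noRd
ci_to_list <- function(s) {
  if (inherits(s, "undefined_statistic")) {
    list(estimate = NULL, lower = NULL, upper = NULL,
         method = s$method, undefined_reason = s$reason)
  } else {
    list(estimate = s$estimate, lower = s$lower, upper = s$upper,
         method = s$method)
  }
}

#' Write a diagnostic report as JSON
#'
#' Schema-versioned JSON document with the raw 2x2 counts and every test
#' characteristic with its CI and method tag. Undefined statistics are
#' written as `null` estimates with a reason string.
#'
#' @param report A `diagnostic_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "diagnostic_report"))
  doc <- list(
    schema = "sepscreen/diagnostic_report/v1",
    n = report$n,
    counts = list(tp = report$counts$tp, fp = report$counts$fp,
                  fn = report$counts$fn, tn = report$counts$tn),
    prevalence = report$prevalence,
    alpha = report$alpha,
    ci_method = report$ci_method,
    statistics = list(
      sensitivity = ci_to_list(report$sensitivity),
      specificity = ci_to_list(report$specificity),
      ppv = ci_to_list(report$ppv),
      npv = ci_to_list(report$npv),
      lr_pos = ci_to_list(report$lr_pos),
      lr_neg = ci_to_list(report$lr_neg)
    )
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' Read a diagnostic report written by [write_report()]
#'
#' @param path Report JSON path.
#' @return A `diagnostic_report` reconstructed from the counts with the
#'   stored alpha and CI method.
#' @export
read_report <- function(path) {
  doc <- jsonlite::read_json(path)
  if (!identical(doc$schema, "sepscreen/diagnostic_report/v1")) {
    stop("not a sepscreen diagnostic report: ", path)
  }
  cm <- confusion_matrix(doc$counts$tp, doc$counts$fp,
                         doc$counts$fn, doc$counts$tn)
  diagnostic_report(cm, alpha = doc$alpha, ci_method = doc$ci_method)
}

#' Write an engine configuration as YAML
#'
#' Thresholds are written on their native scales; durations (staleness and
#' suppression windows) as integer minutes.
#'
#' @param config An [engine_config()].
#' @param path Output YAML path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "engine_config"))
  doc <- list(
    thresholds = config$thresholds,
    staleness_minutes = as.list(round(config$staleness / 60)),
    suppression_minutes = as.list(round(config$suppression / 60)),
    alpha = config$alpha
  )
  yaml::write_yaml(doc, path)
  invisible(path)
}

#' Read an engine configuration from YAML
#'
#' @param path YAML written by [write_config()] (missing keys fall back to
#'   defaults).
#' @return An [engine_config()].
#' @export
read_config <- function(path) {
  doc <- yaml::read_yaml(path)
  th <- do.call(criteria_thresholds, doc$thresholds %||% list())
  stal <- staleness_windows()
  if (!is.null(doc$staleness_minutes)) {
    sm <- doc$staleness_minutes
    stal[names(sm)] <- unlist(sm) * 60
  }
  supp <- c(suspected_sepsis = 48 * 60, not_sepsis = 24 * 60,
            pending_disposition_default = 24 * 60)
  if (!is.null(doc$suppression_minutes)) {
    sm <- doc$suppression_minutes
    supp[names(sm)] <- unlist(sm)
  }
  engine_config(
    thresholds = th, staleness = stal,
    suppression_suspected_hours = supp[["suspected_sepsis"]] / 60,
    suppression_not_sepsis_hours = supp[["not_sepsis"]] / 60,
    suppression_default_hours = supp[["pending_disposition_default"]] / 60,
    alpha = doc$alpha %||% 0.05
  )
}
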