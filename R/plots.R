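#' Plot a diagnostic report
#'
#' Point-and-interval display of the four proportion statistics (top panel)
#' and the two likelihood ratios on a log scale (bottom panel).
#'
#' @param object A `diagnostic_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot diagnostic_report
#' @export
autoplot.diagnostic_report <- function(object, ...) {
  td <- tidy(object)
  td$panel <- ifelse(grepl("^lr_", td$statistic),
                     "likelihood ratio", "proportion")
  td$statistic <- factor(td$statistic, levels = rev(unique(td$statistic)))
  ggplot2::ggplot(td, ggplot2::aes(x = .data$estimate, y = .data$statistic)) +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$conf.low,
                                          xmax = .data$conf.high)) +
    ggplot2::facet_wrap(~panel, ncol = 1, scales = "free") +
    ggplot2::labs(
      x = sprintf("estimate (%d%% CI)", round(100 * (1 - object$alpha))),
      y = NULL,
      title = "Screening alert test characteristics"
    ) +
    ggplot2::theme_minimal()
}

#' Plot a patient timeline
#'
#' Observations faceted by parameter kind over the ED stay, with therapy
#' intervals shaded and fired alerts marked as vertical lines.
#'
#' @param timeline A `sepsis_timeline`.
#' @param alerts Optional alert tibble from [run_screening()] (rows for
#'   other patients are ignored).
#' @return A ggplot object.
#' @export
plot_timeline <- function(timeline, alerts = NULL) {
  stopifnot(inherits(timeline, "sepsis_timeline"))
  obs <- tibble::as_tibble(timeline$observations)
  obs$kind <- factor(obs$kind, levels = parameter_kinds())
  p <- ggplot2::ggplot(obs, ggplot2::aes(x = .data$time, y = .data$value)) +
    ggplot2::geom_step(direction = "hv", colour = "grey55") +
    ggplot2::geom_point(size = 0.9) +
    ggplot2::facet_wrap(~kind, scales = "free_y") +
    ggplot2::labs(
      x = NULL, y = NULL,
      title = paste("Patient", timeline$patient_id),
      subtitle = sprintf("%s area; ED stay %s to %s", timeline$triage_area,
                         format_timestamp(timeline$ed_arrival),
                         format_timestamp(timeline$ed_departure))
    ) +
    ggplot2::theme_minimal()
  if (nrow(timeline$therapies)) {
    th <- timeline$therapies
    th$end[is.na(th$end)] <- timeline$ed_departure
    th <- tibble::as_tibble(th)
    p <- p + ggplot2::geom_rect(
      data = th,
      ggplot2::aes(xmin = .data$start, xmax = .data$end),
      ymin = -Inf, ymax = Inf, alpha = 0.12, fill = "steelblue",
      inherit.aes = FALSE
    )
  }
  if (!is.null(alerts)) {
    a <- alerts[alerts$patient_id == timeline$patient_id, , drop = FALSE]
    if (nrow(a)) {
      p <- p + ggplot2::geom_vline(
        data = tibble::tibble(time = a$time),
        ggplot2::aes(xintercept = .data$time),
        colour = "firebrick", linetype = "dashed"
      )
    }
  }
  p
}

#' Plot the lead-time distribution
#'
#' Histogram of signed alert-to-ICU-referral lead times with the median
#' and quartiles marked.
#'
#' @param lead_times Tibble from [lead_times()] or numeric vector of hours.
#' @param binwidth Histogram bin width in hours.
#' @return A ggplot object.
#' @export
plot_lead_times <- function(lead_times, binwidth = 1) {
  x <- if (is.data.frame(lead_times)) lead_times$lead_time_hours else lead_times
  s <- lead_time_summary(x)
  ggplot2::ggplot(tibble::tibble(hours = x), ggplot2::aes(x = .data$hours)) +
    ggplot2::geom_histogram(binwidth = binwidth, fill = "grey70",
                            colour = "white") +
    ggplot2::geom_vline(xintercept = c(s$q1, s$median, s$q3),
                        linetype = c("dotted", "dashed", "dotted"),
                        colour = "firebrick") +
    ggplot2::labs(
      x = "lead time from first alert to ICU referral (h)", y = "patients",
      title = sprintf("Median %.2f h (Q1-Q3, %.2f-%.2f), n = %d",
                      s$median, s$q1, s$q3, s$n)
    ) +
    ggplot2::theme_minimal()
}
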