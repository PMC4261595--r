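#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a diagnostic report
#'
#' One row per test characteristic with its point estimate and confidence
#' bounds, broom-style.
#'
#' @param x A `diagnostic_report`.
#' @param ... Unused.
#' @return Tibble with columns `statistic`, `estimate`, `conf.low`,
#'   `conf.high`, `method`. Undefined statistics appear with `NA` estimates
#'   and their reason in `method`.
#' @export
#' @examples
#' tidy(diagnostic_report(confusion_matrix(205, 772, 15, 48846)))
tidy.diagnostic_report <- function(x, ...) {
  stats <- c("sensitivity", "specificity", "ppv", "npv", "lr_pos", "lr_neg")
  rows <- purrr::map(stats, function(nm) {
    s <- x[[nm]]
    tibble::tibble(
      statistic = nm,
      estimate = s$estimate,
      conf.low = s$lower,
      conf.high = s$upper,
      method = if (inherits(s, "undefined_statistic")) {
        paste0("undefined: ", s$reason)
      } else {
        s$method
      }
    )
  })
  dplyr::bind_rows(rows)
}

#' Glance at a diagnostic report
#'
#' @param x A `diagnostic_report`.
#' @param ... Unused.
#' @return One-row tibble with the 2x2 counts, `n`, `prevalence`, `alpha`
#'   and the proportion-CI method.
#' @method glance diagnostic_report
#' @export
glance.diagnostic_report <- function(x, ...) {
  tibble::tibble(
    n = x$n, prevalence = x$prevalence,
    tp = x$counts$tp, fp = x$counts$fp,
    fn = x$counts$fn, tn = x$counts$tn,
    alpha = x$alpha, ci_method = x$ci_method
  )
}

#' Tidy a confusion matrix
#'
#' @param x A `confusion_matrix`.
#' @param ... Unused.
#' @return Tibble with `alert`, `reference` and `count` in long form.
#' @method tidy confusion_matrix
#' @export
tidy.confusion_matrix <- function(x, ...) {
  tibble::tibble(
    alert = c(TRUE, TRUE, FALSE, FALSE),
    reference = c(TRUE, FALSE, TRUE, FALSE),
    count = c(x$tp, x$fp, x$fn, x$tn)
  )
}

#' Tidy a lead-time summary
#'
#' @param x A `lead_time_summary`.
#' @param ... Unused.
#' @return One-row tibble with `median`, `q1`, `q3` (hours) and `n`.
#' @method tidy lead_time_summary
#' @export
tidy.lead_time_summary <- function(x, ...) {
  tibble::tibble(median = x$median, q1 = x$q1, q3 = x$q3, n = x$n)
}
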