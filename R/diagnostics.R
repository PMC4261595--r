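#' Patient-level confusion matrix
#'
#' Crosses the screening result (any alert during the ED stay) against the
#' physician reference-standard label into the 2x2 counts on which all test
#' characteristics are computed.
#'
#' @param status Data frame with columns `patient_id` and logical `alert`
#'   (from [patient_alert_status()]).
#' @param labels Data frame with columns `patient_id` and logical `label`
#'   (reference standard: severe sepsis or septic shock, yes/no). The two
#'   patient id sets must be identical.
#' @return A `confusion_matrix`: list with integer `tp`, `fp`, `fn`, `tn`
#'   and total `n`.
#' @export
#' @examples
#' status <- tibble::tibble(patient_id = c("a", "b", "c"),
#'                          alert = c(TRUE, FALSE, TRUE))
#' labels <- tibble::tibble(patient_id = c("a", "b", "c"),
#'                          label = c(TRUE, FALSE, FALSE))
#' build_confusion(status, labels)
build_confusion <- function(status, labels) {
  stopifnot(all(c("patient_id", "alert") %in% names(status)),
            all(c("patient_id", "label") %in% names(labels)))
  if (anyDuplicated(status$patient_id) || anyDuplicated(labels$patient_id)) {
    stop("duplicate patient ids in status or labels")
  }
  only_status <- setdiff(status$patient_id, labels$patient_id)
  only_labels <- setdiff(labels$patient_id, status$patient_id)
  if (length(only_status) || length(only_labels)) {
    stop("patient id sets differ; only in status: {",
         paste(utils::head(only_status, 10), collapse = ", "),
         "}, only in labels: {",
         paste(utils::head(only_labels, 10), collapse = ", "), "}")
  }
  lab <- labels$label[match(status$patient_id, labels$patient_id)]
  alert <- status$alert
  confusion_matrix(
    tp = sum(alert & lab), fp = sum(alert & !lab),
    fn = sum(!alert & lab), tn = sum(!alert & !lab)
  )
}

#' Construct a confusion matrix from counts
#'
#' @param tp,fp,fn,tn Non-negative integer cell counts (true positive,
#'   false positive, false negative, true negative).
#' @return A `confusion_matrix` object.
#' @export
#' @examples
#' confusion_matrix(tp = 205, fp = 772, fn = 15, tn = 48846)
confusion_matrix <- function(tp, fp, fn, tn) {
  counts <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("confusion-matrix cells must be non-negative integers")
  }
  structure(list(tp = as.integer(tp), fp = as.integer(fp),
                 fn = as.integer(fn), tn = as.integer(tn),
                 n = as.integer(tp + fp + fn + tn)),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat("<confusion_matrix> n =", x$n, "\n")
  m <- matrix(c(x$tp, x$fn, x$fp, x$tn), 2, 2,
              dimnames = list(alert = c("positive", "negative"),
                              reference = c("sepsis", "no sepsis")))
  print(m)
  invisible(x)
}

#' @keywords internal
#' @noRd
new_proportion_ci <- function(estimate, lower, upper, alpha, method) {
  structure(list(estimate = estimate, lower = lower, upper = upper,
                 alpha = alpha, method = method),
            class = "proportion_ci")
}

#' Exact (Clopper-Pearson) binomial confidence interval
#'
#' Inverts the binomial tail probabilities via beta quantiles:
#' lower = `qbeta(alpha/2, x, n - x + 1)` (0 when x = 0) and
#' upper = `qbeta(1 - alpha/2, x + 1, n - x)` (1 when x = n). The interval
#' is exact in the sense of guaranteed coverage, hence conservative.
#'
#' @param successes,trials Integer counts, `0 <= successes <= trials`,
#'   `trials >= 1`.
#' @param alpha Two-sided significance level in (0, 1).
#' @return A `proportion_ci`: list with `estimate`, `lower`, `upper`,
#'   `alpha` and `method = "clopper_pearson"`.
#' @export
#' @examples
#' clopper_pearson(205, 220)
clopper_pearson <- function(successes, trials, alpha = 0.05) {
  if (length(successes) != 1L || length(trials) != 1L ||
      is.na(successes) || is.na(trials) ||
      successes != round(successes) || trials != round(trials) ||
      trials < 1 || successes < 0 || successes > trials) {
    stop("need integer counts with 0 <= successes <= trials, trials >= 1")
  }
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 1) {
    stop("alpha must be a single number in (0, 1)")
  }
  x <- successes
  n <- trials
  lower <- if (x == 0) 0 else stats::qbeta(alpha / 2, x, n - x + 1)
  upper <- if (x == n) 1 else stats::qbeta(1 - alpha / 2, x + 1, n - x)
  new_proportion_ci(x / n, lower, upper, alpha, "clopper_pearson")
}

#' Wilson score confidence interval
#'
#' Score-test inversion interval for a binomial proportion, optionally with
#' the Newcombe continuity correction. The continuity-corrected variant is
#' what many clinical-epidemiology calculators report for diagnostic test
#' characteristics.
#'
#' @inheritParams clopper_pearson
#' @param correct Apply the continuity correction (default `TRUE`).
#' @return A `proportion_ci` with method `"wilson_cc"` (or `"wilson"`).
#' @export
#' @examples
#' wilson_ci(205, 220)
wilson_ci <- function(successes, trials, alpha = 0.05, correct = TRUE) {
  if (length(successes) != 1L || length(trials) != 1L ||
      is.na(successes) || is.na(trials) ||
      successes != round(successes) || trials < 1 ||
      successes < 0 || successes > trials) {
    stop("need integer counts with 0 <= successes <= trials, trials >= 1")
  }
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 1) {
    stop("alpha must be a single number in (0, 1)")
  }
  x <- successes
  n <- trials
  p <- x / n
  z <- stats::qnorm(1 - alpha / 2)
  if (correct) {
    lower <- if (x == 0) 0 else {
      (2 * n * p + z^2 - 1 -
         z * sqrt(z^2 - 2 - 1 / n + 4 * p * (n * (1 - p) + 1))) /
        (2 * (n + z^2))
    }
    upper <- if (x == n) 1 else {
      (2 * n * p + z^2 + 1 +
         z * sqrt(z^2 + 2 - 1 / n + 4 * p * (n * (1 - p) - 1))) /
        (2 * (n + z^2))
    }
  } else {
    half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2))
    centre <- p + z^2 / (2 * n)
    lower <- (centre - half) / (1 + z^2 / n)
    upper <- (centre + half) / (1 + z^2 / n)
  }
  new_proportion_ci(p, max(0, lower), min(1, upper), alpha,
                    if (correct) "wilson_cc" else "wilson")
}

#' @keywords internal
#' @noRd
proportion_ci <- function(successes, trials, alpha,
                          method = c("clopper_pearson", "wilson_cc", "wilson")) {
  method <- match.arg(method)
  switch(method,
         clopper_pearson = clopper_pearson(successes, trials, alpha),
         wilson_cc = wilson_ci(successes, trials, alpha, correct = TRUE),
         wilson = wilson_ci(successes, trials, alpha, correct = FALSE))
}

#' Likelihood ratios with log-method confidence intervals
#'
#' LR+ = sensitivity / (1 - specificity), LR- = (1 - sensitivity) /
#' specificity. Confidence intervals use the standard log transform,
#' `exp(log(LR) +/- z * se(log LR))`, with
#' `se^2(log LR+) = 1/tp - 1/(tp+fn) + 1/fp - 1/(fp+tn)` and
#' `se^2(log LR-) = 1/fn - 1/(tp+fn) + 1/tn - 1/(fp+tn)`. A zero cell that
#' makes a ratio undefined raises an error; no continuity correction is
#' applied silently.
#'
#' @param cm A [confusion_matrix()].
#' @param alpha Two-sided significance level.
#' @return List with `lr_pos` and `lr_neg`, each a `ratio_ci` (list with
#'   `estimate`, `lower`, `upper`, `alpha`, `method = "log_normal"`).
#' @export
#' @examples
#' likelihood_ratios(confusion_matrix(205, 772, 15, 48846))
likelihood_ratios <- function(cm, alpha = 0.05) {
  stopifnot(inherits(cm, "confusion_matrix"))
  list(lr_pos = lr_one(cm, alpha, positive = TRUE),
       lr_neg = lr_one(cm, alpha, positive = FALSE))
}

#' @keywords internal
#' @noRd
lr_one <- function(cm, alpha, positive) {
  tp <- cm$tp; fp <- cm$fp; fn <- cm$fn; tn <- cm$tn
  if (tp + fn == 0 || fp + tn == 0) {
    stop("likelihood ratios undefined: a reference-standard margin is empty")
  }
  sens <- tp / (tp + fn)
  spec <- tn / (fp + tn)
  z <- stats::qnorm(1 - alpha / 2)
  if (positive) {
    if (fp == 0 || tp == 0) {
      stop("LR+ undefined: requires tp > 0 and fp > 0 ",
           "(no silent continuity correction)")
    }
    est <- sens / (1 - spec)
    se2 <- 1 / tp - 1 / (tp + fn) + 1 / fp - 1 / (fp + tn)
  } else {
    if (fn == 0 || tn == 0) {
      stop("LR- undefined: requires fn > 0 and tn > 0 ",
           "(no silent continuity correction)")
    }
    est <- (1 - sens) / spec
    se2 <- 1 / fn - 1 / (tp + fn) + 1 / tn - 1 / (fp + tn)
  }
  se <- sqrt(se2)
  structure(list(estimate = est, lower = est * exp(-z * se),
                 upper = est * exp(z * se), alpha = alpha,
                 method = "log_normal"),
            class = "ratio_ci")
}

#' @keywords internal
#' @noRd
undefined_stat <- function(reason, alpha, method) {
  structure(list(estimate = NA_real_, lower = NA_real_, upper = NA_real_,
                 alpha = alpha, method = method, reason = reason),
            class = c("undefined_statistic", "proportion_ci"))
}

#' Diagnostic accuracy report
#'
#' Derives the full set of test characteristics from a patient-level 2x2
#' table: sensitivity `tp/(tp+fn)`, specificity `tn/(fp+tn)`, positive and
#' negative predictive values, prevalence, and both likelihood ratios.
#' Proportions carry exact or score confidence intervals; likelihood ratios
#' carry log-method intervals. A statistic whose margin is empty is
#' reported as an explicit undefined marker (never silently 0 or 1), and
#' the report is still returned.
#'
#' @param cm A [confusion_matrix()] (or data frames `status`/`labels` may
#'   be crossed first via [build_confusion()]).
#' @param alpha Two-sided significance level for all intervals.
#' @param ci_method Proportion CI method: `"clopper_pearson"` (exact,
#'   default) or `"wilson_cc"` / `"wilson"` (score interval with/without
#'   continuity correction).
#' @return A `diagnostic_report`: list with `sensitivity`, `specificity`,
#'   `ppv`, `npv` (each a `proportion_ci`), `lr_pos`, `lr_neg` (each a
#'   `ratio_ci` or undefined marker), `prevalence`, `n`, `counts`, `alpha`,
#'   `ci_method`. Use [tidy()] / [glance()] for tibble views.
#' @export
#' @examples
#' diagnostic_report(confusion_matrix(205, 772, 15, 48846))
diagnostic_report <- function(cm, alpha = 0.05,
                              ci_method = c("clopper_pearson", "wilson_cc",
                                            "wilson")) {
  stopifnot(inherits(cm, "confusion_matrix"))
  ci_method <- match.arg(ci_method)
  tp <- cm$tp; fp <- cm$fp; fn <- cm$fn; tn <- cm$tn

  prop_or_undef <- function(x, n, what) {
    if (n == 0) {
      undefined_stat(paste0(what, " undefined: empty margin"),
                     alpha, ci_method)
    } else {
      proportion_ci(x, n, alpha, ci_method)
    }
  }

  lr_or_undef <- function(positive) {
    tryCatch(lr_one(cm, alpha, positive), error = function(e) {
      structure(list(estimate = NA_real_, lower = NA_real_,
                     upper = NA_real_, alpha = alpha,
                     method = "log_normal",
                     reason = conditionMessage(e)),
                class = c("undefined_statistic", "ratio_ci"))
    })
  }
  lrs <- list(lr_pos = lr_or_undef(TRUE), lr_neg = lr_or_undef(FALSE))

  structure(
    list(
      sensitivity = prop_or_undef(tp, tp + fn, "sensitivity"),
      specificity = prop_or_undef(tn, fp + tn, "specificity"),
      ppv = prop_or_undef(tp, tp + fp, "PPV"),
      npv = prop_or_undef(tn, fn + tn, "NPV"),
      lr_pos = lrs$lr_pos,
      lr_neg = lrs$lr_neg,
      prevalence = if (cm$n > 0) (tp + fn) / cm$n else NA_real_,
      n = cm$n,
      counts = cm,
      alpha = alpha,
      ci_method = ci_method
    ),
    class = "diagnostic_report"
  )
}

#' @export
print.diagnostic_report <- function(x, digits = 4, ...) {
  cat("<diagnostic_report> n =", x$n,
      sprintf(" prevalence = %.4g", x$prevalence),
      sprintf(" (%d%% CIs, %s)\n", round(100 * (1 - x$alpha)), x$ci_method))
  fmt <- function(s, nm) {
    if (inherits(s, "undefined_statistic")) {
      cat(sprintf("  %-12s undefined (%s)\n", nm, s$reason))
    } else {
      cat(sprintf("  %-12s %.*f (%.*f-%.*f)\n", nm, digits, s$estimate,
                  digits, s$lower, digits, s$upper))
    }
  }
  fmt(x$sensitivity, "sensitivity")
  fmt(x$specificity, "specificity")
  fmt(x$ppv, "PPV")
  fmt(x$npv, "NPV")
  fmt(x$lr_pos, "LR+")
  fmt(x$lr_neg, "LR-")
  invisible(x)
}

#' Summarise alert-to-referral lead times
#'
#' Median and quartiles of the signed lead times from first alert to ICU
#' referral, using the linear-interpolation quantile convention
#' (`stats::quantile()` type 7).
#'
#' @param lead_times Data frame with a `lead_time_hours` column (as from
#'   [lead_times()]) or a bare numeric vector of hours. Must be non-empty.
#' @return A `lead_time_summary`: list with `median`, `q1`, `q3` (hours)
#'   and `n`.
#' @export
#' @examples
#' lead_time_summary(c(1, 2, 3, 4))
lead_time_summary <- function(lead_times) {
  x <- if (is.data.frame(lead_times)) lead_times$lead_time_hours else lead_times
  x <- as.numeric(x)
  if (length(x) == 0L || anyNA(x)) {
    stop("lead_time_summary() needs a non-empty vector without NAs")
  }
  q <- stats::quantile(x, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  structure(list(median = q[2L], q1 = q[1L], q3 = q[3L], n = length(x)),
            class = "lead_time_summary")
}

#' @export
print.lead_time_summary <- function(x, ...) {
  cat(sprintf(
    "<lead_time_summary> median %.2f h (Q1-Q3, %.2f-%.2f), n = %d\n",
    x$median, x$q1, x$q3, x$n))
  invisible(x)
}
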