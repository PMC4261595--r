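# internal helpers: time parsing/formatting, truncated distributions,
# lightweight tibble construction for hot paths

#' @keywords internal
#' @noRd
parse_timestamp <- function(x) {
  if (inherits(x, "POSIXct")) return(as.POSIXct(x, tz = "UTC"))
  if (is.numeric(x)) return(as.POSIXct(x, origin = "1970-01-01", tz = "UTC"))
  x <- as.character(x)
  out <- as.POSIXct(strptime(x, "%Y-%m-%dT%H:%M:%OS%z", tz = "UTC"))
  bad <- is.na(out) & !is.na(x)
  if (any(bad)) {
    # tolerate 'Z' suffix and space-separated timestamps
    out[bad] <- suppressWarnings(readr::parse_datetime(x[bad]))
  }
  out
}

#' @keywords internal
#' @noRd
format_timestamp <- function(t) {
  format(as.POSIXct(t, tz = "UTC"), "%Y-%m-%dT%H:%M:%S%z", tz = "UTC")
}

# fast tibble from equal-length vectors; skips validation deliberately
#' @keywords internal
#' @noRd
quick_tbl <- function(...) {
  x <- list(...)
  n <- if (length(x)) length(x[[1L]]) else 0L
  structure(x, class = c("tbl_df", "tbl", "data.frame"),
            row.names = .set_row_names(n))
}

# inverse-CDF sampling from a normal truncated to [lower, upper]
#' @keywords internal
#' @noRd
rtnorm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  plo <- stats::pnorm(lower, mean, sd)
  phi <- stats::pnorm(upper, mean, sd)
  stats::qnorm(stats::runif(n, plo, phi), mean, sd)
}

# inverse-CDF sampling from a log-normal truncated to [lower, upper]
#' @keywords internal
#' @noRd
rtlnorm <- function(n, meanlog, sdlog, lower = 0, upper = Inf) {
  plo <- stats::plnorm(lower, meanlog, sdlog)
  phi <- stats::plnorm(upper, meanlog, sdlog)
  stats::qlnorm(stats::runif(n, plo, phi), meanlog, sdlog)
}

#' @keywords internal
#' @noRd
`%||%` <- function(x, y) if (is.null(x)) y else x

# run expr with a local RNG seed, restoring the caller's RNG state
#' @keywords internal
#' @noRd
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}
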