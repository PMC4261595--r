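#' Distribution specification for one physiologic parameter
#'
#' Generator building block: a truncated normal (`tnorm`) or truncated
#' log-normal (`tlnorm`) sampling distribution with a severity-shift
#' direction. A global severity shift of `delta` moves the location by
#' `delta * shift_dir * scale` (for `tlnorm`, on the log scale), so positive
#' shifts always move a stratum toward more deranged physiology.
#'
#' @param family `"tnorm"` or `"tlnorm"`.
#' @param location Mean (`tnorm`) or meanlog (`tlnorm`).
#' @param scale Standard deviation (`tnorm`) or sdlog (`tlnorm`); may be 0
#'   for a degenerate point mass.
#' @param lower,upper Truncation bounds on the value scale.
#' @param shift_dir +1 if larger values are more deranged, -1 otherwise.
#' @return A `dist_spec` list.
#' @export
dist_spec <- function(family = c("tnorm", "tlnorm"), location, scale,
                      lower = -Inf, upper = Inf, shift_dir = 1) {
  family <- match.arg(family)
  stopifnot(scale >= 0, lower < upper, shift_dir %in% c(-1, 1))
  structure(list(family = family, location = location, scale = scale,
                 lower = lower, upper = upper, shift_dir = shift_dir),
            class = "dist_spec")
}

# inverse-CDF evaluation at uniforms u (vector or matrix), with severity
# shift delta applied to the location
#' @keywords internal
#' @noRd
dist_values <- function(spec, u, delta = 0) {
  loc <- spec$location + delta * spec$shift_dir * spec$scale
  if (spec$scale == 0) {
    v <- rep(if (spec$family == "tnorm") loc else exp(loc), length(u))
  } else if (spec$family == "tnorm") {
    plo <- stats::pnorm(spec$lower, loc, spec$scale)
    phi <- stats::pnorm(spec$upper, loc, spec$scale)
    v <- stats::qnorm(plo + u * (phi - plo), loc, spec$scale)
  } else {
    plo <- stats::plnorm(max(spec$lower, 0), loc, spec$scale)
    phi <- stats::plnorm(spec$upper, loc, spec$scale)
    v <- stats::qlnorm(plo + u * (phi - plo), loc, spec$scale)
  }
  dim(v) <- dim(u)
  v
}

#' @keywords internal
#' @noRd
shift_model <- function(model, delta) {
  if (delta == 0) return(model)
  for (k in parameter_kinds()) {
    s <- model[[k]]
    s$location <- s$location + delta * s$shift_dir * s$scale
    model[[k]] <- s
  }
  model
}

#' Stratum physiology model
#'
#' Per-parameter sampling distributions and therapy-order probabilities for
#' one cohort stratum (septic or non-septic).
#'
#' @param temperature,pulse,respiratory_rate,wbc,sbp,spo2,lactate
#'   [dist_spec()] objects, in the kind's unit.
#' @param fluids_prob,oxygen_prob Probability that an IV fluid bolus /
#'   supplemental oxygen order is placed during the stay.
#' @param therapy_start_range_hours Range (hours after arrival) over which a
#'   therapy order's start time is drawn uniformly.
#' @return A `stratum_model` list.
#' @export
stratum_model <- function(temperature, pulse, respiratory_rate, wbc, sbp,
                          spo2, lactate, fluids_prob, oxygen_prob,
                          therapy_start_range_hours = c(0.25, 1.25)) {
  stopifnot(fluids_prob >= 0, fluids_prob <= 1,
            oxygen_prob >= 0, oxygen_prob <= 1,
            length(therapy_start_range_hours) == 2,
            therapy_start_range_hours[1] <= therapy_start_range_hours[2])
  structure(list(
    temperature = temperature, pulse = pulse,
    respiratory_rate = respiratory_rate, wbc = wbc,
    sbp = sbp, spo2 = spo2, lactate = lactate,
    fluids_prob = fluids_prob, oxygen_prob = oxygen_prob,
    therapy_start_range_hours = therapy_start_range_hours
  ), class = "stratum_model")
}

#' Default septic-stratum physiology
#'
#' Location/scale choices loosely matched to the clinical frequencies
#' typically reported for ED patients with severe sepsis or septic shock
#' (roughly 86% tachycardic, 89% tachypneic, 70% hypotensive, around a
#' quarter hyperlactatemic). These are generator targets for realism, not
#' asserted outcomes; [calibrate_cohort()] applies a global severity shift
#' on top of them.
#'
#' @return A `stratum_model`.
#' @export
septic_stratum_model <- function() {
  stratum_model(
    temperature = dist_spec("tnorm", 37.4, 1.1, 30, 43, +1),
    pulse = dist_spec("tnorm", 103, 17, 30, 220, +1),
    respiratory_rate = dist_spec("tnorm", 26, 5, 6, 80, +1),
    wbc = dist_spec("tnorm", 12, 5.5, 0.3, 80, +1),
    sbp = dist_spec("tnorm", 97, 22, 40, 250, -1),
    spo2 = dist_spec("tnorm", 91.5, 5, 50, 100, -1),
    lactate = dist_spec("tlnorm", log(1.45), 0.62, 0.2, 30, +1),
    fluids_prob = 0.85, oxygen_prob = 0.55
  )
}

#' Default non-septic-stratum physiology
#'
#' Broadly normal ED physiology with realistic tails (about a quarter
#' mildly tachycardic, occasional abnormal white counts and lactates), so
#' that false-positive alerts arise through the same mechanisms as in a
#' real department.
#'
#' @return A `stratum_model`.
#' @export
non_septic_stratum_model <- function() {
  stratum_model(
    temperature = dist_spec("tnorm", 36.9, 0.45, 30, 43, +1),
    pulse = dist_spec("tnorm", 82, 13, 30, 220, +1),
    respiratory_rate = dist_spec("tnorm", 17, 3, 6, 80, +1),
    wbc = dist_spec("tnorm", 8.5, 2.8, 0.3, 80, +1),
    sbp = dist_spec("tnorm", 126, 17, 40, 250, -1),
    spo2 = dist_spec("tnorm", 97.5, 1.8, 50, 100, -1),
    lactate = dist_spec("tlnorm", log(1.1), 0.45, 0.1, 30, +1),
    fluids_prob = 0.12, oxygen_prob = 0.06
  )
}

#' Synthetic ED cohort parameters
#'
#' Generative settings for [simulate_cohort()]: cohort size and prevalence,
#' stratum physiology models, charting cadence by triage area (hourly in
#' the critical area, two-hourly elsewhere), stat-lab turnaround, ED
#' length-of-stay and ICU-referral-delay distributions, and the seed that
#' fully determines the output.
#'
#' @param n_patients Number of patients.
#' @param prevalence Probability a patient belongs to the septic stratum
#'   (default the ~0.44% of an unselected ED population).
#' @param seed Integer seed; the same seed reproduces the cohort
#'   bit-exactly.
#' @param septic,non_septic [stratum_model()]s.
#' @param cadence_hours Named charting cadence `c(critical = 1, other = 2)`.
#' @param lab_turnaround_hours Delay from arrival blood draw to WBC/lactate
#'   result (default 1 h).
#' @param critical_area_prob Probability of triage to the critical area,
#'   per stratum.
#' @param ed_stay Per-stratum log-normal length-of-stay parameters (hours):
#'   list with `meanlog`, `sdlog`, `min`, `max`.
#' @param icu_referral_delay Log-normal recognition-to-referral delay
#'   (hours) for septic patients, anchored at the first fired alert when
#'   one exists and at ED arrival otherwise: `meanlog`, `sdlog`, `min`,
#'   `max`. Default median 4 h.
#' @param disposition_delay_minutes Range of the nurse/physician response
#'   delay from alert to recorded disposition.
#' @param start Cohort period start timestamp.
#' @param window_days Arrival times are uniform over this many days.
#' @param emit_dispositions Generate disposition events for alerted
#'   patients (suspected_sepsis for septic, not_sepsis otherwise).
#' @return A `cohort_params` list.
#' @export
#' @examples
#' p <- cohort_params(n_patients = 200, seed = 42)
#' cohort <- simulate_cohort(p)
#' cohort
cohort_params <- function(n_patients,
                          prevalence = 220 / 49838,
                          seed = 1,
                          septic = septic_stratum_model(),
                          non_septic = non_septic_stratum_model(),
                          cadence_hours = c(critical = 1, other = 2),
                          lab_turnaround_hours = 1,
                          critical_area_prob = c(septic = 0.8,
                                                 non_septic = 0.25),
                          ed_stay = list(
                            septic = list(meanlog = log(6), sdlog = 0.4,
                                          min = 1.5, max = 24),
                            non_septic = list(meanlog = log(4), sdlog = 0.5,
                                              min = 1, max = 24)
                          ),
                          icu_referral_delay = list(meanlog = log(4),
                                                    sdlog = 1.1,
                                                    min = 0.05, max = 96),
                          disposition_delay_minutes = c(5, 30),
                          start = as.POSIXct("2012-10-01 00:00:00",
                                             tz = "UTC"),
                          window_days = 122,
                          emit_dispositions = TRUE) {
  stopifnot(n_patients >= 1, prevalence >= 0, prevalence <= 1,
            all(cadence_hours > 0), lab_turnaround_hours > 0,
            all(critical_area_prob >= 0), all(critical_area_prob <= 1))
  structure(list(
    n_patients = as.integer(n_patients), prevalence = prevalence,
    seed = as.integer(seed), septic = septic, non_septic = non_septic,
    cadence_hours = cadence_hours,
    lab_turnaround_hours = lab_turnaround_hours,
    critical_area_prob = critical_area_prob,
    ed_stay = ed_stay, icu_referral_delay = icu_referral_delay,
    disposition_delay_minutes = disposition_delay_minutes,
    start = as.POSIXct(start, tz = "UTC"), window_days = window_days,
    emit_dispositions = emit_dispositions,
    calibration = NULL
  ), class = "cohort_params")
}

# Draw the structural randomness for one stratum block: triage areas,
# stays, arrival times, uniform deviates for all physiologic values,
# therapy orders and delays. Everything downstream of these draws is
# deterministic, which lets the calibration search re-evaluate the same
# block under different severity shifts (common random numbers).
#' @keywords internal
#' @noRd
gen_block <- function(n, model, params, septic) {
  if (n == 0L) return(NULL)
  cad <- params$cadence_hours
  p_crit <- params$critical_area_prob[[if (septic) "septic" else "non_septic"]]
  area_crit <- stats::runif(n) < p_crit
  st <- params$ed_stay[[if (septic) "septic" else "non_septic"]]
  stay_h <- rtlnorm(n, st$meanlog, st$sdlog, st$min, st$max)
  arr <- as.numeric(params$start) + floor(stats::runif(n, 0, params$window_days * 86400))
  stay_s <- round(stay_h * 3600)
  dep <- arr + stay_s
  cad_s <- ifelse(area_crit, cad[["critical"]], cad[["other"]]) * 3600
  nt <- as.integer(stay_s %/% cad_s) + 1L
  K <- max(nt)
  vital_names <- c("temperature", "pulse", "respiratory_rate", "sbp", "spo2")
  vit_u <- lapply(vital_names, function(k) matrix(stats::runif(n * K), n, K))
  names(vit_u) <- vital_names
  wbc_u <- stats::runif(n)
  lac_u <- stats::runif(n)
  rng <- model$therapy_start_range_hours
  has_fluids <- stats::runif(n) < model$fluids_prob
  fluids_start <- arr + round(stats::runif(n, rng[1], rng[2]) * 3600)
  has_oxygen <- stats::runif(n) < model$oxygen_prob
  oxygen_start <- arr + round(stats::runif(n, rng[1], rng[2]) * 3600)
  has_fluids <- has_fluids & fluids_start < dep
  has_oxygen <- has_oxygen & oxygen_start < dep
  ref_delay_s <- if (septic) {
    rd <- params$icu_referral_delay
    round(rtlnorm(n, rd$meanlog, rd$sdlog, rd$min, rd$max) * 3600)
  } else {
    rep(NA_real_, n)
  }
  dd <- params$disposition_delay_minutes
  disp_delay_s <- round(stats::runif(n, dd[1], dd[2]) * 60)
  # tick times: arrival + (j - 1) * cadence
  tick_s <- matrix(arr, n, K)
  if (K > 1L) for (j in 2:K) tick_s[, j] <- tick_s[, j - 1L] + cad_s
  valid <- outer(nt, seq_len(K), `>=`)
  lab_t <- pmin(arr + params$lab_turnaround_hours * 3600, dep)
  list(n = n, K = K, septic = septic, area_crit = area_crit,
       arr = arr, dep = dep, cad_s = cad_s, nt = nt,
       tick_s = tick_s, valid = valid, lab_t = lab_t,
       vit_u = vit_u, wbc_u = wbc_u, lac_u = lac_u,
       has_fluids = has_fluids, fluids_start = fluids_start,
       has_oxygen = has_oxygen, oxygen_start = oxygen_start,
       ref_delay_s = ref_delay_s, disp_delay_s = disp_delay_s)
}

# physiologic values for a block under a (possibly shifted) stratum model,
# rounded to charted precision (integer pulse/RR/SBP/SpO2, one decimal for
# temperature, WBC and lactate) as they would be entered in the chart
#' @keywords internal
#' @noRd
chart_digits <- c(temperature = 1, pulse = 0, respiratory_rate = 0,
                  wbc = 1, sbp = 0, spo2 = 0, lactate = 1)

#' @keywords internal
#' @noRd
block_values <- function(block, model, delta = 0) {
  vals <- lapply(names(block$vit_u), function(k) {
    round(dist_values(model[[k]], block$vit_u[[k]], delta),
          chart_digits[[k]])
  })
  names(vals) <- names(block$vit_u)
  list(vitals = vals,
       wbc = round(dist_values(model$wbc, block$wbc_u, delta),
                   chart_digits[["wbc"]]),
       lactate = round(dist_values(model$lactate, block$lac_u, delta),
                       chart_digits[["lactate"]]))
}

# Patient-level alert positivity and first-alert time for a block,
# replicating the engine's evaluation semantics (evaluate at every chart
# tick, at the lab-result arrival and at therapy starts; labs available
# from the turnaround time; therapy flags half-open). Suppression does not
# affect whether or when the FIRST alert fires, so any-fire and first-fire
# agree exactly with run_screening(); a test asserts that equivalence.
#' @keywords internal
#' @noRd
block_positivity <- function(block, vv, params,
                             thresholds = criteria_thresholds()) {
  n <- block$n
  K <- block$K
  tick <- block$tick_s
  lab_avail <- tick >= block$lab_t
  wbc_m <- matrix(vv$wbc, n, K)
  lac_m <- matrix(vv$lactate, n, K)
  wbc_m[!lab_avail] <- NA_real_
  lac_m[!lab_avail] <- NA_real_
  fl_on <- block$has_fluids & block$fluids_start <= tick & tick < block$dep
  ox_on <- block$has_oxygen & block$oxygen_start <= tick & tick < block$dep

  ev <- criteria_eval_vec(vv$vitals$temperature, vv$vitals$pulse,
                          vv$vitals$respiratory_rate, wbc_m,
                          vv$vitals$sbp, vv$vitals$spo2, lac_m,
                          fl_on, ox_on, thresholds)
  fire_tick <- ev$fire & block$valid
  dim(fire_tick) <- c(n, K)

  first <- rep(Inf, n)
  for (j in seq_len(K)) {
    first <- pmin(first, ifelse(fire_tick[, j], tick[, j], Inf))
  }

  # evaluation at a per-patient extra time point with carried-forward vitals
  eval_extra <- function(t_vec, active) {
    jl <- pmin(as.integer((t_vec - block$arr) %/% block$cad_s) + 1L, block$nt)
    idx <- cbind(seq_len(n), jl)
    labs <- t_vec >= block$lab_t
    fl <- block$has_fluids & block$fluids_start <= t_vec & t_vec < block$dep
    ox <- block$has_oxygen & block$oxygen_start <= t_vec & t_vec < block$dep
    e <- criteria_eval_vec(
      vv$vitals$temperature[idx], vv$vitals$pulse[idx],
      vv$vitals$respiratory_rate[idx],
      ifelse(labs, vv$wbc, NA_real_),
      vv$vitals$sbp[idx], vv$vitals$spo2[idx],
      ifelse(labs, vv$lactate, NA_real_),
      fl, ox, thresholds)
    fire <- e$fire & active
    first <<- pmin(first, ifelse(fire, t_vec, Inf))
  }

  eval_extra(block$lab_t, rep(TRUE, n))
  eval_extra(block$fluids_start, block$has_fluids)
  eval_extra(block$oxygen_start, block$has_oxygen)

  list(any = is.finite(first), first = first)
}

# Materialize a block into sepsis_timeline objects (ids pids), ordered as
# the block rows. ref_time: absolute ICU-referral seconds per patient
# (septic blocks only).
#' @keywords internal
#' @noRd
block_timelines <- function(block, vv, pids, ref_time = NULL) {
  n <- block$n
  K <- block$K
  vmask <- as.vector(block$valid)
  rid_tick <- rep(seq_len(n), times = K)[vmask]
  t_tick <- as.vector(block$tick_s)[vmask]
  vital_names <- names(vv$vitals)

  pid_i <- c(rep(rid_tick, length(vital_names)), seq_len(n), seq_len(n))
  tt <- c(rep(t_tick, length(vital_names)), block$lab_t, block$lab_t)
  kind <- c(rep(vital_names, each = length(rid_tick)),
            rep("wbc", n), rep("lactate", n))
  val <- c(unlist(lapply(vv$vitals, function(V) as.vector(V)[vmask]),
                  use.names = FALSE),
           vv$wbc, vv$lactate)

  rank <- match(kind, parameter_kinds())
  ord <- order(pid_i, tt, rank)
  pid_i <- pid_i[ord]; tt <- tt[ord]; kind <- kind[ord]; val <- val[ord]
  tt_ct <- as.POSIXct(tt, origin = "1970-01-01", tz = "UTC")

  counts <- 5L * block$nt + 2L
  ends <- cumsum(counts)
  starts <- ends - counts + 1L

  arr_ct <- as.POSIXct(block$arr, origin = "1970-01-01", tz = "UTC")
  dep_ct <- as.POSIXct(block$dep, origin = "1970-01-01", tz = "UTC")
  na_ct <- as.POSIXct(NA, tz = "UTC")

  lapply(seq_len(n), function(i) {
    sel <- starts[i]:ends[i]
    th_kind <- character()
    th_start <- numeric()
    if (block$has_fluids[i]) {
      th_kind <- "iv_fluid_bolus"
      th_start <- block$fluids_start[i]
    }
    if (block$has_oxygen[i]) {
      th_kind <- c(th_kind, "supplemental_oxygen")
      th_start <- c(th_start, block$oxygen_start[i])
    }
    therapies <- if (length(th_kind)) {
      o <- order(th_start)
      quick_tbl(kind = th_kind[o],
                start = as.POSIXct(th_start[o], origin = "1970-01-01",
                                   tz = "UTC"),
                end = rep(na_ct, length(th_kind)))
    } else {
      empty_therapies()
    }
    new_timeline(
      patient_id = pids[i],
      triage_area = if (block$area_crit[i]) "critical" else "other",
      ed_arrival = arr_ct[i], ed_departure = dep_ct[i],
      observations = quick_tbl(time = tt_ct[sel], kind = kind[sel],
                               value = val[sel]),
      therapies = therapies,
      code_status = empty_code_status(),
      icu_referral_time = if (!is.null(ref_time)) {
        as.POSIXct(ref_time[i], origin = "1970-01-01", tz = "UTC")
      } else {
        NULL
      },
      reference_label = block$septic
    )
  })
}

#' Simulate a synthetic ED cohort
#'
#' Generates a seeded cohort of patient timelines with the statistical
#' structure the screening evaluation assumes: a low-prevalence septic
#' stratum, triage-area-dependent charting cadence (vitals re-drawn
#' independently at every tick), one WBC/lactate draw resulting after the
#' lab turnaround, stratum-specific therapy orders (open-ended, active
#' until departure), ICU referral times for septic patients, and — for
#' patients whose timeline fires the alert — a clinician disposition event
#' shortly after the first alert.
#'
#' @param params A [cohort_params()] (possibly from [calibrate_cohort()]).
#' @return A `synthetic_cohort`: list with `timelines` (list of
#'   `sepsis_timeline`), `labels` (tibble `patient_id`, `label`),
#'   `dispositions` (tibble `patient_id`, `time`, `category`) and
#'   `params_echo`.
#' @export
#' @examples
#' cohort <- simulate_cohort(cohort_params(n_patients = 100, seed = 7))
#' length(cohort$timelines)
simulate_cohort <- function(params) {
  stopifnot(inherits(params, "cohort_params"))
  n <- params$n_patients
  out <- with_seed(params$seed, {
    septic <- stats::runif(n) < params$prevalence
    block_s <- gen_block(sum(septic), params$septic, params, septic = TRUE)
    block_n <- gen_block(sum(!septic), params$non_septic, params,
                         septic = FALSE)
    list(septic = septic, block_s = block_s, block_n = block_n)
  })
  septic <- out$septic
  pids <- sprintf("P%06d", seq_len(n))

  timelines <- vector("list", n)
  disp_rows <- list()
  for (stratum in c("s", "n")) {
    block <- out[[paste0("block_", stratum)]]
    if (is.null(block)) next
    is_s <- stratum == "s"
    idx <- which(septic == is_s)
    model <- if (is_s) params$septic else params$non_septic
    vv <- block_values(block, model)
    pos <- if (is_s || params$emit_dispositions) {
      block_positivity(block, vv, params)
    }
    ref_time <- if (is_s) {
      # referral follows clinical recognition: anchor the delay at the
      # first alert when one fired, at arrival otherwise
      ifelse(is.finite(pos$first), pos$first, block$arr) + block$ref_delay_s
    }
    timelines[idx] <- block_timelines(block, vv, pids[idx], ref_time)
    if (params$emit_dispositions) {
      fired <- which(pos$any)
      if (length(fired)) {
        disp_rows[[stratum]] <- quick_tbl(
          patient_id = pids[idx][fired],
          time = as.POSIXct(pos$first[fired] + block$disp_delay_s[fired],
                            origin = "1970-01-01", tz = "UTC"),
          category = rep(if (is_s) "suspected_sepsis" else "not_sepsis",
                         length(fired))
        )
      }
    }
  }

  dispositions <- if (length(disp_rows)) {
    d <- dplyr::bind_rows(disp_rows)
    d[order(d$patient_id, d$time), ]
  } else {
    tibble::tibble(patient_id = character(),
                   time = as.POSIXct(numeric(), origin = "1970-01-01",
                                     tz = "UTC"),
                   category = character())
  }

  structure(
    list(
      timelines = timelines,
      labels = tibble::tibble(patient_id = pids, label = septic),
      dispositions = tibble::as_tibble(dispositions),
      params_echo = params
    ),
    class = "synthetic_cohort"
  )
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("<synthetic_cohort>", length(x$timelines), "patients,",
      sum(x$labels$label), "septic (prevalence",
      sprintf("%.4g)", mean(x$labels$label)), "\n")
  cat("  dispositions:", nrow(x$dispositions),
      " seed:", x$params_echo$seed, "\n")
  invisible(x)
}

#' Calibrate stratum severity to target alert rates
#'
#' Runs a one-dimensional search per stratum over a global severity shift
#' (a common location displacement of every physiologic parameter, in
#' per-parameter scale units, toward or away from derangement) so that the
#' expected patient-level alert probability matches the target rate in each
#' stratum. The search simulates a calibration block once per stratum and
#' re-evaluates it under candidate shifts with common random numbers, so
#' the rate is a monotone step function of the shift and plain bisection
#' converges deterministically.
#'
#' Default targets are the stratum-level alert rates of the reference ED
#' validation cohort: 205/220 among septic patients (sensitivity 0.9318)
#' and 772/49,618 among non-septic patients (false-positive rate 0.0156).
#'
#' @param n_patients Cohort size the returned params will simulate
#'   (minimum 1000).
#' @param seed Integer seed driving both calibration and the returned
#'   params.
#' @param target_septic,target_non_septic Target patient-level alert
#'   probabilities per stratum.
#' @param base Base [cohort_params()] to calibrate.
#' @param n_cal Calibration block sizes per stratum; the non-septic block
#'   is large because its target rate is small.
#' @param delta_range Search interval for the severity shift (scale units).
#' @param max_iter Bisection iterations.
#' @return The calibrated `cohort_params`, with shifted stratum models and
#'   a `calibration` element recording per stratum the shift applied, the
#'   achieved rate on the calibration block, and the target.
#' @export
calibrate_cohort <- function(n_patients, seed,
                             target_septic = 205 / 220,
                             target_non_septic = 772 / 49618,
                             base = cohort_params(n_patients = n_patients,
                                                  seed = seed),
                             n_cal = c(septic = 8000, non_septic = 100000),
                             delta_range = c(-3, 3),
                             max_iter = 12) {
  stopifnot(n_patients >= 1000)
  sub_seeds <- with_seed(seed, sample.int(2147483646L, 2))

  cal_one <- function(model, n, target, sub_seed, septic) {
    block <- with_seed(sub_seed, gen_block(n, model, base, septic))
    rate_at <- function(d) {
      vv <- block_values(block, model, delta = d)
      mean(block_positivity(block, vv, base)$any)
    }
    lo <- delta_range[1]
    hi <- delta_range[2]
    f_lo <- rate_at(lo)
    f_hi <- rate_at(hi)
    if (target < min(f_lo, f_hi) || target > max(f_lo, f_hi)) {
      stop(sprintf(
        paste0("calibration failed for the %s stratum: target %.4g is ",
               "outside the achievable range [%.4g, %.4g] over shifts ",
               "[%g, %g]"),
        if (septic) "septic" else "non-septic",
        target, min(f_lo, f_hi), max(f_lo, f_hi), lo, hi))
    }
    increasing <- f_hi >= f_lo
    for (it in seq_len(max_iter)) {
      mid <- (lo + hi) / 2
      f_mid <- rate_at(mid)
      if ((f_mid < target) == increasing) lo <- mid else hi <- mid
    }
    d <- (lo + hi) / 2
    list(delta = d, achieved = rate_at(d), target = target, n_cal = n)
  }

  cs <- cal_one(base$septic, n_cal[["septic"]], target_septic,
                sub_seeds[1], septic = TRUE)
  cn <- cal_one(base$non_septic, n_cal[["non_septic"]], target_non_septic,
                sub_seeds[2], septic = FALSE)

  base$septic <- shift_model(base$septic, cs$delta)
  base$non_septic <- shift_model(base$non_septic, cn$delta)
  base$calibration <- list(septic = cs, non_septic = cn)
  base
}
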