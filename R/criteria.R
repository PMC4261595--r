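#' Alert criterion thresholds
#'
#' The threshold set defining the screening alert, exposed as a config block
#' so sensitivity analyses can sweep individual cut-points. All comparisons
#' are strict inequalities; values exactly at a threshold do not satisfy the
#' criterion.
#'
#' SIRS criteria: temperature > `temp_high` or < `temp_low` (degrees C);
#' pulse > `pulse_high` (beats/min); respiratory rate > `rr_high`
#' (breaths/min); WBC > `wbc_high` or < `wbc_low` (10^3 cells/uL).
#'
#' Organ-dysfunction criteria: hypotension if SBP < `sbp_low` mm Hg
#' unconditionally, or in the band `[sbp_low, sbp_band)` while an IV fluid
#' bolus is active; hypoxemia if SpO2 < `spo2_low` % unconditionally, or in
#' `[spo2_low, spo2_band)` while supplemental oxygen is active; lactic
#' acidosis if lactate > `lactate_high` mmol/L. The two clauses of each
#' therapy-conditional band partition cleanly: below the unconditional
#' cut-point the criterion is met regardless of therapy.
#'
#' @param temp_high,temp_low,pulse_high,rr_high,wbc_high,wbc_low SIRS
#'   cut-points.
#' @param sbp_low,sbp_band,spo2_low,spo2_band,lactate_high Organ-dysfunction
#'   cut-points.
#' @return Named list of thresholds.
#' @export
#' @examples
#' criteria_thresholds()
criteria_thresholds <- function(temp_high = 38, temp_low = 36,
                                pulse_high = 90, rr_high = 20,
                                wbc_high = 12, wbc_low = 4,
                                sbp_low = 86, sbp_band = 90,
                                spo2_low = 85, spo2_band = 90,
                                lactate_high = 2) {
  stopifnot(temp_low < temp_high, wbc_low < wbc_high,
            sbp_low < sbp_band, spo2_low < spo2_band)
  list(
    temp_high = temp_high, temp_low = temp_low,
    pulse_high = pulse_high, rr_high = rr_high,
    wbc_high = wbc_high, wbc_low = wbc_low,
    sbp_low = sbp_low, sbp_band = sbp_band,
    spo2_low = spo2_low, spo2_band = spo2_band,
    lactate_high = lactate_high
  )
}

#' @keywords internal
#' @noRd
snapshot_value <- function(snapshot, kind) {
  i <- match(kind, snapshot$latest$kind)
  if (is.na(i)) NA_real_ else snapshot$latest$value[i]
}

#' Evaluate the SIRS criteria on a snapshot
#'
#' Judges the four systemic inflammatory response syndrome criteria
#' (temperature, pulse, respiratory rate, white-cell count) against the
#' snapshot's most recent values. A parameter absent from the snapshot is
#' not evaluable and can never satisfy its criterion.
#'
#' @param snapshot A `sepsis_snapshot` from [snapshot_at()].
#' @param thresholds Threshold block from [criteria_thresholds()].
#' @return A `sirs_result`: list with character vectors `met` and
#'   `evaluable` (subsets of temperature, pulse, respiratory_rate, wbc;
#'   `met` is always a subset of `evaluable`).
#' @export
eval_sirs <- function(snapshot, thresholds = criteria_thresholds()) {
  v <- vapply(c("temperature", "pulse", "respiratory_rate", "wbc"),
              function(k) snapshot_value(snapshot, k), numeric(1))
  met <- c(
    temperature = isTRUE(v[["temperature"]] > thresholds$temp_high ||
                           v[["temperature"]] < thresholds$temp_low),
    pulse = isTRUE(v[["pulse"]] > thresholds$pulse_high),
    respiratory_rate = isTRUE(v[["respiratory_rate"]] > thresholds$rr_high),
    wbc = isTRUE(v[["wbc"]] > thresholds$wbc_high ||
                   v[["wbc"]] < thresholds$wbc_low)
  )
  structure(list(met = names(met)[met], evaluable = names(v)[!is.na(v)]),
            class = "sirs_result")
}

#' Evaluate the organ-dysfunction criteria on a snapshot
#'
#' Judges hypotension (therapy-conditional SBP band), hypoxemia
#' (therapy-conditional SpO2 band) and lactic acidosis against the
#' snapshot's most recent values and active-therapy flags.
#'
#' @inheritParams eval_sirs
#' @return An `od_result`: list with character vectors `met` and `evaluable`
#'   (subsets of hypotension, hypoxemia, lactic_acidosis).
#' @export
eval_organ_dysfunction <- function(snapshot, thresholds = criteria_thresholds()) {
  sbp <- snapshot_value(snapshot, "sbp")
  spo2 <- snapshot_value(snapshot, "spo2")
  lac <- snapshot_value(snapshot, "lactate")
  met <- c(
    hypotension = isTRUE(sbp < thresholds$sbp_low) ||
      (isTRUE(sbp >= thresholds$sbp_low & sbp < thresholds$sbp_band) &&
         snapshot$fluids_active),
    hypoxemia = isTRUE(spo2 < thresholds$spo2_low) ||
      (isTRUE(spo2 >= thresholds$spo2_low & spo2 < thresholds$spo2_band) &&
         snapshot$oxygen_active),
    lactic_acidosis = isTRUE(lac > thresholds$lactate_high)
  )
  evaluable <- c("hypotension", "hypoxemia", "lactic_acidosis")[
    !is.na(c(sbp, spo2, lac))]
  structure(list(met = names(met)[met], evaluable = evaluable),
            class = "od_result")
}

#' Combine SIRS and organ-dysfunction results into an alert decision
#'
#' The alert fires when at least two SIRS criteria are met together with at
#' least one organ dysfunction, or when at least two organ dysfunctions are
#' met regardless of SIRS. The rationale reports the first satisfied branch,
#' preferring `sirs_plus_od`.
#'
#' @param sirs A `sirs_result` from [eval_sirs()].
#' @param od An `od_result` from [eval_organ_dysfunction()].
#' @return An `alert_decision`: list with logical `fire`, integer
#'   `sirs_count` and `od_count`, and `rationale` in
#'   `c("sirs_plus_od", "double_od", "none")`.
#' @export
alert_decision <- function(sirs, od) {
  sirs_count <- length(sirs$met)
  od_count <- length(od$met)
  rationale <- if (sirs_count >= 2 && od_count >= 1) {
    "sirs_plus_od"
  } else if (od_count >= 2) {
    "double_od"
  } else {
    "none"
  }
  structure(
    list(fire = rationale != "none", sirs_count = sirs_count,
         od_count = od_count, rationale = rationale),
    class = "alert_decision"
  )
}

# Vectorized criteria evaluation over aligned value vectors. NA means the
# parameter is absent from the snapshot. Returns per-row criterion masks,
# counts and the fire decision. This is the engine's hot path; eval_sirs()
# and eval_organ_dysfunction() are the scalar reference semantics.
#' @keywords internal
#' @noRd
criteria_eval_vec <- function(temperature, pulse, respiratory_rate, wbc,
                              sbp, spo2, lactate,
                              fluids_active, oxygen_active,
                              thresholds = criteria_thresholds()) {
  th <- thresholds
  m_temp <- !is.na(temperature) & (temperature > th$temp_high | temperature < th$temp_low)
  m_pulse <- !is.na(pulse) & pulse > th$pulse_high
  m_rr <- !is.na(respiratory_rate) & respiratory_rate > th$rr_high
  m_wbc <- !is.na(wbc) & (wbc > th$wbc_high | wbc < th$wbc_low)
  m_hypo <- !is.na(sbp) &
    (sbp < th$sbp_low | (sbp < th$sbp_band & fluids_active))
  m_hypox <- !is.na(spo2) &
    (spo2 < th$spo2_low | (spo2 < th$spo2_band & oxygen_active))
  m_lac <- !is.na(lactate) & lactate > th$lactate_high
  sirs_count <- m_temp + m_pulse + m_rr + m_wbc
  od_count <- m_hypo + m_hypox + m_lac
  fire <- (sirs_count >= 2L & od_count >= 1L) | od_count >= 2L
  list(
    sirs = cbind(temperature = m_temp, pulse = m_pulse,
                 respiratory_rate = m_rr, wbc = m_wbc),
    od = cbind(hypotension = m_hypo, hypoxemia = m_hypox,
               lactic_acidosis = m_lac),
    sirs_count = as.integer(sirs_count), od_count = as.integer(od_count),
    fire = fire,
    rationale = ifelse(sirs_count >= 2L & od_count >= 1L, "sirs_plus_od",
                       ifelse(od_count >= 2L, "double_od", "none"))
  )
}
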