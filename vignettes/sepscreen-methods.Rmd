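---
title: "Methods: the sepscreen alert engine, its statistics and its simulator"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the sepscreen alert engine, its statistics and its simulator}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sepscreen)
```

## The screening rule

`sepscreen` replays time-stamped emergency-department (ED) event streams
through a rule-based severe sepsis / septic shock screening alert. The rule
combines the four SIRS (systemic inflammatory response syndrome) criteria
with three organ-dysfunction criteria:

* SIRS: temperature > 38 °C or < 36 °C; pulse > 90 /min; respiratory rate
  > 20 /min; WBC > 12 or < 4 (10³ cells/µL).
* Organ dysfunction: hypotension — SBP < 86 mm Hg unconditionally, or
  SBP in [86, 90) mm Hg while an IV fluid bolus order is active;
  hypoxemia — SpO₂ < 85 % unconditionally, or SpO₂ in [85, 90) % while
  supplemental oxygen is active; lactic acidosis — lactate > 2 mmol/L.
* The alert fires when **two SIRS criteria and one organ dysfunction** are
  met at the same snapshot, **or two organ dysfunctions** are met
  regardless of SIRS.

All comparisons are strict: a value exactly at a cut-point does not satisfy
its criterion. The therapy-conditional bands are read as half-open
intervals so that the two printed clauses of each criterion partition
cleanly — below the unconditional cut-point the criterion holds regardless
of therapy; inside the band it holds only while the therapy order is
active. Whether the two-organ-dysfunction branch should additionally
require SIRS is ambiguous in the source rule layout; this package
implements the layout literally (no SIRS requirement), which is the more
sensitive reading. Mean arterial pressure is deliberately **not** an alert
input: it appears in descriptive severity tables for septic cohorts but
not in the alert rule itself.

All thresholds live in `criteria_thresholds()` so sensitivity analyses can
sweep individual cut-points; the defaults are the rule as printed.

## Snapshot semantics and staleness

The rule is evaluated against a *snapshot*: the most recent value of each
parameter at the evaluation time, with all criteria judged simultaneously
(`snapshot_at()`). A value is usable while its age is strictly less than a
*staleness window*. The source system never states how long a "most
recent" value remains usable, but an unbounded lookback would let a
day-old tachycardia fire alerts indefinitely, so bounded windows are a
design necessity. The defaults are:

* vitals (temperature, pulse, respiratory rate, SBP, SpO₂): **4 h** —
  twice the slowest charting cadence (2 h), so one missed charting round
  does not silence the alert;
* labs (WBC, lactate): **24 h** — ED stat labs are rarely repeated within
  a stay, and a same-day result is still clinically referenced.

Both are configurable (`staleness_windows()`). Therapy intervals are
half-open `[start, end)`; an order with no recorded end is treated as
active until ED departure, because order entry systems record placements
far more reliably than discontinuations. Timestamps are ISO 8601 with
explicit offsets; all internal arithmetic is in seconds. Simultaneous
same-kind observations keep the last record in input order (a corrected
chart entry), with a warning.

## The replay engine and suppression

`run_screening()` evaluates the decision at every *event arrival*
(observation, therapy boundary, code-status change), not on a polling
clock — this matches an event-driven EHR scan and makes replay
deterministic. Several events with one timestamp are applied first and
evaluated once.

After an alert fires, further alerts are suppressed. The suppression
window is anchored at the *alert* time:

* 48 h once a clinician disposition of *suspected sepsis* is recorded;
* 24 h after a *not sepsis* disposition;
* indefinitely when the code status precludes ICU management of sepsis;
* 24 h by default while no disposition has been recorded (the
  conservative reuse of the not-sepsis window; the source protocol is
  silent on the undocumented-disposition case).

The engine fires again at the first qualifying evaluation at or after the
expiry. A disposition always updates the window of the most recent alert
at or before it, and the latest disposition for an alert wins; a
disposition with no preceding alert is a validation error. Because
suppression only ever delays *later* alerts, the first alert per patient —
which drives both the patient-level 2×2 table and the lead-time
statistic — is suppression-invariant.

## Diagnostic accuracy statistics

Patient-level positivity is "at least one alert during the ED stay"
(`patient_alert_status()`), crossed against the physician reference label
into a 2×2 table (`build_confusion()`). `diagnostic_report()` derives
sensitivity, specificity, PPV, NPV, prevalence and both likelihood ratios.

Two proportion-CI methods are provided. `clopper_pearson()` is the exact
beta-quantile interval (guaranteed, conservative coverage; the package
default). `wilson_ci()` is the score interval, by default with the
Newcombe continuity correction — the variant that many
clinical-epidemiology calculators print for diagnostic test
characteristics, and the one that reproduces the published interval bounds
for this alert's validation cohort to their printed precision (the exact
interval gives slightly different bounds, e.g. a sensitivity lower bound
of 89.00 % rather than 88.78 % for 205/220). Keeping both lets users
reproduce published tables while defaulting to the exact method.

Likelihood-ratio intervals use the standard log-normal method:
`exp(log(LR) ± z·se)` with
`se²(log LR+) = 1/tp − 1/(tp+fn) + 1/fp − 1/(fp+tn)` and the analogous
expression for LR−. A zero cell makes the ratio an explicit error — no
silent continuity correction — and inside `diagnostic_report()` any
statistic with an empty margin becomes an explicit undefined marker
(never 0 or 1), with the rest of the report still returned.

Lead time is the signed interval from the *first* alert to ICU referral,
in hours; negative values (referral before alert) are reported as-is.
Quartiles use the linear-interpolation convention (`quantile()` type 7),
the common statistical-package default; published quartiles whose
convention is unknown can therefore only be reproduced approximately.

## The synthetic cohort generator

No patient-level data are published for this kind of alert validation, so
`simulate_cohort()` generates cohorts with the statistical structure the
evaluation assumes:

* **Prevalence** defaults to 0.44 % (≈ 220 septic per 49,838 ED
  arrivals), drawn per patient.
* **Charting cadence**: vitals are charted on arrival and then hourly in
  the critical triage area, two-hourly elsewhere; septic patients are
  triaged to the critical area with probability 0.8, others 0.25.
* **Labs**: one WBC and lactate drawn at arrival, resulted after the
  1 h stat-lab turnaround.
* **Stays**: log-normal, median 6 h (septic) and 4 h (non-septic),
  truncated to [1, 24] h.
* **Physiology**: truncated normal distributions per vital sign and a
  truncated log-normal for lactate, re-drawn independently at every
  charting tick and rounded to charted precision (integer pulse, RR, SBP
  and SpO₂; one decimal for temperature, WBC and lactate), as a nurse
  would enter them. Septic-stratum locations are loosely matched to the
  sign/symptom frequencies reported for ICU-referred septic ED patients
  (~86 % tachycardic, ~89 % tachypneic, ~70 % hypotensive, roughly a
  quarter hyperlactatemic); these are realism targets, not asserted test
  outcomes.
* **Therapy orders**: fluid bolus / oxygen orders with stratum-specific
  probabilities (0.85/0.55 septic, 0.12/0.06 non-septic), starting
  0.25–1.25 h after arrival, open-ended.
* **ICU referral** (septic stratum): a log-normal
  recognition-to-referral delay with median 4 h and sdlog 1.1, anchored at
  the first fired alert when one exists (clinically, referral follows
  recognition) and at arrival otherwise.
* **Dispositions**: alerted patients receive one disposition 5–30 min
  after their first alert — *suspected sepsis* in the septic stratum,
  *not sepsis* otherwise.

A single integer seed fully determines the cohort; the caller's RNG state
is left untouched.

What the generator does **not** emulate: within-patient autocorrelation
and treatment response (each tick is an independent draw), multivariate
dependence between parameters, repeated lab panels, charting gaps and
data-entry errors, and inter-hospital variation. Passing pipeline tests
on these cohorts therefore demonstrates the correctness of the *engine
and statistics*, not the clinical performance of the rule on real
patients.

## Calibration

`calibrate_cohort()` tunes each stratum with a single scalar: a global
*severity shift* that displaces every parameter's location by a common
number of per-parameter scale units toward (positive) or away from
(negative) derangement. The targets are patient-level alert
probabilities — by default 205/220 in the septic stratum and 772/49,618 in
the non-septic stratum, the stratum rates of the alert's reference ED
validation cohort.

The search simulates one calibration block per stratum (8,000 septic and
100,000 non-septic patients by default; the non-septic block is large
because its target rate is ~1.6 %) and re-evaluates the same block under
candidate shifts using common random numbers, so the alert rate is a
monotone step function of the shift and 12 bisection steps converge
deterministically. A target outside the achievable range raises an error
reporting the attainable rates. The achieved in-sample rates and the
shifts are echoed in the returned parameters.

Scoring a calibration block uses a vectorized any-fire computation that
replicates the engine's evaluation semantics exactly (same evaluation
times, staleness, lab availability and therapy flags); its agreement with
`run_screening()` is asserted patient-by-patient in the test suite. A
one-dimensional shift was chosen over multi-parameter fitting
deliberately: it is reproducible, monotone, and cannot overfit the
per-parameter frequencies it is not told about.

## Numerical and degenerate-input choices

* Strict inequalities everywhere; boundary values never satisfy criteria.
* Half-open intervals for therapy activity and suppression expiry (an
  alert may fire exactly at the window's end).
* Observations are validated against per-kind plausibility ranges
  (`plausibility_ranges()`) to reject charting errors such as a
  temperature of 380.
* Empty margins produce undefined markers; `lead_time_summary()` refuses
  empty input; `clopper_pearson()` returns exact 0/1 bounds at x = 0 and
  x = n.
* Event-stream readers collect malformed rows into a line-numbered error
  report and abort only when more than 10 % of rows are malformed.

## Problem sizes used by the test-suite and acceptance runs

Unit and property tests run on single- and few-patient fixtures and on
cohorts of 40–1,500 patients. The end-to-end recovery check calibrates
and simulates 50,000-patient cohorts for three seeds — roughly the size
of the reference four-month ED cohort — and verifies the recovered
sensitivity and false-positive rate within three binomial standard
errors of the stratum targets. Lead-time realism is checked on 1,000
septic patients against the band [3, 5.5] h around the generator's
median-4 h referral delay; the published cohort-level median lead time
(4.02 h) and the clinical-frequency table cannot be reproduced exactly
because per-patient values were never published, so they are covered by
property bounds only.

## Known limitations

* Snapshot alignment means criteria met at *different* times (one now
  stale) never co-fire — the known insensitivity of most-recent-value
  scanning; the staleness windows bound but do not remove it.
* The engine is single-facility: no clock-skew handling, no HL7/FHIR
  ingestion, no paging workflow.
* The generator's independence assumptions make suppressed repeat alerts
  rarer than in real streams with persistent derangement; suppression
  logic is therefore exercised mainly by dedicated property tests, not by
  the synthetic cohorts.
* ROC analysis is out of scope — the alert is a binary rule, not a score.
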