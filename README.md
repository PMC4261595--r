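# sepscreen

Rule-based electronic screening for **severe sepsis and septic shock** in
emergency-department (ED) event streams, with a replay engine,
alert-suppression logic, diagnostic-accuracy statistics, and a seeded
synthetic ED cohort simulator so the whole pipeline can be exercised and
validated without clinical data.

It is aimed at clinical-informatics and quality-improvement teams who want
to prototype, stress-test or re-validate screening-alert logic offline:
feed it per-patient vitals, stat labs (WBC, lactate), therapy orders and
code-status events, and it reproduces what an event-driven EHR scan would
have fired — then scores those alerts against a physician reference
standard.

## The rule

A patient's snapshot (most recent non-stale value per parameter, all
criteria aligned at the same time) fires the alert when

```
(#SIRS >= 2 AND #organ-dysfunction >= 1)  OR  #organ-dysfunction >= 2
```

with SIRS criteria T > 38 °C or < 36 °C, HR > 90/min, RR > 20/min,
WBC > 12 or < 4 ×10³/µL, and organ-dysfunction criteria

* hypotension: SBP < 86 mm Hg, or SBP ∈ [86, 90) with an active IV fluid
  bolus order,
* hypoxemia: SpO₂ < 85 %, or SpO₂ ∈ [85, 90) with active supplemental
  oxygen,
* lactic acidosis: lactate > 2 mmol/L.

After an alert, repeat alerts are suppressed — 48 h if the clinician
disposition is *suspected sepsis*, 24 h if *not sepsis* (also the default
while no disposition is recorded), indefinitely if the code status
precludes ICU care. Accuracy is summarised patient-level: sensitivity,
specificity, PPV, NPV with exact (Clopper–Pearson) or continuity-corrected
Wilson score intervals, likelihood ratios with log-method intervals, and
the signed first-alert-to-ICU-referral lead time (median, quartiles).

## Worked example

```r
library(sepscreen)

# the published validation cohort's patient-level 2x2 counts
cm  <- confusion_matrix(tp = 205, fp = 772, fn = 15, tn = 48846)
diagnostic_report(cm)
#> <diagnostic_report> n = 49838  prevalence = 0.004414  (95% CIs, clopper_pearson)
#>   sensitivity  0.9318 (0.8900-0.9613)
#>   specificity  0.9844 (0.9833-0.9855)
#>   PPV          0.2098 (0.1847-0.2367)
#>   NPV          0.9997 (0.9995-0.9998)
#>   LR+          59.8898 (55.3634-64.7864)
#>   LR-          0.0693 (0.0425-0.1129)
```

A sensitivity of 93 % with a specificity of 98.4 % at 0.44 % prevalence
yields a PPV of only ~21 % — about four false alerts per true septic
patient, the expected cost of screening *every* ED arrival — while the NPV
of 99.97 % makes a silent alert strongly reassuring. The LR+ of ~60 means
a fired alert raises the odds of severe sepsis roughly sixty-fold.

End-to-end on synthetic data:

```r
params <- calibrate_cohort(50000, seed = 1)   # match stratum alert rates
cohort <- simulate_cohort(params)
alerts <- run_screening(cohort$timelines, cohort$dispositions)
status <- patient_alert_status(alerts, cohort$labels$patient_id)
report <- diagnostic_report(build_confusion(status, cohort$labels))
tidy(report)                                   # broom-style tibble
lead_time_summary(lead_times(alerts, cohort$timelines))
autoplot(report)                               # pointrange panel
```

Event streams round-trip through a simple CSV / JSON-lines dialect
(`read_events()` / `write_events()`), configuration through YAML
(`read_config()`), and reports through versioned JSON (`write_report()`).
A thin command-line front end with `simulate` / `screen` / `evaluate` /
`report` subcommands ships in `inst/cli/sepscreen.R`.

## Package layout

| module | contents |
|---|---|
| `R/event-model.R` | timelines, validation, snapshot semantics, staleness |
| `R/criteria.R` | SIRS / organ-dysfunction predicates, combination rule |
| `R/alert-engine.R` | event-driven replay, suppression state, lead times |
| `R/diagnostics.R` | 2×2 table, CIs, likelihood ratios, lead-time summary |
| `R/synth-cohort.R` | seeded cohort generator and severity calibration |
| `R/io.R` | event-stream / labels / alerts / report / config IO |

See `vignettes/sepscreen-methods.Rmd` for the model, the design decisions
and the generator's assumptions and limitations.
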