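test_that("simulation is seed-deterministic and respects prevalence", {
  p <- cohort_params(n_patients = 1000, prevalence = 0.0044, seed = 7)
  co1 <- simulate_cohort(p)
  co2 <- simulate_cohort(p)
  expect_identical(co1$labels, co2$labels)
  expect_identical(co1$dispositions, co2$dispositions)
  expect_identical(co1$timelines, co2$timelines)

  # label count within 4 binomial SEs of the configured prevalence
  k <- sum(co1$labels$label)
  bound <- 4 * sqrt(1000 * 0.0044 * (1 - 0.0044))
  expect_true(abs(k - 1000 * 0.0044) <= bound)

  # prevalence 0 -> all labels negative
  co0 <- simulate_cohort(cohort_params(n_patients = 200, prevalence = 0,
                                       seed = 7))
  expect_false(any(co0$labels$label))
})

test_that("a degenerate all-normal stratum produces zero alerts", {
  normal <- stratum_model(
    temperature = dist_spec("tnorm", 37, 0),
    pulse = dist_spec("tnorm", 80, 0),
    respiratory_rate = dist_spec("tnorm", 16, 0),
    wbc = dist_spec("tnorm", 8, 0),
    sbp = dist_spec("tnorm", 120, 0),
    spo2 = dist_spec("tnorm", 98, 0),
    lactate = dist_spec("tlnorm", log(1), 0),
    fluids_prob = 0.5, oxygen_prob = 0.5
  )
  co <- simulate_cohort(cohort_params(n_patients = 150, prevalence = 0,
                                      seed = 3, non_septic = normal))
  al <- run_screening(co$timelines, co$dispositions)
  expect_equal(nrow(al), 0)
})

test_that("generated timelines satisfy the event-model invariants", {
  co <- simulate_cohort(cohort_params(n_patients = 60, prevalence = 0.3,
                                      seed = 9))
  for (tl in co$timelines) {
    expect_true(all(tl$observations$time >= tl$ed_arrival))
    expect_true(all(tl$observations$time <= tl$ed_departure))
    ord <- order(tl$observations$time,
                 match(tl$observations$kind, parameter_kinds()))
    expect_equal(ord, seq_len(nrow(tl$observations)))
    if (!is.null(tl$icu_referral_time)) {
      expect_gte(as.numeric(tl$icu_referral_time),
                 as.numeric(tl$ed_arrival))
    }
    # round-trip through the event dialect and the validating builder
    rebuilt <- build_timeline(timeline_events(tl))
    expect_equal(rebuilt$observations$value, tl$observations$value)
    expect_equal(rebuilt$therapies$kind, tl$therapies$kind)
  }
  # charting cadence: consecutive vitals ticks 1 h apart in the critical
  # area, 2 h elsewhere; labs resulted 1 h after arrival
  for (tl in co$timelines[1:10]) {
    vit <- tl$observations[tl$observations$kind == "pulse", ]
    if (nrow(vit) >= 2) {
      cad <- unique(diff(as.numeric(vit$time)))
      expect_equal(cad, if (tl$triage_area == "critical") 3600 else 7200)
    }
    lab <- tl$observations[tl$observations$kind == "lactate", ]
    expect_equal(as.numeric(lab$time[1]) - as.numeric(tl$ed_arrival),
                 min(3600, as.numeric(tl$ed_departure) -
                       as.numeric(tl$ed_arrival)))
  }
})

test_that("fast-path positivity agrees with the replay engine", {
  # the calibration search scores patients with a vectorized any-fire
  # computation; it must agree exactly with run_screening on the same
  # generated block
  p <- cohort_params(n_patients = 500, prevalence = 0.4, seed = 31)
  co <- simulate_cohort(p)
  al <- run_screening(co$timelines)
  st <- patient_alert_status(al, co$labels$patient_id)

  out <- sepscreen:::with_seed(p$seed, {
    septic <- stats::runif(p$n_patients) < p$prevalence
    bs <- sepscreen:::gen_block(sum(septic), p$septic, p, TRUE)
    bn <- sepscreen:::gen_block(sum(!septic), p$non_septic, p, FALSE)
    list(septic = septic, bs = bs, bn = bn)
  })
  pos <- logical(p$n_patients)
  first <- rep(Inf, p$n_patients)
  for (s in c(TRUE, FALSE)) {
    b <- if (s) out$bs else out$bn
    m <- if (s) p$septic else p$non_septic
    pp <- sepscreen:::block_positivity(b, sepscreen:::block_values(b, m), p)
    pos[out$septic == s] <- pp$any
    first[out$septic == s] <- pp$first
  }
  expect_identical(unname(pos), st$alert)
  fa <- tapply(as.numeric(al$time), al$patient_id, min)
  ids <- st$patient_id[st$alert]
  expect_equal(as.numeric(fa[ids]),
               first[match(ids, co$labels$patient_id)])
})

test_that("calibration is deterministic and hits its targets in-sample", {
  p1 <- calibrate_cohort(1000, seed = 5,
                         n_cal = c(septic = 1500, non_septic = 4000))
  p2 <- calibrate_cohort(1000, seed = 5,
                         n_cal = c(septic = 1500, non_septic = 4000))
  expect_identical(p1$septic, p2$septic)
  expect_identical(p1$calibration, p2$calibration)
  # achieved in-sample rates near targets (binomial noise of the blocks)
  cs <- p1$calibration$septic
  expect_lt(abs(cs$achieved - cs$target),
            4 * sqrt(cs$target * (1 - cs$target) / cs$n_cal) + 1 / cs$n_cal)
  cn <- p1$calibration$non_septic
  expect_lt(abs(cn$achieved - cn$target),
            4 * sqrt(cn$target * (1 - cn$target) / cn$n_cal) + 1 / cn$n_cal)
  # an unreachable target errors with the achievable range
  expect_error(
    calibrate_cohort(1000, seed = 5, target_non_septic = 0.999999,
                     n_cal = c(septic = 1500, non_septic = 2000)),
    "achievable range")
})

test_that("dispositions follow first alerts with the configured categories", {
  co <- simulate_cohort(cohort_params(n_patients = 400, prevalence = 0.25,
                                      seed = 13))
  al <- run_screening(co$timelines, co$dispositions)
  st <- patient_alert_status(al, co$labels$patient_id)
  # a disposition exists exactly for alerted patients
  expect_setequal(co$dispositions$patient_id, st$patient_id[st$alert])
  lab <- co$labels$label[match(co$dispositions$patient_id,
                               co$labels$patient_id)]
  expect_equal(unique(co$dispositions$category[lab]), "suspected_sepsis")
  expect_equal(unique(co$dispositions$category[!lab]), "not_sepsis")
  # disposition never precedes the patient's first alert
  fa <- tapply(as.numeric(al$time), al$patient_id, min)
  expect_true(all(as.numeric(co$dispositions$time) >=
                    unname(fa[co$dispositions$patient_id])))
})
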