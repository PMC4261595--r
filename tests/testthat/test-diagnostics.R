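table1 <- confusion_matrix(tp = 205, fp = 772, fn = 15, tn = 48846)

test_that("build_confusion counts agree with a brute-force recount", {
  # degenerate all-negative case
  st <- tibble::tibble(patient_id = letters[1:5], alert = FALSE)
  lb <- tibble::tibble(patient_id = letters[1:5], label = FALSE)
  cm <- build_confusion(st, lb)
  expect_equal(c(cm$tp, cm$fp, cm$fn, cm$tn), c(0, 0, 0, 5))

  # random 200-patient assignment vs nested-loop recount
  set.seed(707)
  ids <- sprintf("pt%03d", 1:200)
  st <- tibble::tibble(patient_id = sample(ids), alert = runif(200) < 0.3)
  lb <- tibble::tibble(patient_id = sample(ids), label = runif(200) < 0.1)
  cm <- build_confusion(st, lb)
  counts <- c(tp = 0, fp = 0, fn = 0, tn = 0)
  for (id in ids) {
    a <- st$alert[st$patient_id == id]
    l <- lb$label[lb$patient_id == id]
    cell <- if (a && l) "tp" else if (a) "fp" else if (l) "fn" else "tn"
    counts[cell] <- counts[cell] + 1
  }
  expect_equal(c(cm$tp, cm$fp, cm$fn, cm$tn), unname(counts))
  expect_equal(cm$n, 200)

  # relabeling invariance: permuting ids changes nothing
  perm <- sample.int(200)
  st2 <- st[perm, ]
  cm2 <- build_confusion(st2, lb)
  expect_equal(cm2, cm)

  # mismatched id sets are reported with the symmetric difference
  expect_error(build_confusion(st[-1, ], lb), st$patient_id[1])
})

test_that("clopper_pearson matches tail inversion and handles boundaries", {
  # (7, 19): compare against bisection on the binomial tail probabilities
  invert_tail <- function(x, n, alpha) {
    lo <- stats::uniroot(function(p) stats::pbinom(x - 1, n, p,
                                                   lower.tail = FALSE) -
                           alpha / 2, c(1e-12, 1 - 1e-12), tol = 1e-12)$root
    hi <- stats::uniroot(function(p) stats::pbinom(x, n, p) - alpha / 2,
                         c(1e-12, 1 - 1e-12), tol = 1e-12)$root
    c(lo, hi)
  }
  ci <- clopper_pearson(7, 19, 0.05)
  oracle <- invert_tail(7, 19, 0.05)
  expect_equal(ci$lower, oracle[1], tolerance = 1e-8)
  expect_equal(ci$upper, oracle[2], tolerance = 1e-8)

  # independent cross-check against the exact binomial test
  bt <- stats::binom.test(205, 220)$conf.int
  ci <- clopper_pearson(205, 220)
  expect_equal(c(ci$lower, ci$upper), as.numeric(bt), tolerance = 1e-12)
  expect_equal(ci$estimate, 205 / 220)

  # boundary counts
  expect_equal(clopper_pearson(0, 10)$lower, 0)
  expect_equal(clopper_pearson(10, 10)$upper, 1)
  expect_error(clopper_pearson(11, 10), "successes")
  expect_error(clopper_pearson(5, 10, alpha = 1.2), "alpha")
})

test_that("exact intervals achieve at least nominal coverage", {
  # 2,000 binomial draws at p = 0.93, n = 220; conservative coverage
  set.seed(808)
  p <- 0.93
  x <- stats::rbinom(2000, 220, p)
  covered <- vapply(x, function(xi) {
    ci <- clopper_pearson(xi, 220)
    ci$lower <= p && p <= ci$upper
  }, logical(1))
  expect_gte(mean(covered), 0.95)
})

test_that("likelihood ratios use the log-method standard errors", {
  lr <- likelihood_ratios(table1)
  sens <- 205 / 220
  spec <- 48846 / 49618
  expect_equal(lr$lr_pos$estimate, sens / (1 - spec), tolerance = 1e-12)
  expect_equal(lr$lr_neg$estimate, (1 - sens) / spec, tolerance = 1e-12)
  z <- stats::qnorm(0.975)
  se_pos <- sqrt(1 / 205 - 1 / 220 + 1 / 772 - 1 / 49618)
  expect_equal(lr$lr_pos$lower, lr$lr_pos$estimate * exp(-z * se_pos),
               tolerance = 1e-12)
  expect_equal(lr$lr_pos$upper, lr$lr_pos$estimate * exp(z * se_pos),
               tolerance = 1e-12)
  # a perfect test has an undefined LR+ (no silent continuity correction)
  expect_error(likelihood_ratios(confusion_matrix(10, 0, 2, 50)),
               "LR\\+ undefined")
})

test_that("diagnostic_report matches direct formulas on random tables", {
  set.seed(909)
  for (i in 1:500) {
    cells <- stats::rpois(4, lambda = sample(c(3, 10, 40), 1)) + 1L
    cm <- confusion_matrix(cells[1], cells[2], cells[3], cells[4])
    rep <- diagnostic_report(cm)
    tp <- cells[1]; fp <- cells[2]; fn <- cells[3]; tn <- cells[4]
    expect_equal(rep$sensitivity$estimate, tp / (tp + fn))
    expect_equal(rep$specificity$estimate, tn / (fp + tn))
    expect_equal(rep$ppv$estimate, tp / (tp + fp))
    expect_equal(rep$npv$estimate, tn / (fn + tn))
    expect_equal(rep$prevalence, (tp + fn) / sum(cells))
    # internal identities to numerical tolerance
    expect_equal(rep$lr_pos$estimate * (1 - rep$specificity$estimate),
                 rep$sensitivity$estimate, tolerance = 1e-12)
    expect_equal(rep$lr_neg$estimate * rep$specificity$estimate,
                 1 - rep$sensitivity$estimate, tolerance = 1e-12)
  }
})

test_that("symmetric tables give equal sensitivity and specificity", {
  cm <- confusion_matrix(tp = 30, fp = 7, fn = 7, tn = 30)
  rep <- diagnostic_report(cm)
  expect_equal(rep$sensitivity$estimate, rep$specificity$estimate)
})

test_that("degenerate margins yield undefined markers, not crashes", {
  # prevalence zero: sensitivity undefined
  cm <- confusion_matrix(tp = 0, fp = 5, fn = 0, tn = 95)
  rep <- diagnostic_report(cm)
  expect_s3_class(rep$sensitivity, "undefined_statistic")
  expect_true(is.na(rep$sensitivity$estimate))
  expect_s3_class(rep$lr_pos, "undefined_statistic")
  # specificity still defined
  expect_equal(rep$specificity$estimate, 0.95)
  td <- tidy(rep)
  expect_true(any(grepl("undefined", td$method)))
})

test_that("lead-time summary follows the linear-interpolation convention", {
  s <- lead_time_summary(4.02)
  expect_equal(c(s$q1, s$median, s$q3), c(4.02, 4.02, 4.02))
  s <- lead_time_summary(c(1, 2, 3, 4))
  expect_equal(s$median, 2.5)
  expect_equal(s$q1, 1.75)
  # 200 log-normal draws vs sort-and-interpolate oracle
  set.seed(1010)
  x <- stats::rlnorm(200, log(4), 0.9)
  s <- lead_time_summary(x)
  interp <- function(p) {
    xs <- sort(x)
    h <- (length(xs) - 1) * p + 1
    lo <- floor(h)
    xs[lo] + (h - lo) * (xs[lo + 1] - xs[lo])
  }
  expect_equal(s$median, interp(0.5), tolerance = 1e-12)
  expect_equal(s$q1, interp(0.25), tolerance = 1e-12)
  expect_equal(s$q3, interp(0.75), tolerance = 1e-12)
  expect_true(s$q1 <= s$median && s$median <= s$q3)
  expect_error(lead_time_summary(numeric()), "non-empty")
})

test_that("tidy and glance views expose the report", {
  rep <- diagnostic_report(table1)
  td <- tidy(rep)
  expect_equal(nrow(td), 6)
  expect_true(all(td$conf.low <= td$estimate & td$estimate <= td$conf.high))
  g <- glance(rep)
  expect_equal(g$tp, 205)
  expect_equal(g$n, 49838)
  expect_equal(tidy(table1)$count, c(205, 772, 15, 48846))
})
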