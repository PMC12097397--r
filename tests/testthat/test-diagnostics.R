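test_that("confusion matrices count stays against the morbidity label", {
  a <- make_assessments(c("red", "none"), morbidity = c(TRUE, FALSE))
  m <- confusion_matrix(a, "meows_red")
  expect_equal(unclass(m), c(tp = 1L, fp = 0L, fn = 0L, tn = 1L))

  a <- make_assessments(rep("none", 6), morbidity = rep(c(TRUE, FALSE), 3))
  m <- confusion_matrix(a, "meows_red")
  expect_equal(m[["tp"]] + m[["fp"]], 0L)
  expect_equal(sum(m), 6L)
  expect_error(new_confusion_matrix(-1, 0, 0, 1), "non-negative")
})

test_that("Clopper-Pearson matches binom.test and behaves at the edges", {
  for (n in c(5, 13, 24, 699)) {
    for (x in unique(round(seq(0, n, length.out = 7)))) {
      got <- clopper_pearson(x, n)
      ref <- stats::binom.test(x, n)$conf.int
      expect_equal(got$lo, ref[1], tolerance = 1e-12)
      expect_equal(got$hi, ref[2], tolerance = 1e-12)
      expect_equal(got$point, x / n)
      expect_true(got$lo <= got$point && got$point <= got$hi)
    }
  }
  expect_equal(clopper_pearson(0, 10)$lo, 0)
  expect_equal(clopper_pearson(10, 10)$hi, 1)
  expect_error(clopper_pearson(3, 0), "n must be")

  # bounds are monotone in x at fixed n
  n <- 24
  los <- vapply(0:n, function(x) clopper_pearson(x, n)$lo, 0)
  his <- vapply(0:n, function(x) clopper_pearson(x, n)$hi, 0)
  expect_true(all(diff(los) > 0))
  expect_true(all(diff(his) > 0))
})

test_that("Clopper-Pearson coverage is at least nominal (exhaustive, n <= 30)", {
  # brute-force binomial-tail oracle: for each true p, total probability of
  # the x whose interval covers p
  for (n in c(5, 12, 30)) {
    intervals <- t(vapply(0:n, function(x) {
      ci <- clopper_pearson(x, n)
      c(ci$lo, ci$hi)
    }, numeric(2)))
    for (p in seq(0.05, 0.95, by = 0.05)) {
      covers <- intervals[, 1] <= p & p <= intervals[, 2]
      coverage <- sum(stats::dbinom(0:n, n, p)[covers])
      expect_gte(coverage, 0.95)
    }
  }
})

test_that("sensitivity and specificity reproduce the reconstructed counts", {
  ss <- sens_spec(new_confusion_matrix(22, 265, 2, 434))
  expect_equal(ss$sensitivity$point, 22 / 24)
  ss <- sens_spec(new_confusion_matrix(14, 6, 10, 693))
  expect_equal(ss$specificity$point, 693 / 699)
  ss <- sens_spec(new_confusion_matrix(1, 0, 0, 1))
  expect_equal(ss$sensitivity$point, 1)
  expect_equal(ss$specificity$point, 1)
  expect_error(sens_spec(new_confusion_matrix(0, 3, 0, 4)), "undefined")
})

test_that("predictive values use the prevalence-form logit variance", {
  pv <- predictive_values(new_confusion_matrix(14, 6, 10, 693))
  expect_equal(pv$ppv$point, 0.70)
  # frozen from the closed-form logit variance at these counts
  expect_equal(pv$ppv$lo, 0.4952, tolerance = 1e-3)
  expect_equal(pv$ppv$hi, 0.8468, tolerance = 1e-3)

  pv <- predictive_values(new_confusion_matrix(2, 6, 22, 693))
  expect_equal(pv$ppv$point, 0.25)

  pv <- predictive_values(new_confusion_matrix(1, 0, 0, 1))
  expect_true(pv$ppv$degenerate)
  expect_equal(pv$ppv$point, 1)
})

test_that("likelihood ratios use the log-method standard errors", {
  lr <- likelihood_ratios(new_confusion_matrix(14, 6, 10, 693))
  expect_equal(lr$plr$point, (14 / 24) / (6 / 699), tolerance = 1e-12)
  se_ln <- sqrt(1 / 14 - 1 / 24 + 1 / 6 - 1 / 699)
  expect_equal(lr$plr$lo, lr$plr$point * exp(-1.959964 * se_ln),
               tolerance = 1e-4)

  # an uninformative test has PLR exactly 1
  lr <- likelihood_ratios(new_confusion_matrix(10, 10, 10, 10))
  expect_equal(lr$plr$point, 1)
  expect_equal(lr$nlr$point, 1)

  lr <- likelihood_ratios(new_confusion_matrix(5, 0, 2, 10))
  expect_true(lr$plr$degenerate)
  expect_true(is.infinite(lr$plr$point))
  lr <- likelihood_ratios(new_confusion_matrix(5, 2, 0, 10))
  expect_true(lr$nlr$degenerate)
  expect_equal(lr$nlr$point, 0)
  expect_equal(lr$nlr$lo, 0)
})

test_that("Bayes identity links predictive values to se/sp and prevalence", {
  set.seed(23)
  for (i in 1:40) {
    m <- new_confusion_matrix(sample(1:50, 1), sample(1:50, 1),
                              sample(1:50, 1), sample(1:50, 1))
    se <- m[["tp"]] / (m[["tp"]] + m[["fn"]])
    sp <- m[["tn"]] / (m[["fp"]] + m[["tn"]])
    prev <- (m[["tp"]] + m[["fn"]]) / sum(m)
    pv <- predictive_values(m)
    expect_equal(pv$ppv$point,
                 se * prev / (se * prev + (1 - sp) * (1 - prev)),
                 tolerance = 1e-12)
    expect_equal(pv$npv$point,
                 sp * (1 - prev) / (sp * (1 - prev) + (1 - se) * prev),
                 tolerance = 1e-12)
    # an informative test (positive Youden index) has PLR > 1 and NLR < 1
    lr <- likelihood_ratios(m)
    youden <- se + sp - 1
    if (youden != 0) {
      expect_equal(lr$plr$point > 1, youden > 0)
      expect_equal(lr$nlr$point < 1, youden > 0)
    }
  }
})

test_that("evaluate_cohort returns six reports plus prevalence", {
  a <- make_assessments(
    rep(c("red", "yellow", "green", "none"), times = c(5, 10, 10, 25)),
    morbidity = rep(c(TRUE, FALSE), times = c(4, 46)),
    worst_ews = rep(c("emergency", "inform", "none"), times = c(3, 10, 37)))
  ev <- evaluate_cohort(a)
  expect_named(ev$reports, names(test_definitions()))
  expect_equal(ev$prevalence$point, 4 / 50)
  tps <- vapply(ev$reports[c("meows_red", "meows_yellow", "meows_green")],
                function(r) r$matrix[["tp"]], integer(1))
  none_tp <- sum(a$morbidity & a$worst_meows == "none")
  expect_equal(sum(tps) + none_tp, sum(a$morbidity))

  expect_error(evaluate_cohort(make_assessments(c("red", "none"),
                                                c(FALSE, FALSE))),
               "degenerate")
})

test_that("the four exclusive strata partition both outcome groups", {
  cohort <- generate_cohort(cohort_config(n_women = 400), seed = 31)
  a <- assess_cohort(cohort)
  ev <- evaluate_cohort(a)
  strata <- ev$reports[c("meows_red", "meows_yellow", "meows_green")]
  tp_sum <- sum(vapply(strata, function(r) r$matrix[["tp"]], integer(1))) +
    sum(a$morbidity & a$worst_meows == "none")
  fp_sum <- sum(vapply(strata, function(r) r$matrix[["fp"]], integer(1))) +
    sum(!a$morbidity & a$worst_meows == "none")
  expect_equal(tp_sum, sum(a$morbidity))
  expect_equal(fp_sum, sum(!a$morbidity))
})

test_that("report formatting matches the published conventions", {
  expect_equal(ewstriage:::fmt_percent(0.9167), "92%")
  expect_equal(ewstriage:::fmt_percent(0.00676), "0.7%")
  expect_equal(ewstriage:::fmt_percent(0.625), "63%")   # half-up
  expect_equal(ewstriage:::fmt_ratio(0.0356), "0.04")
  expect_equal(ewstriage:::fmt_ratio(67.958), "68.0")
  expect_equal(ewstriage:::fmt_ratio(0.9246), "0.9")
  expect_equal(ewstriage:::fmt_percent_1dp(24 / 723), "3.3%")

  rep <- diagnostic_report(new_confusion_matrix(14, 6, 10, 693))
  f <- format_report(rep)
  expect_equal(unname(f["plr"]), "68.0 (28.6-161.5)")
  expect_equal(unname(f["sensitivity"]), "58% (37%-78%)")
})
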