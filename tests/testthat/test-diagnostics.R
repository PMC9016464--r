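test_that("confusion tallies match an exhaustive toy count", {
  cls <- factor(c("high", "high", "low", "indeterminate", "low", "high",
                  "indeterminate", "low"),
                levels = c("low", "indeterminate", "high"))
  d <- c(TRUE, FALSE, FALSE, TRUE, TRUE, TRUE, FALSE, FALSE)
  cs <- confusion(cls, d)
  expect_equal(cs$tp, 2); expect_equal(cs$fp, 1)
  expect_equal(cs$tn, 2); expect_equal(cs$fn, 1)
  expect_equal(cs$indeterminate_pos, 1)
  expect_equal(cs$indeterminate_neg, 1)
  # conservation against random vectors
  withr::with_seed(2, {
    for (k in 1:20) {
      n <- sample(5:60, 1)
      cls <- factor(sample(c("low", "indeterminate", "high"), n, TRUE),
                    levels = c("low", "indeterminate", "high"))
      d <- sample(c(TRUE, FALSE), n, TRUE)
      cs <- confusion(cls, d)
      expect_equal(sum(unlist(unclass(cs))), n)
      expect_equal(cs$tp, sum(cls == "high" & d))
      expect_equal(cs$fn, sum(cls == "low" & d))
    }
  })
  expect_error(confusion(cls, d[-1]), "equal length")
})

test_that("all-high classifications of all-positive subjects are all tp", {
  cs <- confusion(rep(TRUE, 7), rep(TRUE, 7))
  expect_equal(cs$tp, 7)
  expect_equal(cs$fp + cs$tn + cs$fn, 0)
})

test_that("metrics reproduce the printed rule-out worked example", {
  # printed stratum counts for the nonobese band: 303 below the rule-out
  # cutoff (286 controls / 17 cases), 236 indeterminate (175/61),
  # 61 above the rule-in cutoff (24/37); rule-out screen positive = at or
  # above the rule-out cutoff
  cs <- confusion_counts(tp = 61 + 37, fp = 175 + 24, tn = 286, fn = 17)
  m <- dx_metrics(cs, lr_mode = "integer_percent")
  expect_equal(round_half_up(100 * m$se), 85)
  expect_equal(round_half_up(100 * m$sp), 59)
  expect_equal(round_half_up(100 * m$ppv), 33)
  expect_equal(round_half_up(100 * m$npv), 94)
  expect_equal(round(m$lr_pos, 2), 2.07)
  expect_equal(round(m$lr_neg, 2), 0.25)
})

test_that("a perfect classifier attains unit metrics and NND of 1", {
  m <- dx_metrics(confusion_counts(tp = 20, fp = 0, tn = 30, fn = 0))
  expect_equal(m$se, 1); expect_equal(m$sp, 1)
  expect_equal(m$ppv, 1); expect_equal(m$npv, 1)
  expect_equal(m$nnd, 1)
})

test_that("NND is the inverse Youden index on integer-percent inputs", {
  # Se 79%, Sp 87% -> Youden 0.66 -> NND 1.5 at 1 d.p.
  cs <- confusion_counts(tp = 79, fn = 21, tn = 87, fp = 13)
  m <- dx_metrics(cs, lr_mode = "integer_percent")
  expect_equal(round(m$nnd, 1), 1.5)
  # undefined when Se + Sp <= 1
  m2 <- dx_metrics(confusion_counts(tp = 10, fn = 90, tn = 50, fp = 50))
  expect_true(is.na(m2$nnd))
})

test_that("zero denominators give undefined metrics, not NaN", {
  m <- dx_metrics(confusion_counts(tp = 0, fp = 0, tn = 10, fn = 5))
  expect_true(is.na(m$ppv))
  expect_false(is.nan(m$se))
})

test_that("Clopper-Pearson intervals match binom.test", {
  for (x in c(0, 3, 17, 20)) {
    ref <- stats::binom.test(x, 20)$conf.int
    got <- fibroscores:::clopper_pearson(x, 20)
    expect_equal(unname(got), as.numeric(ref), tolerance = 1e-8)
  }
})

test_that("dual-cutoff performance evaluates both cutoffs and the zone", {
  df <- toy_scores()
  rule <- cutoff_rule("toy", lower = 0.5, upper = 1.0)
  perf <- dual_cutoff_performance(df$score, df$condition, rule)
  # hand trace: scores >= 0.5 are positive for the lower cutoff
  pos_lo <- df$score >= 0.5
  expect_equal(perf$se[perf$cutoff == "lower"],
               sum(pos_lo & df$condition) / sum(df$condition))
  expect_equal(perf$sp[perf$cutoff == "lower"],
               sum(!pos_lo & !df$condition) / sum(!df$condition))
  pos_hi <- df$score > 1.0
  expect_equal(perf$se[perf$cutoff == "upper"],
               sum(pos_hi & df$condition) / sum(df$condition))
  expect_equal(perf$indeterminate_fraction,
               rep(mean(df$score >= 0.5 & df$score <= 1.0), 2))
  # a perfectly separating score with cutoffs straddling the gap
  sep <- c(rep(1, 10), rep(5, 10))
  lab <- rep(c(FALSE, TRUE), each = 10)
  p2 <- dual_cutoff_performance(sep, lab, cutoff_rule("s", 2, 3))
  expect_equal(p2$se, c(1, 1))
  expect_equal(p2$sp, c(1, 1))
  expect_equal(p2$indeterminate_fraction, c(0, 0))
  expect_error(dual_cutoff_performance(sep, rep(TRUE, 20),
                                       cutoff_rule("s", 2, 3)),
               "both condition")
})

test_that("combined metrics count indeterminates as correct", {
  df <- toy_scores()
  rule <- cutoff_rule("toy", lower = 0.5, upper = 1.0)
  m <- combined_dual_metrics(df$score, df$condition, rule)
  # brute-force application of the convention
  cls <- classify_dual(df$score, rule)
  tp <- sum(cls == "high" & df$condition) +
    sum(cls == "indeterminate" & df$condition)
  fn <- sum(cls == "low" & df$condition)
  tn <- sum(cls == "low" & !df$condition) +
    sum(cls == "indeterminate" & !df$condition)
  fp <- sum(cls == "high" & !df$condition)
  expect_equal(m$se, tp / (tp + fn))
  expect_equal(m$sp, tn / (tn + fp))
  # all-indeterminate edge: the convention yields perfect metrics
  m2 <- combined_dual_metrics(rep(0.7, 10),
                              rep(c(TRUE, FALSE), 5),
                              cutoff_rule("t", 0, 1))
  expect_equal(m2$se, 1); expect_equal(m2$sp, 1)
  # no indeterminates: identical to the single-cutoff metrics
  sep <- c(1, 1, 5, 5); lab <- c(FALSE, FALSE, TRUE, TRUE)
  m3 <- combined_dual_metrics(sep, lab, cutoff_rule("t", 3, 3))
  m4 <- dx_metrics(confusion(sep >= 3, lab))
  expect_equal(m3$se, m4$se); expect_equal(m3$sp, m4$sp)
})

test_that("predictive values project to a target prevalence by Bayes", {
  pv <- predictive_values_at_prevalence(0.85, 0.95, 0.15)
  expect_equal(pv$ppv, 0.750)
  expect_equal(round(pv$npv, 3), 0.973)
  expect_equal(pv$accuracy, 0.935)
  z <- predictive_values_at_prevalence(0.8, 0.9, 0)
  expect_equal(z$ppv, 0); expect_equal(z$npv, 1)
  one <- predictive_values_at_prevalence(1, 1, 0.3)
  expect_equal(unlist(one), c(ppv = 1, npv = 1, accuracy = 1))
})
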