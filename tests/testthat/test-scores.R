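test_that("FIB-4 matches its closed form and guards its domain", {
  expect_equal(fib4(50, 40, 40, 250), 50 * 40 / (250 * sqrt(40)))
  expect_equal(round(fib4(50, 40, 40, 250), 4), 1.2649)
  expect_equal(fib4(50, 0, 40, 250), 0)
  expect_error(fib4(50, 40, 0, 250), class = "fibroscores_domain_error")
  expect_error(fib4(50, 40, 40, 0), class = "fibroscores_domain_error")
  expect_true(is.na(fib4(NA, 40, 40, 250)))
})

test_that("NFS matches its linear form, including exact BMI linearity", {
  expect_equal(round(nfs(50, 30, 1, 40, 40, 250, 4.0), 3), -0.775)
  base <- nfs(50, 30, 1, 40, 40, 250, 4.0)
  expect_equal(nfs(50, 40, 1, 40, 40, 250, 4.0) - base, 0.94)
  expect_error(nfs(50, 30, 1, 40, 0, 250, 4.0),
               class = "fibroscores_domain_error")
})

test_that("APRI and BARD follow their published definitions", {
  expect_equal(apri(80, 200, ast_uln = 40), 1.0)
  expect_equal(apri(40, 100, ast_uln = 40), 1.0)
  expect_equal(apri(0, 200), 0)
  expect_error(apri(40, 0), class = "fibroscores_domain_error")
  expect_error(apri(40, 200, ast_uln = 0),
               class = "fibroscores_domain_error")

  expect_equal(bard(29, 36, 40, TRUE), 4L)  # 1 + 2 + 1
  expect_equal(bard(25, 20, 40, FALSE), 0L)
  expect_equal(bard(40, 20, 40, FALSE), 1L) # BMI point only
  # exactly three breakpoints
  expect_equal(bard(27.99, 20, 40, FALSE), 0L)
  expect_equal(bard(28, 20, 40, FALSE), 1L)
  expect_equal(bard(25, 32, 40, FALSE), 2L) # ratio 0.8 boundary inclusive
  expect_equal(bard(25, 31.9, 40, FALSE), 0L)
})

test_that("logistic scores stay in (0,1) and ADAPT increases in PRO-C3", {
  co <- score_coefficients()
  spec <- cohort_preset("overweight_obese", n = 1000, seed = 3)
  coh <- generate_cohort(spec)
  h <- hfs(coh$age, coh$sex == "male", coh$ast, coh$albumin,
           compute_homa_ir(coh$glucose_fasting, coh$insulin_fasting),
           coh$diabetes, coh$platelets, co)
  m <- mack3(compute_homa_ir(coh$glucose_fasting, coh$insulin_fasting),
             coh$ast, coh$ck18_m30, co)
  expect_true(all(h > 0 & h < 1, na.rm = TRUE))
  expect_true(all(m > 0 & m < 1, na.rm = TRUE))
  a <- adapt(55, c(5, 10, 20, 40), 250, FALSE, co)
  expect_true(all(diff(a) > 0))
  expect_true(all(a > 0))
  # finite-difference monotonicity of ADAPT in PRO-C3 at random points
  withr::with_seed(9, {
    for (k in 1:20) {
      age <- runif(1, 20, 75); plt <- runif(1, 80, 400)
      pc <- runif(1, 5, 40)
      expect_gt(adapt(age, pc + 1, plt, FALSE, co),
                adapt(age, pc, plt, FALSE, co))
    }
  })
})

test_that("monotonicity of the simple scores holds under finite differences", {
  withr::with_seed(4, {
    for (k in 1:25) {
      age <- runif(1, 20, 75); ast <- runif(1, 10, 200)
      alt <- runif(1, 10, 200); plt <- runif(1, 60, 450)
      bmi <- runif(1, 20, 55); alb <- runif(1, 3, 5)
      expect_gt(fib4(age + 1, ast, alt, plt), fib4(age, ast, alt, plt))
      expect_gt(fib4(age, ast + 1, alt, plt), fib4(age, ast, alt, plt))
      expect_lt(fib4(age, ast, alt + 1, plt), fib4(age, ast, alt, plt))
      expect_lt(fib4(age, ast, alt, plt + 1), fib4(age, ast, alt, plt))
      expect_gt(apri(ast + 1, plt), apri(ast, plt))
      expect_lt(apri(ast, plt + 1), apri(ast, plt))
      expect_gt(nfs(age + 1, bmi, 1, ast, alt, plt, alb),
                nfs(age, bmi, 1, ast, alt, plt, alb))
      expect_gt(nfs(age, bmi + 1, 1, ast, alt, plt, alb),
                nfs(age, bmi, 1, ast, alt, plt, alb))
      expect_lt(nfs(age, bmi, 1, ast, alt, plt + 1, alb),
                nfs(age, bmi, 1, ast, alt, plt, alb))
      expect_lt(nfs(age, bmi, 1, ast, alt, plt, alb + 0.1),
                nfs(age, bmi, 1, ast, alt, plt, alb))
    }
  })
})

test_that("score_panel propagates missing inputs and is pure", {
  coh <- generate_cohort(cohort_preset("overweight_obese", n = 60, seed = 5))
  coh$ck18_m30[1] <- NA
  coh$pro_c3[2] <- NA
  pan <- score_panel(coh)
  expect_true(is.na(pan$mack3[1]))
  expect_false(is.na(pan$fib4[1]))
  expect_true(is.na(pan$adapt[2]) && is.na(pan$fibc3[2]))
  expect_false(is.na(pan$nfs[2]))
  # per-score availability equals the brute-force complete-input count
  av <- score_availability(pan)
  expect_equal(av$n_available[av$score == "mack3"],
               sum(stats::complete.cases(coh[, c("glucose_fasting",
                                                 "insulin_fasting", "ast",
                                                 "ck18_m30")])))
  expect_equal(av$n_available[av$score == "adapt"],
               sum(stats::complete.cases(coh[, c("age", "pro_c3",
                                                 "platelets", "diabetes")])))
  # purity: identical output on a second evaluation
  expect_identical(pan, score_panel(coh))
})

test_that("coefficient config is finite and provenance-stamped", {
  co <- score_coefficients()
  expect_s3_class(co, "score_coefficients")
  for (s in c("hfs", "adapt", "fibc3", "mack3")) {
    expect_true(nzchar(co[[s]]$provenance))
  }
  expect_equal(co$apri$ast_uln, 40)
})

test_that("MACK-3 rule-in cutoff separates high-risk records", {
  co <- score_coefficients()
  # a record engineered to sit above the 0.549 rule-in threshold
  hi <- mack3(homa_ir = 8, ast = 120, ck18_m30 = 900, co)
  lo <- mack3(homa_ir = 1, ast = 20, ck18_m30 = 100, co)
  rule <- published_cutoff_rules()$mack3
  expect_gt(hi, 0.549)
  expect_equal(as.character(classify_dual(c(hi, lo), rule)),
               c("high", "low"))
})
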