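#' Two-stage sequential testing rule
#'
#' The first stage is a dual-cutoff test (typically FIB-4): subjects below
#' its lower cutoff are final low risk and above its upper cutoff final
#' high risk. Only first-stage indeterminates take the second, binary
#' test. The second test is either a single cutoff or, for the
#' BMI-adjusted NFS, one rule-out cutoff per BMI band.
#'
#' @param first A dual [cutoff_rule()] (both cutoffs present).
#' @param second Either a single number (the second test's cutoff) or, for
#'   a BMI-banded second test, a numeric vector with one cutoff per band of
#'   `bands`.
#' @param second_name Name of the second-stage score (informational).
#' @param bands A [bmi_bands()]; only used for banded second cutoffs.
#' @return A `sequential_rule` object.
#' @examples
#' sequential_rule(published_cutoff_rules()$fib4, 6.3287, "adapt")
#' @export
sequential_rule <- function(first, second, second_name = "second",
                            bands = bmi_bands()) {
  stopifnot(inherits(first, "cutoff_rule"))
  if (is.null(first$lower) || is.null(first$upper)) {
    abort("the first-stage rule must have both cutoffs")
  }
  if (!length(second) %in% c(1L, length(bands$labels))) {
    abort("second must be one cutoff, or one per BMI band")
  }
  structure(
    list(first = first, second = second, second_name = second_name,
         bands = bands, banded = length(second) > 1),
    class = "sequential_rule"
  )
}

#' Classify subjects with a sequential two-test algorithm
#'
#' First-stage low/high calls are final; first-stage indeterminates are
#' resolved by the second test (second score at or above its cutoff =>
#' high). The output is binary; an indeterminate subject whose second score
#' is missing is returned `NA` (unclassifiable).
#'
#' @param first_score First-stage score values.
#' @param second_score Second-stage score values (same subjects).
#' @param rule A [sequential_rule()].
#' @param age Ages (for the first rule's age-adjusted cutoff).
#' @param bmi BMIs; required when the rule's second test is BMI-banded.
#' @return Factor with levels `low`, `high`.
#' @export
sequential_classify <- function(first_score, second_score, rule,
                                age = NULL, bmi = NULL) {
  stopifnot(inherits(rule, "sequential_rule"))
  n <- length(first_score)
  stage1 <- classify_dual(first_score, rule$first, age)
  cut2 <- if (rule$banded) {
    if (is.null(bmi)) abort("bmi is required for a BMI-banded second test")
    unname(rule$second[as.integer(assign_bmi_band(bmi, rule$bands))])
  } else {
    rep(rule$second, n)
  }
  out <- dplyr::case_when(
    stage1 == "low" ~ "low",
    stage1 == "high" ~ "high",
    stage1 == "indeterminate" & second_score >= cut2 ~ "high",
    stage1 == "indeterminate" & second_score < cut2 ~ "low",
    .default = NA_character_
  )
  factor(out, levels = c("low", "high"))
}

#' Performance of a sequential algorithm
#'
#' Diagnostic metrics of the binary sequential classification, plus the
#' reduction in false positives relative to using the first test's lower
#' cutoff alone (score >= lower cutoff => positive): subjects whose
#' referral the second test avoids.
#'
#' @param df Cohort tibble containing the two score columns (and `age`,
#'   `bmi` if used by the rule).
#' @param first_score,second_score Names of the score columns.
#' @param condition Logical target-condition labels.
#' @param rule A [sequential_rule()].
#' @param ... Passed to [dx_metrics()].
#' @return List with `metrics` (a `dx_metrics` row), `fp_sequential`,
#'   `fp_first_alone`, `fp_reduction` (fraction), `n_high`,
#'   `n_unclassifiable`.
#' @export
sequential_performance <- function(df, first_score, second_score,
                                   condition, rule, ...) {
  d <- as.logical(condition)
  keep <- !is.na(df[[first_score]]) & !is.na(d)
  df <- df[keep, , drop = FALSE]; d <- d[keep]
  if (sum(d) == 0 || sum(!d) == 0) {
    abort("both classes must be present")
  }
  cls <- sequential_classify(df[[first_score]], df[[second_score]], rule,
                             age = df$age, bmi = df$bmi)
  mets <- dx_metrics(confusion(cls == "high", d), ...)
  fp_seq <- sum(cls == "high" & !d, na.rm = TRUE)
  first_alone <- classify_dual(df[[first_score]], rule$first, df$age) != "low"
  fp_single <- sum(first_alone & !d)
  list(
    metrics = mets,
    fp_sequential = fp_seq,
    fp_first_alone = fp_single,
    fp_reduction = if (fp_single > 0) 1 - fp_seq / fp_single else NA_real_,
    n_high = sum(cls == "high", na.rm = TRUE),
    n_unclassifiable = sum(is.na(cls))
  )
}
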