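#' Decision thresholds for a score
#'
#' A cutoff rule holds a lower (rule-out) and/or upper (rule-in) threshold,
#' optionally an age-adjusted lower threshold applied to subjects aged >= 65
#' years, with the orientation "higher score = more diseased". A rule with a
#' single cutoff describes a binary test (positive iff score >= cutoff).
#'
#' @param score Score name (informational).
#' @param lower,upper Thresholds; at least one must be given and
#'   `lower <= upper` when both are.
#' @param age_adjusted_lower Optional replacement for `lower` at age >= 65.
#' @param age_threshold Age (years) from which the age-adjusted lower
#'   cutoff applies. Default 65.
#' @return A `cutoff_rule` object.
#' @examples
#' cutoff_rule("fib4", lower = 1.3, upper = 2.67, age_adjusted_lower = 2.0)
#' @export
cutoff_rule <- function(score, lower = NULL, upper = NULL,
                        age_adjusted_lower = NULL, age_threshold = 65) {
  if (is.null(lower) && is.null(upper)) {
    abort("a cutoff rule needs at least one of 'lower' and 'upper'")
  }
  if (!is.null(lower) && !is.null(upper) && lower > upper) {
    abort("'lower' must be <= 'upper'")
  }
  structure(
    list(score = score, lower = lower, upper = upper,
         age_adjusted_lower = age_adjusted_lower,
         age_threshold = age_threshold),
    class = "cutoff_rule"
  )
}

#' @export
print.cutoff_rule <- function(x, ...) {
  adj <- if (is.null(x$age_adjusted_lower)) "" else
    paste0(" (", x$age_adjusted_lower, " at age >= ", x$age_threshold, ")")
  cat("<cutoff_rule> ", x$score, ": lower ",
      x$lower %||% "-", adj, ", upper ", x$upper %||% "-", "\n", sep = "")
  invisible(x)
}

#' Published cutoff rules for the composite scores
#'
#' The previously published advanced-fibrosis cutoffs used as defaults:
#' FIB-4 1.3 (2.0 at age >= 65) / 2.67; NFS -1.455 (0.12) / 0.676;
#' HFS 0.12 / 0.47; single cutoffs APRI 1, BARD 2, ADAPT 6.3287, FIBC3 0.4;
#' and the fibrotic-NASH rule MACK-3 0.134 / 0.549.
#'
#' @return Named list of [cutoff_rule()] objects.
#' @export
published_cutoff_rules <- function() {
  list(
    fib4 = cutoff_rule("fib4", lower = 1.3, upper = 2.67,
                       age_adjusted_lower = 2.0),
    nfs = cutoff_rule("nfs", lower = -1.455, upper = 0.676,
                      age_adjusted_lower = 0.12),
    hfs = cutoff_rule("hfs", lower = 0.12, upper = 0.47),
    apri = cutoff_rule("apri", lower = 1),
    bard = cutoff_rule("bard", lower = 2),
    adapt = cutoff_rule("adapt", lower = 6.3287),
    fibc3 = cutoff_rule("fibc3", lower = 0.4),
    mack3 = cutoff_rule("mack3", lower = 0.134, upper = 0.549)
  )
}

#' Classify scores against a dual- or single-cutoff rule
#'
#' For a dual rule: `high` if the value is above the upper cutoff, `low` if
#' below the lower cutoff, `indeterminate` otherwise (boundary values fall
#' in the indeterminate zone, matching rule-out rows printed as "< lower"
#' and rule-in rows as "> upper"). When the subject is aged at or above the
#' rule's age threshold and an age-adjusted lower cutoff exists, it replaces
#' the lower cutoff. For a single-cutoff rule the classification is binary:
#' `high` iff value >= cutoff.
#'
#' @param value Numeric score values.
#' @param rule A [cutoff_rule()].
#' @param age Ages in years (recycled); only used when the rule carries an
#'   age-adjusted cutoff.
#' @return Factor with levels `low`, `indeterminate`, `high` (`NA` for
#'   missing values).
#' @export
classify_dual <- function(value, rule, age = NULL) {
  stopifnot(inherits(rule, "cutoff_rule"))
  n <- length(value)
  if (is.null(age)) age <- rep(NA_real_, n)
  age <- rep_len(age, n)

  lvls <- c("low", "indeterminate", "high")
  single <- is.null(rule$lower) || is.null(rule$upper)
  if (single) {
    cut <- rule$lower %||% rule$upper
    out <- ifelse(value >= cut, "high", "low")
    return(factor(out, levels = lvls))
  }
  lower <- rep(rule$lower, n)
  if (!is.null(rule$age_adjusted_lower)) {
    use_adj <- !is.na(age) & age >= rule$age_threshold
    lower[use_adj] <- rule$age_adjusted_lower
  }
  out <- dplyr::case_when(
    value > rule$upper ~ "high",
    value < lower ~ "low",
    !is.na(value) ~ "indeterminate",
    .default = NA_character_
  )
  factor(out, levels = lvls)
}
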