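#' Compare two classification rates
#'
#' Paired binary outcomes (the same subjects classified by two tests) are
#' compared with the exact McNemar test: the two-sided exact binomial test
#' on the discordant pairs, `p = 1` when there are none. Unpaired
#' proportions are compared with the Pearson chi-squared test (no
#' continuity correction).
#'
#' @param x,y Logical vectors. Paired: the two tests' outcomes on the same
#'   subjects. Unpaired: the outcomes in the two independent groups.
#' @param paired Whether `x` and `y` are paired.
#' @return A tibble with `p_value`, `statistic` (discordant-pair count or
#'   chi-squared statistic) and `method`.
#' @export
compare_rates <- function(x, y, paired = TRUE) {
  x <- as.logical(x); y <- as.logical(y)
  if (paired) {
    if (length(x) != length(y)) abort("paired vectors must be equal length")
    keep <- !is.na(x) & !is.na(y)
    b <- sum(x[keep] & !y[keep])
    c_ <- sum(!x[keep] & y[keep])
    p <- if (b + c_ == 0) 1 else binom.test(b, b + c_, 0.5)$p.value
    tibble(p_value = p, statistic = b + c_, method = "exact McNemar")
  } else {
    tab <- rbind(c(sum(x, na.rm = TRUE), sum(!x, na.rm = TRUE)),
                 c(sum(y, na.rm = TRUE), sum(!y, na.rm = TRUE)))
    ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
    tibble(p_value = ct$p.value, statistic = unname(ct$statistic),
           method = "Pearson chi-squared")
  }
}

# weighted generalized score statistic for one predictive value:
# arms defined by selector vectors (subjects contributing to each arm's
# predictive value), outcome = reference standard (possibly negated for NPV)
wgs_statistic <- function(in1, in2, outcome) {
  n1 <- sum(in1); n2 <- sum(in2)
  if (n1 == 0 || n2 == 0) {
    abort("a predictive value is undefined in one arm (no qualifying subjects)")
  }
  pv1 <- sum(outcome[in1]) / n1
  pv2 <- sum(outcome[in2]) / n2
  # null common value, weighted by arm sizes
  p0 <- (n1 * pv1 + n2 * pv2) / (n1 + n2)
  # per-subject score contributions to the difference, residuals under H0
  u <- in1 * (outcome - p0) / n1 - in2 * (outcome - p0) / n2
  v0 <- sum(u^2)
  delta <- pv1 - pv2
  stat <- if (v0 > 0) delta^2 / v0 else if (delta == 0) 0 else Inf
  p <- if (is.finite(stat)) pchisq(stat, df = 1, lower.tail = FALSE) else 0
  if (v0 == 0 && delta == 0) p <- 1
  list(pv1 = pv1, pv2 = pv2, statistic = stat, p_value = p)
}

#' Compare predictive values of two paired binary tests
#'
#' Weighted generalized score test for the difference in positive and
#' negative predictive values of two binary tests applied to the same
#' subjects: under the null, a common predictive value (weighted by the
#' number of qualifying subjects per test) is substituted, and the
#' statistic is the squared PV difference over its robust per-subject
#' score variance, referred to chi-squared with 1 df.
#'
#' @param test1,test2 Logical vectors: the two tests' positive/negative
#'   calls on the same subjects.
#' @param condition Logical reference-standard labels.
#' @return A tibble with one row per predictive value (`metric` =
#'   `"ppv"`/`"npv"`), the two estimates, the statistic and the two-sided
#'   p-value.
#' @export
compare_predictive_values <- function(test1, test2, condition) {
  test1 <- as.logical(test1); test2 <- as.logical(test2)
  condition <- as.logical(condition)
  if (length(test1) != length(test2) ||
      length(test1) != length(condition)) {
    abort("inputs must be paired (equal length)")
  }
  keep <- !is.na(test1) & !is.na(test2) & !is.na(condition)
  t1 <- test1[keep]; t2 <- test2[keep]; d <- condition[keep]
  ppv <- wgs_statistic(t1, t2, as.numeric(d))
  npv <- wgs_statistic(!t1, !t2, as.numeric(!d))
  tibble(
    metric = c("ppv", "npv"),
    estimate_1 = c(ppv$pv1, npv$pv1),
    estimate_2 = c(ppv$pv2, npv$pv2),
    statistic = c(ppv$statistic, npv$statistic),
    p_value = c(ppv$p_value, npv$p_value)
  )
}
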