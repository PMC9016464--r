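#' Tally a classification against the reference standard
#'
#' Accepts either a binary classification (logical, or factor from a
#' single-cutoff [classify_dual()]) or a three-level low/indeterminate/high
#' factor. Condition-positive subjects left in the indeterminate zone are
#' counted as `indeterminate_pos`, condition-negatives as
#' `indeterminate_neg`; the six counts always sum to the number of
#' classified subjects.
#'
#' @param classification Logical vector (`TRUE` = test positive) or factor
#'   with levels `low`, `indeterminate`, `high`.
#' @param condition Logical vector of reference-standard labels.
#' @return A `confusion_summary` object (list of counts `tp`, `fp`, `tn`,
#'   `fn`, `indeterminate_pos`, `indeterminate_neg`).
#' @export
confusion <- function(classification, condition) {
  if (length(classification) != length(condition)) {
    abort("classification and condition must have equal length")
  }
  keep <- !is.na(classification) & !is.na(condition)
  cl <- classification[keep]
  d <- as.logical(condition)[keep]
  if (is.logical(cl) || is.numeric(cl)) {
    cl <- factor(ifelse(as.logical(cl), "high", "low"),
                 levels = c("low", "indeterminate", "high"))
  }
  structure(
    list(
      tp = sum(cl == "high" & d), fp = sum(cl == "high" & !d),
      tn = sum(cl == "low" & !d), fn = sum(cl == "low" & d),
      indeterminate_pos = sum(cl == "indeterminate" & d),
      indeterminate_neg = sum(cl == "indeterminate" & !d)
    ),
    class = "confusion_summary"
  )
}

#' Build a confusion summary from counts
#'
#' Convenience constructor used when reconstructing published contingency
#' tables.
#'
#' @param tp,fp,tn,fn,indeterminate_pos,indeterminate_neg Non-negative
#'   counts.
#' @return A `confusion_summary` object.
#' @export
confusion_counts <- function(tp, fp, tn, fn,
                             indeterminate_pos = 0, indeterminate_neg = 0) {
  cs <- list(tp = tp, fp = fp, tn = tn, fn = fn,
             indeterminate_pos = indeterminate_pos,
             indeterminate_neg = indeterminate_neg)
  if (any(unlist(cs) < 0)) abort("counts must be non-negative")
  structure(cs, class = "confusion_summary")
}

#' @export
print.confusion_summary <- function(x, ...) {
  cat("<confusion_summary> tp", x$tp, "fp", x$fp, "tn", x$tn, "fn", x$fn,
      "ind+", x$indeterminate_pos, "ind-", x$indeterminate_neg, "\n")
  invisible(x)
}

# Clopper-Pearson exact CI via the beta closed form
clopper_pearson <- function(x, n, level = 0.95) {
  a <- (1 - level) / 2
  lo <- ifelse(x == 0, 0, qbeta(a, x, n - x + 1))
  hi <- ifelse(x == n, 1, qbeta(1 - a, x + 1, n - x))
  c(lower = lo, upper = hi)
}

#' Diagnostic accuracy metrics from a confusion summary
#'
#' Sensitivity, specificity, predictive values (each with exact
#' Clopper-Pearson confidence intervals), likelihood ratios, number needed
#' to diagnose (`1 / Youden`, Youden = Se + Sp - 1) and the indeterminate
#' fraction. Indeterminate subjects are excluded from the denominators; see
#' [combined_dual_metrics()] for the indeterminate-as-correct convention.
#'
#' In `lr_mode = "integer_percent"`, sensitivity and specificity are first
#' rounded to whole percent (half away from zero) before forming the
#' likelihood ratios and NND, reproducing published tables whose LR columns
#' derive from the printed integer percentages. `"raw"` (default) is the
#' analytic mode.
#'
#' Zero denominators make the affected metric `NA` ("undefined") rather
#' than propagating NaN; `NND` is `NA` when Se + Sp <= 1.
#'
#' @param cs A `confusion_summary` from [confusion()] or
#'   [confusion_counts()].
#' @param ci_level Two-sided confidence level (default 0.95).
#' @param lr_mode `"raw"` or `"integer_percent"`.
#' @return A one-row tibble of class `dx_metrics`.
#' @examples
#' dx_metrics(confusion_counts(tp = 98, fp = 199, tn = 286, fn = 17))
#' @export
dx_metrics <- function(cs, ci_level = 0.95,
                       lr_mode = c("raw", "integer_percent")) {
  stopifnot(inherits(cs, "confusion_summary"))
  lr_mode <- arg_match(lr_mode)
  n_pos <- cs$tp + cs$fn
  n_neg <- cs$tn + cs$fp
  n_all <- n_pos + n_neg + cs$indeterminate_pos + cs$indeterminate_neg

  prop <- function(x, n) if (n > 0) x / n else NA_real_
  ci <- function(x, n) {
    if (n > 0) clopper_pearson(x, n, ci_level) else c(NA_real_, NA_real_)
  }
  se <- prop(cs$tp, n_pos); se_ci <- ci(cs$tp, n_pos)
  sp <- prop(cs$tn, n_neg); sp_ci <- ci(cs$tn, n_neg)
  ppv <- prop(cs$tp, cs$tp + cs$fp); ppv_ci <- ci(cs$tp, cs$tp + cs$fp)
  npv <- prop(cs$tn, cs$tn + cs$fn); npv_ci <- ci(cs$tn, cs$tn + cs$fn)

  se_lr <- se; sp_lr <- sp
  if (lr_mode == "integer_percent") {
    se_lr <- round_half_up(100 * se) / 100
    sp_lr <- round_half_up(100 * sp) / 100
  }
  lr_pos <- if (!is.na(se_lr) && !is.na(sp_lr) && sp_lr < 1) {
    se_lr / (1 - sp_lr)
  } else NA_real_
  lr_neg <- if (!is.na(se_lr) && !is.na(sp_lr) && sp_lr > 0) {
    (1 - se_lr) / sp_lr
  } else NA_real_
  youden <- se_lr + sp_lr - 1
  nnd <- if (!is.na(youden) && youden > 0) 1 / youden else NA_real_

  out <- tibble(
    se = se, se_lower = se_ci[[1]], se_upper = se_ci[[2]],
    sp = sp, sp_lower = sp_ci[[1]], sp_upper = sp_ci[[2]],
    ppv = ppv, ppv_lower = ppv_ci[[1]], ppv_upper = ppv_ci[[2]],
    npv = npv, npv_lower = npv_ci[[1]], npv_upper = npv_ci[[2]],
    lr_pos = lr_pos, lr_neg = lr_neg, nnd = nnd,
    indeterminate_fraction =
      prop(cs$indeterminate_pos + cs$indeterminate_neg, n_all),
    n = n_all
  )
  class(out) <- c("dx_metrics", class(out))
  out
}

#' Per-cutoff performance of a dual-cutoff rule
#'
#' Evaluates the rule's lower cutoff as a binary rule-out screen
#' (score >= lower => positive) and its upper cutoff as a binary rule-in
#' test (score > upper => positive), and reports the indeterminate
#' fraction (subjects between the cutoffs).
#'
#' @param scores Numeric score values.
#' @param condition Logical reference-standard labels.
#' @param rule A dual [cutoff_rule()].
#' @param ages Optional ages (for age-adjusted lower cutoffs).
#' @param ... Passed to [dx_metrics()] (e.g. `lr_mode`).
#' @return Tibble with one `dx_metrics` row per cutoff (`cutoff` column
#'   `"lower"`/`"upper"`) and the shared `indeterminate_fraction`.
#' @export
dual_cutoff_performance <- function(scores, condition, rule, ages = NULL,
                                    ...) {
  stopifnot(inherits(rule, "cutoff_rule"))
  keep <- !is.na(scores) & !is.na(condition)
  scores <- scores[keep]; condition <- condition[keep]
  ages <- if (is.null(ages)) NULL else ages[keep]
  if (sum(condition) == 0 || sum(!condition) == 0) {
    abort("both condition-positive and -negative subjects are required")
  }
  cls <- classify_dual(scores, rule, ages)
  ind_frac <- mean(cls == "indeterminate")

  res <- list()
  if (!is.null(rule$lower)) {
    pos_lo <- cls != "low" # >= (age-adjusted) lower cutoff
    res$lower <- dx_metrics(confusion(pos_lo, condition), ...)
  }
  if (!is.null(rule$upper)) {
    pos_hi <- cls == "high" # > upper cutoff
    res$upper <- dx_metrics(confusion(pos_hi, condition), ...)
  }
  out <- bind_rows(res, .id = "cutoff")
  out$indeterminate_fraction <- ind_frac
  out
}

#' Combined dual-cutoff metrics under the indeterminate-as-correct convention
#'
#' Reports the combined performance of a two-cutoff test, counting
#' indeterminate condition-positive subjects as true positives and
#' indeterminate condition-negatives as true negatives (subjects in the
#' gray zone are assumed to be resolved by the reference standard).
#'
#' @inheritParams dual_cutoff_performance
#' @return A `dx_metrics` row.
#' @export
combined_dual_metrics <- function(scores, condition, rule, ages = NULL,
                                  ...) {
  keep <- !is.na(scores) & !is.na(condition)
  scores <- scores[keep]; condition <- condition[keep]
  ages <- if (is.null(ages)) NULL else ages[keep]
  cls <- classify_dual(scores, rule, ages)
  cs <- confusion(cls, condition)
  cs2 <- confusion_counts(
    tp = cs$tp + cs$indeterminate_pos,
    fp = cs$fp,
    tn = cs$tn + cs$indeterminate_neg,
    fn = cs$fn
  )
  out <- dx_metrics(cs2, ...)
  out$indeterminate_fraction <-
    (cs$indeterminate_pos + cs$indeterminate_neg) / length(scores)
  out
}

#' Project predictive values to a target prevalence
#'
#' Bayes' projection of sensitivity and specificity to a population with
#' the given condition prevalence:
#' `PPV = Se pi / (Se pi + (1 - Sp)(1 - pi))`,
#' `NPV = Sp (1 - pi) / (Sp (1 - pi) + (1 - Se) pi)`,
#' `accuracy = Se pi + Sp (1 - pi)`.
#' Boundary conventions: at prevalence 0, `PPV = 0` and `NPV = 1`; at
#' prevalence 1, `PPV = 1` and `NPV = 0`.
#'
#' @param se,sp Sensitivity and specificity, in `[0, 1]`.
#' @param prevalence Condition prevalence, in `[0, 1]`.
#' @return Tibble with `ppv`, `npv`, `accuracy`.
#' @examples
#' predictive_values_at_prevalence(0.85, 0.95, 0.15)
#' @export
predictive_values_at_prevalence <- function(se, sp, prevalence) {
  stopifnot(all(se >= 0 & se <= 1), all(sp >= 0 & sp <= 1),
            all(prevalence >= 0 & prevalence <= 1))
  num_p <- se * prevalence
  den_p <- se * prevalence + (1 - sp) * (1 - prevalence)
  num_n <- sp * (1 - prevalence)
  den_n <- sp * (1 - prevalence) + (1 - se) * prevalence
  tibble(
    ppv = ifelse(den_p > 0, num_p / den_p, ifelse(prevalence >= 1, 1, 0)),
    npv = ifelse(den_n > 0, num_n / den_n, ifelse(prevalence <= 0, 1, 0)),
    accuracy = se * prevalence + sp * (1 - prevalence)
  )
}
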