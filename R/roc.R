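#' Empirical ROC curve with AUROC and DeLong confidence interval
#'
#' Orientation: higher score = more diseased. The AUROC is the tie-corrected
#' Mann-Whitney statistic (concordant pairs count 1, tied pairs 1/2); the
#' confidence interval uses the DeLong structural-components variance.
#' Curve points are evaluated at every unique observed threshold (positive
#' iff score >= threshold), plus the degenerate `Inf` point.
#'
#' @param scores Numeric score values.
#' @param condition Logical reference-standard labels; both classes must be
#'   present.
#' @param ci_level Confidence level for the AUROC CI.
#' @return A `roc_curve` object: list with `points` (tibble of `threshold`,
#'   `se`, `sp`), `auroc`, `ci`, `n_pos`, `n_neg`.
#' @export
roc_curve <- function(scores, condition, ci_level = 0.95) {
  keep <- !is.na(scores) & !is.na(condition)
  x <- scores[keep]
  d <- as.logical(condition)[keep]
  if (sum(d) == 0 || sum(!d) == 0) {
    abort("both classes must be present to build a ROC curve")
  }
  thr <- c(sort(unique(x)), Inf)
  pts <- tibble(
    threshold = thr,
    se = map_dbl(thr, ~ mean(x[d] >= .x)),
    sp = map_dbl(thr, ~ mean(x[!d] < .x))
  )
  a <- auroc(x, d)
  v <- delong_components(x, d)
  se_auc <- sqrt(v$var)
  z <- qnorm(1 - (1 - ci_level) / 2)
  ci <- c(max(0, a - z * se_auc), min(1, a + z * se_auc))
  structure(
    list(points = pts, auroc = a, ci = ci, ci_level = ci_level,
         n_pos = sum(d), n_neg = sum(!d)),
    class = "roc_curve"
  )
}

#' Area under the ROC curve (Mann-Whitney form)
#'
#' @inheritParams roc_curve
#' @return AUROC in `[0, 1]`.
#' @export
auroc <- function(scores, condition) {
  keep <- !is.na(scores) & !is.na(condition)
  x <- scores[keep]
  d <- as.logical(condition)[keep]
  n1 <- sum(d); n0 <- sum(!d)
  if (n1 == 0 || n0 == 0) abort("both classes must be present")
  r <- rank(x, ties.method = "average")
  (sum(r[d]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# DeLong structural components for one score: placement values and the
# variance of the empirical AUROC.
delong_components <- function(scores, condition) {
  d <- as.logical(condition)
  xs <- scores[d]; ys <- scores[!d]
  m <- length(xs); n <- length(ys)
  psi <- function(x, y) (x > y) + 0.5 * (x == y)
  v10 <- map_dbl(xs, ~ mean(psi(.x, ys)))  # per-case placements
  v01 <- map_dbl(ys, ~ mean(psi(xs, .x)))  # per-control placements
  theta <- mean(v10)
  s10 <- if (m > 1) stats::var(v10) else 0
  s01 <- if (n > 1) stats::var(v01) else 0
  list(theta = theta, v10 = v10, v01 = v01,
       var = s10 / m + s01 / n)
}

#' DeLong confidence interval for a single AUROC
#'
#' @inheritParams roc_curve
#' @return Tibble with `auroc`, `lower`, `upper`.
#' @export
delong_ci <- function(scores, condition, ci_level = 0.95) {
  rc <- roc_curve(scores, condition, ci_level)
  tibble(auroc = rc$auroc, lower = rc$ci[[1]], upper = rc$ci[[2]])
}

#' DeLong test comparing two correlated AUROCs
#'
#' Paired comparison of the AUROCs of two scores measured on the same
#' subjects, using the DeLong structural-components estimator of the
#' variance/covariance of the empirical AUROCs and a normal reference for
#' the two-sided p-value.
#'
#' @param scores_a,scores_b Paired score vectors (same subjects).
#' @param condition Logical reference-standard labels.
#' @return A `delong_test` object: list with `auroc_a`, `auroc_b`, `delta`,
#'   `var_delta`, `z`, `p_value`, `degenerate`.
#' @export
delong_test <- function(scores_a, scores_b, condition) {
  if (length(scores_a) != length(scores_b) ||
      length(scores_a) != length(condition)) {
    abort("scores_a, scores_b and condition must be paired (equal length)")
  }
  keep <- !is.na(scores_a) & !is.na(scores_b) & !is.na(condition)
  a <- scores_a[keep]; b <- scores_b[keep]
  d <- as.logical(condition)[keep]
  ca <- delong_components(a, d)
  cb <- delong_components(b, d)
  m <- sum(d); n <- sum(!d)
  cov10 <- if (m > 1) stats::cov(ca$v10, cb$v10) else 0
  cov01 <- if (n > 1) stats::cov(ca$v01, cb$v01) else 0
  var_delta <- ca$var + cb$var - 2 * (cov10 / m + cov01 / n)
  delta <- ca$theta - cb$theta
  degenerate <- var_delta <= .Machine$double.eps
  z <- if (degenerate && delta == 0) 0 else delta / sqrt(var_delta)
  p <- if (degenerate) {
    if (delta == 0) 1 else NA_real_
  } else {
    2 * pnorm(-abs(z))
  }
  structure(
    list(auroc_a = ca$theta, auroc_b = cb$theta, delta = delta,
         var_delta = var_delta, z = z, p_value = p,
         degenerate = degenerate, n_pos = m, n_neg = n),
    class = "delong_test"
  )
}

#' @export
print.delong_test <- function(x, ...) {
  cat("<delong_test> AUROC", signif(x$auroc_a, 4), "vs",
      signif(x$auroc_b, 4), " z =", signif(x$z, 4),
      " p =", signif(x$p_value, 4), "\n")
  invisible(x)
}

#' Obuchowski measure for ordinal disease stage
#'
#' The probability that the biomarker correctly ranks two randomly chosen
#' patients of different fibrosis stages, penalizing pairs in proportion to
#' their stage difference. Over all subject pairs with different stages,
#' a pair scores 1 if the biomarker orders them concordantly with stage,
#' 1/2 if tied, 0 otherwise; the pair weight is
#' `penalty_per_stage * |stage difference|` and the measure is the weighted
#' mean pair score. With the default linear penalty the scale factor
#' cancels in the normalization, so the measure only depends on the weights
#' being proportional to the stage difference. The confidence interval is a
#' leave-one-out jackknife with a normal reference.
#'
#' With exactly two stage groups the measure reduces to the AUROC.
#'
#' @param scores Numeric biomarker values (higher = more diseased).
#' @param stages Ordinal stages (integers 0-4).
#' @param penalty_per_stage Weight per unit stage difference (default 0.25).
#' @param ci_level Confidence level.
#' @return An `obuchowski` object: list with `estimate`, `se`, `ci`, `n`.
#' @export
obuchowski <- function(scores, stages, penalty_per_stage = 0.25,
                       ci_level = 0.95) {
  keep <- !is.na(scores) & !is.na(stages)
  x <- scores[keep]; s <- stages[keep]
  n <- length(x)
  if (length(unique(s)) < 2) {
    abort("at least two distinct stages are required")
  }
  # per-subject accumulations so the jackknife is O(n^2)
  num_i <- numeric(n)
  den_i <- numeric(n)
  for (i in seq_len(n - 1)) {
    j <- (i + 1):n
    diff_s <- s[j] - s[i]
    active <- diff_s != 0
    if (!any(active)) next
    w <- penalty_per_stage * abs(diff_s[active])
    concord <- sign(x[j][active] - x[i]) * sign(diff_s[active])
    cscore <- ifelse(concord > 0, 1, ifelse(concord == 0, 0.5, 0))
    contrib_n <- w * cscore
    num_i[i] <- num_i[i] + sum(contrib_n)
    den_i[i] <- den_i[i] + sum(w)
    num_i[j[active]] <- num_i[j[active]] + contrib_n
    den_i[j[active]] <- den_i[j[active]] + w
  }
  num <- sum(num_i) / 2
  den <- sum(den_i) / 2
  est <- num / den
  # leave-one-out estimates from the totals minus subject i's pairs
  loo_den <- den - den_i
  ok <- loo_den > 0
  loo <- ifelse(ok, (num - num_i) / loo_den, est)
  se <- sqrt((n - 1) / n * sum((loo - mean(loo))^2))
  z <- qnorm(1 - (1 - ci_level) / 2)
  structure(
    list(estimate = est, se = se,
         ci = c(max(0, est - z * se), min(1, est + z * se)),
         ci_level = ci_level, n = n,
         penalty_per_stage = penalty_per_stage),
    class = "obuchowski"
  )
}

#' @export
print.obuchowski <- function(x, ...) {
  cat("<obuchowski> ", signif(x$estimate, 4), " (",
      round(100 * x$ci_level), "% CI ", signif(x$ci[[1]], 4), "-",
      signif(x$ci[[2]], 4), "), n = ", x$n, "\n", sep = "")
  invisible(x)
}
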