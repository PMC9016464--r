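#' Tidy a ROC curve into its threshold table
#'
#' @param x A [roc_curve()] object.
#' @param ... Unused.
#' @return Tibble with `threshold`, `se`, `sp`.
#' @export
tidy.roc_curve <- function(x, ...) x$points

#' One-row summary of a ROC curve
#'
#' @inheritParams tidy.roc_curve
#' @return Tibble with `auroc`, `ci_lower`, `ci_upper`, `n_pos`, `n_neg`.
#' @export
glance.roc_curve <- function(x, ...) {
  tibble(auroc = x$auroc, ci_lower = x$ci[[1]], ci_upper = x$ci[[2]],
         n_pos = x$n_pos, n_neg = x$n_neg)
}

#' @export
print.roc_curve <- function(x, ...) {
  cat("<roc_curve> AUROC ", signif(x$auroc, 4), " (",
      round(100 * x$ci_level), "% CI ", signif(x$ci[[1]], 4), "-",
      signif(x$ci[[2]], 4), "); ", x$n_pos, " cases / ", x$n_neg,
      " controls\n", sep = "")
  invisible(x)
}

#' Tidy a DeLong AUROC comparison
#'
#' @param x A [delong_test()] object.
#' @param ... Unused.
#' @return One-row tibble with the two AUROCs, their difference, `z` and
#'   `p_value`.
#' @export
tidy.delong_test <- function(x, ...) {
  tibble(auroc_a = x$auroc_a, auroc_b = x$auroc_b, delta = x$delta,
         z = x$z, p_value = x$p_value, degenerate = x$degenerate)
}

#' @rdname tidy.delong_test
#' @export
glance.delong_test <- function(x, ...) tidy(x)

#' Tidy an Obuchowski measure
#'
#' @param x An [obuchowski()] object.
#' @param ... Unused.
#' @return One-row tibble with `estimate`, `std_error`, `ci_lower`,
#'   `ci_upper`, `n`.
#' @export
tidy.obuchowski <- function(x, ...) {
  tibble(estimate = x$estimate, std_error = x$se,
         ci_lower = x$ci[[1]], ci_upper = x$ci[[2]], n = x$n)
}

#' @rdname tidy.obuchowski
#' @export
glance.obuchowski <- function(x, ...) tidy(x)

#' Tidy a confusion summary into a count table
#'
#' @param x A [confusion()] object.
#' @param ... Unused.
#' @return Tibble of cell names and counts.
#' @export
tidy.confusion_summary <- function(x, ...) {
  tibble(cell = names(unclass(x)), count = unlist(unclass(x), use.names = FALSE))
}
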