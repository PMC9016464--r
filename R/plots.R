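#' Plot a ROC curve
#'
#' @param object A [roc_curve()] object.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.roc_curve <- function(object, ...) {
  pts <- object$points %>% arrange(.data$se)
  ggplot2::ggplot(pts, ggplot2::aes(x = 1 - .data$sp, y = .data$se)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_step(direction = "vh") +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "1 - specificity", y = "Sensitivity",
      title = sprintf("AUROC %.3f (%.0f%% CI %.3f-%.3f)", object$auroc,
                      100 * object$ci_level, object$ci[[1]], object$ci[[2]])
    ) +
    ggplot2::theme_minimal()
}

#' Plot derived BMI-band cutoffs with achieved sensitivity/specificity
#'
#' Shows, per BMI band and cutoff role, the derivation-set and
#' validation-set sensitivity (rule-out roles) or specificity (rule-in).
#'
#' @param object A `bmi_cutoff_set` from [derive_bmi_cutoffs()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.bmi_cutoff_set <- function(object, ...) {
  long <- object %>%
    select("bmi_band", "role", "se_derivation", "sp_derivation",
           "se_validation", "sp_validation") %>%
    tidyr::pivot_longer(-c("bmi_band", "role"),
                        names_to = c("metric", "set"), names_sep = "_",
                        values_to = "value")
  ggplot2::ggplot(long,
                  ggplot2::aes(x = .data$role, y = .data$value,
                               fill = .data$set)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::facet_grid(.data$metric ~ .data$bmi_band) +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = "Proportion", fill = NULL) +
    ggplot2::theme_minimal()
}

#' Score distribution by fibrosis stage
#'
#' Quick diagnostic plot of a score column stratified by histological
#' stage.
#'
#' @param panel A [score_panel()] tibble with `fibrosis_stage`.
#' @param score Score column name.
#' @return A ggplot.
#' @export
plot_score_by_stage <- function(panel, score = "fib4") {
  df <- panel %>%
    filter(!is.na(.data[[score]]), !is.na(.data$fibrosis_stage))
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$fibrosis_stage),
                                   y = .data[[score]])) +
    ggplot2::geom_boxplot(outlier.alpha = 0.3) +
    ggplot2::labs(x = "Fibrosis stage", y = score) +
    ggplot2::theme_minimal()
}
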