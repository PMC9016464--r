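#' BMI band configuration
#'
#' Ordered half-open BMI intervals partitioning (0, Inf). Defaults follow
#' the obesity classification used for BMI-adjusted cutoffs: nonobese
#' `[0, 30)`, obese `[30, 40)`, morbidly obese `[40, Inf)` kg/m^2.
#'
#' @param breaks Increasing positive interior break points.
#' @param labels Band labels (one more than `breaks`).
#' @return A `bmi_bands` object.
#' @export
bmi_bands <- function(breaks = c(30, 40),
                      labels = c("nonobese", "obese", "morbidly_obese")) {
  if (is.unsorted(breaks, strictly = TRUE) || any(breaks <= 0)) {
    abort("breaks must be strictly increasing and positive")
  }
  if (length(labels) != length(breaks) + 1) {
    abort("need one more label than breaks")
  }
  structure(list(breaks = breaks, labels = labels), class = "bmi_bands")
}

#' Assign BMI values to bands
#'
#' Each BMI maps to exactly one half-open band `[lower, upper)`.
#'
#' @param bmi Positive BMI values, kg/m^2.
#' @param bands A [bmi_bands()] configuration.
#' @return Factor of band labels.
#' @examples
#' assign_bmi_band(c(29.9, 30, 40)) # nonobese, obese, morbidly_obese
#' @export
assign_bmi_band <- function(bmi, bands = bmi_bands()) {
  if (any(bmi <= 0, na.rm = TRUE)) {
    abort("bmi must be positive", class = "fibroscores_domain_error")
  }
  cut(bmi, breaks = c(0, bands$breaks, Inf), labels = bands$labels,
      right = FALSE)
}

#' Stratified derivation/validation split
#'
#' Randomly splits records into derivation and validation subsets in the
#' given ratio, within each BMI band and stratified on the target condition
#' so that case prevalence is preserved to within one subject per stratum.
#' Fully reproducible from `seed`.
#'
#' @param df Cohort tibble with a `bmi` column.
#' @param condition Logical target-condition labels (same length as rows).
#' @param ratio Derivation fraction (default 0.7).
#' @param bands A [bmi_bands()] configuration.
#' @param seed Integer seed.
#' @return `df` with columns `bmi_band`, `.condition` and `split`
#'   (`"derivation"`/`"validation"`).
#' @export
split_derivation_validation <- function(df, condition, ratio = 0.7,
                                        bands = bmi_bands(), seed = 1L) {
  stopifnot(ratio > 0, ratio < 1, length(condition) == nrow(df))
  df <- df %>%
    mutate(bmi_band = assign_bmi_band(.data$bmi, bands),
           .condition = as.logical(condition))
  zero_case <- df %>%
    group_by(.data$bmi_band) %>%
    summarise(cases = sum(.data$.condition), .groups = "drop") %>%
    filter(.data$cases == 0)
  if (nrow(zero_case) > 0) {
    warn(paste0("band(s) without cases: ",
                paste(zero_case$bmi_band, collapse = ", ")))
  }
  withr::with_seed(seed, {
    df %>%
      group_by(.data$bmi_band, .data$.condition) %>%
      mutate(split = {
        k <- round_half_up(dplyr::n() * ratio)
        out <- rep("validation", dplyr::n())
        out[sample.int(dplyr::n(), k)] <- "derivation"
        out
      }) %>%
      ungroup()
  })
}

# empirical se/sp over candidate cutoffs (positive iff score >= cutoff);
# candidates are midpoints between adjacent distinct observed scores plus
# the two infinite sentinels, so >=/> conventions coincide at candidates
cutoff_grid <- function(scores, condition) {
  d <- as.logical(condition)
  u <- sort(unique(scores))
  cand <- c(-Inf, if (length(u) > 1) (head(u, -1) + tail(u, -1)) / 2, Inf)
  tibble(
    cutoff = cand,
    se = map_dbl(cand, ~ mean(scores[d] >= .x)),
    sp = map_dbl(cand, ~ mean(scores[!d] < .x))
  )
}

#' Derive rule-out, rule-in and best-single cutoffs
#'
#' Candidate cutoffs are the midpoints between adjacent distinct observed
#' scores plus the infinite sentinels; a subject is test-positive iff their
#' score is at or above the cutoff. Three cutoffs are selected on the
#' derivation data:
#' * `best_single` maximizes Youden's index (ties broken toward the lower
#'   cutoff);
#' * `rule_out` is the largest cutoff with sensitivity at or above
#'   `se_target` (which maximizes specificity subject to the sensitivity
#'   floor);
#' * `rule_in` is the smallest cutoff with specificity at or above
#'   `sp_target` (maximizing sensitivity subject to the specificity floor).
#'
#' The sensitivity/specificity anchors (defaults 0.85/0.95) are chosen so
#' that, at a planning prevalence of 15%, the projected NPV is >= 95% and
#' PPV >= 75% with accuracy >= 90% (see
#' [predictive_values_at_prevalence()]). An unattainable target yields an
#' `NA` cutoff with `attainable = FALSE`.
#'
#' @param scores Numeric score values (higher = more diseased).
#' @param condition Logical labels; both classes must be present.
#' @param se_target Sensitivity floor for the rule-out cutoff.
#' @param sp_target Specificity floor for the rule-in cutoff.
#' @return Tibble with one row per `role` (`rule_out`, `rule_in`,
#'   `best_single`): `cutoff`, achieved `se`, `sp`, `youden`,
#'   `attainable`.
#' @export
derive_cutoffs <- function(scores, condition, se_target = 0.85,
                           sp_target = 0.95) {
  keep <- !is.na(scores) & !is.na(condition)
  scores <- scores[keep]; condition <- as.logical(condition)[keep]
  if (sum(condition) == 0 || sum(!condition) == 0) {
    abort("both classes must be present to derive cutoffs")
  }
  g <- cutoff_grid(scores, condition) %>%
    mutate(youden = .data$se + .data$sp - 1)

  pick <- function(rows, which_cutoff) {
    if (nrow(rows) == 0) {
      tibble(cutoff = NA_real_, se = NA_real_, sp = NA_real_,
             youden = NA_real_, attainable = FALSE)
    } else {
      r <- if (which_cutoff == "max") {
        rows[which.max(rows$cutoff), ]
      } else {
        rows[which.min(rows$cutoff), ]
      }
      mutate(r, attainable = TRUE)
    }
  }

  best <- g %>% filter(.data$youden == max(.data$youden)) %>% pick("min")
  rule_out <- g %>% filter(.data$se >= se_target) %>%
    filter(.data$sp == max(.data$sp)) %>% pick("min")
  rule_in <- g %>% filter(.data$sp >= sp_target) %>%
    filter(.data$se == max(.data$se)) %>% pick("min")

  bind_rows(
    rule_out = rule_out, rule_in = rule_in, best_single = best,
    .id = "role"
  )
}

#' Derive BMI-band-specific cutoffs with a derivation/validation split
#'
#' Runs the full pipeline: band assignment, stratified 70:30 split,
#' cutoff derivation per band on the derivation subset, and application of
#' the derived cutoffs to the validation subset.
#'
#' @param df Cohort tibble with `bmi` and the score column.
#' @param score Name of the score column (default `"nfs"`).
#' @param condition Logical target labels.
#' @param se_target,sp_target Floors passed to [derive_cutoffs()].
#' @param ratio Derivation fraction.
#' @param bands A [bmi_bands()].
#' @param seed Split seed.
#' @return A `bmi_cutoff_set` object: tibble with one row per band and
#'   role, derived cutoff and achieved metrics in both subsets.
#' @export
derive_bmi_cutoffs <- function(df, score = "nfs", condition,
                               se_target = 0.85, sp_target = 0.95,
                               ratio = 0.7, bands = bmi_bands(),
                               seed = 1L) {
  stopifnot(score %in% names(df))
  keep <- !is.na(df[[score]]) & !is.na(condition)
  df <- df[keep, , drop = FALSE]
  condition <- condition[keep]
  sp <- split_derivation_validation(df, condition, ratio, bands, seed)

  res <- map(levels(sp$bmi_band), function(b) {
    bd <- sp %>% filter(.data$bmi_band == b)
    der <- bd %>% filter(.data$split == "derivation")
    val <- bd %>% filter(.data$split == "validation")
    if (sum(der$.condition) == 0 || sum(!der$.condition) == 0) return(NULL)
    cuts <- derive_cutoffs(der[[score]], der$.condition,
                           se_target, sp_target) %>%
      rename(se_derivation = "se", sp_derivation = "sp")
    val_metrics <- map(cuts$cutoff, function(cc) {
      if (is.na(cc) || sum(val$.condition) == 0 ||
          sum(!val$.condition) == 0) {
        return(tibble(se_validation = NA_real_, sp_validation = NA_real_))
      }
      pos <- val[[score]] >= cc
      tibble(se_validation = mean(pos[val$.condition]),
             sp_validation = mean(!pos[!val$.condition]))
    }) %>% list_rbind()
    dplyr::bind_cols(
      tibble(bmi_band = b, n_derivation = nrow(der),
             n_validation = nrow(val),
             cases_derivation = sum(der$.condition),
             cases_validation = sum(val$.condition)),
      cuts, val_metrics
    )
  }) %>% list_rbind()
  class(res) <- c("bmi_cutoff_set", class(res))
  attr(res, "score") <- score
  res
}

#' Apply BMI-band cutoffs and report stratified performance
#'
#' Produces the application report for a set of band-specific rule-out /
#' rule-in / best-single cutoffs: per band, the subject counts below the
#' rule-out cutoff, between the cutoffs and above the rule-in cutoff
#' (split by condition status), followed by the rule-out screen
#' (score >= rule_out positive), rule-in test (score > rule_in positive)
#' and best-single test (score >= best_single positive) metrics with
#' integer-percent likelihood ratios.
#'
#' @param df Cohort tibble with `bmi` and the score column.
#' @param score Score column name.
#' @param condition Logical target labels.
#' @param cutoffs Tibble with columns `bmi_band`, `role`, `cutoff` (as from
#'   [derive_bmi_cutoffs()]), or a named list
#'   `list(band = c(rule_out=, rule_in=, best_single=))`.
#' @param bands A [bmi_bands()].
#' @param lr_mode Passed to [dx_metrics()]; default `"integer_percent"` to
#'   match published application tables.
#' @return List with `strata` (per-band zone counts) and `metrics`
#'   (per-band, per-role `dx_metrics` rows).
#' @export
validate_cutoffs <- function(df, score, condition, cutoffs,
                             bands = bmi_bands(),
                             lr_mode = "integer_percent") {
  if (is.list(cutoffs) && !is.data.frame(cutoffs)) {
    cutoffs <- imap(cutoffs, ~ tibble(bmi_band = .y,
                                      role = names(.x),
                                      cutoff = unname(.x))) %>% list_rbind()
  }
  keep <- !is.na(df[[score]]) & !is.na(condition)
  df <- df[keep, , drop = FALSE]
  condition <- as.logical(condition)[keep]
  band <- assign_bmi_band(df$bmi, bands)

  one_band <- function(b) {
    sel <- band == b
    x <- df[[score]][sel]; d <- condition[sel]
    cb <- cutoffs %>% filter(.data$bmi_band == b)
    co <- setNames(cb$cutoff, cb$role)
    zvec <- dplyr::case_when(
      x < co[["rule_out"]] ~ "below_rule_out",
      x > co[["rule_in"]] ~ "above_rule_in",
      .default = "indeterminate"
    )
    zones <- c("below_rule_out", "indeterminate", "above_rule_in")
    strata <- tibble(
      zone = zones,
      n = map_dbl(zones, ~ sum(zvec == .x)),
      n_neg = map_dbl(zones, ~ sum(zvec == .x & !d)),
      n_pos = map_dbl(zones, ~ sum(zvec == .x & d)),
      bmi_band = b
    )
    mets <- bind_rows(
      rule_out = dx_metrics(confusion(x >= co[["rule_out"]], d),
                            lr_mode = lr_mode),
      rule_in = dx_metrics(confusion(x > co[["rule_in"]], d),
                           lr_mode = lr_mode),
      best_single = dx_metrics(confusion(x >= co[["best_single"]], d),
                               lr_mode = lr_mode),
      .id = "role"
    ) %>% mutate(bmi_band = b)
    list(strata = strata, metrics = mets)
  }
  parts <- map(intersect(levels(band), unique(cutoffs$bmi_band)), one_band)
  list(
    strata = map(parts, "strata") %>% list_rbind(),
    metrics = map(parts, "metrics") %>% list_rbind()
  )
}
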