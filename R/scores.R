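#' Load the composite-score coefficient tables
#'
#' Coefficients for HFS, ADAPT, FIBC3 and MACK-3 (and the APRI AST upper
#' limit of normal) live in a versioned YAML config transcribed from the
#' source publications of each score; every entry carries a provenance
#' string. Keeping them in data rather than code makes the transcription
#' auditable and overridable.
#'
#' @param path Path to a coefficient YAML file; defaults to the config
#'   shipped with the package.
#' @return A list of per-score coefficient tables (class
#'   `"score_coefficients"`).
#' @export
score_coefficients <- function(path = system.file("extdata",
                                                  "score_coefficients.yaml",
                                                  package = "fibroscores")) {
  cfg <- yaml::read_yaml(path)
  num <- unlist(lapply(cfg[c("hfs", "adapt", "fibc3", "mack3")], function(s) {
    unlist(s[setdiff(names(s), "provenance")])
  }))
  if (any(!is.finite(num))) abort("all score coefficients must be finite")
  structure(cfg, class = "score_coefficients")
}

.check_domain <- function(ok, msg) {
  if (any(!ok, na.rm = TRUE)) {
    abort(msg, class = "fibroscores_domain_error")
  }
}

#' Fibrosis-4 index (FIB-4)
#'
#' `FIB-4 = age x AST / (platelets x sqrt(ALT))`.
#'
#' @param age Age, years.
#' @param ast,alt Aminotransferases, U/L. `alt` must be positive.
#' @param platelets Platelet count, 10^9/L. Must be positive.
#' @return Numeric vector; `NA` where any input is missing.
#' @examples
#' fib4(50, 40, 40, 250) # 1.2649
#' @export
fib4 <- function(age, ast, alt, platelets) {
  .check_domain(alt > 0, "FIB-4 requires ALT > 0")
  .check_domain(platelets > 0, "FIB-4 requires platelets > 0")
  age * ast / (platelets * sqrt(alt))
}

#' NAFLD fibrosis score (NFS)
#'
#' `NFS = -1.675 + 0.037 age + 0.094 BMI + 1.13 IFG/diabetes
#'  + 0.99 AST/ALT - 0.013 platelets - 0.66 albumin`, with albumin in g/dL.
#'
#' @param age Age, years.
#' @param bmi Body mass index, kg/m^2.
#' @param ifg_or_diabetes 0/1 (or logical): impaired fasting glucose or
#'   diabetes present.
#' @param ast,alt Aminotransferases, U/L; `alt` must be positive.
#' @param platelets Platelet count, 10^9/L.
#' @param albumin Serum albumin, g/dL (canonical unit; divide g/L by 10).
#' @return Numeric vector.
#' @examples
#' nfs(50, 30, 1, 40, 40, 250, 4.0) # -0.775
#' @export
nfs <- function(age, bmi, ifg_or_diabetes, ast, alt, platelets, albumin) {
  .check_domain(alt > 0, "NFS requires ALT > 0")
  -1.675 + 0.037 * age + 0.094 * bmi + 1.13 * as.numeric(ifg_or_diabetes) +
    0.99 * ast / alt - 0.013 * platelets - 0.66 * albumin
}

#' AST-to-platelet ratio index (APRI)
#'
#' `APRI = 100 x (AST / ULN) / platelets` with ULN the AST upper limit of
#' normal (default 40 U/L, configurable via [score_coefficients()]).
#'
#' @param ast AST, U/L.
#' @param platelets Platelet count, 10^9/L; must be positive.
#' @param ast_uln AST upper limit of normal, U/L; must be positive.
#' @return Numeric vector.
#' @examples
#' apri(80, 200) # 1.0
#' @export
apri <- function(ast, platelets, ast_uln = 40) {
  .check_domain(ast_uln > 0, "APRI requires a positive AST ULN")
  .check_domain(platelets > 0, "APRI requires platelets > 0")
  100 * (ast / ast_uln) / platelets
}

#' BARD score
#'
#' Points: BMI >= 28 kg/m^2 scores 1, AST/ALT ratio >= 0.8 scores 2,
#' diabetes scores 1; total 0-4.
#'
#' @inheritParams nfs
#' @param diabetes Logical (or 0/1).
#' @return Integer vector in 0..4.
#' @examples
#' bard(29, 36, 40, TRUE) # 4
#' @export
bard <- function(bmi, ast, alt, diabetes) {
  .check_domain(alt > 0, "BARD requires ALT > 0")
  as.integer((bmi >= 28) + 2 * (ast / alt >= 0.8) + as.numeric(diabetes))
}

#' Hepamet fibrosis score (HFS)
#'
#' Logistic score in banded age, sex, AST, albumin, HOMA-IR, diabetes and
#' platelets; output in (0, 1), higher = more fibrosis. Band boundaries use
#' closed lower bounds, per the source publication; coefficients come from
#' the provenance-stamped config (see [score_coefficients()]).
#'
#' @param age Age, years.
#' @param male Logical (or 0/1): male sex.
#' @param ast AST, U/L.
#' @param albumin Albumin, g/dL.
#' @param homa_ir HOMA-IR (see [compute_homa_ir()]).
#' @param diabetes Logical (or 0/1).
#' @param platelets Platelet count, 10^9/L.
#' @param coeffs A [score_coefficients()] object.
#' @return Numeric vector in (0, 1).
#' @export
hfs <- function(age, male, ast, albumin, homa_ir, diabetes, platelets,
                coeffs = score_coefficients()) {
  tr <- coeffs$hfs$terms
  x <- coeffs$hfs$intercept -
    tr$age_45_64 * (age >= 45 & age < 65) -
    tr$age_ge_65 * (age >= 65) -
    tr$male * as.numeric(male) -
    tr$ast_35_69 * (ast >= 35 & ast < 70) -
    tr$ast_ge_70 * (ast >= 70) -
    tr$albumin_4_449 * (albumin >= 4 & albumin < 4.5) -
    tr$albumin_lt_4 * (albumin < 4) -
    tr$homa_2_399 * (homa_ir >= 2 & homa_ir < 4) -
    tr$homa_ge_4 * (homa_ir >= 4) -
    tr$diabetes * as.numeric(diabetes) -
    tr$platelets_155_219 * (platelets >= 155 & platelets < 220) -
    tr$platelets_lt_155 * (platelets < 155)
  1 / (1 + exp(x))
}

#' ADAPT score
#'
#' `ADAPT = exp(log10(age x PRO-C3 / sqrt(platelets))) + diabetes`.
#' Strictly positive and increasing in PRO-C3.
#'
#' @param age Age, years.
#' @param pro_c3 PRO-C3, ng/mL; must be positive.
#' @param platelets Platelet count, 10^9/L; must be positive.
#' @param diabetes Logical (or 0/1).
#' @inheritParams hfs
#' @return Numeric vector > 0.
#' @export
adapt <- function(age, pro_c3, platelets, diabetes,
                  coeffs = score_coefficients()) {
  .check_domain(pro_c3 > 0, "ADAPT requires PRO-C3 > 0")
  .check_domain(platelets > 0, "ADAPT requires platelets > 0")
  exp(log10(age * pro_c3 / sqrt(platelets))) +
    coeffs$adapt$diabetes_points * as.numeric(diabetes)
}

#' FIB-C3 score
#'
#' Linear predictor in age, BMI, diabetes, platelets and PRO-C3.
#'
#' @inheritParams adapt
#' @param bmi Body mass index, kg/m^2.
#' @return Numeric vector.
#' @export
fibc3 <- function(age, bmi, diabetes, platelets, pro_c3,
                  coeffs = score_coefficients()) {
  cf <- coeffs$fibc3
  cf$intercept + cf$age * age + cf$bmi * bmi +
    cf$diabetes * as.numeric(diabetes) +
    cf$platelets * platelets + cf$pro_c3 * pro_c3
}

#' MACK-3 score
#'
#' Logistic score in HOMA-IR, AST and CK-18 M30, designed to detect
#' fibrotic NASH; output in (0, 1).
#'
#' @inheritParams hfs
#' @param ck18_m30 CK-18 M30, U/L.
#' @return Numeric vector in (0, 1).
#' @export
mack3 <- function(homa_ir, ast, ck18_m30, coeffs = score_coefficients()) {
  cf <- coeffs$mack3
  x <- cf$intercept + cf$homa_ir * homa_ir + cf$ast * ast +
    cf$ck18_m30 * ck18_m30
  1 / (1 + exp(-x))
}

#' Compute the eight-score panel for a cohort
#'
#' Adds one column per composite score (`fib4`, `nfs`, `apri`, `bard`,
#' `hfs`, `adapt`, `fibc3`, `mack3`) plus `homa_ir`. A score is missing
#' exactly when one of its required inputs is missing; no imputation is
#' performed, mirroring per-score complete-case analysis.
#'
#' The NFS diabetes/IFG indicator is `diabetes | ifg`; where `ifg` is
#' missing but fasting glucose is present, [read_cohort()] and
#' [generate_cohort()] have already derived it.
#'
#' @param df Canonical cohort tibble (see [cohort_columns]).
#' @param coeffs A [score_coefficients()] object.
#' @return `df` with score columns appended.
#' @examples
#' coh <- generate_cohort(cohort_preset("overweight_obese", n = 50, seed = 1))
#' panel <- score_panel(coh)
#' dplyr::count(panel, is.na(mack3))
#' @export
score_panel <- function(df, coeffs = score_coefficients()) {
  stopifnot(is.data.frame(df))
  homa <- compute_homa_ir(df$glucose_fasting, df$insulin_fasting)
  ifg_dm <- pmax(as.numeric(df$diabetes), as.numeric(df$ifg))
  male <- df$sex == "male"
  df %>%
    mutate(
      homa_ir = homa,
      fib4 = fib4(.data$age, .data$ast, .data$alt, .data$platelets),
      nfs = nfs(.data$age, .data$bmi, ifg_dm, .data$ast, .data$alt,
                .data$platelets, .data$albumin),
      apri = apri(.data$ast, .data$platelets, coeffs$apri$ast_uln),
      bard = bard(.data$bmi, .data$ast, .data$alt, .data$diabetes),
      hfs = hfs(.data$age, male, .data$ast, .data$albumin, homa,
                .data$diabetes, .data$platelets, coeffs),
      adapt = adapt(.data$age, .data$pro_c3, .data$platelets,
                    .data$diabetes, coeffs),
      fibc3 = fibc3(.data$age, .data$bmi, .data$diabetes, .data$platelets,
                    .data$pro_c3, coeffs),
      mack3 = mack3(homa, .data$ast, .data$ck18_m30, coeffs)
    )
}

#' Per-score availability in a panel
#'
#' @param panel Output of [score_panel()].
#' @return Tibble with `score` and `n_available` (complete-input records).
#' @export
score_availability <- function(panel) {
  sc <- c("fib4", "nfs", "apri", "bard", "hfs", "adapt", "fibc3", "mack3")
  tibble(score = sc,
         n_available = map_dbl(sc, ~ sum(!is.na(panel[[.x]]))))
}
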