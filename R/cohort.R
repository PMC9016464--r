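#' Canonical patient-record columns
#'
#' Column names and canonical units used throughout the package. One row per
#' biopsied subject; laboratory values are stored in the units the score
#' formulae expect: albumin g/dL, platelets 10^9/L, glucose mmol/L, insulin
#' mU/L, AST/ALT U/L.
#'
#' @format A named character vector mapping column name to unit ("" for
#'   unitless or categorical fields).
#' @export
cohort_columns <- c(
  id = "", cohort = "",
  age = "years", sex = "male/female", bmi = "kg/m^2",
  ast = "U/L", alt = "U/L", platelets = "10^9/L", albumin = "g/dL",
  glucose_fasting = "mmol/L", insulin_fasting = "mU/L",
  diabetes = "logical", ifg = "logical",
  pro_c3 = "ng/mL", ck18_m30 = "U/L", ck18_m65 = "U/L",
  fibrosis_stage = "F0-F4", nash = "logical", nas = "0-8"
)

.mandatory_cols <- c("age", "sex", "bmi", "ast", "alt", "platelets", "albumin")
.numeric_cols <- c(
  "age", "bmi", "ast", "alt", "platelets", "albumin",
  "glucose_fasting", "insulin_fasting", "pro_c3", "ck18_m30", "ck18_m65",
  "fibrosis_stage", "nas"
)
.logical_cols <- c("diabetes", "ifg", "nash")

#' Read and validate a patient cohort from CSV
#'
#' Reads a patient table, renames columns to the canonical names of
#' [cohort_columns], converts declared units to canonical ones, validates
#' each row against the record invariants and derives impaired fasting
#' glucose (IFG) where only glucose is available. Rows that fail validation
#' are dropped and reported (with row number and reason) in the `rejected`
#' attribute of the result.
#'
#' Supported unit declarations: `albumin` in `"g/dL"` (canonical) or
#' `"g/L"` (divided by 10); `glucose_fasting` in `"mmol/L"` (canonical) or
#' `"mg/dL"` (divided by 18.016). Unit conversion is idempotent: declaring
#' the canonical unit leaves values untouched.
#'
#' @param path Path to a CSV file with a header row.
#' @param col_map Optional named character vector mapping canonical column
#'   names (names) to the file's column names (values), e.g.
#'   `c(ast = "AST_UL")`. Unmapped canonical columns are looked up by their
#'   own name.
#' @param units Optional named character vector declaring the file's units
#'   for `albumin` and/or `glucose_fasting`.
#' @param ifg_glucose_threshold Fasting glucose (mmol/L) at or above which a
#'   subject with no explicit IFG flag is labelled IFG. Default 5.6.
#' @return A tibble of validated records in canonical units, with attributes
#'   `rejected` (tibble of `row`, `reason`) and `n_input`.
#' @seealso [write_cohort()], [validate_cohort()]
#' @export
read_cohort <- function(path, col_map = NULL, units = NULL,
                        ifg_glucose_threshold = 5.6) {
  stopifnot(file.exists(path))
  raw <- readr::read_csv(path, show_col_types = FALSE,
                         col_types = readr::cols(.default = readr::col_character()))
  canon <- names(cohort_columns)
  take <- setNames(canon, canon)
  if (!is.null(col_map)) take[names(col_map)] <- unname(col_map)

  missing_mand <- .mandatory_cols[!take[.mandatory_cols] %in% names(raw)]
  if (length(missing_mand) > 0) {
    abort(paste0("mandatory column(s) missing from ", path, ": ",
                 paste(take[missing_mand], collapse = ", ")),
          class = "fibroscores_schema_error")
  }

  df <- tibble(.rows = nrow(raw))
  for (cc in canon) {
    df[[cc]] <- if (take[[cc]] %in% names(raw)) raw[[take[[cc]]]] else NA_character_
  }
  if (all(is.na(df$id))) df$id <- as.character(seq_len(nrow(df)))

  # type coercion with per-row error capture
  bad <- rep(NA_character_, nrow(df))
  for (cc in .numeric_cols) {
    v <- df[[cc]]
    num <- suppressWarnings(as.numeric(v))
    nonnum <- !is.na(v) & is.na(num)
    bad[nonnum & is.na(bad)] <- paste0("non-numeric value in '", cc, "'")
    df[[cc]] <- num
  }
  for (cc in .logical_cols) {
    v <- tolower(trimws(df[[cc]]))
    lg <- dplyr::case_when(
      v %in% c("true", "t", "1", "yes") ~ TRUE,
      v %in% c("false", "f", "0", "no") ~ FALSE,
      .default = NA
    )
    bad[!is.na(df[[cc]]) & is.na(lg) & is.na(bad)] <-
      paste0("unparseable logical in '", cc, "'")
    df[[cc]] <- lg
  }
  df$sex <- tolower(trimws(df$sex))
  bad[!is.na(df$sex) & !df$sex %in% c("male", "female") & is.na(bad)] <-
    "sex must be 'male' or 'female'"

  # declared unit conversions
  df <- convert_units(df, units)

  # derive IFG from fasting glucose when no explicit flag is present
  df$ifg <- ifelse(is.na(df$ifg) & !is.na(df$glucose_fasting),
                   df$glucose_fasting >= ifg_glucose_threshold, df$ifg)

  chk <- validate_cohort(df)
  bad[is.na(bad) & !is.na(chk)] <- chk[is.na(bad) & !is.na(chk)]

  rejected <- tibble(row = which(!is.na(bad)), reason = bad[!is.na(bad)])
  out <- df[is.na(bad), , drop = FALSE]
  if (nrow(rejected) > 0) {
    inform(paste0(nrow(rejected), " row(s) rejected during validation; ",
                  "see attr(, 'rejected')"))
  }
  attr(out, "rejected") <- rejected
  attr(out, "n_input") <- nrow(raw)
  out
}

# apply declared unit conversions to canonical units; idempotent because the
# canonical declaration is a no-op
convert_units <- function(df, units = NULL) {
  if (is.null(units)) return(df)
  known <- list(
    albumin = c("g/dL" = 1, "g/L" = 0.1),
    glucose_fasting = c("mmol/L" = 1, "mg/dL" = 1 / 18.016)
  )
  for (fld in names(units)) {
    if (!fld %in% names(known)) {
      abort(paste0("no unit conversion defined for field '", fld, "'"))
    }
    u <- units[[fld]]
    if (!u %in% names(known[[fld]])) {
      abort(paste0("unknown unit '", u, "' for field '", fld, "'"))
    }
    df[[fld]] <- df[[fld]] * known[[fld]][[u]]
  }
  df
}

#' Validate cohort records against the record invariants
#'
#' @param df A tibble in canonical columns (see [cohort_columns]).
#' @return A character vector with one element per row: `NA` if the row is
#'   valid, otherwise the first violated invariant.
#' @export
validate_cohort <- function(df) {
  reason <- rep(NA_character_, nrow(df))
  flag <- function(cond, msg) {
    cond[is.na(cond)] <- FALSE
    reason[cond & is.na(reason)] <<- msg
  }
  flag(df$age <= 0, "age must be > 0")
  flag(df$bmi <= 0, "bmi must be > 0")
  flag(df$ast < 0, "ast must be >= 0")
  flag(df$alt < 0, "alt must be >= 0")
  flag(df$platelets <= 0, "platelets must be > 0")
  flag(df$albumin <= 0, "albumin must be > 0")
  flag(!is.na(df$fibrosis_stage) &
         (!df$fibrosis_stage %in% 0:4), "fibrosis_stage must be in 0..4")
  flag(!is.na(df$nas) & (df$nas < 0 | df$nas > 8 | df$nas != round(df$nas)),
       "nas must be an integer in 0..8")
  flag(is.na(df$age), "age is mandatory")
  flag(is.na(df$bmi), "bmi is mandatory")
  reason
}

#' Write a cohort back to CSV in canonical units
#'
#' Inverse of [read_cohort()] for already-canonical data: a read/write
#' round-trip reproduces canonical values exactly.
#'
#' @param df Canonical cohort tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(df, path) {
  readr::write_csv(df[, intersect(names(cohort_columns), names(df))], path)
  invisible(path)
}

#' Homeostasis model assessment of insulin resistance (HOMA-IR)
#'
#' `HOMA-IR = glucose (mmol/L) x insulin (mU/L) / 22.5`. Missing inputs
#' give a missing result; negative inputs are a domain error.
#'
#' @param glucose_fasting Fasting glucose, mmol/L.
#' @param insulin_fasting Fasting insulin, mU/L.
#' @return Numeric vector of HOMA-IR values (unitless).
#' @examples
#' compute_homa_ir(6.1, 15) # 4.067
#' @export
compute_homa_ir <- function(glucose_fasting, insulin_fasting) {
  if (any(glucose_fasting < 0, na.rm = TRUE) ||
      any(insulin_fasting < 0, na.rm = TRUE)) {
    abort("glucose and insulin must be non-negative",
          class = "fibroscores_domain_error")
  }
  glucose_fasting * insulin_fasting / 22.5
}

#' Histological target conditions
#'
#' Returns the reference-standard label for each record:
#' * `advanced_fibrosis`: stage F3-F4,
#' * `significant_fibrosis`: stage F2-F4,
#' * `fibrotic_nash`: NASH with NAFLD Activity Score >= 4 and stage >= F2.
#'
#' @param df Canonical cohort tibble with histology columns.
#' @param condition One of `"advanced_fibrosis"`, `"significant_fibrosis"`,
#'   `"fibrotic_nash"`.
#' @return Logical vector (`NA` where the needed histology is missing).
#' @export
target_label <- function(df,
                         condition = c("advanced_fibrosis",
                                       "significant_fibrosis",
                                       "fibrotic_nash")) {
  condition <- arg_match(condition)
  switch(condition,
    advanced_fibrosis = df$fibrosis_stage >= 3,
    significant_fibrosis = df$fibrosis_stage >= 2,
    fibrotic_nash = df$nash & df$nas >= 4 & df$fibrosis_stage >= 2
  )
}
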