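# Cohort tables: one row per patient with clinical variables and outcomes.
#
# Canonical CSV header (empty field = missing):
#   id,sex,age_years,ct_grade,days_since_injury,gcs_total,gose_3mo,gose_6mo
# CT grade follows the Marshall-style 1-6 coding (1 = no visible intracranial
# pathology, 6 = non-evacuated mass lesion); GCS total is 3-15; GOSE is the
# 8-level extended Glasgow Outcome Scale (1 = death ... 8 = upper good
# recovery). Feature columns extracted from EEG may be appended later.

COHORT_COLUMNS <- c("id", "sex", "age_years", "ct_grade", "days_since_injury",
                    "gcs_total", "gose_3mo", "gose_6mo")

#' Validate a cohort table
#'
#' Checks uniqueness of patient ids and the admissible ranges of CT grade
#' (1-6), total GCS (3-15) and GOSE (1-8, missing allowed).
#'
#' @param df data frame with at least the canonical cohort columns.
#' @return `df`, invisibly, with class `cohort_table` prepended.
#' @export
validate_cohort <- function(df) {
  missing_cols <- setdiff(COHORT_COLUMNS, names(df))
  if (length(missing_cols))
    stop_eegprog("cohort table missing columns: %s",
                 paste(missing_cols, collapse = ", "), class = "eegprog_cohort")
  if (nrow(df) == 0)
    stop_eegprog("cohort table has no rows", class = "eegprog_cohort")
  if (anyDuplicated(df$id))
    stop_eegprog("duplicate patient ids: %s",
                 paste(unique(df$id[duplicated(df$id)]), collapse = ", "),
                 class = "eegprog_cohort")
  bad_range <- function(x, lo, hi, what) {
    bad <- !is.na(x) & (x < lo | x > hi | x != round(x))
    if (any(bad))
      stop_eegprog("%s out of range %d-%d for id(s): %s", what, lo, hi,
                   paste(df$id[bad], collapse = ", "), class = "eegprog_cohort")
  }
  bad_range(df$ct_grade, 1, 6, "ct_grade")
  bad_range(df$gcs_total, 3, 15, "gcs_total")
  bad_range(df$gose_3mo, 1, 8, "gose_3mo")
  bad_range(df$gose_6mo, 1, 8, "gose_6mo")
  if (anyNA(df$ct_grade) || anyNA(df$gcs_total))
    stop_eegprog("ct_grade and gcs_total must not be missing; offending id(s): %s",
                 paste(df$id[is.na(df$ct_grade) | is.na(df$gcs_total)], collapse = ", "),
                 class = "eegprog_cohort")
  if (!inherits(df, "cohort_table")) class(df) <- c("cohort_table", class(df))
  invisible(df)
}

#' Read a cohort CSV
#'
#' @param path CSV file with the canonical header
#'   `id,sex,age_years,ct_grade,days_since_injury,gcs_total,gose_3mo,gose_6mo`;
#'   empty fields are missing values. Extra (feature) columns are preserved.
#' @return A validated `cohort_table` data frame.
#' @export
read_cohort <- function(path) {
  if (!file.exists(path))
    stop_eegprog("cohort file not found: %s", path, class = "eegprog_cohort")
  df <- tryCatch(utils::read.csv(path, stringsAsFactors = FALSE, na.strings = ""),
                 error = function(e) stop_eegprog("cannot parse cohort CSV %s: %s",
                                                  path, conditionMessage(e),
                                                  class = "eegprog_cohort"))
  if (nrow(df) == 0)
    stop_eegprog("cohort file %s has no data rows", path, class = "eegprog_cohort")
  for (col in c("age_years", "ct_grade", "days_since_injury",
                "gcs_total", "gose_3mo", "gose_6mo"))
    if (col %in% names(df)) df[[col]] <- as.numeric(df[[col]])
  df$id <- as.character(df$id)
  df$sex <- as.character(df$sex)
  validate_cohort(df)
  df
}

#' Write a cohort table as CSV
#' @param df a cohort table.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(df, path) {
  validate_cohort(as.data.frame(df))
  utils::write.csv(as.data.frame(df), path, row.names = FALSE, na = "")
  invisible(path)
}

#' Path to the bundled example cohort table
#'
#' An 18-patient acute traumatic brain injury cohort (demographics, CT grade,
#' days since injury, total GCS at EEG, and GOSE outcomes at 3 and 6 months;
#' one patient lost to 6-month follow-up), used in examples and for the
#' descriptive statistics recomputed by the acceptance script.
#' @return file path of the CSV.
#' @export
example_cohort_path <- function() {
  system.file("extdata", "cohort_tbi18.csv", package = "eegprog", mustWork = TRUE)
}
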