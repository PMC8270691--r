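CLINICAL_COLUMNS <- c(
  "patient_id", "sample_id", "time_days", "sledai", "state", "age_group",
  "sex", "race", "drug_cs", "drug_hc", "drug_is", "drug_ifnk", "cohort"
)

#' Read a per-visit clinical table
#'
#' Reads the normalized longitudinal clinical schema: one row per visit with
#' patient id, sample id, days since baseline, SLEDAI score, disease state
#' (`SLE`/`healthy`), demographics (`age_group`, `sex`, `race`), drug
#' exposure flags (`drug_cs`, `drug_hc`, `drug_is`, `drug_ifnk`) and a
#' `cohort` label. Rows are re-sorted by `time_days` within patient and a
#' 0-based `visit_index` is (re)assigned. An empty SLEDAI cell is read as
#' missing (never as 0, since 0 is a valid score); non-numeric SLEDAI is
#' flagged missing as well, and exclusion of incomplete patients is handled
#' downstream by [exclude_patients()].
#'
#' @param path Path to a CSV file with the required column names.
#' @return A validated `data.frame`, one row per visit.
#' @seealso [write_clinical()], [validate_clinical()]
#' @export
read_clinical <- function(path) {
  if (!file.exists(path)) stop_("clinical file not found: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(CLINICAL_COLUMNS, names(df))
  if (length(missing_cols)) {
    stop_("clinical table is missing required column(s): %s",
          paste(missing_cols, collapse = ", "))
  }
  # empty or unparseable SLEDAI becomes missing (0 is a valid score and is
  # never used as a missing-value sentinel)
  df$sledai <- suppressWarnings(as.numeric(as.character(df$sledai)))
  for (d in c("drug_cs", "drug_hc", "drug_is", "drug_ifnk")) {
    df[[d]] <- as.logical(df[[d]])
  }
  df$time_days <- as.numeric(df$time_days)
  df <- resort_visits(df)
  validate_clinical(df)
}

#' Write a clinical table as CSV
#' @param clinical Clinical `data.frame` (see [read_clinical()] for schema).
#' @param path Output path.
#' @export
write_clinical <- function(clinical, path) {
  utils::write.csv(clinical, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# Sort visits within patient by time and reassign 0-based visit_index.
#' @noRd
resort_visits <- function(df) {
  ord <- order(df$patient_id, df$time_days)
  df <- df[ord, , drop = FALSE]
  df$visit_index <- stats::ave(df$time_days, df$patient_id,
                               FUN = function(t) seq_along(t) - 1L)
  rownames(df) <- NULL
  df
}

#' Validate a clinical table
#'
#' Enforces the schema invariants: unique sample ids, known `state` levels,
#' non-negative times, SLEDAI within \[0, 105\] when present, healthy rows
#' with SLEDAI exactly 0, and strictly increasing visit indices per patient.
#'
#' @param clinical Clinical `data.frame`.
#' @return The table, invisibly (invisibly returned so it can be chained).
#' @export
validate_clinical <- function(clinical) {
  if (anyDuplicated(clinical$sample_id)) {
    stop_("duplicated sample_id in clinical table")
  }
  if (!all(clinical$state %in% c("SLE", "healthy"))) {
    stop_("state must be 'SLE' or 'healthy'")
  }
  if (any(clinical$time_days < 0, na.rm = TRUE)) stop_("negative time_days")
  sl <- clinical$sledai
  if (any(sl < 0 | sl > 105, na.rm = TRUE)) {
    stop_("SLEDAI outside [0, 105]")
  }
  healthy <- clinical$state == "healthy"
  if (any(healthy & (is.na(sl) | sl != 0))) {
    stop_("healthy rows must have SLEDAI = 0")
  }
  inc <- tapply(clinical$visit_index, clinical$patient_id,
                function(v) all(diff(v) > 0) || length(v) == 1)
  if (!all(unlist(inc))) stop_("visit_index not strictly increasing within patient")
  invisible(clinical)
}
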