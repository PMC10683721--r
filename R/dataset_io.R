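# CSV round-trip of patient tables plus a ground-truth JSON sidecar.

patient_schema_columns <- function() {
  c("arrival_to_scan", "infarction", "nihss", "precise_onset", "prior_mrs",
    "stroke_team", "anticoagulant", "onset_to_arrival", "onset_during_sleep",
    "age")
}

#' Validate a patient table against the dataset schema
#'
#' Checks the presence of the ten model features (plus the label when
#' `require_label`), rejects unknown non-decoy columns, and checks every
#' feature against its declared domain. Errors name the offending column.
#'
#' @param table A data.frame.
#' @param require_label Require the binary `thrombolysis` column.
#' @return The table, invisibly, when valid.
#' @export
validate_patient_table <- function(table, require_label = TRUE) {
  required <- patient_schema_columns()
  if (require_label) required <- c(required, "thrombolysis")
  missing <- setdiff(required, names(table))
  if (length(missing)) {
    stop("schema error: missing column(s) ", paste0("`", missing, "`", collapse = ", "))
  }
  extra <- setdiff(names(table), c(required, "thrombolysis"))
  bad_extra <- extra[!grepl("^decoy_[0-9]+$", extra)]
  if (length(bad_extra)) {
    stop("schema error: unknown column(s) ",
         paste0("`", bad_extra, "`", collapse = ", "))
  }
  if (nrow(table) == 0) return(invisible(table))
  doms <- feature_domains()
  for (f in names(doms)) {
    if (!all(doms[[f]](table[[f]]))) {
      stop("schema error: column `", f, "` contains out-of-domain values")
    }
  }
  if (!is.character(table$stroke_team) && !is.factor(table$stroke_team)) {
    stop("schema error: column `stroke_team` must be character")
  }
  if (require_label && !all(table$thrombolysis %in% c(0, 1))) {
    stop("schema error: column `thrombolysis` must be binary 0/1")
  }
  if (require_label &&
      any(table$thrombolysis == 1 & table$infarction == 0)) {
    stop("schema error: column `thrombolysis` is 1 for a haemorrhagic record")
  }
  invisible(table)
}

#' Write a patient table (and optional ground-truth sidecar) to CSV
#'
#' @param table Schema-conformant labelled patient table.
#' @param path CSV destination.
#' @param truth Optional list of ground-truth quantities (hospital offsets,
#'   effect parameters, config); written as JSON to `<path>.truth.json`.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(table, path, truth = NULL) {
  validate_patient_table(table)
  utils::write.csv(table, path, row.names = FALSE)
  if (!is.null(truth)) {
    truth <- truth[!vapply(truth, is.function, TRUE)]
    jsonlite::write_json(truth, paste0(path, ".truth.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(path)
}

#' Read and validate a patient table from CSV
#'
#' @param path CSV produced by [write_dataset()].
#' @return Validated patient table.
#' @export
read_dataset <- function(path) {
  table <- utils::read.csv(path, stringsAsFactors = FALSE)
  table$stroke_team <- as.character(table$stroke_team)
  for (col in c("nihss", "prior_mrs", "thrombolysis")) {
    if (col %in% names(table)) table[[col]] <- as.integer(table[[col]])
  }
  validate_patient_table(table)
  table
}
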