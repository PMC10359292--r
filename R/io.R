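trial_csv_columns <- c(
  "session", "block", "condition", "stimulus_id", "p_self", "p_partner",
  "outcome", "trial_index"
)

#' Read and write trial tables as CSV
#'
#' The trial CSV schema has columns `session`, `block`, `condition`,
#' `stimulus_id`, `p_self`, `p_partner`, `outcome`, `trial_index`. Reading
#' validates the schema and fails with a named error on missing columns.
#'
#' @param trials Trial tibble.
#' @param path File path.
#' @return `read_trial_csv()` returns the trial tibble.
#' @export
write_trial_csv <- function(trials, path) {
  missing_cols <- setdiff(trial_csv_columns, names(trials))
  if (length(missing_cols) > 0) {
    abort(sprintf("Trial table lacks column(s): %s",
                  paste(missing_cols, collapse = ", ")))
  }
  readr::write_csv(trials[trial_csv_columns], path)
  invisible(path)
}

#' @rdname write_trial_csv
#' @export
read_trial_csv <- function(path) {
  trials <- readr::read_csv(path, show_col_types = FALSE)
  missing_cols <- setdiff(trial_csv_columns, names(trials))
  if (length(missing_cols) > 0) {
    abort(sprintf("Trial CSV lacks column(s): %s",
                  paste(missing_cols, collapse = ", ")))
  }
  trials
}

#' Read and write signal containers
#'
#' Lick, gaze and LFP objects are stored as single-object RDS containers
#' tagged with a schema name, preserving all numeric payloads losslessly.
#'
#' @param x A `lick_data`, `gaze_data` or `lfp_data` object.
#' @param path File path.
#' @return `read_signals()` returns the stored object after checking its
#'   class tag.
#' @export
write_signals <- function(x, path) {
  if (!inherits(x, c("lick_data", "gaze_data", "lfp_data"))) {
    abort("`x` must be a lick_data, gaze_data or lfp_data object.")
  }
  saveRDS(x, path)
  invisible(path)
}

#' @rdname write_signals
#' @export
read_signals <- function(path) {
  x <- readRDS(path)
  if (!inherits(x, c("lick_data", "gaze_data", "lfp_data"))) {
    abort("File does not contain a recognised signal container.")
  }
  x
}

#' Write and read a study report as JSON
#'
#' @param report A `study_report` (or any list of summaries).
#' @param path File path.
#' @return `read_report()` returns the parsed list.
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, force = TRUE)
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
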