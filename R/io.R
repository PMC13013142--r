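#' Read a call table from CSV
#'
#' The canonical on-disk format is UTF-8, comma-separated, with a header
#' row. Required columns: `context`, `individual_id`, `sequence_id`,
#' `position`, `duration_s`; optional columns `cue_number`, `correct`,
#' `onset_s`, `offset_s` are picked up when present. All invariants of
#' [call_table()] are checked on read and violations are reported with the
#' offending rows or sequence ids.
#'
#' @param path Path to a CSV file.
#' @return A validated [call_table()].
#' @export
read_call_table <- function(path) {
  if (!file.exists(path)) {
    stop_menzerath("io_error", sprintf("file not found: %s", path))
  }
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         fileEncoding = "UTF-8")
  optional <- c("cue_number", "correct", "onset_s", "offset_s")
  for (col in intersect(optional, names(raw))) {
    raw[[col]] <- switch(col,
      cue_number = as.integer(raw[[col]]),
      correct = as.logical(raw[[col]]),
      as.numeric(raw[[col]]))
  }
  call_table(raw)
}

#' Write a call table to CSV
#'
#' Numeric columns are written with 17 significant digits so that a
#' write/read round trip reproduces every field bit-exactly.
#'
#' @param table A [call_table()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_call_table <- function(table, path) {
  stopifnot(inherits(table, "call_table"))
  out <- as.data.frame(table)
  for (col in names(out)) {
    if (is.double(out[[col]])) {
      out[[col]] <- ifelse(is.na(out[[col]]), NA,
                           sprintf("%.17g", out[[col]]))
    }
  }
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE,
                   fileEncoding = "UTF-8", na = "")
  invisible(path)
}

#' Write a trial table (participant, cue number, outcome) to CSV
#'
#' @param trials A data frame as returned by [simulate_trials()], with
#'   columns `participant_id`, `cue_number`, `correct`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trial_table <- function(trials, path) {
  stopifnot(all(c("participant_id", "cue_number", "correct") %in%
                  names(trials)))
  utils::write.csv(trials, path, row.names = FALSE, quote = TRUE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a trial table from CSV
#'
#' @param path Path to a CSV file with columns `participant_id`,
#'   `cue_number`, `correct`.
#' @return A data frame.
#' @export
read_trial_table <- function(path) {
  if (!file.exists(path)) {
    stop_menzerath("io_error", sprintf("file not found: %s", path))
  }
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         fileEncoding = "UTF-8")
  required <- c("participant_id", "cue_number", "correct")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0L) {
    stop_menzerath("format_error",
      sprintf("trial table is missing column(s): %s",
              paste(missing_cols, collapse = ", ")))
  }
  raw$participant_id <- as.character(raw$participant_id)
  raw$cue_number <- as.integer(raw$cue_number)
  raw$correct <- as.logical(raw$correct)
  raw
}
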