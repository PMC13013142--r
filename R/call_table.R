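#' Construct a validated call table
#'
#' A call table is the package's universal exchange format: one row per
#' vocalization, tagged with the identifiers the mixed model needs as
#' grouping factors. Columns:
#'
#' * `context` — dataset label, e.g. `"trained_crow"`, `"wild_crow"`, `"human"`.
#' * `individual_id` — the bird / recording / participant producing the call
#'   (the individual random-intercept grouping).
#' * `sequence_id` — the sequence (trial or bout) the call belongs to (the
#'   sequence random-intercept grouping).
#' * `position` — 1-based ordinal position of the call within its sequence.
#' * `duration_s` — call duration in seconds (> 0).
#' * optional: `cue_number` (integer >= 1), `correct` (logical),
#'   `onset_s` / `offset_s` (reals with `offset_s > onset_s`).
#'
#' Invariants enforced: positive durations; within every sequence the
#' positions are exactly `1..n` with no gaps or duplicates; each sequence
#' maps to a single individual and a single context; where onset/offset are
#' present, `duration_s` equals `offset_s - onset_s` to within 1e-6 s.
#'
#' @param x A data frame with the columns above.
#' @return An object of class `call_table` (a data frame).
#' @seealso [read_call_table()], [filter_calls()], [sequence_sizes()]
#' @export
call_table <- function(x) {
  x <- as.data.frame(x, stringsAsFactors = FALSE)
  required <- c("context", "individual_id", "sequence_id", "position", "duration_s")
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols) > 0L) {
    stop_menzerath("format_error",
      sprintf("call table is missing required column(s): %s",
              paste(missing_cols, collapse = ", ")))
  }
  x$context <- as.character(x$context)
  x$individual_id <- as.character(x$individual_id)
  x$sequence_id <- as.character(x$sequence_id)
  x$position <- as.integer(x$position)
  x$duration_s <- as.numeric(x$duration_s)
  validate_call_table(x)
  x <- x[order_sequences(x), , drop = FALSE]
  rownames(x) <- NULL
  class(x) <- c("call_table", "data.frame")
  x
}

# stable ordering: by sequence (first appearance) then position
order_sequences <- function(x) {
  first_seen <- match(x$sequence_id, unique(x$sequence_id))
  order(first_seen, x$position)
}

validate_call_table <- function(x) {
  bad_dur <- which(!is.finite(x$duration_s) | x$duration_s <= 0)
  if (length(bad_dur) > 0L) {
    stop_menzerath("validation_error",
      sprintf("non-positive or missing duration_s in row(s): %s",
              paste(utils::head(bad_dur, 20L), collapse = ", ")))
  }
  bad_pos <- which(is.na(x$position) | x$position < 1L)
  if (length(bad_pos) > 0L) {
    stop_menzerath("validation_error",
      sprintf("position < 1 or missing in row(s): %s",
              paste(utils::head(bad_pos, 20L), collapse = ", ")))
  }
  pos_by_seq <- split(x$position, x$sequence_id)
  bad_seq <- names(pos_by_seq)[!vapply(pos_by_seq, function(p) {
    identical(sort(p), seq_len(length(p)))
  }, logical(1L))]
  if (length(bad_seq) > 0L) {
    stop_menzerath("validation_error",
      sprintf("sequence(s) with gapped or duplicated positions: %s",
              paste(utils::head(bad_seq, 20L), collapse = ", ")))
  }
  ind_by_seq <- vapply(split(x$individual_id, x$sequence_id),
                       function(v) length(unique(v)), integer(1L))
  if (any(ind_by_seq > 1L)) {
    stop_menzerath("validation_error",
      sprintf("sequence(s) spanning multiple individuals: %s",
              paste(utils::head(names(ind_by_seq)[ind_by_seq > 1L], 20L),
                    collapse = ", ")))
  }
  ctx_by_seq <- vapply(split(x$context, x$sequence_id),
                       function(v) length(unique(v)), integer(1L))
  if (any(ctx_by_seq > 1L)) {
    stop_menzerath("validation_error",
      sprintf("sequence(s) spanning multiple contexts: %s",
              paste(utils::head(names(ctx_by_seq)[ctx_by_seq > 1L], 20L),
                    collapse = ", ")))
  }
  if (all(c("onset_s", "offset_s") %in% names(x))) {
    has_times <- !is.na(x$onset_s) & !is.na(x$offset_s)
    mismatch <- which(has_times &
      abs((x$offset_s - x$onset_s) - x$duration_s) > 1e-6)
    if (length(mismatch) > 0L) {
      stop_menzerath("validation_error",
        sprintf("duration_s != offset_s - onset_s (tol 1e-6 s) in row(s): %s",
                paste(utils::head(mismatch, 20L), collapse = ", ")))
    }
  }
  invisible(x)
}

#' Number of calls in each sequence
#'
#' @param table A [call_table()].
#' @return A named integer vector, one element per sequence (in order of
#'   first appearance), giving the sequence size `n_j`.
#' @export
sequence_sizes <- function(table) {
  stopifnot(inherits(table, "call_table"))
  ids <- unique(table$sequence_id)
  n <- vapply(split(table$position, table$sequence_id)[ids], max, integer(1L))
  n
}

# attach per-row seq_size, log_size, position_cat columns used by the model
model_frame_calls <- function(table) {
  n <- sequence_sizes(table)
  data.frame(
    log_dur = log(table$duration_s),
    log_size = log(as.numeric(n[table$sequence_id])),
    position = as.numeric(table$position),
    position_cat = factor(table$position),
    sequence_id = factor(table$sequence_id),
    individual_id = factor(table$individual_id),
    stringsAsFactors = FALSE
  )
}

#' Subset a call table by context, sequence size, or trial outcome
#'
#' `exclude_singles` drops every sequence of size one; linguistic studies of
#' Menzerath's law often exclude these because a single element coincides
#' with the whole sequence. Error trials are kept by default (the default
#' analysis uses all trials); `correct_only` is an explicit opt-in and
#' requires a `correct` column.
#'
#' @param table A [call_table()].
#' @param context Optional context label to keep.
#' @param exclude_singles Drop sequences with a single call?
#' @param correct_only Keep only correct trials?
#' @return A [call_table()] subset. An empty result is an error of class
#'   `menzerath_empty_table`, never a silent zero-row table.
#' @export
filter_calls <- function(table, context = NULL, exclude_singles = FALSE,
                         correct_only = FALSE) {
  stopifnot(inherits(table, "call_table"))
  keep <- rep(TRUE, nrow(table))
  if (!is.null(context)) keep <- keep & table$context %in% context
  if (correct_only) {
    if (!"correct" %in% names(table)) {
      stop_menzerath("format_error",
        "correct_only = TRUE but the table has no 'correct' column")
    }
    keep <- keep & !is.na(table$correct) & table$correct
  }
  out <- table[keep, , drop = FALSE]
  if (exclude_singles && nrow(out) > 0L) {
    class(out) <- c("call_table", "data.frame")
    n <- sequence_sizes(out)
    out <- out[n[out$sequence_id] >= 2L, , drop = FALSE]
  }
  if (nrow(out) == 0L) {
    stop_menzerath("empty_table",
      "filter removed every call; no table to analyse")
  }
  rownames(out) <- NULL
  class(out) <- c("call_table", "data.frame")
  out
}

#' @export
summary.call_table <- function(object, ...) {
  n_seq_by_ind <- vapply(
    split(object$sequence_id, object$individual_id),
    function(v) length(unique(v)), integer(1L))
  n_call_by_ind <- vapply(split(seq_len(nrow(object)), object$individual_id),
                          length, integer(1L))
  per_individual <- data.frame(
    individual_id = names(n_call_by_ind),
    n_calls = as.integer(n_call_by_ind),
    n_sequences = as.integer(n_seq_by_ind[names(n_call_by_ind)]),
    row.names = NULL, stringsAsFactors = FALSE
  )
  sizes <- sequence_sizes(object)
  out <- list(
    n_calls = nrow(object),
    n_sequences = length(unique(object$sequence_id)),
    n_individuals = length(unique(object$individual_id)),
    contexts = sort(unique(object$context)),
    size_table = table(sizes),
    per_individual = per_individual
  )
  class(out) <- "summary.call_table"
  out
}

#' @export
print.summary.call_table <- function(x, ...) {
  cat("Call table:", x$n_calls, "vocalizations,", x$n_sequences,
      "sequences,", x$n_individuals, "individuals\n")
  cat("Context(s):", paste(x$contexts, collapse = ", "), "\n")
  cat("Sequence sizes:\n")
  print(x$size_table)
  cat("Per individual:\n")
  print(x$per_individual, row.names = FALSE)
  invisible(x)
}

#' @export
print.call_table <- function(x, ...) {
  cat(sprintf("<call_table: %d calls, %d sequences, %d individuals>\n",
              nrow(x), length(unique(x$sequence_id)),
              length(unique(x$individual_id))))
  NextMethod()
}

# classed conditions so callers can distinguish failure modes
stop_menzerath <- function(subclass, message) {
  stop(structure(
    class = c(paste0("menzerath_", subclass), "menzerath_error",
              "error", "condition"),
    list(message = message, call = sys.call(-1))
  ))
}
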