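#' Pearson correlation of first/last call duration with sequence size
#'
#' One point per sequence: the duration of the first (position 1) and last
#' (position n) call against the sequence size n. For singleton sequences the
#' single call serves as both first and last; set `include_singles = FALSE`
#' to drop them.
#'
#' @param table A [call_table()].
#' @param include_singles Include sequences of size one (default `TRUE`)?
#' @return An object of class `boundary_correlation` with elements `r_first`,
#'   `p_first`, `r_last`, `p_last`, `n_sequences_used`.
#' @export
first_last_correlation <- function(table, include_singles = TRUE) {
  stopifnot(inherits(table, "call_table"))
  if (!include_singles) table <- filter_calls(table, exclude_singles = TRUE)
  sizes <- sequence_sizes(table)
  by_seq <- split(table[, c("position", "duration_s")], table$sequence_id)
  ids <- names(sizes)
  first_d <- vapply(ids, function(id) {
    d <- by_seq[[id]]; d$duration_s[d$position == 1L]
  }, numeric(1L))
  last_d <- vapply(ids, function(id) {
    d <- by_seq[[id]]; d$duration_s[d$position == max(d$position)]
  }, numeric(1L))
  n <- as.numeric(sizes)
  if (length(n) < 3L || length(unique(n)) < 2L) {
    stop_menzerath("model_error",
      "need >= 3 sequences with >= 2 distinct sizes for the correlation")
  }
  if (stats::sd(first_d) == 0 || stats::sd(last_d) == 0) {
    stop_menzerath("degenerate_error",
      "zero variance in first/last call durations: correlation undefined")
  }
  ct_first <- stats::cor.test(first_d, n, method = "pearson")
  ct_last <- stats::cor.test(last_d, n, method = "pearson")
  structure(list(
    r_first = unname(ct_first$estimate),
    p_first = ct_first$p.value,
    r_last = unname(ct_last$estimate),
    p_last = ct_last$p.value,
    n_sequences_used = length(n)
  ), class = "boundary_correlation")
}

#' @export
print.boundary_correlation <- function(x, ...) {
  cat(sprintf("First/last call duration vs sequence size (n = %d sequences)\n",
              x$n_sequences_used))
  cat(sprintf("  first: r = %+0.3f, p = %0.4g\n", x$r_first, x$p_first))
  cat(sprintf("  last:  r = %+0.3f, p = %0.4g\n", x$r_last, x$p_last))
  invisible(x)
}

#' Final-lengthening test on relative call durations
#'
#' For every sequence with at least two calls, each call's relative duration
#' is its duration divided by the mean duration of its sequence (so relative
#' durations average to 1 within a sequence). The relative duration of the
#' final call is then compared with the mean relative duration of the
#' non-final calls across sequences with a paired t-test (sequences as the
#' unit of analysis, df = number of sequences - 1). A positive t indicates
#' final lengthening. Singleton sequences are excluded: their only call is
#' the sequence mean, leaving no non-final partner.
#'
#' If every paired difference is exactly zero (all calls in every sequence
#' equal), the result is reported as `t = 0`, `p = 1`.
#'
#' @param table A [call_table()].
#' @return An object of class `final_lengthening` with elements
#'   `mean_relative_final`, `mean_relative_nonfinal`, `t_statistic`, `df`,
#'   `p_value`, `n_sequences`.
#' @export
final_lengthening_test <- function(table) {
  stopifnot(inherits(table, "call_table"))
  sizes <- sequence_sizes(table)
  multi <- names(sizes)[sizes >= 2L]
  if (length(multi) < 2L) {
    stop_menzerath("model_error",
      "need >= 2 sequences with >= 2 calls for the paired test")
  }
  by_seq <- split(table[, c("position", "duration_s")], table$sequence_id)
  rel_final <- numeric(length(multi))
  rel_nonfinal <- numeric(length(multi))
  for (i in seq_along(multi)) {
    d <- by_seq[[multi[i]]]
    d <- d[order(d$position), , drop = FALSE]
    rel <- d$duration_s / mean(d$duration_s)
    rel_final[i] <- rel[length(rel)]
    rel_nonfinal[i] <- mean(rel[-length(rel)])
  }
  diffs <- rel_final - rel_nonfinal
  df <- length(diffs) - 1L
  if (all(diffs == 0)) {
    tt <- list(statistic = 0, p.value = 1)
  } else {
    ht <- stats::t.test(rel_final, rel_nonfinal, paired = TRUE)
    tt <- list(statistic = unname(ht$statistic), p.value = ht$p.value)
  }
  structure(list(
    mean_relative_final = mean(rel_final),
    mean_relative_nonfinal = mean(rel_nonfinal),
    t_statistic = tt$statistic,
    df = df,
    p_value = tt$p.value,
    n_sequences = length(multi)
  ), class = "final_lengthening")
}

#' @export
print.final_lengthening <- function(x, ...) {
  cat(sprintf("Final lengthening (paired t over %d sequences)\n",
              x$n_sequences))
  cat(sprintf("  mean relative final %0.4f vs non-final %0.4f\n",
              x$mean_relative_final, x$mean_relative_nonfinal))
  cat(sprintf("  t(%d) = %0.3f, p = %0.4g\n", x$df, x$t_statistic,
              x$p_value))
  invisible(x)
}

#' Mean first/last call duration by sequence size
#'
#' Support table for boundary-prosody plots: for each sequence size, the mean
#' (and SEM) of first- and last-call durations.
#'
#' @param table A [call_table()].
#' @return A data frame with columns `size`, `mean_first`, `sem_first`,
#'   `mean_last`, `sem_last`, `n_sequences`.
#' @export
boundary_profile <- function(table) {
  stopifnot(inherits(table, "call_table"))
  sizes <- sequence_sizes(table)
  by_seq <- split(table[, c("position", "duration_s")], table$sequence_id)
  ids <- names(sizes)
  first_d <- vapply(ids, function(id) {
    d <- by_seq[[id]]; d$duration_s[d$position == 1L]
  }, numeric(1L))
  last_d <- vapply(ids, function(id) {
    d <- by_seq[[id]]; d$duration_s[d$position == max(d$position)]
  }, numeric(1L))
  sem <- function(v) if (length(v) > 1L) stats::sd(v) / sqrt(length(v)) else NA_real_
  out <- do.call(rbind, lapply(sort(unique(sizes)), function(s) {
    sel <- sizes == s
    data.frame(size = s,
               mean_first = mean(first_d[sel]), sem_first = sem(first_d[sel]),
               mean_last = mean(last_d[sel]), sem_last = sem(last_d[sel]),
               n_sequences = sum(sel))
  }))
  rownames(out) <- NULL
  out
}
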