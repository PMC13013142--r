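#' Shuffle null distribution of the Menzerath slopes
#'
#' Monte-Carlo null without production constraints: in each iteration the
#' call durations are permuted among all calls of the same individual (the
#' sequence scaffold — sizes, positions, ids — is untouched), the mixed model
#' is refit, and the size and position slopes are recorded. Shuffling
#' destroys any association between duration and sequence size/position
#' while conserving every individual's duration multiset.
#'
#' Because the model structure is identical across iterations, refits reuse
#' the observed model's design via [lme4::refit()].
#'
#' @param table A [call_table()].
#' @param n_iter Number of Monte-Carlo iterations (default 1000).
#' @param seed Integer seed; the slope arrays are reproducible from it.
#' @param include_singles,reml As in [fit_menzerath()].
#' @return A `null_distribution` object; see [empirical_p()].
#' @export
shuffle_null <- function(table, n_iter = 1000L, seed = 1L,
                         include_singles = TRUE, reml = TRUE) {
  stopifnot(n_iter >= 1L)
  observed <- fit_menzerath(table, include_singles = include_singles,
                            reml = reml)
  mf <- observed$frame
  by_ind <- split(seq_len(nrow(mf)), mf$individual_id)
  set.seed(as.integer(seed))
  slopes <- matrix(NA_real_, nrow = n_iter, ncol = 2L,
                   dimnames = list(NULL, c("log_size", "position")))
  log_dur <- mf$log_dur
  for (it in seq_len(n_iter)) {
    shuffled <- log_dur
    for (idx in by_ind) {
      if (length(idx) > 1L) shuffled[idx] <- log_dur[sample(idx)]
    }
    m <- suppressWarnings(suppressMessages(
      lme4::refit(observed$model, newresp = shuffled)))
    fe <- lme4::fixef(m)
    slopes[it, ] <- fe[c("log_size", "position")]
  }
  new_null_distribution("shuffle", slopes,
                        observed_size = coef(observed)[["log_size"]],
                        observed_position = coef(observed)[["position"]],
                        n_iter = n_iter, seed = seed, observed_fit = observed)
}

#' Generate one production-constrained pseudo-sequence
#'
#' Implements the duration-matching rule: call durations are sampled with
#' replacement from `pool` until the cumulative duration strictly exceeds
#' `real_total`; if the overshoot exceeds 50% of the duration of the last
#' sampled call, the last call is removed, otherwise the sequence is accepted
#' as is. Positions are 1..m in sampling order. The rule can return an empty
#' sequence when a single oversized draw already overshoots by more than half
#' of itself.
#'
#' @param real_total Total duration (seconds) of the real sequence; > 0.
#' @param pool Non-empty vector of positive durations to sample from.
#' @return Numeric vector of sampled durations (possibly empty).
#' @examples
#' set.seed(1)
#' generate_pseudo_sequence(10, pool = 3)  # 3,3,3,3 overshoots by 2 > 1.5
#' @export
generate_pseudo_sequence <- function(real_total, pool) {
  if (length(pool) == 0L) {
    stop_menzerath("config_error", "empty duration pool")
  }
  stopifnot(real_total > 0, all(pool > 0))
  out <- numeric(0)
  total <- 0
  while (total <= real_total) {
    draw <- pool[sample.int(length(pool), 1L)]
    out <- c(out, draw)
    total <- total + draw
  }
  overshoot <- total - real_total
  if (overshoot > 0.5 * out[length(out)]) {
    out <- out[-length(out)]
  }
  out
}

#' Production-constraint null distribution of the Menzerath slopes
#'
#' Monte-Carlo null with production constraints: in each iteration every real
#' sequence is replaced by a pseudo-sequence built by
#' [generate_pseudo_sequence()] from that individual's pooled duration
#' distribution, so pseudo-sequences match real sequences in cumulative
#' duration but are free to vary in call count. The same mixed model is then
#' refit on the pseudo table. A slope distribution at least as negative as
#' the observed one indicates that compression can arise from
#' duration-matching alone.
#'
#' Pseudo-sequences that come out empty (a single oversized draw removed by
#' the 50% rule) are dropped from that iteration's table.
#'
#' @inheritParams shuffle_null
#' @return A `null_distribution` object whose `pseudo_check` element records,
#'   over all iterations, the worst-case violation of the 50%-overshoot band
#'   (it should be `0`).
#' @export
production_constraint_null <- function(table, n_iter = 1000L, seed = 1L,
                                       include_singles = TRUE, reml = TRUE) {
  stopifnot(n_iter >= 1L)
  observed <- fit_menzerath(table, include_singles = include_singles,
                            reml = reml)
  if (!include_singles) table <- filter_calls(table, exclude_singles = TRUE)
  pools <- split(table$duration_s, table$individual_id)
  seqs <- unique(table$sequence_id)
  seq_ind <- vapply(split(table$individual_id, table$sequence_id)[seqs],
                    `[`, character(1L), 1L)
  seq_total <- vapply(split(table$duration_s, table$sequence_id)[seqs],
                      sum, numeric(1L))
  seq_ctx <- vapply(split(table$context, table$sequence_id)[seqs],
                    `[`, character(1L), 1L)
  set.seed(as.integer(seed))
  slopes <- matrix(NA_real_, nrow = n_iter, ncol = 2L,
                   dimnames = list(NULL, c("log_size", "position")))
  band_violations <- 0L
  n_empty <- 0L
  for (it in seq_len(n_iter)) {
    durs <- vector("list", length(seqs))
    for (s in seq_along(seqs)) {
      ps <- generate_pseudo_sequence(seq_total[s], pools[[seq_ind[s]]])
      if (length(ps) == 0L) { n_empty <- n_empty + 1L; next }
      tot <- sum(ps)
      if (tot > seq_total[s]) {                 # last call kept
        if (tot - seq_total[s] > 0.5 * ps[length(ps)] + 1e-12) {
          band_violations <- band_violations + 1L
        }
      }                                         # else removed: total <= real
      durs[[s]] <- ps
    }
    keep <- lengths(durs) > 0L
    sizes <- lengths(durs[keep])
    pseudo <- call_table(data.frame(
      context = rep.int(seq_ctx[keep], sizes),
      individual_id = rep.int(seq_ind[keep], sizes),
      sequence_id = rep.int(sprintf("it%04d_%s", it, seqs[keep]), sizes),
      position = sequence(sizes),
      duration_s = unlist(durs[keep], use.names = FALSE),
      stringsAsFactors = FALSE
    ))
    fit <- suppressWarnings(
      fit_menzerath(pseudo, include_singles = TRUE, reml = reml,
                    df_method = "residual"))
    slopes[it, ] <- coef(fit)[c("log_size", "position")]
  }
  out <- new_null_distribution("production_constraint", slopes,
    observed_size = coef(observed)[["log_size"]],
    observed_position = coef(observed)[["position"]],
    n_iter = n_iter, seed = seed, observed_fit = observed)
  out$pseudo_check <- list(band_violations = band_violations,
                           n_empty_sequences = n_empty)
  out
}

new_null_distribution <- function(model, slopes, observed_size,
                                  observed_position, n_iter, seed,
                                  observed_fit) {
  out <- list(
    model = model,
    slopes_size = slopes[, "log_size"],
    slopes_position = slopes[, "position"],
    observed_size = observed_size,
    observed_position = observed_position,
    n_iter = n_iter,
    seed = seed,
    empirical_p_size = empirical_p(slopes[, "log_size"], observed_size),
    empirical_p_position = empirical_p(slopes[, "position"],
                                       observed_position),
    observed_fit = observed_fit
  )
  class(out) <- "null_distribution"
  out
}

#' Two-sided empirical p-value with finite-sample correction
#'
#' `(r + 1) / (n + 1)`, where `r` counts null statistics at least as extreme
#' (in absolute value) as the observed one among `n` Monte-Carlo draws. The
#' correction keeps the p-value off zero for finite `n`.
#'
#' @param null_values Numeric vector of null statistics.
#' @param observed Observed statistic.
#' @return A p-value in `[1/(n+1), 1]`.
#' @export
empirical_p <- function(null_values, observed) {
  null_values <- null_values[is.finite(null_values)]
  r <- sum(abs(null_values) >= abs(observed))
  (r + 1) / (length(null_values) + 1)
}

#' @export
print.null_distribution <- function(x, ...) {
  cat(sprintf("Monte-Carlo null (%s), %d iterations, seed %d\n",
              x$model, x$n_iter, x$seed))
  cat(sprintf("  size slope:     observed %+0.4f | null mean %+0.4f (sd %0.4f) | p = %0.4g\n",
              x$observed_size, mean(x$slopes_size), stats::sd(x$slopes_size),
              x$empirical_p_size))
  cat(sprintf("  position slope: observed %+0.4f | null mean %+0.4f (sd %0.4f) | p = %0.4g\n",
              x$observed_position, mean(x$slopes_position),
              stats::sd(x$slopes_position), x$empirical_p_position))
  invisible(x)
}

#' Violin-style plot of a null slope distribution
#'
#' Draws the Monte-Carlo slope density as a mirrored (violin) polygon with
#' the observed slope overplotted as a circle, in the style of
#' slope-vs-chance panels.
#'
#' @param x A `null_distribution`.
#' @param which `"size"` or `"position"`.
#' @param ... Passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.null_distribution <- function(x, which = c("size", "position"), ...) {
  which <- match.arg(which)
  vals <- if (which == "size") x$slopes_size else x$slopes_position
  obs <- if (which == "size") x$observed_size else x$observed_position
  d <- stats::density(vals)
  w <- d$y / max(d$y) * 0.4
  graphics::plot(NA, xlim = c(0.4, 1.8),
                 ylim = range(c(d$x, obs)),
                 xlab = "", ylab = sprintf("%s slope", which),
                 xaxt = "n", ...)
  graphics::polygon(c(1 - w, rev(1 + w)), c(d$x, rev(d$x)),
                    col = "grey80", border = "grey40")
  graphics::points(1, obs, pch = 21, bg = "white", cex = 1.4)
  graphics::axis(1, at = 1, labels = x$model)
  invisible(x)
}
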