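#' Configuration for the synthetic call-sequence generator
#'
#' The generator is the exact generative inverse of the fitted mixed model:
#' for each sequence j of individual k with drawn size n,
#' `log(duration) = beta0 + beta1*log(n) + beta2*position + u_j + v_k + w_pos + eps`,
#' with `u_j ~ N(0, sigma_seq^2)` per sequence, `v_k ~ N(0, sigma_ind^2)` per
#' individual, `w_pos ~ N(0, sigma_pos^2)` drawn once per position category and
#' shared across all sequences (the crossed structure of the model), and
#' i.i.d. residuals `eps ~ N(0, sigma_eps^2)`.
#'
#' @param beta0 Intercept on the log-seconds scale.
#' @param beta1 Slope on log sequence size (negative under Menzerath's law).
#' @param beta2 Slope on ordinal position.
#' @param sigma_seq,sigma_ind,sigma_pos,sigma_eps Standard deviations (>= 0)
#'   of the sequence, individual, and position-category random intercepts and
#'   of the residual.
#' @param n_individuals Number of individuals.
#' @param sequences_per_individual Sequences generated per individual.
#' @param size_distribution Sequence-size distribution; one of
#'   `size_uniform(a, b)`, `size_categorical(prob)` (probabilities over sizes
#'   `1..K`), or `size_geometric(mean)` (geometric on `1, 2, ...` with the
#'   given mean, truncated at `max`).
#' @param context Context label written into the table.
#' @return A list of class `synthetic_config`.
#' @seealso [simulate_call_table()], [preset_config()]
#' @export
synthetic_config <- function(beta0 = log(0.2), beta1 = -0.022, beta2 = 0.034,
                             sigma_seq = 0.1, sigma_ind = 0.1,
                             sigma_pos = 0.02, sigma_eps = 0.3,
                             n_individuals = 3L,
                             sequences_per_individual = 500L,
                             size_distribution = size_uniform(1L, 4L),
                             context = "synthetic") {
  stopifnot(sigma_seq >= 0, sigma_ind >= 0, sigma_pos >= 0, sigma_eps >= 0,
            n_individuals >= 1L, sequences_per_individual >= 1L,
            inherits(size_distribution, "size_distribution"))
  structure(list(
    beta0 = beta0, beta1 = beta1, beta2 = beta2,
    sigma_seq = sigma_seq, sigma_ind = sigma_ind,
    sigma_pos = sigma_pos, sigma_eps = sigma_eps,
    n_individuals = as.integer(n_individuals),
    sequences_per_individual = as.integer(sequences_per_individual),
    size_distribution = size_distribution,
    context = context
  ), class = "synthetic_config")
}

#' Sequence-size distributions for the generator
#'
#' @param a,b Integer bounds of the uniform support (`a >= 1`).
#' @return A function of class `size_distribution` drawing `n` sizes.
#' @rdname size_distribution
#' @export
size_uniform <- function(a, b) {
  stopifnot(a >= 1L, b >= a)
  support <- seq.int(a, b)
  structure(function(n) support[sample.int(length(support), n, replace = TRUE)],
            class = c("size_distribution", "function"),
            label = sprintf("uniform(%d,%d)", a, b))
}

#' @param prob Numeric vector of probabilities over sizes `1..length(prob)`.
#' @rdname size_distribution
#' @export
size_categorical <- function(prob) {
  stopifnot(length(prob) >= 1L, all(prob >= 0), sum(prob) > 0)
  if (sum(prob[-1]) == 0 && length(prob) > 1L && prob[1] == 0) {
    stop_menzerath("config_error", "size distribution has no support")
  }
  k <- length(prob)
  structure(function(n) sample.int(k, n, replace = TRUE, prob = prob),
            class = c("size_distribution", "function"),
            attr_label = NULL,
            label = sprintf("categorical(K=%d)", k))
}

#' @param mean Target mean of the geometric size distribution (> 1).
#' @param max Truncation point.
#' @rdname size_distribution
#' @export
size_geometric <- function(mean = 3, max = 12L) {
  stopifnot(mean > 1, max >= 2L)
  p <- 1 / mean  # support 1,2,... with mean 1/p
  structure(function(n) pmin(stats::rgeom(n, p) + 1L, as.integer(max)),
            class = c("size_distribution", "function"),
            label = sprintf("geometric(mean=%g,max=%d)", mean, max))
}

#' Study-shaped generator presets
#'
#' `"trained_crow"`: 3 individuals, cue range 1-4, weak compression
#' (`beta1 = -0.022`) and positive position slope (`beta2 = 0.034`).
#' `"human"`: 26 individuals, cue range 1-8, positive size slope
#' (`beta1 = 0.033`) and negative position slope (`beta2 = -0.023`).
#' `"wild_crow"`: strong compression (`beta1 = -0.164`, `beta2 = 0.003`) with
#' a truncated-geometric size distribution; the wild size distribution is a
#' stand-in (not reported for the source recordings) and should not be used
#' for quantitative claims about wild data.
#'
#' @param which One of `"trained_crow"`, `"wild_crow"`, `"human"`.
#' @param ... Overrides passed to [synthetic_config()].
#' @return A `synthetic_config`.
#' @export
preset_config <- function(which = c("trained_crow", "wild_crow", "human"),
                          ...) {
  which <- match.arg(which)
  base <- switch(which,
    trained_crow = list(beta0 = log(0.2), beta1 = -0.022, beta2 = 0.034,
                        n_individuals = 3L, sequences_per_individual = 1500L,
                        size_distribution = size_uniform(1L, 4L),
                        context = "trained_crow"),
    human = list(beta0 = log(0.25), beta1 = 0.033, beta2 = -0.023,
                 n_individuals = 26L, sequences_per_individual = 156L,
                 size_distribution = size_uniform(1L, 8L),
                 context = "human"),
    wild_crow = list(beta0 = log(0.25), beta1 = -0.164, beta2 = 0.003,
                     n_individuals = 40L, sequences_per_individual = 28L,
                     size_distribution = size_geometric(mean = 2.8, max = 12L),
                     context = "wild_crow"))
  args <- utils::modifyList(base, list(...))
  do.call(synthetic_config, args)
}

#' Simulate a call table from a generative mixed-model configuration
#'
#' @param config A [synthetic_config()].
#' @param seed Integer seed; the table is fully reproducible from it.
#' @return A [call_table()] with one row per simulated call.
#' @examples
#' cfg <- synthetic_config(sigma_seq = 0, sigma_ind = 0, sigma_pos = 0,
#'                         sigma_eps = 0, beta0 = log(0.1), beta1 = 0,
#'                         beta2 = 0)
#' tab <- simulate_call_table(cfg, seed = 1)
#' stopifnot(all(tab$duration_s == 0.1))
#' @export
simulate_call_table <- function(config, seed = 1L) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(as.integer(seed))
  n_seq_total <- config$n_individuals * config$sequences_per_individual
  sizes <- config$size_distribution(n_seq_total)
  if (any(sizes < 1L)) {
    stop_menzerath("config_error",
      "size distribution produced sizes below 1")
  }
  ind_of_seq <- rep(seq_len(config$n_individuals),
                    each = config$sequences_per_individual)
  v <- stats::rnorm(config$n_individuals, 0, config$sigma_ind)
  u <- stats::rnorm(n_seq_total, 0, config$sigma_seq)
  max_pos <- max(sizes)
  w <- stats::rnorm(max_pos, 0, config$sigma_pos)

  n_calls <- sum(sizes)
  seq_row <- rep.int(seq_len(n_seq_total), sizes)
  position <- sequence(sizes)
  eps <- stats::rnorm(n_calls, 0, config$sigma_eps)
  log_dur <- config$beta0 +
    config$beta1 * log(sizes[seq_row]) +
    config$beta2 * position +
    u[seq_row] + v[ind_of_seq[seq_row]] + w[position] + eps

  call_table(data.frame(
    context = config$context,
    individual_id = sprintf("ind%02d", ind_of_seq[seq_row]),
    sequence_id = sprintf("seq%06d", seq_row),
    position = position,
    duration_s = exp(log_dur),
    stringsAsFactors = FALSE
  ))
}

#' Configuration for simulated cued-number trials
#'
#' Trial outcomes are Bernoulli with a linear success-probability model
#' (matching the accuracy analysis, which is linear on the proportion-correct
#' scale): `p = intercept + slope*cue + a_p + b_p*cue`, with per-participant
#' random intercepts `a_p` and random slopes `b_p`, clipped to `[0, 1]`.
#'
#' @param accuracy_intercept Success probability at cue 0 before clipping.
#' @param accuracy_slope Change in success probability per cue increment.
#' @param cue_range Integer range of cue numbers, e.g. `1:8`.
#' @param trials_per_participant Trials per participant (cues drawn uniformly).
#' @param n_participants Number of participants.
#' @param participant_intercept_sd,participant_slope_sd Random-effect SDs.
#' @return A list of class `trial_config`.
#' @export
trial_config <- function(accuracy_intercept = 1.005,
                         accuracy_slope = -0.007,
                         cue_range = 1:8,
                         trials_per_participant = 156L,
                         n_participants = 26L,
                         participant_intercept_sd = 0.01,
                         participant_slope_sd = 0.003) {
  stopifnot(accuracy_intercept > 0,
            participant_intercept_sd >= 0, participant_slope_sd >= 0,
            all(cue_range >= 1L), trials_per_participant >= 1L,
            n_participants >= 1L)
  structure(list(
    accuracy_intercept = accuracy_intercept,
    accuracy_slope = accuracy_slope,
    cue_range = as.integer(cue_range),
    trials_per_participant = as.integer(trials_per_participant),
    n_participants = as.integer(n_participants),
    participant_intercept_sd = participant_intercept_sd,
    participant_slope_sd = participant_slope_sd
  ), class = "trial_config")
}

#' Simulate cued-number trial outcomes
#'
#' @param config A [trial_config()].
#' @param seed Integer seed.
#' @return A data frame with columns `participant_id`, `cue_number`,
#'   `correct`. The number of probability clips applied (values pushed back
#'   into `[0, 1]`) is attached as attribute `n_clipped` and reported with a
#'   message when positive.
#' @export
simulate_trials <- function(config, seed = 1L) {
  stopifnot(inherits(config, "trial_config"))
  set.seed(as.integer(seed))
  a <- stats::rnorm(config$n_participants, 0, config$participant_intercept_sd)
  b <- stats::rnorm(config$n_participants, 0, config$participant_slope_sd)
  pid <- rep(seq_len(config$n_participants),
             each = config$trials_per_participant)
  cue <- sample(config$cue_range,
                length(pid), replace = TRUE)
  p_raw <- config$accuracy_intercept + config$accuracy_slope * cue +
    a[pid] + b[pid] * cue
  p <- pmin(pmax(p_raw, 0), 1)
  n_clipped <- sum(p_raw != p)
  if (n_clipped > 0L) {
    message(sprintf("simulate_trials: clipped %d success probabilities to [0, 1]",
                    n_clipped))
  }
  out <- data.frame(
    participant_id = sprintf("p%02d", pid),
    cue_number = as.integer(cue),
    correct = stats::runif(length(pid)) < p,
    stringsAsFactors = FALSE
  )
  attr(out, "n_clipped") <- n_clipped
  out
}
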