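#' Spectral flatness (Wiener entropy) of a signal
#'
#' Per STFT frame, flatness is the geometric mean divided by the arithmetic
#' mean of the power spectrum; the returned value is the mean over frames
#' with nonzero energy. Broadband noise approaches 1, tonal signals approach
#' 0. Default analysis: 512-sample Hann window with 50% overlap.
#'
#' @param signal Mono numeric vector.
#' @param sample_rate Sampling rate in Hz (recorded only; the metric is
#'   dimensionless).
#' @param window STFT window length in samples.
#' @param overlap Fractional window overlap in `[0, 1)`.
#' @return A number in `[0, 1]`. An all-zero signal is an error of class
#'   `menzerath_degenerate_error`.
#' @export
spectral_flatness <- function(signal, sample_rate, window = 512L,
                              overlap = 0.5) {
  stopifnot(length(signal) >= window, overlap >= 0, overlap < 1)
  hop <- max(1L, as.integer(round(window * (1 - overlap))))
  w <- hann_window(window)
  starts <- seq.int(1L, length(signal) - window + 1L, by = hop)
  vals <- numeric(0)
  half <- window %/% 2L + 1L
  for (s in starts) {
    frame <- signal[s:(s + window - 1L)] * w
    p <- Mod(stats::fft(frame))[seq_len(half)]^2
    am <- mean(p)
    if (am == 0) next
    gm <- if (any(p == 0)) 0 else exp(mean(log(p)))
    vals <- c(vals, gm / am)
  }
  if (length(vals) == 0L) {
    stop_menzerath("degenerate_error",
      "all-zero signal: spectral flatness undefined")
  }
  mean(vals)
}

#' Temporal entropy of a signal
#'
#' Signal energy is accumulated over consecutive non-overlapping frames, the
#' frame energies are normalized to a probability distribution, and the
#' Shannon entropy of that distribution is divided by `log(n_frames)`.
#' Power spread uniformly across time gives 1; energy concentrated in a
#' single frame gives 0.
#'
#' @param signal Mono numeric vector covering at least two full frames.
#' @param sample_rate Sampling rate in Hz (recorded only).
#' @param frame Frame length in samples; a trailing partial frame is dropped.
#' @return A number in `[0, 1]`. An all-zero signal is an error of class
#'   `menzerath_degenerate_error`.
#' @export
temporal_entropy <- function(signal, sample_rate, frame = 512L) {
  n_frames <- length(signal) %/% frame
  if (n_frames < 2L) {
    stop_menzerath("model_error",
      "signal shorter than two frames: temporal entropy undefined")
  }
  x <- signal[seq_len(n_frames * frame)]
  e <- colSums(matrix(x^2, nrow = frame))
  tot <- sum(e)
  if (tot == 0) {
    stop_menzerath("degenerate_error",
      "all-zero signal: temporal entropy undefined")
  }
  p <- e / tot
  p <- p[p > 0]
  -sum(p * log(p)) / log(n_frames)
}

hann_window <- function(n) {
  0.5 - 0.5 * cos(2 * pi * seq.int(0L, n - 1L) / (n - 1L))
}

#' Pre-screen a recording for segmentation suitability
#'
#' Computes spectral flatness and temporal entropy of a WAV file and applies
#' the exclusion thresholds used for noisy field recordings: files with
#' spectral flatness above `flatness_max` (broadband noise) or temporal
#' entropy above `entropy_max` (power spread uniformly across time, no sharp
#' onset/offset structure) fail the screen. Multi-channel audio is downmixed
#' by channel averaging.
#'
#' @param path Path to a PCM WAV file.
#' @param flatness_max Spectral-flatness threshold (default 0.05).
#' @param entropy_max Temporal-entropy threshold (default 0.85).
#' @param window,overlap STFT parameters passed to the metrics.
#' @return An object of class `screen_metrics` with elements
#'   `spectral_flatness`, `temporal_entropy`, `pass`, `thresholds`.
#' @export
prescreen <- function(path, flatness_max = 0.05, entropy_max = 0.85,
                      window = 512L, overlap = 0.5) {
  wav <- read_wav(path)
  x <- rowMeans(wav$samples)
  screen_metrics(
    spectral_flatness = spectral_flatness(x, wav$sample_rate,
                                          window = window, overlap = overlap),
    temporal_entropy = temporal_entropy(x, wav$sample_rate, frame = window),
    flatness_max = flatness_max, entropy_max = entropy_max
  )
}

#' @rdname prescreen
#' @param spectral_flatness,temporal_entropy Precomputed metric values.
#' @export
screen_metrics <- function(spectral_flatness, temporal_entropy,
                           flatness_max = 0.05, entropy_max = 0.85) {
  structure(list(
    spectral_flatness = spectral_flatness,
    temporal_entropy = temporal_entropy,
    pass = spectral_flatness <= flatness_max &&
      temporal_entropy <= entropy_max,
    thresholds = c(flatness_max = flatness_max, entropy_max = entropy_max)
  ), class = "screen_metrics")
}

#' @export
print.screen_metrics <- function(x, ...) {
  cat(sprintf("spectral flatness %0.4f (max %0.2f), temporal entropy %0.4f (max %0.2f) -> %s\n",
              x$spectral_flatness, x$thresholds[["flatness_max"]],
              x$temporal_entropy, x$thresholds[["entropy_max"]],
              if (x$pass) "PASS" else "FAIL"))
  invisible(x)
}

#' Detect call onsets/offsets from the amplitude envelope
#'
#' The Hilbert-magnitude envelope of the signal is smoothed with a short
#' moving average; the noise floor is estimated as a low percentile of the
#' smoothed envelope and segments are the contiguous runs above
#' `noise floor x threshold_factor`. Runs separated by less than `min_gap_s`
#' are merged and segments shorter than `min_dur_s` are dropped.
#'
#' @param signal Mono numeric vector.
#' @param sample_rate Sampling rate in Hz.
#' @param noise_floor_percentile Percentile (0-1) of the envelope used as the
#'   noise-floor estimate.
#' @param threshold_factor Multiple of the noise floor that counts as signal.
#' @param min_gap_s Gaps shorter than this (seconds) are merged.
#' @param min_dur_s Segments shorter than this (seconds) are dropped.
#' @param smooth_s Moving-average window (seconds) for envelope smoothing.
#' @return A data frame of class `segment_list` with columns `onset_s`,
#'   `offset_s`, sorted and disjoint.
#' @export
detect_calls <- function(signal, sample_rate, noise_floor_percentile = 0.1,
                         threshold_factor = 3, min_gap_s = 0.03,
                         min_dur_s = 0.02, smooth_s = 0.01) {
  stopifnot(length(signal) > 0L, sample_rate > 0)
  env <- hilbert_envelope(signal)
  k <- max(1L, as.integer(round(smooth_s * sample_rate)))
  env <- moving_average(env, k)
  floor_est <- stats::quantile(env, noise_floor_percentile, names = FALSE)
  thr <- floor_est * threshold_factor
  above <- env > thr
  runs <- rle(above)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  seg <- cbind(start = starts[runs$values], end = ends[runs$values])
  if (nrow(seg) == 0L) return(empty_segments())
  # merge short gaps
  merged <- seg[1, , drop = FALSE]
  min_gap <- min_gap_s * sample_rate
  if (nrow(seg) > 1L) {
    for (i in 2:nrow(seg)) {
      gap <- seg[i, "start"] - merged[nrow(merged), "end"] - 1L
      if (gap < min_gap) {
        merged[nrow(merged), "end"] <- seg[i, "end"]
      } else {
        merged <- rbind(merged, seg[i, , drop = FALSE])
      }
    }
  }
  dur <- (merged[, "end"] - merged[, "start"] + 1L) / sample_rate
  merged <- merged[dur >= min_dur_s, , drop = FALSE]
  if (nrow(merged) == 0L) return(empty_segments())
  out <- data.frame(onset_s = (merged[, "start"] - 1L) / sample_rate,
                    offset_s = merged[, "end"] / sample_rate)
  class(out) <- c("segment_list", "data.frame")
  out
}

empty_segments <- function() {
  out <- data.frame(onset_s = numeric(0), offset_s = numeric(0))
  class(out) <- c("segment_list", "data.frame")
  out
}

hilbert_envelope <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2L == 0L) {
    h[1L] <- 1; h[n %/% 2L + 1L] <- 1
    h[2:(n %/% 2L)] <- 2
  } else {
    h[1L] <- 1
    if (n > 1L) h[2:((n + 1L) %/% 2L)] <- 2
  }
  Mod(stats::fft(X * h, inverse = TRUE) / n)
}

# centered moving average with edge replication
moving_average <- function(x, k) {
  if (k <= 1L) return(x)
  half <- k %/% 2L
  padded <- c(rep(x[1L], half), x, rep(x[length(x)], k - half - 1L))
  cs <- cumsum(padded)
  (cs[k:length(padded)] - c(0, cs[seq_len(length(padded) - k)])) / k
}

#' Turn detected segments into call records
#'
#' Convenience mapping from a [detect_calls()] result to call-table rows with
#' `duration_s = offset_s - onset_s`. Grouping of segments into sequences is
#' left to the caller (all segments here become one sequence in temporal
#' order).
#'
#' @param segments A `segment_list`.
#' @param individual_id,sequence_id,context Identifiers for the new rows.
#' @return A [call_table()].
#' @export
segments_to_calls <- function(segments, individual_id, sequence_id,
                              context = "segmented") {
  stopifnot(inherits(segments, "segment_list"), nrow(segments) > 0L)
  call_table(data.frame(
    context = context,
    individual_id = individual_id,
    sequence_id = sequence_id,
    position = seq_len(nrow(segments)),
    duration_s = segments$offset_s - segments$onset_s,
    onset_s = segments$onset_s,
    offset_s = segments$offset_s,
    stringsAsFactors = FALSE
  ))
}
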