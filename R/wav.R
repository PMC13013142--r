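#' Minimal PCM WAV reader
#'
#' Reads an uncompressed RIFF/WAVE file (16-bit integer PCM, mono or
#' multi-channel). Samples are rescaled to `[-1, 1]`.
#'
#' @param path Path to a `.wav` file.
#' @return A list with `samples` (a channels-in-columns numeric matrix) and
#'   `sample_rate` (Hz).
#' @export
read_wav <- function(path) {
  if (!file.exists(path)) {
    stop_menzerath("io_error", sprintf("file not found: %s", path))
  }
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4L, useBytes = TRUE)
  if (!identical(riff, "RIFF")) {
    stop_menzerath("io_error", sprintf("not a RIFF file: %s", path))
  }
  invisible(readBin(con, "integer", 1L, size = 4L, endian = "little"))
  wave <- readChar(con, 4L, useBytes = TRUE)
  if (!identical(wave, "WAVE")) {
    stop_menzerath("io_error", sprintf("not a WAVE file: %s", path))
  }
  fmt <- NULL
  data_raw <- NULL
  repeat {
    id <- readChar(con, 4L, useBytes = TRUE)
    if (length(id) == 0L || nchar(id) < 4L) break
    size <- readBin(con, "integer", 1L, size = 4L, endian = "little")
    if (identical(id, "fmt ")) {
      fmt <- list(
        audio_format = readBin(con, "integer", 1L, size = 2L,
                               endian = "little", signed = FALSE),
        n_channels = readBin(con, "integer", 1L, size = 2L,
                             endian = "little", signed = FALSE),
        sample_rate = readBin(con, "integer", 1L, size = 4L,
                              endian = "little"),
        byte_rate = readBin(con, "integer", 1L, size = 4L,
                            endian = "little"),
        block_align = readBin(con, "integer", 1L, size = 2L,
                              endian = "little", signed = FALSE),
        bits = readBin(con, "integer", 1L, size = 2L, endian = "little",
                       signed = FALSE)
      )
      extra <- size - 16L
      if (extra > 0L) invisible(readBin(con, "raw", extra))
    } else if (identical(id, "data")) {
      data_raw <- readBin(con, "raw", size)
      if (size %% 2L == 1L) invisible(readBin(con, "raw", 1L))
    } else {
      invisible(readBin(con, "raw", size + size %% 2L))
    }
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt) || is.null(data_raw)) {
    stop_menzerath("io_error", sprintf("missing fmt/data chunk: %s", path))
  }
  if (fmt$audio_format != 1L || fmt$bits != 16L) {
    stop_menzerath("io_error",
      sprintf("only 16-bit integer PCM supported (got format %d, %d bits)",
              fmt$audio_format, fmt$bits))
  }
  n <- length(data_raw) %/% 2L
  if (n == 0L) {
    stop_menzerath("io_error", sprintf("empty data chunk: %s", path))
  }
  ints <- readBin(data_raw, "integer", n, size = 2L, endian = "little",
                  signed = TRUE)
  samples <- matrix(ints / 32768, ncol = fmt$n_channels, byrow = TRUE)
  list(samples = samples, sample_rate = fmt$sample_rate)
}

#' Minimal PCM WAV writer
#'
#' Writes mono 16-bit integer PCM. Samples outside `[-1, 1]` are clipped.
#'
#' @param samples Numeric vector in `[-1, 1]`.
#' @param sample_rate Sampling rate in Hz.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_wav <- function(samples, sample_rate, path) {
  stopifnot(length(samples) > 0L, sample_rate > 0)
  ints <- as.integer(pmin(pmax(round(samples * 32768), -32768), 32767))
  n_bytes <- length(ints) * 2L
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + n_bytes), con, size = 4L, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4L, endian = "little")
  writeBin(1L, con, size = 2L, endian = "little")   # PCM
  writeBin(1L, con, size = 2L, endian = "little")   # mono
  writeBin(as.integer(sample_rate), con, size = 4L, endian = "little")
  writeBin(as.integer(sample_rate * 2L), con, size = 4L, endian = "little")
  writeBin(2L, con, size = 2L, endian = "little")   # block align
  writeBin(16L, con, size = 2L, endian = "little")  # bits
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(n_bytes), con, size = 4L, endian = "little")
  writeBin(ints, con, size = 2L, endian = "little")
  invisible(path)
}
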