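#' Construct a waveform
#'
#' A mono PCM audio clip with amplitudes normalized to \[-1, 1\].
#'
#' @param samples Numeric amplitude vector in \[-1, 1\].
#' @param sample_rate Sampling rate in Hz (positive).
#' @param source_id Free-text identifier (e.g. originating file).
#' @return An object of class `waveform`. Duration in seconds is
#'   `length(samples) / sample_rate` (see [wave_duration()]).
#' @export
waveform <- function(samples, sample_rate, source_id = "") {
  samples <- as.numeric(samples)
  if (anyNA(samples)) stopf("waveform samples must not be NA")
  if (length(samples) && (min(samples) < -1 || max(samples) > 1)) {
    stopf("waveform amplitudes must lie in [-1, 1]")
  }
  if (!is.numeric(sample_rate) || length(sample_rate) != 1L || sample_rate <= 0) {
    stopf("sample_rate must be a single positive number")
  }
  structure(list(samples = samples, sample_rate = sample_rate,
                 source_id = as.character(source_id)),
            class = "waveform")
}

#' @export
length.waveform <- function(x) length(x$samples)

#' Duration of a waveform in seconds
#' @param wave A [waveform()].
#' @return `length(samples) / sample_rate`.
#' @export
wave_duration <- function(wave) {
  stopifnot(inherits(wave, "waveform"))
  length(wave$samples) / wave$sample_rate
}

#' @export
print.waveform <- function(x, ...) {
  cat(sprintf("<waveform '%s'> %d samples @ %d Hz (%.2f s)\n", x$source_id,
              length(x$samples), as.integer(x$sample_rate), wave_duration(x)))
  invisible(x)
}

read_u16 <- function(raw, off) {
  as.integer(raw[off]) + 256L * as.integer(raw[off + 1L])
}
read_u32 <- function(raw, off) {
  as.numeric(raw[off]) + 256 * as.numeric(raw[off + 1L]) +
    65536 * as.numeric(raw[off + 2L]) + 16777216 * as.numeric(raw[off + 3L])
}

#' Read a PCM WAV file
#'
#' Supports uncompressed RIFF/WAVE with 8-, 16- or 24-bit integer PCM at
#' any sample rate. Amplitudes are scaled to \[-1, 1\]; multi-channel
#' audio is averaged to mono. The header-declared sample rate is taken as
#' authoritative.
#'
#' @param path Path to a `.wav` file.
#' @return A [waveform()] with `source_id = path`.
#' @export
read_wav <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  raw <- readBin(path, "raw", n = file.info(path)$size)
  if (length(raw) < 44L || rawToChar(raw[1:4]) != "RIFF" ||
      rawToChar(raw[9:12]) != "WAVE") {
    stopf("not a RIFF/WAVE file: %s", path)
  }
  # walk chunks for fmt and data
  off <- 13L
  fmt <- NULL
  data_raw <- NULL
  while (off + 8L <= length(raw)) {
    cid <- rawToChar(raw[off:(off + 3L)])
    csz <- read_u32(raw, off + 4L)
    body <- (off + 8L):min(off + 7L + csz, length(raw))
    if (cid == "fmt ") fmt <- raw[body]
    if (cid == "data") data_raw <- raw[body]
    off <- off + 8L + csz + (csz %% 2)  # chunks are word-aligned
  }
  if (is.null(fmt) || is.null(data_raw)) stopf("missing fmt/data chunk: %s", path)
  audio_format <- read_u16(fmt, 1L)
  if (audio_format != 1L) {
    stopf("unsupported (compressed or non-PCM) WAV format %d in %s", audio_format, path)
  }
  n_channels <- read_u16(fmt, 3L)
  sample_rate <- read_u32(fmt, 5L)
  bits <- read_u16(fmt, 15L)
  x <- switch(as.character(bits),
    "8" = (as.integer(data_raw) - 128L) / 128,
    "16" = readBin(data_raw, "integer", n = length(data_raw) %/% 2L,
                   size = 2L, signed = TRUE, endian = "little") / 32768,
    "24" = {
      n <- length(data_raw) %/% 3L
      b <- matrix(as.integer(data_raw[seq_len(3L * n)]), nrow = 3L)
      v <- b[1L, ] + 256 * b[2L, ] + 65536 * b[3L, ]
      v <- ifelse(v >= 8388608, v - 16777216, v)
      v / 8388608
    },
    stopf("unsupported bit depth %d in %s", bits, path)
  )
  if (n_channels > 1L) {
    n_frames <- length(x) %/% n_channels
    x <- colMeans(matrix(x[seq_len(n_frames * n_channels)], nrow = n_channels))
  }
  waveform(x, sample_rate, source_id = path)
}

#' Write a waveform as a PCM WAV file
#'
#' @param wave A [waveform()].
#' @param path Output path.
#' @param bits Bit depth, one of 8, 16 (default), 24. Quantization error
#'   is at most one least-significant bit of the chosen depth.
#' @return `path`, invisibly.
#' @export
write_wav <- function(wave, path, bits = 16L) {
  stopifnot(inherits(wave, "waveform"))
  if (!bits %in% c(8L, 16L, 24L)) stopf("bits must be 8, 16 or 24")
  full <- 2^(bits - 1)
  codes <- pmin(pmax(round(wave$samples * full), -full), full - 1)
  payload <- switch(as.character(bits),
    "8" = as.raw(codes + 128),
    "16" = writeBin(as.integer(codes), raw(), size = 2L, endian = "little"),
    "24" = {
      v <- ifelse(codes < 0, codes + 16777216, codes)
      b <- rbind(v %% 256, (v %/% 256) %% 256, v %/% 65536)
      as.raw(as.vector(b))
    })
  sr <- as.integer(round(wave$sample_rate))
  block_align <- bits %/% 8L
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + length(payload)), con, size = 4L, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(c(16L), con, size = 4L, endian = "little")
  writeBin(as.integer(c(1L, 1L)), con, size = 2L, endian = "little")  # PCM, mono
  writeBin(as.integer(c(sr, sr * block_align)), con, size = 4L, endian = "little")
  writeBin(as.integer(c(block_align, bits)), con, size = 2L, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(length(payload)), con, size = 4L, endian = "little")
  writeBin(payload, con)
  invisible(path)
}
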