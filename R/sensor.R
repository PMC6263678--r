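#' ADC specification of the noise sensor
#'
#' Models the LM-393-style sensor front end: the microphone voltage swings
#' between `v_low` (GND, 0 V) and `v_high` (VCC, 5 V) and is quantized by a
#' 10-bit ADC into `2^resolution_bits` levels; one peak-to-peak intensity
#' level is emitted per frame at `frame_rate_hz` frames per second.
#'
#' @param resolution_bits ADC resolution in bits (default 10, i.e. 1024
#'   levels).
#' @param v_low,v_high Voltage rails in volts (defaults 0 and 5).
#' @param frame_rate_hz Output frames per second (default 138).
#' @return An object of class `adc_spec`.
#' @export
adc_spec <- function(resolution_bits = 10L, v_low = 0, v_high = 5,
                     frame_rate_hz = 138) {
  if (resolution_bits < 1L) stopf("resolution_bits must be >= 1")
  if (v_high <= v_low) stopf("v_high must exceed v_low")
  if (frame_rate_hz <= 0) stopf("frame_rate_hz must be positive")
  structure(list(resolution_bits = as.integer(resolution_bits),
                 v_low = v_low, v_high = v_high, frame_rate_hz = frame_rate_hz),
            class = "adc_spec")
}

#' One least-significant bit of the ADC, in volts
#'
#' The voltage step between adjacent ADC codes:
#' `(v_high - v_low) / (2^bits - 1)`, i.e. 5/1023 V for the default
#' 10-bit 0--5 V converter. Every peak-to-peak intensity level is an
#' integer multiple of this quantity.
#'
#' @param spec An [adc_spec()].
#' @return LSB size in volts.
#' @export
adc_lsb <- function(spec = adc_spec()) {
  (spec$v_high - spec$v_low) / (2^spec$resolution_bits - 1)
}

quantize_codes <- function(samples, spec) {
  span <- 2^spec$resolution_bits - 1
  v <- (samples + 1) / 2  # amplitude -> fraction of the rail span
  pmin(pmax(floor(v * span + 0.5), 0), span)
}

#' Partition a waveform into sensor frames
#'
#' Frame `i` (0-based) covers sample indices
#' `[floor(i * sr / fr), floor((i+1) * sr / fr))`; frames are
#' non-overlapping and exhaustive up to the last complete frame, so a
#' waveform of `n` samples yields `floor(n * fr / sr)` frames.
#'
#' @param wave A [waveform()] with `sample_rate >= spec$frame_rate_hz`.
#' @param spec An [adc_spec()].
#' @return List of numeric amplitude windows, one per frame.
#' @export
frame_waveform <- function(wave, spec = adc_spec()) {
  stopifnot(inherits(wave, "waveform"))
  sr <- wave$sample_rate
  fr <- spec$frame_rate_hz
  if (sr < fr) stopf("sample rate %g below frame rate %g", sr, fr)
  nf <- floor(length(wave$samples) * fr / sr)
  if (nf < 1L) stopf("event too short: %d samples yield no complete frame at %g frames/s",
                     length(wave$samples), fr)
  starts <- floor((0:nf) * sr / fr)  # 0-based boundaries
  lapply(seq_len(nf), function(i) wave$samples[(starts[i] + 1L):starts[i + 1L]])
}

#' Peak-to-peak intensity level of one frame
#'
#' The amplitude window is mapped to the voltage rails
#' (`v = v_low + (a+1)/2 * (v_high - v_low)`), quantized to ADC codes by
#' round-half-up, and the difference between the maximum and minimum code
#' is converted back to volts. The result lies in `[0, v_high - v_low]`
#' and is always an integer multiple of [adc_lsb()].
#'
#' @param frame Non-empty numeric amplitude window in \[-1, 1\].
#' @param spec An [adc_spec()].
#' @return Peak-to-peak level in volts.
#' @export
peak_to_peak_level <- function(frame, spec = adc_spec()) {
  if (length(frame) == 0L) stopf("empty frame")
  codes <- quantize_codes(frame, spec)
  (max(codes) - min(codes)) * adc_lsb(spec)
}

#' Simulate the noise sensor on a waveform
#'
#' Composition of [frame_waveform()] and [peak_to_peak_level()]: the
#' waveform is framed at `spec$frame_rate_hz` and each frame is reduced to
#' its quantized peak-to-peak voltage, giving the intensity-level sequence
#' the wearable sensor would report.
#'
#' @param wave A [waveform()].
#' @param spec An [adc_spec()].
#' @param label Optional class label for the resulting sequence.
#' @param event_id Identifier (defaults to the waveform's `source_id`).
#' @return An [intensity_sequence()] at `rate_hz = spec$frame_rate_hz`.
#' @export
waveform_to_intensity <- function(wave, spec = adc_spec(), label = NA_character_,
                                  event_id = NULL) {
  stopifnot(inherits(wave, "waveform"))
  sr <- wave$sample_rate
  fr <- spec$frame_rate_hz
  if (sr < fr) stopf("sample rate %g below frame rate %g", sr, fr)
  n <- length(wave$samples)
  nf <- floor(n * fr / sr)
  if (nf < 1L) stopf("event too short: %d samples yield no complete frame at %g frames/s", n, fr)
  codes <- quantize_codes(wave$samples, spec)
  starts <- floor((0:nf) * sr / fr)
  lvl <- vapply(seq_len(nf), function(i) {
    w <- codes[(starts[i] + 1L):starts[i + 1L]]
    max(w) - min(w)
  }, numeric(1)) * adc_lsb(spec)
  intensity_sequence(lvl, rate_hz = fr, label = label,
                     event_id = if (is.null(event_id)) wave$source_id else event_id)
}

#' Convert intensity levels to decibels
#'
#' `20 * log10(max(v, v_floor) / v_ref)`. The floor defaults to one ADC
#' LSB so that the quietest nonzero reading maps to 0 dB under the default
#' reference and silence does not produce `-Inf`.
#'
#' @param values Nonnegative voltages.
#' @param v_ref Reference voltage (> 0); default one LSB of `spec`.
#' @param spec An [adc_spec()] used for the default reference/floor.
#' @param v_floor Values below this are clamped before the log (default
#'   one LSB of `spec`).
#' @return Numeric vector in dB.
#' @export
to_db <- function(values, v_ref = adc_lsb(spec), spec = adc_spec(),
                  v_floor = adc_lsb(spec)) {
  if (v_ref <= 0) stopf("v_ref must be positive")
  if (any(values < 0)) stopf("intensity values must be nonnegative")
  20 * log10(pmax(values, v_floor) / v_ref)
}

#' Root mean square error between two equal-length sequences
#'
#' `sqrt(mean((a - b)^2))`: the square root of the arithmetic average of
#' the squared residuals. Used as the similarity measure between
#' sound-derived intensity and sensor-derived intensity level; smaller
#' values mean more similar series.
#'
#' @param a,b Numeric vectors of equal length (use [align_lengths()]
#'   first if they differ).
#' @return Nonnegative scalar, symmetric in `a` and `b`.
#' @export
rmse <- function(a, b) {
  if (length(a) != length(b)) {
    stopf("length mismatch (%d vs %d): resample with align_lengths() first",
          length(a), length(b))
  }
  if (length(a) < 1L) stopf("need at least one value")
  sqrt(mean((a - b)^2))
}

#' Resample two sequences to a common length
#'
#' Both sequences are resampled to `target_length` with the cubic
#' convolution kernel of [resize_cubic()], so that series recorded at
#' different durations can be compared point-wise.
#'
#' @param a,b Non-empty numeric vectors.
#' @param target_length Common output length (>= 2).
#' @return List with resampled `a` and `b`.
#' @export
align_lengths <- function(a, b, target_length) {
  if (target_length < 2L) stopf("target_length must be >= 2")
  if (length(a) < 1L || length(b) < 1L) stopf("sequences must be non-empty")
  list(a = resize_to_length(a, target_length),
       b = resize_to_length(b, target_length))
}

# Endpoint-anchored cubic resampling: sample 0 maps to sample 0 and
# sample n-1 to target_length-1, so series of different durations overlay
# over their full extent (no extrapolation past the last sample).
resize_to_length <- function(x, target_length, kernel_a = -0.5) {
  n <- length(x)
  if (n == target_length) return(x)
  if (n == 1L) return(rep(x, target_length))
  u <- (0:(target_length - 1L)) * (n - 1) / (target_length - 1)
  cubic_interp_at(x, u, scale = target_length / n, kernel_a = kernel_a)
}

#' Class-pair RMSE matrix between two intensity datasets
#'
#' Reproduces the similarity analysis between sound-derived intensity and
#' simulated intensity level: entry (i, j) is the mean RMSE between
#' events of class i from `reference` and events of class j from
#' `simulated`, after converting to dB (optionally) and resampling every
#' event to a common length. Within a class, events are paired by matched
#' `event_id` when both datasets contain exactly the same ids; otherwise
#' the mean is taken over the full cross product of event pairs.
#'
#' When the same events feed both paths, the diagonal (same-class) entries
#' are expected to be smaller than the off-diagonal entries of their row
#' — the noise sensor preserves enough of each class's envelope to
#' resemble its own class most.
#'
#' @param reference [labeled_dataset()] of sound-derived intensity.
#' @param simulated [labeled_dataset()] of sensor-simulated intensity.
#' @param target_length Common resampled length; default the median event
#'   length across both datasets.
#' @param scale `"db"` (default, the plotting convention for intensity
#'   level) or `"volts"`.
#' @param spec [adc_spec()] supplying the dB reference and floor.
#' @return A 4x4 numeric matrix (class `rmse_matrix`) with rows indexing
#'   `reference` classes and columns `simulated` classes.
#' @export
rmse_matrix <- function(reference, simulated, target_length = NULL,
                        scale = c("db", "volts"), spec = adc_spec()) {
  scale <- match.arg(scale)
  stopifnot(inherits(reference, "labeled_dataset"),
            inherits(simulated, "labeled_dataset"))
  classes <- reference$class_names
  if (!identical(classes, simulated$class_names)) {
    stopf("datasets disagree on class names")
  }
  if (is.null(target_length)) {
    target_length <- max(2L, round(stats::median(c(dataset_lengths(reference),
                                                   dataset_lengths(simulated)))))
  }
  aligned <- function(ds) {
    labs <- dataset_labels(ds)
    out <- lapply(classes, function(cl) {
      ss <- ds$sequences[labs == cl]
      if (length(ss) == 0L) stopf("class '%s' has no events", cl)
      vals <- lapply(ss, function(s) {
        v <- s$values
        if (scale == "db") v <- to_db(v, spec = spec)
        resize_to_length(v, target_length)
      })
      mat <- do.call(rbind, vals)
      rownames(mat) <- vapply(ss, function(s) s$event_id, character(1))
      mat
    })
    names(out) <- classes
    out
  }
  A <- aligned(reference)
  B <- aligned(simulated)
  m <- matrix(NA_real_, length(classes), length(classes),
              dimnames = list(classes, classes))
  for (i in classes) {
    for (j in classes) {
      a <- A[[i]]
      b <- B[[j]]
      matched <- i == j && nrow(a) == nrow(b) &&
        setequal(rownames(a), rownames(b)) && !anyDuplicated(rownames(a))
      if (matched) {
        b2 <- b[rownames(a), , drop = FALSE]
        m[i, j] <- mean(sqrt(rowMeans((a - b2)^2)))
      } else {
        # mean over the cross product, via the squared-norm expansion
        sq <- outer(rowSums(a^2), rep(1, nrow(b))) +
          outer(rep(1, nrow(a)), rowSums(b^2)) - 2 * tcrossprod(a, b)
        m[i, j] <- mean(sqrt(pmax(sq, 0) / ncol(a)))
      }
    }
  }
  structure(m, class = c("rmse_matrix", "matrix", "array"))
}

#' @export
print.rmse_matrix <- function(x, ...) {
  cat("Mean RMSE, reference classes (rows) vs simulated classes (columns):\n")
  print(round(unclass(x), 2))
  invisible(x)
}

#' Export an RMSE matrix as CSV
#' @param x An [rmse_matrix()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_rmse_csv <- function(x, path) {
  df <- data.frame(class = rownames(x), unclass(x), check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
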