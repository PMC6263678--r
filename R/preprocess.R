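#' Preprocessing configuration
#'
#' Controls the normalize -> interpolate -> pad pipeline that turns
#' variable-length intensity sequences into fixed-width model input.
#'
#' @param interpolation_factor Length multiplier applied by cubic
#'   interpolation (default 3: tripling the sequence length is the
#'   setting at which classification accuracy peaks before degrading at
#'   larger factors).
#' @param max_dim Model input length before interpolation (default 647,
#'   one more than the longest observed howling event); the padded width
#'   after interpolation is `round(max_dim * interpolation_factor)`.
#' @param pad_value Right-padding value (default 0, the normalized floor).
#' @param kernel_a Sharpness parameter of the cubic convolution kernel
#'   (default -0.5, the classical Keys kernel).
#' @return An object of class `preprocess_config`.
#' @export
preprocess_config <- function(interpolation_factor = 3, max_dim = 647L,
                              pad_value = 0, kernel_a = -0.5) {
  if (interpolation_factor <= 0) stopf("interpolation_factor must be positive")
  if (max_dim < 2L) stopf("max_dim must be >= 2")
  structure(list(interpolation_factor = interpolation_factor,
                 max_dim = as.integer(max_dim), pad_value = pad_value,
                 kernel_a = kernel_a),
            class = "preprocess_config")
}

#' 0--1 normalization
#'
#' Affine rescaling `(x - min(x)) / (max(x) - min(x))` so a non-constant
#' sequence spans exactly \[0, 1\]. Removes the between-event loudness
#' differences that would otherwise dominate classification. A constant
#' sequence has no span; it is mapped to all zeros with a warning so that
#' pipelines survive silent clips.
#'
#' @param x Numeric vector (length >= 2) or an [intensity_sequence()]
#'   (normalized in place, preserving metadata).
#' @return Same shape as the input, values in \[0, 1\].
#' @export
normalize01 <- function(x) UseMethod("normalize01")

#' @export
normalize01.intensity_sequence <- function(x) {
  x$values <- normalize01(x$values)
  x
}

#' @export
normalize01.numeric <- function(x) {
  if (length(x) < 2L) stopf("normalize01 needs at least 2 values")
  rng <- range(x)
  if (rng[1] == rng[2]) {
    warning("constant sequence: 0-1 normalization degenerate, returning zeros",
            call. = FALSE)
    return(rep(0, length(x)))
  }
  (x - rng[1]) / (rng[2] - rng[1])
}

# Keys cubic convolution kernel; a = -0.5 reproduces polynomials up to
# degree 3 between samples, any a reproduces constants and lines.
cubic_kernel <- function(x, a = -0.5) {
  ax <- abs(x)
  w <- numeric(length(x))
  near <- ax <= 1
  mid <- ax > 1 & ax < 2
  w[near] <- (a + 2) * ax[near]^3 - (a + 3) * ax[near]^2 + 1
  w[mid] <- a * ax[mid]^3 - 5 * a * ax[mid]^2 + 8 * a * ax[mid] - 4 * a
  w
}

#' Resize a sequence by cubic convolution interpolation
#'
#' One-dimensional cubic convolution (the 1-D restriction of bicubic
#' image resampling): each output value is a weighted sum of the four
#' nearest input samples, with weights given by the piecewise-cubic Keys
#' kernel evaluated at the sample distances. Output position `i`
#' (0-based) is anchored at input coordinate `i / factor`, so input
#' values are reproduced exactly at integer-aligned positions. Boundary
#' samples are edge-replicated. When `factor < 1` the kernel is widened
#' by `1/factor` (anti-aliasing low-pass), the standard guard against
#' aliasing when shrinking.
#'
#' @param x Numeric vector, length >= 2.
#' @param factor Positive length multiplier; output length is
#'   `round(length(x) * factor)`.
#' @param kernel_a Kernel sharpness parameter (default -0.5).
#' @return Numeric vector of length `round(length(x) * factor)`.
#' @export
resize_cubic <- function(x, factor, kernel_a = -0.5) {
  if (!is.numeric(factor) || length(factor) != 1L || factor <= 0) {
    stopf("factor must be a single positive number")
  }
  n <- length(x)
  if (n < 2L) stopf("resize_cubic needs at least 2 values")
  m <- as.integer(round(n * factor))
  if (m < 1L) stopf("factor %g collapses the sequence to zero length", factor)
  u <- (0:(m - 1L)) / factor            # input coordinate of each output
  cubic_interp_at(x, u, factor, kernel_a)
}

# Evaluate the cubic convolution interpolant of x (samples at 0..n-1,
# edge-replicated) at coordinates u; `scale` < 1 widens the kernel for
# anti-aliasing when shrinking.
cubic_interp_at <- function(x, u, scale = 1, kernel_a = -0.5) {
  n <- length(x)
  m <- length(u)
  kscale <- if (scale < 1) scale else 1
  support <- 2 / kscale
  lo <- ceiling(u - support)
  nw <- as.integer(floor(2 * support)) + 2L
  # window sample indices (m x nw), edge-replicated into [0, n-1]
  js <- outer(lo, 0:(nw - 1L), `+`)
  w <- matrix(cubic_kernel((u - js) * kscale, a = kernel_a) * kscale,
              nrow = m)
  w <- w / rowSums(w)
  jc <- pmin(pmax(js, 0L), n - 1L)
  rowSums(w * matrix(x[jc + 1L], nrow = m))
}

#' Right-pad a sequence to a fixed length
#'
#' @param x Numeric vector no longer than `target_length`.
#' @param target_length Output length.
#' @param pad_value Fill value (default 0).
#' @return `x` followed by `target_length - length(x)` copies of
#'   `pad_value`.
#' @export
pad_to <- function(x, target_length, pad_value = 0) {
  if (length(x) > target_length) {
    stopf("sequence length %d exceeds target %d: increase max_dim",
          length(x), target_length)
  }
  if (length(x) == target_length) return(x)
  c(x, rep(pad_value, target_length - length(x)))
}

#' Preprocess a dataset into model-ready arrays
#'
#' Per event: 0--1 normalization, cubic interpolation by
#' `interpolation_factor`, right-padding to the fixed width
#' `round(max_dim * interpolation_factor)`. Class indices follow the
#' dataset's `class_names` order (canonically barking, growling, howling,
#' whining).
#'
#' @param dataset A non-empty [labeled_dataset()] of labeled events.
#' @param config A [preprocess_config()].
#' @return A list of class `model_input` with elements `X` (numeric
#'   matrix, events x width), `y` (integer class indices, 1-based),
#'   `class_names`, and `config`.
#' @export
preprocess_dataset <- function(dataset, config = preprocess_config()) {
  stopifnot(inherits(dataset, "labeled_dataset"),
            inherits(config, "preprocess_config"))
  if (length(dataset) == 0L) stopf("dataset is empty")
  labs <- dataset_labels(dataset)
  if (anyNA(labs)) stopf("all events must be labeled for model input")
  width <- as.integer(round(config$max_dim * config$interpolation_factor))
  rows <- lapply(dataset$sequences, function(s) {
    v <- normalize01(s$values)
    if (config$interpolation_factor != 1) {
      v <- resize_cubic(v, config$interpolation_factor, config$kernel_a)
    }
    pad_to(v, width, config$pad_value)
  })
  X <- do.call(rbind, rows)
  rownames(X) <- vapply(dataset$sequences, function(s) s$event_id, character(1))
  y <- match(labs, dataset$class_names)
  structure(list(X = X, y = y, class_names = dataset$class_names,
                 config = config),
            class = "model_input")
}

#' @export
print.model_input <- function(x, ...) {
  cat(sprintf("<model_input> %d events x width %d (factor %g), classes: %s\n",
              nrow(x$X), ncol(x$X), x$config$interpolation_factor,
              paste(x$class_names, collapse = ", ")))
  invisible(x)
}
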