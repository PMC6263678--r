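#' The four dog sound-event classes
#'
#' Canonical class order used throughout the package: barking, growling,
#' howling, whining. Barking signals alert, growling threat, howling
#' loneliness, and whining fear or separation anxiety. All class-indexed
#' structures (datasets, confusion matrices, RMSE matrices) follow this
#' order.
#'
#' @return Character vector of the four class names, in canonical order.
#' @export
dog_sound_classes <- function() {
  c("barking", "growling", "howling", "whining")
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

#' Construct an intensity sequence
#'
#' One vocalization event as the noise sensor reports it: a vector of
#' intensity levels in volts (0--5 V, one value per frame) at a nominal
#' frame rate of 138 samples per second.
#'
#' @param values Numeric vector of intensity levels in volts; every value
#'   must lie in \[0, 5\] and the sequence must be non-empty.
#' @param rate_hz Nominal sampling rate in Hz (default 138, the sensor's
#'   output rate).
#' @param label Class label, one of [dog_sound_classes()], or `NA` for an
#'   unlabeled event.
#' @param event_id Identifier for the event (free text).
#' @return An object of class `intensity_sequence`.
#' @export
intensity_sequence <- function(values, rate_hz = 138, label = NA_character_,
                               event_id = "") {
  values <- as.numeric(values)
  if (length(values) < 1L) stopf("an intensity sequence needs at least one value")
  if (anyNA(values)) stopf("intensity values must not be NA")
  if (any(values < 0 | values > 5)) {
    stopf("intensity values must lie in [0, 5] V (got range [%g, %g])",
          min(values), max(values))
  }
  if (!is.numeric(rate_hz) || length(rate_hz) != 1L || rate_hz <= 0) {
    stopf("rate_hz must be a single positive number")
  }
  if (!is.na(label) && !label %in% dog_sound_classes()) {
    stopf("unknown label '%s' (expected one of: %s)", label,
          paste(dog_sound_classes(), collapse = ", "))
  }
  structure(list(values = values, rate_hz = rate_hz,
                 label = as.character(label), event_id = as.character(event_id)),
            class = "intensity_sequence")
}

#' @export
length.intensity_sequence <- function(x) length(x$values)

#' @export
print.intensity_sequence <- function(x, ...) {
  cat(sprintf("<intensity_sequence '%s'> %s, %d samples @ %g Hz, range [%.2f, %.2f] V\n",
              x$event_id, ifelse(is.na(x$label), "unlabeled", x$label),
              length(x$values), x$rate_hz, min(x$values), max(x$values)))
  invisible(x)
}

#' Construct a labeled dataset of intensity sequences
#'
#' @param sequences List of [intensity_sequence()] objects, each carrying a
#'   label found in `class_names`.
#' @param class_names Ordered class labels; defaults to the canonical
#'   four-class order of [dog_sound_classes()].
#' @param split_seed Optional integer recording the seed used to split this
#'   dataset (bookkeeping only).
#' @return An object of class `labeled_dataset`.
#' @export
labeled_dataset <- function(sequences, class_names = dog_sound_classes(),
                            split_seed = NA_integer_) {
  if (!is.list(sequences)) stopf("sequences must be a list of intensity_sequence objects")
  ok <- vapply(sequences, inherits, logical(1), "intensity_sequence")
  if (length(sequences) && !all(ok)) {
    stopf("element %d of sequences is not an intensity_sequence", which(!ok)[1])
  }
  labs <- vapply(sequences, function(s) s$label, character(1))
  bad <- !is.na(labs) & !labs %in% class_names
  if (any(bad)) {
    stopf("sequence %d has label '%s' not in class_names", which(bad)[1], labs[bad][1])
  }
  structure(list(sequences = sequences, class_names = class_names,
                 split_seed = as.integer(split_seed)),
            class = "labeled_dataset")
}

#' @export
length.labeled_dataset <- function(x) length(x$sequences)

#' Per-class event counts
#'
#' @param dataset A [labeled_dataset()].
#' @return Named integer vector over `class_names`; counts sum to the total
#'   number of labeled events.
#' @export
class_counts <- function(dataset) {
  stopifnot(inherits(dataset, "labeled_dataset"))
  labs <- dataset_labels(dataset)
  tab <- table(factor(labs, levels = dataset$class_names))
  stats::setNames(as.integer(tab), dataset$class_names)
}

dataset_labels <- function(dataset) {
  vapply(dataset$sequences, function(s) s$label, character(1))
}

dataset_lengths <- function(dataset) {
  vapply(dataset$sequences, function(s) length(s$values), integer(1))
}

#' @export
print.labeled_dataset <- function(x, ...) {
  cc <- class_counts(x)
  cat(sprintf("<labeled_dataset> %d events (%s), %d total samples\n",
              length(x), paste(sprintf("%s %d", names(cc), cc), collapse = ", "),
              sum(dataset_lengths(x))))
  invisible(x)
}

#' Subset a labeled dataset by event index
#'
#' @param x A `labeled_dataset`.
#' @param i Integer or logical index over events.
#' @param ... Unused.
#' @return A `labeled_dataset` over the selected events.
#' @export
`[.labeled_dataset` <- function(x, i, ...) {
  labeled_dataset(x$sequences[i], class_names = x$class_names,
                  split_seed = x$split_seed)
}

#' Read an intensity-sequence dataset from CSV
#'
#' The canonical (long) dialect has header `event_id,label,index,volts`,
#' one row per sample, with samples of each event in `index` order. A wide
#' dialect (one possibly ragged row per event: `event_id,label,v1,v2,...`)
#' is accepted on read only. Values are validated to the sensor's 0--5 V
#' range and labels against `class_names`.
#'
#' @param path Path to a CSV file.
#' @param class_names Permitted labels (default [dog_sound_classes()]).
#' @return A [labeled_dataset()]; one [intensity_sequence()] per `event_id`,
#'   sample order preserved. A header-only file yields an empty dataset.
#' @export
read_intensity_csv <- function(path, class_names = dog_sound_classes()) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  header <- strsplit(readLines(path, n = 1L), ",")[[1]]
  long <- identical(trimws(header)[1:4], c("event_id", "label", "index", "volts"))
  if (long) {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    if (nrow(df) == 0L) return(labeled_dataset(list(), class_names))
    bad <- which(!is.finite(df$volts) | df$volts < 0 | df$volts > 5)
    if (length(bad)) {
      stopf("%s row %d: volts value %g outside [0, 5]", path, bad[1] + 1L, df$volts[bad[1]])
    }
    badlab <- which(!df$label %in% class_names)
    if (length(badlab)) {
      stopf("%s row %d: unknown label '%s'", path, badlab[1] + 1L, df$label[badlab[1]])
    }
    ids <- unique(df$event_id)
    seqs <- lapply(ids, function(id) {
      rows <- df[df$event_id == id, , drop = FALSE]
      rows <- rows[order(rows$index), , drop = FALSE]
      intensity_sequence(rows$volts, label = rows$label[1], event_id = id)
    })
  } else {
    # ragged wide rows: event_id,label,v1,v2,...
    lines <- readLines(path)[-1L]
    lines <- lines[nzchar(trimws(lines))]
    seqs <- lapply(seq_along(lines), function(k) {
      fields <- strsplit(lines[k], ",")[[1]]
      if (length(fields) < 3L) stopf("%s row %d: too few fields", path, k + 1L)
      vals <- suppressWarnings(as.numeric(fields[-(1:2)]))
      if (anyNA(vals)) stopf("%s row %d: non-numeric intensity value", path, k + 1L)
      if (any(vals < 0 | vals > 5)) stopf("%s row %d: volts outside [0, 5]", path, k + 1L)
      if (!fields[2] %in% class_names) stopf("%s row %d: unknown label '%s'", path, k + 1L, fields[2])
      intensity_sequence(vals, label = fields[2], event_id = fields[1])
    })
  }
  labeled_dataset(seqs, class_names)
}

#' Write an intensity-sequence dataset to CSV (long format)
#'
#' Values are printed at full double precision so that
#' `read_intensity_csv(write_intensity_csv(d, p))` reproduces `d` exactly.
#'
#' @param dataset A non-empty [labeled_dataset()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_intensity_csv <- function(dataset, path) {
  stopifnot(inherits(dataset, "labeled_dataset"))
  if (length(dataset) == 0L) stopf("refusing to write an empty dataset")
  rows <- lapply(dataset$sequences, function(s) {
    data.frame(event_id = s$event_id, label = s$label,
               index = seq_along(s$values),
               volts = formatC(s$values, digits = 17, format = "g"),
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  ok <- tryCatch({
    utils::write.table(df, path, sep = ",", row.names = FALSE, quote = FALSE)
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stopf("cannot write to %s", path)
  invisible(path)
}

#' Per-class summary of event lengths
#'
#' Order statistics (minimum, maximum, arithmetic mean, median) of the
#' per-event sample counts, by class. The median of an even number of
#' events is the mean of the two central values. Classes with no events
#' are reported with `n_events = 0` and `NA` statistics.
#'
#' @param dataset A non-empty [labeled_dataset()].
#' @return A `data.frame` with columns `class`, `n_events`, `min`, `max`,
#'   `mean`, `median`, one row per class in `class_names` order.
#' @export
summarize_lengths <- function(dataset) {
  stopifnot(inherits(dataset, "labeled_dataset"))
  if (length(dataset) == 0L) stopf("dataset is empty")
  labs <- dataset_labels(dataset)
  lens <- dataset_lengths(dataset)
  rows <- lapply(dataset$class_names, function(cl) {
    x <- lens[labs == cl]
    if (length(x) == 0L) {
      data.frame(class = cl, n_events = 0L, min = NA_integer_, max = NA_integer_,
                 mean = NA_real_, median = NA_real_)
    } else {
      data.frame(class = cl, n_events = length(x), min = min(x), max = max(x),
                 mean = mean(x), median = stats::median(x))
    }
  })
  do.call(rbind, rows)
}

# Run fn under a temporary RNG state seeded with `seed`, restoring the
# caller's stream afterwards so library code never perturbs user RNG.
with_seed <- function(seed, fn) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  fn()
}

#' Stratified train/test split
#'
#' Splits a dataset by class: within each class the events are shuffled
#' under `seed` and the first `round(train_fraction * n)` go to the
#' training set. The split is deterministic given the seed, and train and
#' test partition the dataset exactly.
#'
#' @param dataset A [labeled_dataset()]; every class present must have at
#'   least 2 events.
#' @param train_fraction Proportion of each class assigned to training
#'   (strictly between 0 and 1; default 0.7, i.e. the 70/30 convention
#'   under which 1200 events split into 840 train and 360 test).
#' @param seed Integer seed controlling the shuffle.
#' @return List with elements `train` and `test`, both `labeled_dataset`s
#'   carrying `split_seed = seed`.
#' @export
split_dataset <- function(dataset, train_fraction = 0.7, seed = 1L) {
  stopifnot(inherits(dataset, "labeled_dataset"))
  if (!(train_fraction > 0 && train_fraction < 1)) {
    stopf("train_fraction must be strictly between 0 and 1")
  }
  labs <- dataset_labels(dataset)
  idx_by_class <- split(seq_along(labs), factor(labs, levels = dataset$class_names))
  small <- vapply(idx_by_class, function(i) length(i) == 1L, logical(1))
  if (any(small)) {
    stopf("cannot stratify: class '%s' has fewer than 2 events",
          names(idx_by_class)[small][1])
  }
  picks <- with_seed(seed, function() {
    lapply(idx_by_class, function(i) {
      if (length(i) == 0L) return(integer(0))
      i_shuf <- i[sample.int(length(i))]
      n_train <- round(train_fraction * length(i))
      i_shuf[seq_len(n_train)]
    })
  })
  train_idx <- sort(unlist(picks, use.names = FALSE))
  test_idx <- setdiff(seq_along(labs), train_idx)
  out <- list(train = dataset[train_idx], test = dataset[test_idx])
  out$train$split_seed <- as.integer(seed)
  out$test$split_seed <- as.integer(seed)
  out
}
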