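test_that("intensity_sequence enforces the sensor's value range and labels", {
  s <- intensity_sequence(c(0, 2.5, 5), label = "barking", event_id = "e1")
  expect_s3_class(s, "intensity_sequence")
  expect_length(s, 3L)
  expect_error(intensity_sequence(c(1, 5.5)), "\\[0, 5\\]")
  expect_error(intensity_sequence(c(1, -0.1)), "\\[0, 5\\]")
  expect_error(intensity_sequence(numeric(0)), "at least one")
  expect_error(intensity_sequence(1, rate_hz = 0), "positive")
  expect_error(intensity_sequence(1, label = "meowing"), "unknown label")
})

test_that("labeled_dataset validates labels and reports counts that sum to the total", {
  seqs <- lapply(c("barking", "barking", "whining"), function(cl) {
    intensity_sequence(runif(5, 0, 5), label = cl, event_id = cl)
  })
  ds <- labeled_dataset(seqs)
  cc <- class_counts(ds)
  expect_identical(sum(cc), 3L)
  expect_identical(cc[["barking"]], 2L)
  expect_identical(cc[["howling"]], 0L)
  expect_length(labeled_dataset(list()), 0L)
  expect_length(ds[1:2], 2L)
  expect_error(labeled_dataset(list(intensity_sequence(1, label = "barking")),
                               class_names = c("growling", "howling")),
               "not in class_names")
})

test_that("the packaged worked-example fixture loads as 4 events of 64 samples", {
  ds <- read_intensity_csv(example_intensity_csv())
  expect_length(ds, 4L)
  expect_true(all(class_counts(ds) == 1L))
  lens <- vapply(ds$sequences, length, integer(1))
  expect_true(all(lens == 64L))
  bark <- ds$sequences[[which(vapply(ds$sequences, function(s) s$label,
                                     character(1)) == "barking")]]
  expect_equal(bark$values[1:3], c(4.82, 4.81, 4.79))
  whine <- ds$sequences[[which(vapply(ds$sequences, function(s) s$label,
                                      character(1)) == "whining")]]
  expect_equal(whine$values[1], 0.01)
  expect_equal(max(whine$values), 3.54)
})

test_that("intensity CSV round-trips losslessly and validates on read", {
  ds <- generate_dataset(synth_config(events_per_class = 8L, seed = 3L))
  path <- withr::local_tempfile(fileext = ".csv")
  write_intensity_csv(ds, path)
  back <- read_intensity_csv(path)
  expect_length(back, length(ds))
  expect_identical(class_counts(back), class_counts(ds))
  for (k in seq_along(ds$sequences)) {
    expect_identical(back$sequences[[k]]$values, ds$sequences[[k]]$values)
    expect_identical(back$sequences[[k]]$label, ds$sequences[[k]]$label)
    expect_identical(back$sequences[[k]]$event_id, ds$sequences[[k]]$event_id)
  }
  # header-only file
  empty <- withr::local_tempfile(fileext = ".csv")
  writeLines("event_id,label,index,volts", empty)
  expect_length(read_intensity_csv(empty), 0L)
  # out-of-range value reported with its row number
  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("event_id,label,index,volts", "e1,barking,1,2.0",
               "e1,barking,2,5.5"), bad)
  expect_error(read_intensity_csv(bad), "row 3")
  badlab <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("event_id,label,index,volts", "e1,mooing,1,2.0"), badlab)
  expect_error(read_intensity_csv(badlab), "unknown label")
  expect_error(write_intensity_csv(labeled_dataset(list()), path), "empty")
})

test_that("wide ragged CSV rows are accepted on read", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("event_id,label,values", "e1,barking,1,2,3",
               "e2,howling,0.5,1.5,2.5,3.5,4.5"), path)
  ds <- read_intensity_csv(path)
  expect_length(ds, 2L)
  expect_identical(ds$sequences[[2]]$values, c(0.5, 1.5, 2.5, 3.5, 4.5))
})

test_that("length summaries are per-class order statistics with mean-of-central-pair medians", {
  seqs <- c(
    lapply(c(5, 47, 19, 19), function(n) {
      intensity_sequence(runif(n, 0, 5), label = "barking")
    }),
    list(intensity_sequence(runif(64, 0, 5), label = "howling"))
  )
  sm <- summarize_lengths(labeled_dataset(seqs))
  bk <- sm[sm$class == "barking", ]
  expect_equal(c(bk$min, bk$max, bk$mean, bk$median), c(5, 47, 22.5, 19))
  hw <- sm[sm$class == "howling", ]
  expect_equal(c(hw$min, hw$max, hw$mean, hw$median), c(64, 64, 64, 64))
  # absent class flagged with zero events
  gr <- sm[sm$class == "growling", ]
  expect_identical(gr$n_events, 0L)
  expect_true(is.na(gr$mean))
  # even-count median is the mean of the two central values
  ev <- summarize_lengths(labeled_dataset(lapply(c(4, 6, 10, 20), function(n) {
    intensity_sequence(runif(n, 0, 5), label = "whining")
  })))
  expect_equal(ev[ev$class == "whining", "median"], 8)
})

test_that("stratified 70/30 split partitions 1200 events into 840/360 with 210/90 per class", {
  ds <- generate_dataset(synth_config(events_per_class = 300L, seed = 11L))
  sp <- split_dataset(ds, 0.7, seed = 42L)
  expect_length(sp$train, 840L)
  expect_length(sp$test, 360L)
  expect_true(all(class_counts(sp$train) == 210L))
  expect_true(all(class_counts(sp$test) == 90L))
  ids <- function(d) vapply(d$sequences, function(s) s$event_id, character(1))
  expect_length(intersect(ids(sp$train), ids(sp$test)), 0L)
  expect_setequal(c(ids(sp$train), ids(sp$test)), ids(ds))
  # deterministic under the seed
  sp2 <- split_dataset(ds, 0.7, seed = 42L)
  expect_identical(ids(sp2$train), ids(sp$train))
  sp3 <- split_dataset(ds, 0.7, seed = 43L)
  expect_false(identical(ids(sp3$train), ids(sp$train)))
})

test_that("split handles small classes and rejects singletons", {
  seqs <- unlist(lapply(dog_sound_classes(), function(cl) {
    lapply(1:2, function(i) intensity_sequence(runif(4, 0, 5), label = cl,
                                               event_id = paste0(cl, i)))
  }), recursive = FALSE)
  sp <- split_dataset(labeled_dataset(seqs), 0.5, seed = 1L)
  expect_true(all(class_counts(sp$train) == 1L))
  expect_true(all(class_counts(sp$test) == 1L))
  one <- labeled_dataset(list(intensity_sequence(1:3 / 2, label = "barking"),
                              intensity_sequence(1:3 / 2, label = "howling"),
                              intensity_sequence(1:3 / 2, label = "howling")))
  expect_error(split_dataset(one, 0.5, seed = 1L), "fewer than 2")
  expect_error(split_dataset(one, 1.0, seed = 1L), "between 0 and 1")
})
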