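test_that("0-1 normalization spans [0, 1] exactly and is idempotent", {
  expect_equal(normalize01(c(0, 5)), c(0, 1))
  expect_equal(normalize01(c(1.59, 2.38, 4.82)), c(0, 0.2446, 1),
               tolerance = 1e-4)
  set.seed(8)
  for (k in 1:5) {
    x <- runif(50, 0, 5)
    nx <- normalize01(x)
    expect_equal(range(nx), c(0, 1))
    expect_equal(normalize01(nx), nx)
  }
  expect_warning(z <- normalize01(c(2, 2, 2)), "constant")
  expect_identical(z, c(0, 0, 0))
  expect_error(normalize01(3), "at least 2")
  # sequences keep their metadata
  s <- intensity_sequence(c(1, 3, 5), label = "howling", event_id = "h")
  ns <- normalize01(s)
  expect_s3_class(ns, "intensity_sequence")
  expect_identical(ns$values, c(0, 0.5, 1))
  expect_identical(ns$label, "howling")
})

test_that("cubic resize has the documented lengths and reproduces aligned samples", {
  x <- sin(2 * pi * (0:99) / 37)
  expect_lt(max(abs(resize_cubic(x, 1) - x)), 1e-9)
  expect_length(resize_cubic(runif(646), 3), 1938L)  # longest event, tripled
  up <- resize_cubic(x, 3)
  expect_length(up, 300L)
  expect_lt(max(abs(up[seq(1, 298, by = 3)] - x)), 1e-9)
  expect_error(resize_cubic(x, 0), "positive")
  expect_error(resize_cubic(x, -2), "positive")
})

test_that("cubic convolution reproduces constants everywhere and lines on full windows", {
  expect_equal(resize_cubic(rep(2.7, 10), 3.3), rep(2.7, 33))
  expect_equal(resize_cubic(rep(1.1, 10), 0.5, kernel_a = -0.75), rep(1.1, 5))
  # linear ramp: interior positions (full 4-sample windows) are exact
  r <- resize_cubic(c(0, 1, 2, 3), 3)
  u <- (0:11) / 3
  interior <- u >= 1 & u <= 2
  expect_lt(max(abs(r[interior] - u[interior])), 1e-6)
  long <- resize_cubic(0:19 / 19, 4)
  uu <- (0:79) / 4 / 19
  inner <- seq_along(long)[(0:79) / 4 >= 1 & (0:79) / 4 <= 18]
  expect_lt(max(abs(long[inner] - uu[inner])), 1e-9)
})

test_that("cubic interpolation matches a local polynomial oracle on smooth signals", {
  # quadratic data: compare interpolated values against the exact quadratic
  # on interior windows (Keys kernel with a = -0.5 is third-order accurate)
  q <- (0:19)^2 / 50
  up <- resize_cubic(q, 5)
  u <- (0:99) / 5
  inner <- u >= 2 & u <= 17
  expect_lt(max(abs(up[inner] - u[inner]^2 / 50)), 0.01)
  # brute-force oracle: value at u from the cubic fit to the 4 nearest samples
  x <- sin((0:29) / 4)
  up2 <- resize_cubic(x, 2)
  for (u0 in c(5.5, 10.5, 20.5)) {
    j <- floor(u0) + (-1:2)
    fit <- lm(y ~ poly(t, 3, raw = TRUE), data.frame(t = j, y = x[j + 1]))
    oracle <- unname(predict(fit, data.frame(t = u0)))
    expect_lt(abs(up2[u0 * 2 + 1] - oracle), 0.02)
  }
})

test_that("shrink-then-grow round trip stays close on band-limited signals", {
  x <- sin(2 * pi * (0:149) / 50) * 0.5 + 0.5
  rt <- resize_cubic(resize_cubic(x, 3), 1 / 3)
  expect_length(rt, 150L)
  expect_lt(sqrt(mean((rt - x)^2)), 0.05)
  dn <- resize_cubic(resize_cubic(x, 1 / 3), 3)
  expect_lt(sqrt(mean((dn - x)^2)), 0.05)
})

test_that("padding is right-sided, exact and guarded", {
  p <- pad_to(1:64 / 64, 647)
  expect_length(p, 647L)
  expect_identical(p[1:64], 1:64 / 64)
  expect_true(all(p[65:647] == 0))
  expect_identical(pad_to(1:5, 5L), 1:5)
  expect_identical(pad_to(c(1, 2), 4, pad_value = -1), c(1, 2, -1, -1))
  expect_error(pad_to(1:10, 5), "increase max_dim")
})

test_that("preprocess_dataset emits the fixed width round(max_dim * factor)", {
  ds <- read_intensity_csv(example_intensity_csv())
  pp <- preprocess_dataset(ds, preprocess_config(interpolation_factor = 3))
  expect_identical(dim(pp$X), c(4L, 1941L))
  # 64 samples tripled: informative part is 192 wide, the rest padding
  expect_true(all(pp$X[, 193:1941] == 0))
  expect_true(any(pp$X[, 1:192] != 0))
  # cubic convolution may overshoot the normalized range slightly; the
  # informative values stay near [0, 1]
  expect_true(all(pp$X > -0.25 & pp$X < 1.25))
  expect_identical(pp$class_names, dog_sound_classes())
  expect_identical(pp$y, match(vapply(ds$sequences, function(s) s$label,
                                      character(1)), dog_sound_classes()))
  pp1 <- preprocess_dataset(ds, preprocess_config(interpolation_factor = 1))
  expect_identical(ncol(pp1$X), 647L)
  ppf <- preprocess_dataset(ds, preprocess_config(interpolation_factor = 2.5,
                                                  max_dim = 100))
  expect_identical(ncol(ppf$X), 250L)
})
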