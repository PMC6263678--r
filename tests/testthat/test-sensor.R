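test_that("framing yields floor(n * 138 / sr) non-overlapping exhaustive frames", {
  w <- waveform(sin(2 * pi * 300 * (0:5326) / 22050) * 0.5, 22050)
  fr <- frame_waveform(w)
  expect_length(fr, 33L)  # floor(5327 * 138 / 22050)
  expect_identical(sum(lengths(fr)), length(unlist(fr)))
  # frames tile the first floor(n*138/sr)*sr/138 samples without overlap
  expect_equal(unlist(fr), w$samples[seq_len(sum(lengths(fr)))])
  one <- waveform(runif(138, -1, 1), 138)
  expect_length(frame_waveform(one), 138L)
  expect_true(all(lengths(frame_waveform(one)) == 1L))
  sec <- waveform(runif(22050, -1, 1), 22050)
  expect_length(frame_waveform(sec), 138L)
  expect_error(frame_waveform(waveform(runif(50, -1, 1), 22050)), "too short")
})

test_that("peak-to-peak level is the quantized code span in volts", {
  spec <- adc_spec()
  expect_identical(peak_to_peak_level(rep(0.37, 20), spec), 0)
  expect_equal(peak_to_peak_level(c(-1, 0.2, 1), spec), 5)  # codes 0..1023
  # dense sine of amplitude 0.5 spans about half the rails
  s <- 0.5 * sin(2 * pi * (0:999) / 1000)
  expect_lt(abs(peak_to_peak_level(s, spec) - 2.5), adc_lsb(spec))
  expect_error(peak_to_peak_level(numeric(0)), "empty")
})

test_that("every intensity level is an integer multiple of one LSB (5/1023 V)", {
  set.seed(7)
  lsb <- adc_lsb(adc_spec())
  expect_equal(lsb, 5 / 1023)
  for (k in 1:5) {
    w <- waveform(runif(3000, -1, 1) * runif(1), 2000)
    iv <- waveform_to_intensity(w)
    expect_true(all(abs(iv$values / lsb - round(iv$values / lsb)) < 1e-9))
    expect_true(all(iv$values >= 0 & iv$values <= 5))
  }
})

test_that("sensing a 1-s clip yields 138 values and silence maps to zero", {
  w <- waveform(0.8 * sin(2 * pi * 500 * (0:22049) / 22050), 22050)
  iv <- waveform_to_intensity(w, label = "barking")
  expect_s3_class(iv, "intensity_sequence")
  expect_length(iv, 138L)
  expect_equal(iv$rate_hz, 138)
  silent <- waveform_to_intensity(waveform(numeric(2000), 2000))
  expect_true(all(silent$values == 0))
})

test_that("attenuating a waveform never increases any intensity level", {
  set.seed(21)
  w <- waveform(runif(4000, -1, 1), 4000)
  base <- waveform_to_intensity(w)$values
  for (k in c(0.9, 0.5, 0.2, 0.05)) {
    scaled <- waveform_to_intensity(waveform(w$samples * k, 4000))$values
    expect_true(all(scaled <= base + 1e-12))
  }
})

test_that("dB conversion uses the reference and a one-LSB floor", {
  expect_equal(to_db(0.25, v_ref = 0.25), 0)
  expect_equal(to_db(2.5, v_ref = 0.25), 20)
  expect_equal(to_db(5), 20 * log10(1023))
  # silence is clamped to the floor instead of -Inf
  expect_equal(to_db(0), 0)
  expect_error(to_db(1, v_ref = 0), "positive")
})

test_that("rmse is the root mean squared residual and a metric on equal-length series", {
  expect_identical(rmse(1:5, 1:5), 0)
  expect_equal(rmse(c(0, 0), c(3, 4)), sqrt(25 / 2))
  expect_equal(rmse(sin(1:50), sin(1:50) + 0.7), 0.7)
  set.seed(2)
  a <- runif(30); b <- runif(30)
  expect_identical(rmse(a, b), rmse(b, a))
  expect_gte(rmse(a, b), 0)
  expect_lt(rmse(a, a + 1e-14), 1e-12)
  expect_error(rmse(1:3, 1:4), "align_lengths")
})

test_that("align_lengths overlays series of different durations", {
  al <- align_lengths(sin(1:33 / 5), cos(1:33 / 5), 33)
  expect_identical(al$a, sin(1:33 / 5))
  al2 <- align_lengths(1:10 / 10, 1:30 / 30, 30)
  expect_length(al2$a, 30L)
  ramp <- align_lengths(seq(0, 1, length.out = 5), seq(0, 1, length.out = 50), 50)
  expect_lt(rmse(ramp$a, ramp$b), 0.05)
  expect_error(align_lengths(1, 2, 1), "target_length")
})

test_that("rmse_matrix has a zero diagonal for identical datasets with matched ids", {
  ds <- generate_dataset(synth_config(events_per_class = 5L, seed = 9L))
  m <- rmse_matrix(ds, ds, target_length = 40L)
  expect_identical(dim(m), c(4L, 4L))
  expect_true(all(diag(m) == 0))
  expect_true(all(m >= 0))
})

test_that("paired audio/sensor data produces a diagonally dominant RMSE matrix", {
  paired <- generate_paired_data(synth_config(events_per_class = 15L, seed = 4L),
                                 sample_rate = 8000)
  sensed <- labeled_dataset(lapply(seq_along(paired$waveforms), function(k) {
    waveform_to_intensity(paired$waveforms[[k]],
                          label = paired$intensity$sequences[[k]]$label,
                          event_id = paired$intensity$sequences[[k]]$event_id)
  }))
  m <- rmse_matrix(paired$intensity, sensed, target_length = 60L)
  for (i in 1:4) {
    off <- m[i, -i]
    expect_lt(m[i, i], mean(off))
  }
})
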