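# small architecture + dataset used across classifier unit tests; the
# full-size parameter-recovery runs live in test-acceptance.R
tiny_config <- function(...) {
  args <- utils::modifyList(
    list(conv_filters = c(4L, 6L, 4L), conv_kernel_sizes = c(8L, 5L, 3L),
         lstm_units = 3L, batch_size = 16L, epochs = 5L, seed = 7L),
    list(...))
  do.call(lstm_fcn_config, args)
}

tiny_inputs <- function(n_per_class = 10L, factor = 1, max_dim = 80L, seed = 3L) {
  tpl <- lapply(default_templates(), function(t) {
    t$length_max <- min(t$length_max, 78L)
    t$length_mean <- min(t$length_mean, 60)
    t$length_median <- min(t$length_median, 55)
    t
  })
  ds <- generate_dataset(synth_config(events_per_class = n_per_class,
                                      seed = seed, templates = tpl))
  preprocess_dataset(ds, preprocess_config(interpolation_factor = factor,
                                           max_dim = max_dim))
}

test_that("the model builds with the configured feature widths and a 4-way softmax", {
  cfg <- tiny_config(input_length = 60L)
  m <- build_model(cfg)
  expect_identical(nrow(m$params$Wd), 4L)             # softmax outputs
  expect_identical(ncol(m$params$Wd), 4L + 3L)        # GAP width + lstm units
  one <- lstm_fcn_config(conv_filters = c(1L, 1L, 1L), lstm_units = 1L,
                         input_length = 60L)
  expect_identical(ncol(build_model(one)$params$Wd), 2L)
  expect_error(build_model(lstm_fcn_config(input_length = 5L)), "kernel")
  expect_error(build_model(lstm_fcn_config()), "input_length")
})

test_that("softmax outputs are probabilities for trained and untrained models", {
  cfg <- tiny_config(input_length = 80L)
  m <- build_model(cfg)
  m$class_names <- dog_sound_classes()
  X <- matrix(runif(6 * 80), 6, 80)
  pr <- predict(m, X)
  expect_identical(dim(pr), c(6L, 4L))
  expect_true(all(abs(rowSums(pr) - 1) < 1e-6))
  expect_true(all(pr >= 0))
  tr <- tiny_inputs()
  fit <- train(tiny_config(), tr)
  pr2 <- predict(fit, tr)
  expect_true(all(abs(rowSums(pr2) - 1) < 1e-6))
})

test_that("compiled branch gradients match the plain-R double-precision oracle", {
  cfg <- tiny_config(input_length = 23L, dropout_after_lstm = 0)
  p <- barkline:::with_seed(5L, function() barkline:::nn_init_params(cfg, 23L))
  run <- barkline:::nn_init_running(cfg)
  set.seed(5)
  xb <- matrix(runif(23 * 6), 23, 6)
  ref <- ref_fcn_forward(p, cfg, xb, run, train = TRUE)
  ctx <- barkline:::nn_new_ctx(cfg, 23L, 6L)
  fcn <- barkline:::cpp_fcn_forward_ctx(ctx, xb, barkline:::fcn_param_list(p),
                                        run, TRUE, 0.99, 1e-3)
  expect_lt(max(abs(ref$gap - fcn$gap)), 1e-5)
  expect_lt(max(abs(ref$running[[3]]$va - fcn$running[[3]]$va)), 1e-5)
  dgap <- matrix(rnorm(cfg$conv_filters[3] * 6), cfg$conv_filters[3], 6)
  gref <- ref_fcn_backward(p, cfg, ref$caches, dgap, 23L, 6L)
  gcpp <- barkline:::cpp_fcn_backward_ctx(ctx, dgap)
  for (nm in names(gref)) {
    denom <- max(abs(gref[[nm]]), 1)
    expect_lt(max(abs(gref[[nm]] - gcpp[[nm]])) / denom, 1e-4)
  }
})

test_that("classifier head gradients agree with finite differences", {
  cfg <- tiny_config(input_length = 15L, dropout_after_lstm = 0)
  p <- barkline:::with_seed(2L, function() barkline:::nn_init_params(cfg, 15L))
  run <- barkline:::nn_init_running(cfg)
  set.seed(2)
  xb <- matrix(runif(15 * 5), 15, 5)
  y <- c(1L, 2L, 3L, 4L, 1L)
  ctx <- barkline:::nn_new_ctx(cfg, 15L, 5L)
  lossfn <- function(pp) {
    fw <- barkline:::nn_forward(pp, run, cfg, xb, train = TRUE, ctx = ctx)
    -mean(log(fw$probs[cbind(y, 1:5)]))
  }
  fw <- barkline:::nn_forward(p, run, cfg, xb, train = TRUE, ctx = ctx)
  g <- barkline:::nn_backward(p, cfg, fw$cache, y, ctx = ctx)
  eps <- 1e-5
  for (nm in c("Wi", "Wg", "Wo", "bi", "Wd", "bd")) {
    for (i in sample(length(p[[nm]]), 3L)) {
      p2 <- p; p2[[nm]][i] <- p2[[nm]][i] + eps
      p3 <- p; p3[[nm]][i] <- p3[[nm]][i] - eps
      num <- (lossfn(p2) - lossfn(p3)) / (2 * eps)
      expect_lt(abs(num - g[[nm]][i]), 1e-3 + 1e-2 * abs(num))
    }
  }
})

test_that("training is deterministic under its seed and records history", {
  tr <- tiny_inputs()
  fit1 <- train(tiny_config(), tr)
  fit2 <- train(tiny_config(), tr)
  expect_identical(fit1$params$Wd, fit2$params$Wd)
  expect_identical(fit1$history$loss, fit2$history$loss)
  expect_identical(nrow(fit1$history), 5L)
  fit3 <- train(tiny_config(seed = 8L), tr)
  expect_false(identical(fit1$params$Wd, fit3$params$Wd))
})

test_that("a one-epoch run on 8 events completes with a single history row", {
  tr <- tiny_inputs(n_per_class = 2L)
  fit <- train(tiny_config(), tr, epochs = 1L)
  expect_identical(nrow(fit$history), 1L)
  expect_true(is.finite(fit$history$loss[1]))
})

test_that("evaluation reports accuracy as confusion-matrix trace over total", {
  tr <- tiny_inputs(n_per_class = 8L)
  fit <- train(tiny_config(), tr, epochs = 3L)
  ev <- evaluate(fit, tr)
  expect_identical(sum(ev$confusion), length(tr$y))
  expect_equal(ev$accuracy, sum(diag(ev$confusion)) / sum(ev$confusion))
  expect_identical(unname(rowSums(ev$confusion)),
                   as.numeric(table(factor(tr$y, 1:4))))
  expect_identical(ev$per_class$class, dog_sound_classes())
  # a constant predictor on a balanced set scores exactly chance, and
  # arg-max ties resolve to the lowest class index
  rigged <- fit
  rigged$params$Wd[] <- 0
  rigged$params$bd[] <- 0
  ev2 <- evaluate(rigged, tr)
  expect_equal(ev2$accuracy, 0.25)
  expect_true(all(ev2$confusion[, 1] == rowSums(ev2$confusion)))
})

test_that("evaluation rejects mismatched class names", {
  tr <- tiny_inputs(n_per_class = 3L)
  fit <- train(tiny_config(), tr, epochs = 1L)
  bad <- tr
  bad$class_names <- rev(tr$class_names)
  expect_error(evaluate(fit, bad), "class names")
})

test_that("a single-factor sweep equals a direct preprocess/train/evaluate run", {
  tpl <- lapply(default_templates(), function(t) {
    t$length_max <- min(t$length_max, 78L); t$length_mean <- min(t$length_mean, 60)
    t$length_median <- min(t$length_median, 55); t
  })
  ds <- generate_dataset(synth_config(events_per_class = 8L, seed = 3L,
                                      templates = tpl))
  cfg <- tiny_config(epochs = 3L)
  pc <- preprocess_config(interpolation_factor = 1, max_dim = 80L)
  sw <- sweep_interpolation_factor(ds, factors = 1, config = cfg,
                                   preprocess = pc, split_seed = 2L)
  expect_identical(sw$factor, 1)
  sp <- split_dataset(ds, 0.7, seed = 2L)
  fit <- train(cfg, preprocess_dataset(sp$train, pc))
  direct <- evaluate(fit, preprocess_dataset(sp$test, pc))$accuracy
  expect_equal(sw$accuracy, direct)
  expect_error(sweep_interpolation_factor(ds, numeric(0)), "at least one")
  expect_error(sweep_interpolation_factor(ds, c(1, -3)), "positive")
})
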