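#' LSTM-FCN architecture and training configuration
#'
#' The dual-branch time-series classifier: a fully convolutional branch
#' (three temporal-convolution blocks, each followed by batch
#' normalization and ReLU, then global average pooling) in parallel with
#' an LSTM branch fed through a dimension shuffle (the length-L
#' univariate series becomes a single time step of L features), followed
#' by dropout. The pooled and recurrent features are concatenated and
#' mapped to class probabilities by a dense softmax layer.
#'
#' Defaults follow the published setup: convolution filters 128/256/128,
#' batch size 128, 4 classes, 2000 epochs. Kernel sizes (8, 5, 3), 8 LSTM
#' units, dropout 0.8 and the Adam optimizer at 1e-3 follow the LSTM-FCN
#' lineage the architecture derives from. `epochs = 200` is a practical
#' desk-scale setting; accuracy bounds in this package are lower bounds,
#' so fewer epochs only risks undershooting, never inflating, results.
#'
#' @param conv_filters Integer triple of convolution filter counts.
#' @param conv_kernel_sizes Integer triple of kernel widths.
#' @param lstm_units LSTM state size.
#' @param dropout_after_lstm Dropout rate applied to the LSTM output
#'   during training.
#' @param n_classes Number of softmax outputs.
#' @param input_length Expected series length, or `NULL` to infer from
#'   the training data (the preprocessed width,
#'   `round(max_dim * interpolation_factor)`, 1941 under the defaults).
#' @param batch_size Minibatch size.
#' @param epochs Number of passes over the training data.
#' @param learning_rate Adam step size.
#' @param seed Integer seed controlling initialization, shuffling and
#'   dropout.
#' @return An object of class `lstm_fcn_config`.
#' @export
lstm_fcn_config <- function(conv_filters = c(128L, 256L, 128L),
                            conv_kernel_sizes = c(8L, 5L, 3L),
                            lstm_units = 8L, dropout_after_lstm = 0.8,
                            n_classes = 4L, input_length = NULL,
                            batch_size = 128L, epochs = 2000L,
                            learning_rate = 1e-3, seed = 17L) {
  stopifnot(length(conv_filters) == 3L, length(conv_kernel_sizes) == 3L,
            all(conv_filters >= 1L), all(conv_kernel_sizes >= 1L),
            lstm_units >= 1L, n_classes >= 2L, batch_size >= 1L,
            epochs >= 1L, learning_rate > 0,
            dropout_after_lstm >= 0, dropout_after_lstm < 1)
  structure(list(conv_filters = as.integer(conv_filters),
                 conv_kernel_sizes = as.integer(conv_kernel_sizes),
                 lstm_units = as.integer(lstm_units),
                 dropout_after_lstm = dropout_after_lstm,
                 n_classes = as.integer(n_classes),
                 input_length = if (is.null(input_length)) NULL else as.integer(input_length),
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs),
                 learning_rate = learning_rate, seed = as.integer(seed)),
            class = "lstm_fcn_config")
}

#' Build an untrained LSTM-FCN model
#'
#' Initializes parameters for the architecture described in
#' [lstm_fcn_config()]. The concatenated feature width is
#' `conv_filters[3] + lstm_units` (last filter count from global average
#' pooling plus the LSTM state).
#'
#' @param config An [lstm_fcn_config()]; `input_length` must be set (it
#'   is inferred automatically when building through [train()]).
#' @return An object of class `lstm_fcn_model`.
#' @export
build_model <- function(config) {
  stopifnot(inherits(config, "lstm_fcn_config"))
  if (is.null(config$input_length)) {
    stopf("config$input_length must be set to build a model directly")
  }
  if (config$input_length < max(config$conv_kernel_sizes)) {
    stopf("input_length %d shorter than the largest kernel %d",
          config$input_length, max(config$conv_kernel_sizes))
  }
  params <- with_seed(config$seed, function() {
    nn_init_params(config, config$input_length)
  })
  structure(list(config = config, params = params,
                 running = nn_init_running(config),
                 class_names = NULL, history = NULL),
            class = "lstm_fcn_model")
}

#' @export
print.lstm_fcn_model <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("<lstm_fcn_model> input %d, conv %s (kernels %s), lstm %d, %d classes%s\n",
              cfg$input_length, paste(cfg$conv_filters, collapse = "/"),
              paste(cfg$conv_kernel_sizes, collapse = "/"), cfg$lstm_units,
              cfg$n_classes,
              if (is.null(x$history)) " (untrained)"
              else sprintf(", trained %d epochs (final loss %.4f)",
                           nrow(x$history), x$history$loss[nrow(x$history)])))
  invisible(x)
}

#' Train an LSTM-FCN classifier
#'
#' Minimizes softmax cross-entropy with Adam at the configured learning
#' rate, batch size and epoch count. Deterministic given `config$seed`
#' (initialization, epoch shuffles and dropout masks all derive from it).
#'
#' @param model An `lstm_fcn_model` from [build_model()], or an
#'   [lstm_fcn_config()] (a model is built to match the data), or `NULL`
#'   (the default config is used).
#' @param train_set A `model_input` from [preprocess_dataset()], or a
#'   list with `X` (events x length matrix), `y` (integer labels 1..K)
#'   and `class_names`.
#' @param epochs Optional override of the configured epoch count.
#' @return A `trained_classifier`: the fitted model with `class_names`
#'   and a per-epoch `history` data frame (`epoch`, `loss`, `accuracy`).
#' @export
train <- function(model = NULL, train_set, epochs = NULL) {
  if (is.null(model)) model <- lstm_fcn_config()
  if (inherits(model, "lstm_fcn_config")) {
    cfg <- model
    if (is.null(cfg$input_length)) cfg$input_length <- ncol(train_set$X)
    model <- build_model(cfg)
  }
  stopifnot(inherits(model, "lstm_fcn_model"))
  config <- model$config
  if (!is.null(epochs)) config$epochs <- as.integer(epochs)
  X <- train_set$X
  y <- as.integer(train_set$y)
  if (ncol(X) != config$input_length) {
    stopf("training width %d does not match model input_length %d",
          ncol(X), config$input_length)
  }
  if (length(unique(y)) < 2L) stopf("need at least 2 classes present to train")
  if (max(y) > config$n_classes) stopf("label index %d exceeds n_classes", max(y))
  n <- nrow(X)
  p <- model$params
  running <- model$running
  st <- adam_init(p)
  ctx <- nn_new_ctx(config, config$input_length,
                    min(config$batch_size, n))
  hist_loss <- numeric(config$epochs)
  hist_acc <- numeric(config$epochs)
  with_seed(config$seed + 1L, function() {
    for (ep in seq_len(config$epochs)) {
      ord <- sample.int(n)
      losses <- c()
      hits <- 0L
      for (b0 in seq(1L, n, by = config$batch_size)) {
        idx <- ord[b0:min(b0 + config$batch_size - 1L, n)]
        xb <- t(X[idx, , drop = FALSE])
        fw <- nn_forward(p, running, config, xb, train = TRUE, ctx = ctx)
        running <<- fw$running
        pr <- fw$probs[cbind(y[idx], seq_along(idx))]
        loss <- -mean(log(pmax(pr, 1e-12)))
        if (!is.finite(loss)) {
          stopf("training diverged (non-finite loss at epoch %d); try a lower learning_rate", ep)
        }
        losses <- c(losses, loss)
        hits <- hits + sum(max.col(t(fw$probs), ties.method = "first") == y[idx])
        g <- nn_backward(p, config, fw$cache, y[idx], ctx = ctx)
        upd <- adam_step(p, g, st, config$learning_rate)
        p <<- upd$p
        st <<- upd$st
      }
      hist_loss[ep] <<- mean(losses)
      hist_acc[ep] <<- hits / n
    }
  })
  model$params <- p
  # inference-mode batch-norm statistics: pooled over the training set
  # under the final weights (running averages lag the weight trajectory)
  model$running <- nn_calibrate_running(p, config, X, ctx)
  model$config <- config
  model$class_names <- train_set$class_names
  model$history <- data.frame(epoch = seq_len(config$epochs),
                              loss = hist_loss, accuracy = hist_acc)
  class(model) <- c("trained_classifier", class(model))
  model
}

#' Predict class probabilities
#'
#' @param object A `trained_classifier` (or untrained `lstm_fcn_model`).
#' @param newdata A `model_input` or a numeric matrix (events x
#'   input_length).
#' @param ... Unused.
#' @return Matrix of class probabilities (events x classes); every row
#'   sums to 1.
#' @export
predict.lstm_fcn_model <- function(object, newdata, ...) {
  X <- if (is.list(newdata)) newdata$X else newdata
  if (is.null(dim(X))) X <- matrix(X, nrow = 1L)
  if (ncol(X) != object$config$input_length) {
    stopf("input width %d does not match model input_length %d",
          ncol(X), object$config$input_length)
  }
  probs <- matrix(NA_real_, nrow(X), object$config$n_classes)
  step <- max(1L, object$config$batch_size)
  ctx <- nn_new_ctx(object$config, object$config$input_length,
                    min(step, nrow(X)))
  for (b0 in seq(1L, nrow(X), by = step)) {
    idx <- b0:min(b0 + step - 1L, nrow(X))
    fw <- nn_forward(object$params, object$running, object$config,
                     t(X[idx, , drop = FALSE]), train = FALSE, ctx = ctx)
    probs[idx, ] <- t(fw$probs)
  }
  if (!is.null(object$class_names)) colnames(probs) <- object$class_names
  probs
}

#' Evaluate a trained classifier on a test set
#'
#' Hard predictions are the arg-max of the class probabilities, ties
#' broken toward the lowest class index.
#'
#' @param model A `trained_classifier`.
#' @param test_set A `model_input` preprocessed identically to the
#'   training data.
#' @return An `eval_report`: list with `accuracy` (trace of the confusion
#'   matrix over its total), `per_class` (data frame of precision and
#'   recall), and `confusion` (counts, rows = true class).
#' @export
evaluate <- function(model, test_set) {
  stopifnot(inherits(model, "lstm_fcn_model"))
  if (!is.null(model$class_names) && !is.null(test_set$class_names) &&
      !identical(model$class_names, test_set$class_names)) {
    stopf("class names of model and test set disagree")
  }
  probs <- predict(model, test_set)
  pred <- max.col(probs, ties.method = "first")
  truth <- as.integer(test_set$y)
  K <- model$config$n_classes
  cn <- model$class_names %||% paste0("class", seq_len(K))
  confusion <- table(factor(truth, 1:K), factor(pred, 1:K))
  dimnames(confusion) <- list(truth = cn, predicted = cn)
  confusion <- unclass(confusion)
  diagc <- diag(confusion)
  per_class <- data.frame(
    class = cn,
    precision = ifelse(colSums(confusion) > 0, diagc / colSums(confusion), NA_real_),
    recall = ifelse(rowSums(confusion) > 0, diagc / rowSums(confusion), NA_real_),
    row.names = NULL)
  structure(list(accuracy = sum(diagc) / sum(confusion),
                 per_class = per_class, confusion = confusion),
            class = "eval_report")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> accuracy %.4f on %d events\n", x$accuracy,
              sum(x$confusion)))
  print(x$confusion)
  invisible(x)
}

#' Serialize an evaluation report as JSON
#' @param report An `eval_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_eval_json <- function(report, path) {
  jsonlite::write_json(list(accuracy = report$accuracy,
                            per_class = report$per_class,
                            confusion = unname(apply(report$confusion, 1L,
                                                     as.integer, simplify = FALSE))),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Accuracy as a function of the interpolation factor
#'
#' For each factor, runs the full preprocess / split / train / evaluate
#' pipeline on the same dataset under a common split seed and reports
#' test accuracy. Lengthening the sequences (up to about a factor of 3)
#' is expected to raise accuracy relative to the raw length; larger
#' factors degrade it.
#'
#' @param dataset A [labeled_dataset()].
#' @param factors Positive interpolation factors to sweep.
#' @param config [lstm_fcn_config()] used for every factor
#'   (`input_length` is re-derived per factor).
#' @param preprocess [preprocess_config()] template; its
#'   `interpolation_factor` is overridden per factor.
#' @param train_fraction,split_seed Stratified split parameters shared by
#'   all factors.
#' @param seeds Training seeds; accuracies are averaged over them.
#' @return Data frame with columns `factor` and `accuracy` (mean over
#'   `seeds`), one row per factor in the given order.
#' @export
sweep_interpolation_factor <- function(dataset, factors,
                                       config = lstm_fcn_config(),
                                       preprocess = preprocess_config(),
                                       train_fraction = 0.7, split_seed = 1L,
                                       seeds = config$seed) {
  if (length(factors) < 1L) stopf("need at least one factor")
  if (any(factors <= 0)) stopf("factors must be positive")
  split <- split_dataset(dataset, train_fraction, seed = split_seed)
  acc <- vapply(factors, function(f) {
    pc <- preprocess
    pc$interpolation_factor <- f
    tr <- preprocess_dataset(split$train, pc)
    te <- preprocess_dataset(split$test, pc)
    mean(vapply(seeds, function(s) {
      cfg <- config
      cfg$seed <- as.integer(s)
      cfg$input_length <- ncol(tr$X)
      fit <- train(cfg, tr)
      evaluate(fit, te)$accuracy
    }, numeric(1)))
  }, numeric(1))
  data.frame(factor = factors, accuracy = acc)
}
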