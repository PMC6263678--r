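# Network-level plumbing for the LSTM-FCN. The convolutional branch runs
# in the fused compiled kernels (src/fcn_branch.cpp) against a persistent
# context that owns the activation buffers; the LSTM branch, dropout,
# dense softmax head, loss and Adam run here in double precision (their
# activations are tiny: lstm_units + conv_filters[3] values per event).

sigmoid <- function(x) 1 / (1 + exp(-x))

glorot <- function(nr, nc) {
  lim <- sqrt(6 / (nr + nc))
  matrix(stats::runif(nr * nc, -lim, lim), nr, nc)
}

he_normal <- function(nr, nc, fan_in) {
  matrix(stats::rnorm(nr * nc, sd = sqrt(2 / fan_in)), nr, nc)
}

nn_init_params <- function(config, input_length) {
  Fs <- config$conv_filters
  Ks <- config$conv_kernel_sizes
  U <- config$lstm_units
  L <- input_length
  Cs <- c(1L, Fs[1], Fs[2])
  p <- list()
  for (i in 1:3) {
    p[[paste0("W", i)]] <- he_normal(Fs[i], Cs[i] * Ks[i], Cs[i] * Ks[i])
    p[[paste0("b", i)]] <- numeric(Fs[i])
    p[[paste0("gamma", i)]] <- rep(1, Fs[i])
    p[[paste0("beta", i)]] <- numeric(Fs[i])
  }
  # single-step LSTM: with zero initial state the forget gate is inert,
  # so only input, candidate and output gates carry parameters
  for (g in c("Wi", "Wg", "Wo")) p[[g]] <- glorot(U, L)
  p$bi <- numeric(U); p$bg <- numeric(U); p$bo <- numeric(U)
  p$Wd <- glorot(config$n_classes, Fs[3] + U)
  p$bd <- numeric(config$n_classes)
  p
}

nn_init_running <- function(config) {
  lapply(1:3, function(i) list(mu = numeric(config$conv_filters[i]),
                               va = rep(1, config$conv_filters[i])))
}

nn_new_ctx <- function(config, input_length, batch_max) {
  cpp_fcn_ctx_new(config$conv_filters, config$conv_kernel_sizes,
                  as.integer(input_length), as.integer(batch_max))
}

fcn_param_list <- function(p) {
  list(p$W1, p$b1, p$gamma1, p$beta1,
       p$W2, p$b2, p$gamma2, p$beta2,
       p$W3, p$b3, p$gamma3, p$beta3)
}

# Forward pass over a batch. xb: L x B (series in columns). The FCN
# branch leaves its activations inside ctx; nn_backward must be called
# before the next forward on the same context.
nn_forward <- function(p, running, config, xb, train, ctx,
                       bn_momentum = 0.9) {
  fcn <- cpp_fcn_forward_ctx(ctx, xb, fcn_param_list(p), running, train,
                             bn_momentum, 1e-3)
  gap <- fcn$gap
  # LSTM branch: dimension shuffle makes the series one time step of L features
  zi <- p$Wi %*% xb + p$bi
  zg <- p$Wg %*% xb + p$bg
  zo <- p$Wo %*% xb + p$bo
  gi <- sigmoid(zi); gg <- tanh(zg); go <- sigmoid(zo)
  tc <- tanh(gi * gg)
  h <- go * tc
  if (train && config$dropout_after_lstm > 0) {
    keep <- 1 - config$dropout_after_lstm
    mask <- matrix(stats::runif(length(h)) < keep, nrow(h), ncol(h)) / keep
    hd <- h * mask
  } else {
    mask <- NULL
    hd <- h
  }
  z <- rbind(gap, hd)
  logits <- p$Wd %*% z + p$bd
  logits <- logits - rep(apply(logits, 2L, max), each = nrow(logits))
  e <- exp(logits)
  probs <- e / rep(colSums(e), each = nrow(e))
  cache <- list(B = ncol(xb), xb = xb, gi = gi, gg = gg, go = go, tc = tc,
                mask = mask, z = z, probs = probs)
  list(probs = probs, cache = cache, running = fcn$running)
}

# Backward pass from softmax cross-entropy. y: integer class per column.
# Consumes the FCN activations still held in ctx from the last forward.
nn_backward <- function(p, config, cache, y, ctx) {
  B <- cache$B
  Fs3 <- config$conv_filters[3]
  dlogits <- cache$probs
  dlogits[cbind(y, seq_len(B))] <- dlogits[cbind(y, seq_len(B))] - 1
  dlogits <- dlogits / B
  g <- list()
  g$Wd <- tcrossprod(dlogits, cache$z)
  g$bd <- rowSums(dlogits)
  dz <- crossprod(p$Wd, dlogits)
  dgap <- dz[seq_len(Fs3), , drop = FALSE]
  dhd <- dz[Fs3 + seq_len(config$lstm_units), , drop = FALSE]
  dh <- if (is.null(cache$mask)) dhd else dhd * cache$mask
  dgo <- dh * cache$tc
  dc <- dh * cache$go * (1 - cache$tc^2)
  dgi <- dc * cache$gg
  dgg <- dc * cache$gi
  dzo <- dgo * cache$go * (1 - cache$go)
  dzi <- dgi * cache$gi * (1 - cache$gi)
  dzg <- dgg * (1 - cache$gg^2)
  g$Wo <- tcrossprod(dzo, cache$xb); g$bo <- rowSums(dzo)
  g$Wi <- tcrossprod(dzi, cache$xb); g$bi <- rowSums(dzi)
  g$Wg <- tcrossprod(dzg, cache$xb); g$bg <- rowSums(dzg)
  c(cpp_fcn_backward_ctx(ctx, dgap), g)
}

# Population batch-norm statistics under the current weights, following
# the inference recipe of the batch-normalization formulation, computed
# layer by layer: when layer j's moments are collected, layers below j
# propagate in inference mode with their already-pooled statistics, so
# the result does not depend on how the training set happens to be
# batched (batch-mode lower layers would make the pooled moments depend
# on batch composition). Per-batch moments are pooled weighted by batch
# size, with variance via E[y^2] - E[y]^2 so unequal batch means pool
# exactly. Running averages collected *during* training lag the weight
# trajectory badly at few batches per epoch; this pass replaces them.
nn_calibrate_running <- function(p, config, X, ctx) {
  n <- nrow(X)
  running <- nn_init_running(config)
  for (j in 1:3) {
    acc <- list(w = 0, mu = 0, m2 = 0)
    for (b0 in seq(1L, n, by = config$batch_size)) {
      idx <- b0:min(b0 + config$batch_size - 1L, n)
      fcn <- cpp_fcn_forward_ctx(ctx, t(X[idx, , drop = FALSE]),
                                 fcn_param_list(p), running, TRUE, 0, 1e-3,
                                 j - 1L)
      bs <- fcn$running[[j]]  # momentum 0: exact batch moments of layer j
      w <- length(idx)
      acc$w <- acc$w + w
      acc$mu <- acc$mu + w * bs$mu
      acc$m2 <- acc$m2 + w * (bs$va + bs$mu^2)
    }
    mu <- acc$mu / acc$w
    running[[j]] <- list(mu = mu, va = pmax(acc$m2 / acc$w - mu^2, 0))
  }
  running
}

adam_init <- function(p) {
  list(m = lapply(p, function(x) x * 0), v = lapply(p, function(x) x * 0),
       t = 0L)
}

adam_step <- function(p, g, st, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  st$t <- st$t + 1L
  bc1 <- 1 - beta1^st$t
  bc2 <- 1 - beta2^st$t
  for (nm in names(p)) {
    st$m[[nm]] <- beta1 * st$m[[nm]] + (1 - beta1) * g[[nm]]
    st$v[[nm]] <- beta2 * st$v[[nm]] + (1 - beta2) * g[[nm]]^2
    p[[nm]] <- p[[nm]] - lr * (st$m[[nm]] / bc1) /
      (sqrt(st$v[[nm]] / bc2) + eps)
  }
  list(p = p, st = st)
}
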