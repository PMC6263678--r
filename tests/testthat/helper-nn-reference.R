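# Plain-R double-precision reference implementation of the FCN branch
# (im2col convolution, batch normalization, ReLU, global average pooling)
# used as the independent oracle for the package's fused compiled kernels.
# Activation layout matches the compiled path: C x (L*B), position fastest.

ref_im2col <- function(x, C, K, L, B) {
  pl <- (K - 1L) %/% 2L
  idx <- rep((0:(B - 1L)) * (L + K - 1L), each = L) + pl + seq_len(L)
  xp <- matrix(0, C, (L + K - 1L) * B)
  xp[, idx] <- x
  col <- matrix(0, C * K, L * B)
  for (k in seq_len(K)) {
    col[((k - 1L) * C + 1L):(k * C), ] <- xp[, idx + (k - 1L - pl)]
  }
  col
}

ref_col2im <- function(dcol, C, K, L, B) {
  pl <- (K - 1L) %/% 2L
  idx <- rep((0:(B - 1L)) * (L + K - 1L), each = L) + pl + seq_len(L)
  dxp <- matrix(0, C, (L + K - 1L) * B)
  for (k in seq_len(K)) {
    sh <- idx + (k - 1L - pl)
    dxp[, sh] <- dxp[, sh] + dcol[((k - 1L) * C + 1L):(k * C), ]
  }
  dxp[, idx, drop = FALSE]
}

# forward through the three conv+bn+relu blocks and GAP; returns gap and
# the caches needed for the reference backward
ref_fcn_forward <- function(p, config, xb, running, train = TRUE,
                            momentum = 0.99, eps = 1e-3) {
  L <- nrow(xb); B <- ncol(xb)
  Fs <- config$conv_filters
  Ks <- config$conv_kernel_sizes
  Cs <- c(1L, Fs[1], Fs[2])
  a <- matrix(xb, 1L, L * B)
  caches <- list()
  for (i in 1:3) {
    col <- ref_im2col(a, Cs[i], Ks[i], L, B)
    y <- p[[paste0("W", i)]] %*% col + p[[paste0("b", i)]]
    if (train) {
      mu <- rowMeans(y)
      va <- rowMeans((y - mu)^2)
      running[[i]] <- list(mu = momentum * running[[i]]$mu + (1 - momentum) * mu,
                           va = momentum * running[[i]]$va + (1 - momentum) * va)
    } else {
      mu <- running[[i]]$mu
      va <- running[[i]]$va
    }
    invstd <- 1 / sqrt(va + eps)
    xhat <- (y - mu) * invstd
    out <- xhat * p[[paste0("gamma", i)]] + p[[paste0("beta", i)]]
    out <- out * (out > 0)
    caches[[i]] <- list(x = a, col = col, xhat = xhat, invstd = invstd,
                        out = out)
    a <- out
  }
  gap <- t(sapply(seq_len(Fs[3]), function(f) {
    colMeans(matrix(a[f, ], L, B))
  }))
  list(gap = gap, caches = caches, running = running)
}

ref_fcn_backward <- function(p, config, caches, dgap, L, B) {
  Fs <- config$conv_filters
  Ks <- config$conv_kernel_sizes
  Cs <- c(1L, Fs[1], Fs[2])
  da <- matrix(0, Fs[3], L * B)
  for (b in seq_len(B)) {
    da[, ((b - 1L) * L + 1L):(b * L)] <- dgap[, b] / L
  }
  g <- list()
  for (i in 3:1) {
    ch <- caches[[i]]
    da <- da * (ch$out > 0)
    gamma <- p[[paste0("gamma", i)]]
    g[[paste0("gamma", i)]] <- rowSums(da * ch$xhat)
    g[[paste0("beta", i)]] <- rowSums(da)
    dxhat <- da * gamma
    dy <- (dxhat - rowMeans(dxhat) - ch$xhat * rowMeans(dxhat * ch$xhat)) *
      ch$invstd
    g[[paste0("W", i)]] <- tcrossprod(dy, ch$col)
    g[[paste0("b", i)]] <- rowSums(dy)
    da <- ref_col2im(crossprod(p[[paste0("W", i)]], dy), Cs[i], Ks[i], L, B)
  }
  g
}
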