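# Low-level layer primitives for the segmentation network.
#
# Tensors are 4D arrays [H, W, C, N] (height, width, channels, batch).
# Convolutions use im2col + BLAS matmul; weights for a k x k convolution are
# stored as a (k*k*Cin) x Cout matrix whose rows are ordered offset-major
# (for each of the k*k kernel offsets, all Cin channels). Backward passes
# recompute the patch matrix from the cached layer input to keep memory flat.

# zero-pad spatial dims by p on each side
pad_spatial <- function(x, p) {
  if (p == 0) return(x)
  d <- dim(x)
  out <- array(0, c(d[1] + 2 * p, d[2] + 2 * p, d[3], d[4]))
  out[(p + 1):(p + d[1]), (p + 1):(p + d[2]), , ] <- x
  out
}

# im2col: [H, W, C, N] -> (H*W*N) x (k*k*C) patch matrix, built as a single
# indexed gather from the padded array (row r = (h, w, n) with h fastest;
# column c = (offset - 1) * C + channel, offsets enumerated dy-major)
im2col <- function(x, k) {
  d <- dim(x)
  p <- (k - 1) %/% 2
  xp <- pad_spatial(x, p)
  H <- d[1]; W <- d[2]; C <- d[3]; N <- d[4]
  Hp <- H + 2 * p; Wp <- W + 2 * p
  hh <- rep.int(seq_len(H), W * N)
  ww <- rep.int(rep(seq_len(W), each = H), N)
  nn <- rep(seq_len(N), each = H * W)
  base <- hh + (ww - 1) * Hp + (nn - 1) * (Hp * Wp * C)
  offs <- expand.grid(ci = seq_len(C) - 1L, dx = 0:(k - 1), dy = 0:(k - 1))
  col_off <- offs$dy + offs$dx * Hp + offs$ci * (Hp * Wp)
  idx <- outer(base, col_off, `+`)
  dim(idx) <- NULL  # plain vector: matrix indexing would mean coordinates
  P <- xp[idx]
  dim(P) <- c(H * W * N, k * k * C)
  P
}

conv_fwd <- function(x, W, b, k) {
  d <- dim(x)
  P <- im2col(x, k)
  out <- P %*% W
  out <- sweep(out, 2, b, `+`)
  dim(out) <- c(d[1], d[2], d[4], ncol(W))  # [H, W, N, Cout]
  out <- aperm(out, c(1, 2, 4, 3))
  # keep the patch matrix for backward when it is small; recompute otherwise
  list(out = out, x = x, P = if (length(P) <= 3e7) P else NULL)
}

conv_bwd <- function(dout, cache, W, k) {
  x <- cache$x
  d <- dim(x)
  H <- d[1]; W_ <- d[2]; C <- d[3]; N <- d[4]
  Cout <- ncol(W)
  dO <- aperm(dout, c(1, 2, 4, 3))
  dim(dO) <- c(H * W_ * N, Cout)
  P <- if (!is.null(cache$P)) cache$P else im2col(x, k)
  dW <- crossprod(P, dO)
  db <- colSums(dO)
  # input gradient = convolution of dout with the 180-degree-flipped kernels
  # (channels transposed): another im2col + matmul instead of a scatter-add
  k2 <- k * k
  Warr <- W
  dim(Warr) <- c(C, k2, Cout)
  Wflip <- aperm(Warr[, k2:1, , drop = FALSE], c(3, 2, 1))
  dim(Wflip) <- c(Cout * k2, C)
  dx <- im2col(dout, k) %*% Wflip
  dim(dx) <- c(H, W_, N, C)
  dx <- aperm(dx, c(1, 2, 4, 3))
  list(dx = dx, dW = dW, db = db)
}

# batch normalization over (H, W, N) per channel
bn_fwd <- function(x, gamma, beta, state, training, momentum = 0.9, eps = 1e-5) {
  d <- dim(x)
  xm <- aperm(x, c(1, 2, 4, 3))
  dim(xm) <- c(d[1] * d[2] * d[4], d[3])
  if (training) {
    mu <- colMeans(xm)
    v <- colMeans(xm^2) - mu^2
    state$mean <- momentum * state$mean + (1 - momentum) * mu
    state$var <- momentum * state$var + (1 - momentum) * v
  } else {
    mu <- state$mean
    v <- state$var
  }
  invstd <- 1 / sqrt(v + eps)
  xhat <- sweep(sweep(xm, 2, mu), 2, invstd, `*`)
  out <- sweep(sweep(xhat, 2, gamma, `*`), 2, beta, `+`)
  dim(out) <- c(d[1], d[2], d[4], d[3])
  out <- aperm(out, c(1, 2, 4, 3))
  list(out = out, xhat = xhat, invstd = invstd, state = state, dims = d)
}

bn_bwd <- function(dout, cache, gamma) {
  d <- cache$dims
  m <- d[1] * d[2] * d[4]
  dy <- aperm(dout, c(1, 2, 4, 3))
  dim(dy) <- c(m, d[3])
  xhat <- cache$xhat
  dgamma <- colSums(dy * xhat)
  dbeta <- colSums(dy)
  dxhat <- sweep(dy, 2, gamma, `*`)
  t1 <- sweep(dxhat, 2, colMeans(dxhat))
  t2 <- sweep(xhat, 2, colMeans(dxhat * xhat), `*`)
  dx <- sweep(t1 - t2, 2, cache$invstd, `*`)
  dim(dx) <- c(d[1], d[2], d[4], d[3])
  dx <- aperm(dx, c(1, 2, 4, 3))
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

maxpool_fwd <- function(x) {
  d <- dim(x)
  a <- list(x[seq(1, d[1], 2), seq(1, d[2], 2), , , drop = FALSE],
            x[seq(2, d[1], 2), seq(1, d[2], 2), , , drop = FALSE],
            x[seq(1, d[1], 2), seq(2, d[2], 2), , , drop = FALSE],
            x[seq(2, d[1], 2), seq(2, d[2], 2), , , drop = FALSE])
  out <- pmax(a[[1]], a[[2]], a[[3]], a[[4]])
  list(out = out, parts = a, dims = d)
}

maxpool_bwd <- function(dout, cache) {
  d <- cache$dims
  dx <- array(0, d)
  out <- cache$out
  taken <- array(FALSE, dim(out))
  rows <- list(seq(1, d[1], 2), seq(2, d[1], 2), seq(1, d[1], 2), seq(2, d[1], 2))
  cols <- list(seq(1, d[2], 2), seq(1, d[2], 2), seq(2, d[2], 2), seq(2, d[2], 2))
  for (i in 1:4) {
    hit <- (cache$parts[[i]] == out) & !taken
    taken <- taken | hit
    g <- dout * hit
    dx[rows[[i]], cols[[i]], , ] <- dx[rows[[i]], cols[[i]], , , drop = FALSE] + g
  }
  dx
}

upsample_fwd <- function(x) {
  d <- dim(x)
  x[rep(seq_len(d[1]), each = 2), rep(seq_len(d[2]), each = 2), , , drop = FALSE]
}

upsample_bwd <- function(dout) {
  d <- dim(dout)
  dout[seq(1, d[1], 2), seq(1, d[2], 2), , , drop = FALSE] +
    dout[seq(2, d[1], 2), seq(1, d[2], 2), , , drop = FALSE] +
    dout[seq(1, d[1], 2), seq(2, d[2], 2), , , drop = FALSE] +
    dout[seq(2, d[1], 2), seq(2, d[2], 2), , , drop = FALSE]
}

concat_channels <- function(a, b) {
  da <- dim(a); db <- dim(b)
  out <- array(0, c(da[1], da[2], da[3] + db[3], da[4]))
  out[, , seq_len(da[3]), ] <- a
  out[, , da[3] + seq_len(db[3]), ] <- b
  out
}
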