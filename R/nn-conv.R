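# Convolutional primitives on channel-first (C, H, W, B) arrays, built on the
# compiled im2col/col2im kernels so the heavy lifting is one BLAS matmul per
# layer. The channel-first layout lets per-channel statistics and scalings
# recycle naturally (a length-C vector recycles down a (C, H*W*B) matrix),
# avoiding array permutations in the hot path.

conv2d_fwd <- function(x, p, stride = 1, pad = 0) {
  d <- dim(x)
  k <- dim(p$W)[1]
  stopifnot(d[1] == dim(p$W)[3])
  cols <- im2col_cpp(x, d[1], d[2], d[3], d[4], k, stride, pad)
  wmat <- matrix(aperm(p$W, c(3, 1, 2, 4)), k * k * d[1]) # rows: c,kh,kw
  out <- crossprod(wmat, cols) + p$b                      # Cout x (oH*oW*B)
  oH <- (d[2] + 2 * pad - k) %/% stride + 1
  oW <- (d[3] + 2 * pad - k) %/% stride + 1
  dim(out) <- c(dim(p$W)[4], oH, oW, d[4])                # in-place reshape
  list(out = out, cols = cols, in_dim = d, stride = stride, pad = pad, k = k)
}

conv2d_bwd <- function(dy, p, cache, input_grad = TRUE) {
  d <- cache$in_dim
  k <- cache$k
  c_out <- dim(p$W)[4]
  dymat <- matrix(dy, c_out)                              # Cout x (oH*oW*B)
  dwmat <- tcrossprod(dymat, cache$cols)                  # Cout x (c,kh,kw)
  dx <- NULL
  if (input_grad) {
    wmat <- matrix(aperm(p$W, c(3, 1, 2, 4)), k * k * d[1], c_out)
    dcols <- wmat %*% dymat
    dx <- col2im_cpp(dcols, d[1], d[2], d[3], d[4], k, cache$stride, cache$pad)
  }
  dW <- aperm(array(t(dwmat), c(d[1], k, k, c_out)), c(2, 3, 1, 4))
  list(dx = dx, dW = dW, db = rowSums(dymat))
}

## ---- batch normalization ----------------------------------------------------

# Per-channel batch norm over (H, W, B). Running statistics live in `buf`
# (list(mean, var)) and are returned updated when train = TRUE.
batchnorm_fwd <- function(x, p, buf, train, momentum = 0.1, eps = 1e-5) {
  d <- dim(x)
  C <- d[1]
  n <- d[2] * d[3] * d[4]
  xm <- matrix(x, C)                                      # C x (H*W*B)
  if (train) {
    mu <- rowMeans(xm)
    v <- rowMeans(xm^2) - mu^2
    buf$mean <- (1 - momentum) * buf$mean + momentum * mu
    buf$var <- (1 - momentum) * buf$var + momentum * v * n / max(n - 1, 1)
  } else {
    mu <- buf$mean
    v <- buf$var
  }
  istd <- 1 / sqrt(v + eps)
  xhat <- (xm - mu) * istd                                # length-C recycling
  out <- xhat * p$g + p$b
  dim(out) <- d
  list(out = out, xhat = xhat, istd = istd, dims = d, train = train, buf = buf)
}

batchnorm_bwd <- function(dy, p, cache) {
  d <- cache$dims
  C <- d[1]
  n <- d[2] * d[3] * d[4]
  dym <- matrix(dy, C)
  xhat <- cache$xhat
  dg <- rowSums(dym * xhat)
  db <- rowSums(dym)
  dxhat <- dym * p$g
  if (cache$train) {
    s1 <- rowSums(dxhat)
    s2 <- rowSums(dxhat * xhat)
    dxm <- (dxhat - s1 / n - xhat * (s2 / n)) * cache$istd
  } else {
    dxm <- dxhat * cache$istd
  }
  dim(dxm) <- d
  list(dx = dxm, dg = dg, db = db)
}

## ---- pooling ----------------------------------------------------------------

maxpool_fwd <- function(x, k, stride, pad = 0) {
  d <- dim(x)
  r <- maxpool_cpp(x, d[1], d[2], d[3], d[4], k, stride, pad)
  list(out = r$out, argmax = r$argmax, in_dim = d)
}

maxpool_bwd <- function(dy, cache) {
  dx <- numeric(prod(cache$in_dim))
  acc <- tapply(as.vector(dy), as.vector(cache$argmax), sum)
  dx[as.integer(names(acc))] <- acc
  array(dx, dim = cache$in_dim)
}

# Global average pooling: (C, H, W, B) -> C x B.
gap_fwd <- function(x) {
  d <- dim(x)
  hw <- d[2] * d[3]
  m <- matrix(x, d[1] * hw, d[4])
  out <- matrix(0, d[1], d[4])
  for (b in seq_len(d[4]))
    out[, b] <- rowMeans(matrix(m[, b], d[1], hw))
  list(out = out, in_dim = d)
}

gap_bwd <- function(dy, cache) {
  d <- cache$in_dim
  hw <- d[2] * d[3]
  array(dy[, rep(seq_len(d[4]), each = hw)] / hw, dim = d)
}
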