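# Residual CNN branch: a five-stage, stride-32 backbone followed by
# squeeze-and-excitation channel recalibration and projection to the shared
# embedding dimension. The backbone is a flat list of named blocks so that
# intermediate activations (and their gradients, for Grad-CAM) are addressable
# by block name.

## ---- block constructors -----------------------------------------------------

block_convbn <- function(name, c_in, c_out, k, stride, pad) {
  list(type = "convbn", name = name, k = k, stride = stride, pad = pad,
       params = list(conv = conv_init(k, c_in, c_out), bn = batchnorm_init(c_out)),
       buffers = list(bn = list(mean = numeric(c_out), var = rep(1, c_out))))
}

block_maxpool <- function(name, k, stride, pad) {
  list(type = "maxpool", name = name, k = k, stride = stride, pad = pad,
       params = list(), buffers = list())
}

# Two 3x3 convs with a projected 1x1 shortcut (used by the reduced backbone).
block_res <- function(name, c_in, c_out, stride, res_gain = 1) {
  list(type = "res", name = name, stride = stride,
       params = list(conv1 = conv_init(3, c_in, c_out), bn1 = batchnorm_init(c_out),
                     conv2 = conv_init(3, c_out, c_out),
                     bn2 = batchnorm_init(c_out, gain = res_gain),
                     convs = conv_init(1, c_in, c_out), bns = batchnorm_init(c_out)),
       buffers = list(bn1 = list(mean = numeric(c_out), var = rep(1, c_out)),
                      bn2 = list(mean = numeric(c_out), var = rep(1, c_out)),
                      bns = list(mean = numeric(c_out), var = rep(1, c_out))))
}

# 1x1 -> 3x3 -> 1x1 bottleneck (full-scale backbone); shortcut projected when
# the shape changes, identity otherwise.
block_bottleneck <- function(name, c_in, c_mid, c_out, stride, res_gain = 1) {
  proj <- (stride != 1L) || (c_in != c_out)
  p <- list(conv1 = conv_init(1, c_in, c_mid), bn1 = batchnorm_init(c_mid),
            conv2 = conv_init(3, c_mid, c_mid), bn2 = batchnorm_init(c_mid),
            conv3 = conv_init(1, c_mid, c_out),
            bn3 = batchnorm_init(c_out, gain = res_gain))
  b <- list(bn1 = list(mean = numeric(c_mid), var = rep(1, c_mid)),
            bn2 = list(mean = numeric(c_mid), var = rep(1, c_mid)),
            bn3 = list(mean = numeric(c_out), var = rep(1, c_out)))
  if (proj) {
    p$convs <- conv_init(1, c_in, c_out)
    p$bns <- batchnorm_init(c_out)
    b$bns <- list(mean = numeric(c_out), var = rep(1, c_out))
  }
  list(type = "bottleneck", name = name, stride = stride, proj = proj,
       params = p, buffers = b)
}

## ---- branch constructor -----------------------------------------------------

#' Build the CNN branch
#'
#' Constructs the residual backbone (five stages, total stride 32), the SE
#' recalibration gate and the projection to the shared embedding dimension,
#' with freshly initialized weights drawn from the current RNG state.
#'
#' @param config a configuration list from [histofuse_config()]; only the
#'   `model` entry is consulted.
#' @return a `cnn_branch` list with `blocks`, `se`, `proj`, `out_channels`,
#'   `stride` and `dim`.
#' @export
cnn_branch <- function(config) {
  m <- config$model
  d <- m$fusion$dim
  if (m$cnn$scale == "full") {
    blocks <- list(block_convbn("stage0.conv", 3, 64, 7, 2, 3),
                   block_maxpool("stage0", 3, 2, 1))
    layout <- list(stage1 = c(3, 64, 256, 1), stage2 = c(4, 128, 512, 2),
                   stage3 = c(6, 256, 1024, 2), stage4 = c(3, 512, 2048, 2))
    res_gain <- 1 / sqrt(sum(vapply(layout, `[`, numeric(1), 1)))
    c_in <- 64
    for (st in names(layout)) {
      n_blk <- layout[[st]][1]; c_mid <- layout[[st]][2]
      c_out <- layout[[st]][3]; s <- layout[[st]][4]
      for (i in seq_len(n_blk)) {
        blocks[[length(blocks) + 1L]] <- block_bottleneck(
          paste0(st, ".block", i), c_in, c_mid, c_out, if (i == 1L) s else 1L,
          res_gain = res_gain)
        c_in <- c_out
      }
    }
    out_channels <- 2048
  } else {
    ch <- m$cnn$channels
    stopifnot(length(ch) == 5)
    blocks <- list(block_convbn("stage0", 3, ch[1], 3, 2, 1))
    for (i in 2:5) {
      blocks[[length(blocks) + 1L]] <-
        block_res(paste0("stage", i - 1L), ch[i - 1L], ch[i], 2L,
                  res_gain = 0.5)
    }
    out_channels <- ch[5]
  }
  se_hidden <- max(1L, out_channels %/% m$cnn$se_ratio)
  structure(list(
    blocks = blocks,
    se = list(fc1 = linear_init(out_channels, se_hidden),
              fc2 = linear_init(se_hidden, out_channels, scale = 1)),
    proj = linear_init(out_channels, d, scale = 1),
    out_channels = out_channels, stride = 32L, dim = d,
    scale = m$cnn$scale
  ), class = "cnn_branch")
}

## ---- block forward/backward -------------------------------------------------

cnn_block_fwd <- function(blk, x, train) {
  switch(blk$type,
    convbn = {
      c1 <- conv2d_fwd(x, blk$params$conv, blk$stride, blk$pad)
      b1 <- batchnorm_fwd(c1$out, blk$params$bn, blk$buffers$bn, train)
      r1 <- relu_fwd(b1$out)
      list(out = r1$out, cache = list(c1 = c1, b1 = b1, r1 = r1),
           buffers = list(bn = b1$buf))
    },
    maxpool = {
      mp <- maxpool_fwd(x, blk$k, blk$stride, blk$pad)
      list(out = mp$out, cache = mp, buffers = list())
    },
    res = {
      c1 <- conv2d_fwd(x, blk$params$conv1, blk$stride, 1)
      b1 <- batchnorm_fwd(c1$out, blk$params$bn1, blk$buffers$bn1, train)
      r1 <- relu_fwd(b1$out)
      c2 <- conv2d_fwd(r1$out, blk$params$conv2, 1, 1)
      b2 <- batchnorm_fwd(c2$out, blk$params$bn2, blk$buffers$bn2, train)
      cs <- conv2d_fwd(x, blk$params$convs, blk$stride, 0)
      bs <- batchnorm_fwd(cs$out, blk$params$bns, blk$buffers$bns, train)
      ro <- relu_fwd(b2$out + bs$out)
      list(out = ro$out,
           cache = list(c1 = c1, b1 = b1, r1 = r1, c2 = c2, b2 = b2,
                        cs = cs, bs = bs, ro = ro),
           buffers = list(bn1 = b1$buf, bn2 = b2$buf, bns = bs$buf))
    },
    bottleneck = {
      c1 <- conv2d_fwd(x, blk$params$conv1, 1, 0)
      b1 <- batchnorm_fwd(c1$out, blk$params$bn1, blk$buffers$bn1, train)
      r1 <- relu_fwd(b1$out)
      c2 <- conv2d_fwd(r1$out, blk$params$conv2, blk$stride, 1)
      b2 <- batchnorm_fwd(c2$out, blk$params$bn2, blk$buffers$bn2, train)
      r2 <- relu_fwd(b2$out)
      c3 <- conv2d_fwd(r2$out, blk$params$conv3, 1, 0)
      b3 <- batchnorm_fwd(c3$out, blk$params$bn3, blk$buffers$bn3, train)
      if (blk$proj) {
        cs <- conv2d_fwd(x, blk$params$convs, blk$stride, 0)
        bs <- batchnorm_fwd(cs$out, blk$params$bns, blk$buffers$bns, train)
        short <- bs$out
      } else {
        cs <- NULL; bs <- NULL; short <- x
      }
      ro <- relu_fwd(b3$out + short)
      bufs <- list(bn1 = b1$buf, bn2 = b2$buf, bn3 = b3$buf)
      if (blk$proj) bufs$bns <- bs$buf
      list(out = ro$out,
           cache = list(c1 = c1, b1 = b1, r1 = r1, c2 = c2, b2 = b2, r2 = r2,
                        c3 = c3, b3 = b3, cs = cs, bs = bs, ro = ro),
           buffers = bufs)
    },
    stop("unknown block type: ", blk$type))
}

cnn_block_bwd <- function(blk, dy, cache, input_grad = TRUE) {
  switch(blk$type,
    convbn = {
      dr <- relu_bwd(dy, cache$r1)
      db <- batchnorm_bwd(dr, blk$params$bn, cache$b1)
      dc <- conv2d_bwd(db$dx, blk$params$conv, cache$c1, input_grad)
      list(dx = dc$dx,
           grads = list(conv = list(W = dc$dW, b = dc$db),
                        bn = list(g = db$dg, b = db$db)))
    },
    maxpool = list(dx = maxpool_bwd(dy, cache), grads = list()),
    res = {
      dsum <- relu_bwd(dy, cache$ro)
      dbs <- batchnorm_bwd(dsum, blk$params$bns, cache$bs)
      dcs <- conv2d_bwd(dbs$dx, blk$params$convs, cache$cs, input_grad)
      db2 <- batchnorm_bwd(dsum, blk$params$bn2, cache$b2)
      dc2 <- conv2d_bwd(db2$dx, blk$params$conv2, cache$c2)
      dr1 <- relu_bwd(dc2$dx, cache$r1)
      db1 <- batchnorm_bwd(dr1, blk$params$bn1, cache$b1)
      dc1 <- conv2d_bwd(db1$dx, blk$params$conv1, cache$c1, input_grad)
      list(dx = if (input_grad) dc1$dx + dcs$dx else NULL,
           grads = list(conv1 = list(W = dc1$dW, b = dc1$db),
                        bn1 = list(g = db1$dg, b = db1$db),
                        conv2 = list(W = dc2$dW, b = dc2$db),
                        bn2 = list(g = db2$dg, b = db2$db),
                        convs = list(W = dcs$dW, b = dcs$db),
                        bns = list(g = dbs$dg, b = dbs$db)))
    },
    bottleneck = {
      dsum <- relu_bwd(dy, cache$ro)
      db3 <- batchnorm_bwd(dsum, blk$params$bn3, cache$b3)
      dc3 <- conv2d_bwd(db3$dx, blk$params$conv3, cache$c3)
      dr2 <- relu_bwd(dc3$dx, cache$r2)
      db2 <- batchnorm_bwd(dr2, blk$params$bn2, cache$b2)
      dc2 <- conv2d_bwd(db2$dx, blk$params$conv2, cache$c2)
      dr1 <- relu_bwd(dc2$dx, cache$r1)
      db1 <- batchnorm_bwd(dr1, blk$params$bn1, cache$b1)
      dc1 <- conv2d_bwd(db1$dx, blk$params$conv1, cache$c1)
      g <- list(conv1 = list(W = dc1$dW, b = dc1$db),
                bn1 = list(g = db1$dg, b = db1$db),
                conv2 = list(W = dc2$dW, b = dc2$db),
                bn2 = list(g = db2$dg, b = db2$db),
                conv3 = list(W = dc3$dW, b = dc3$db),
                bn3 = list(g = db3$dg, b = db3$db))
      if (blk$proj) {
        dbs <- batchnorm_bwd(dsum, blk$params$bns, cache$bs)
        dcs <- conv2d_bwd(dbs$dx, blk$params$convs, cache$cs)
        g$convs <- list(W = dcs$dW, b = dcs$db)
        g$bns <- list(g = dbs$dg, b = dbs$db)
        dx <- dc1$dx + dcs$dx
      } else {
        dx <- dc1$dx + dsum
      }
      list(dx = dx, grads = g)
    })
}

## ---- branch-level operations ------------------------------------------------

#' Extract local feature maps
#'
#' Runs an image batch through the residual backbone. Spatial dimensions must
#' be divisible by the total stride (32); the output has `H/32 x W/32` spatial
#' extent and the backbone's final channel count (2048 at full scale).
#'
#' @param images numeric array `(H, W, 3, B)` with values in `[0, 1]`.
#' @param branch a [cnn_branch()] object.
#' @param train logical; `TRUE` uses batch statistics in the normalization
#'   layers (training mode).
#' @return the final feature map, a channel-first `(C, h, w, B)` array. With
#'   `full = TRUE` (internal use) a list carrying per-block caches as well.
#' @param full return the full cache list instead of just the feature map.
#' @export
extract_local_features <- function(images, branch, train = FALSE, full = FALSE) {
  d <- dim(images)
  if (length(d) == 3L) { dim(images) <- c(d, 1L); d <- dim(images) }
  if (d[1] %% branch$stride != 0 || d[2] %% branch$stride != 0) {
    stop("image spatial dims (", d[1], "x", d[2], ") must be divisible by ",
         "the backbone stride ", branch$stride)
  }
  if (d[3] != 3L) stop("expected 3 input channels, got ", d[3])
  x <- aperm(images, c(3, 1, 2, 4))          # to channel-first
  caches <- vector("list", length(branch$blocks))
  activations <- list()
  for (i in seq_along(branch$blocks)) {
    blk <- branch$blocks[[i]]
    r <- cnn_block_fwd(blk, x, train)
    x <- r$out
    caches[[i]] <- r$cache
    activations[[blk$name]] <- x
    if (train && length(r$buffers)) branch$blocks[[i]]$buffers <- r$buffers
  }
  if (!full) return(x)
  list(out = x, caches = caches, activations = activations, branch = branch)
}

# Backward through the backbone. `capture` names blocks whose output
# gradients should be recorded (Grad-CAM). Returns dx, per-block grads
# (named list parallel to branch$blocks) and the captured activation grads.
cnn_backbone_bwd <- function(branch, dy, caches, capture = character(),
                             input_grad = FALSE) {
  n <- length(branch$blocks)
  grads <- vector("list", n)
  act_grads <- list()
  for (i in rev(seq_len(n))) {
    blk <- branch$blocks[[i]]
    if (blk$name %in% capture) act_grads[[blk$name]] <- dy
    r <- cnn_block_bwd(blk, dy, caches[[i]], input_grad = input_grad || i > 1L)
    grads[[i]] <- r$grads
    dy <- r$dx
  }
  list(dx = dy, grads = grads, act_grads = act_grads)
}

#' Squeeze-and-excitation channel recalibration
#'
#' Pools the feature map globally per channel, passes the descriptor through a
#' two-layer bottleneck (ReLU then sigmoid) and rescales every channel by the
#' resulting gate in `(0, 1)`.
#'
#' @param features channel-first `(C, h, w, B)` feature map.
#' @param gate SE parameters: `list(fc1 = list(W, b), fc2 = list(W, b))` with
#'   `fc1` mapping `C -> C/r` and `fc2` back to `C`.
#' @return list with `features` (recalibrated map, same shape), `gate`
#'   (`B x C` matrix of sigmoid weights) and `cache` for the backward pass.
#' @export
se_recalibrate <- function(features, gate) {
  d <- dim(features)
  if (ncol(gate$fc1$W) != d[1])
    stop("SE gate expects ", ncol(gate$fc1$W), " channels, got ", d[1])
  hw <- d[2] * d[3]
  g <- gap_fwd(features)                       # C x B descriptor
  l1 <- linear_fwd(g$out, gate$fc1)
  r1 <- relu_fwd(l1$out)
  l2 <- linear_fwd(r1$out, gate$fc2)
  s <- sigmoid(l2$out)                         # C x B in (0,1)
  scale <- s[, rep(seq_len(d[4]), each = hw), drop = FALSE]  # C x (hw*B)
  out <- array(matrix(features, d[1]) * scale, d)
  list(features = out, gate = t(s),
       cache = list(g = g, l1 = l1, r1 = r1, l2 = l2, s = s, x = features,
                    scale = scale))
}

se_bwd <- function(dy, gate, cache) {
  d <- dim(cache$x)
  hw <- d[2] * d[3]
  dx_direct <- array(matrix(dy, d[1]) * cache$scale, d)
  prod_m <- matrix(dy * cache$x, d[1] * hw, d[4])
  ds <- matrix(0, d[1], d[4])
  for (b in seq_len(d[4]))
    ds[, b] <- rowSums(matrix(prod_m[, b], d[1], hw))
  dl2 <- ds * cache$s * (1 - cache$s)
  g2 <- linear_bwd(dl2, gate$fc2, cache$l2)
  dr1 <- relu_bwd(g2$dx, cache$r1)
  g1 <- linear_bwd(dr1, gate$fc1, cache$l1)
  du <- gap_bwd(g1$dx, cache$g)
  list(dx = dx_direct + du,
       grads = list(fc1 = list(W = g1$dW, b = g1$db),
                    fc2 = list(W = g2$dW, b = g2$db)))
}

#' Project pooled CNN features to the shared embedding
#'
#' Global average pooling of the (recalibrated) feature map followed by a
#' linear map to the shared dimension `d`.
#'
#' @param features channel-first `(C, h, w, B)` feature map.
#' @param proj `list(W, b)` with `W` of shape `d x C`.
#' @return `B x d` embedding matrix.
#' @export
project_cnn_embedding <- function(features, proj) {
  if (ncol(proj$W) != dim(features)[1])
    stop("projection expects ", ncol(proj$W), " channels, got ",
         dim(features)[1])
  g <- gap_fwd(features)
  t(linear_fwd(g$out, proj)$out)
}
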