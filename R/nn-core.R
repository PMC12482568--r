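# Minimal dense neural-network primitives (forward + explicit backward).
#
# Conventions used throughout the package:
#   * vector-valued batches are D x n matrices (columns are samples/tokens),
#   * image batches are (H, W, C, B) arrays,
#   * token sequences are (D, T, B) arrays,
#   * every *_bwd() takes the upstream gradient with the same shape as the
#     forward output and returns the input gradient plus parameter gradients.

#' @useDynLib histofuse, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm runif rpois quantile sd pt p.adjust t.test setNames
#' @importFrom utils read.csv write.csv modifyList
NULL

## ---- initializers -----------------------------------------------------------

# He-style fan-in init for a dense layer mapping d_in -> d_out.
linear_init <- function(d_in, d_out, scale = sqrt(2)) {
  list(W = matrix(rnorm(d_out * d_in, sd = scale / sqrt(d_in)), d_out, d_in),
       b = numeric(d_out))
}

conv_init <- function(k, c_in, c_out) {
  fan_in <- k * k * c_in
  list(W = array(rnorm(k * k * c_in * c_out, sd = sqrt(2 / fan_in)),
                 dim = c(k, k, c_in, c_out)),
       b = numeric(c_out))
}

layernorm_init <- function(d) list(g = rep(1, d), b = numeric(d))

# The last norm of each residual block is initialized with gain 1/sqrt(L)
# (L = residual blocks in the backbone), which keeps the activation variance
# bounded with depth at initialization instead of growing geometrically.
batchnorm_init <- function(c, gain = 1) list(g = rep(gain, c), b = numeric(c))

## ---- dense layer ------------------------------------------------------------

linear_fwd <- function(x, p) {
  list(out = p$W %*% x + p$b, x = x)
}

linear_bwd <- function(dy, p, cache) {
  list(dx = crossprod(p$W, dy),
       dW = tcrossprod(dy, cache$x),
       db = rowSums(dy))
}

## ---- activations ------------------------------------------------------------

relu_fwd <- function(x) list(out = pmax(x, 0), mask = x > 0)
relu_bwd <- function(dy, cache) dy * cache$mask

# Exact GELU x * Phi(x).
gelu_fwd <- function(x) list(out = x * stats::pnorm(x), x = x)
gelu_bwd <- function(dy, cache) {
  x <- cache$x
  dy * (stats::pnorm(x) + x * stats::dnorm(x))
}

sigmoid <- function(x) 1 / (1 + exp(-x))

## ---- layer normalization ----------------------------------------------------

# LayerNorm over the feature dimension of a D x n matrix (per column).
layernorm_fwd <- function(x, p, eps = 1e-5) {
  mu <- colMeans(x)
  xc <- sweep(x, 2, mu)
  v <- colMeans(xc^2)
  istd <- 1 / sqrt(v + eps)
  xhat <- sweep(xc, 2, istd, `*`)
  list(out = p$g * xhat + p$b, xhat = xhat, istd = istd)
}

layernorm_bwd <- function(dy, p, cache) {
  xhat <- cache$xhat
  D <- nrow(xhat)
  dxhat <- dy * p$g
  # per-column: dx = istd/D * (D*dxhat - sum(dxhat) - xhat * sum(dxhat*xhat))
  s1 <- colSums(dxhat)
  s2 <- colSums(dxhat * xhat)
  dx <- sweep(D * dxhat - matrix(s1, D, length(s1), byrow = TRUE) -
                sweep(xhat, 2, s2, `*`), 2, cache$istd / D, `*`)
  list(dx = dx, dg = rowSums(dy * xhat), db = rowSums(dy))
}

## ---- softmax / dropout ------------------------------------------------------

# Numerically stable softmax over rows of an n x C matrix.
softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

dropout_fwd <- function(x, rate, train) {
  if (!train || rate <= 0) return(list(out = x, mask = NULL))
  mask <- array(runif(length(x)) >= rate, dim = dim(x) %||% length(x))
  list(out = x * mask / (1 - rate), mask = mask, rate = rate)
}

dropout_bwd <- function(dy, cache) {
  if (is.null(cache$mask)) return(dy)
  dy * cache$mask / (1 - cache$rate)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## ---- parameter tree utilities ----------------------------------------------

# Flatten a nested list of numeric arrays into a flat named list
# ("cnn.stage1.conv.W", ...). Used by the optimizer and checkpointing.
flatten_params <- function(x, prefix = "") {
  out <- list()
  nms <- names(x) %||% as.character(seq_along(x))
  if (is.null(names(x)) && length(x)) nms <- as.character(seq_along(x))
  for (i in seq_along(x)) {
    key <- if (nzchar(prefix)) paste0(prefix, ".", nms[i]) else nms[i]
    if (is.list(x[[i]])) {
      out <- c(out, flatten_params(x[[i]], key))
    } else if (is.double(x[[i]])) {   # integer fields (e.g. head counts) are
      out[[key]] <- x[[i]]           # structural, not trainable
    }
  }
  out
}

# Inverse of flatten_params(): write flat entries back into the skeleton.
unflatten_params <- function(flat, skeleton, prefix = "") {
  nms <- names(skeleton) %||% as.character(seq_along(skeleton))
  for (i in seq_along(skeleton)) {
    key <- if (nzchar(prefix)) paste0(prefix, ".", nms[i]) else nms[i]
    if (is.list(skeleton[[i]])) {
      skeleton[[i]] <- unflatten_params(flat, skeleton[[i]], key)
    } else if (!is.null(flat[[key]])) {
      skeleton[[i]] <- flat[[key]]
    }
  }
  skeleton
}

# Elementwise accumulate two parameter-gradient trees of identical shape.
accumulate_grads <- function(a, b) {
  if (is.null(a)) return(b)
  if (is.null(b)) return(a)
  if (is.numeric(a)) return(a + b)
  for (nm in names(b)) a[[nm]] <- accumulate_grads(a[[nm]], b[[nm]])
  a
}

# Evaluate `code` under a temporary RNG seed, restoring the caller's state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
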