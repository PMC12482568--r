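# Vision Transformer branch. Images are cut into P x P patches, linearly
# projected, prepended with a learned [CLS] token and summed with a learned
# position encoding. A stack of pre-norm encoder blocks (LN -> MSA -> residual,
# LN -> MLP -> residual) is run, the [CLS] state is tapped after each
# configured block, and the taps are averaged into the branch embedding.

vit_block_init <- function(d, heads, mlp_dim) {
  list(ln1 = layernorm_init(d), msa = msa_init(d, heads),
       ln2 = layernorm_init(d),
       fc1 = linear_init(d, mlp_dim), fc2 = linear_init(mlp_dim, d))
}

#' Build the ViT branch
#'
#' @param config configuration list from [histofuse_config()]; consults
#'   `model$vit` (`patch_size`, `depth`, `dim`, `heads`, `mlp_ratio`,
#'   `tap_layers`, `image_size`).
#' @return a `vit_branch` list with patch projection, CLS token, position
#'   encoding and encoder blocks, initialized from the current RNG state.
#' @export
vit_branch <- function(config) {
  v <- config$model$vit
  if (any(v$tap_layers < 1 | v$tap_layers > v$depth))
    stop("tap layers must lie in [1, ", v$depth, "]")
  P <- v$patch_size
  n_patch <- (v$image_size %/% P)^2
  structure(list(
    patch = linear_init(3 * P * P, v$dim, scale = 1),
    cls = rnorm(v$dim, sd = 0.02),
    pe = matrix(rnorm(v$dim * (n_patch + 1), sd = 0.02), v$dim, n_patch + 1),
    blocks = lapply(seq_len(v$depth), function(i)
      vit_block_init(v$dim, v$heads, round(v$dim * v$mlp_ratio))),
    patch_size = P, dim = v$dim, depth = v$depth, heads = v$heads,
    tap_layers = sort(v$tap_layers), n_patch = n_patch
  ), class = "vit_branch")
}

#' Tokenize an image batch
#'
#' Cuts each image into non-overlapping `P x P` patches (column-major over the
#' patch grid), projects each flattened patch to the token dimension, prepends
#' the `[CLS]` token and adds the learned position encoding once.
#'
#' @param images `(H, W, 3, B)` array; `H` and `W` must be divisible by the
#'   patch size.
#' @param branch a [vit_branch()] object.
#' @return list with `tokens` (`(D, N+1, B)` array, first token is `[CLS]`) and
#'   the cache used by the backward pass.
#' @export
patch_embed <- function(images, branch) {
  d <- dim(images)
  if (length(d) == 3L) { dim(images) <- c(d, 1L); d <- dim(images) }
  P <- branch$patch_size
  if (d[1] %% P != 0 || d[2] %% P != 0)
    stop("image dims (", d[1], "x", d[2], ") not divisible by patch size ", P)
  N <- (d[1] %/% P) * (d[2] %/% P)
  if (N != branch$n_patch)
    stop("image yields ", N, " patches but the position encoding was built ",
         "for ", branch$n_patch)
  xcf <- aperm(images, c(3, 1, 2, 4))          # channel-first for im2col
  cols <- im2col_cpp(xcf, 3L, d[1], d[2], d[4], P, P, 0L)      # (3P^2) x (N*B)
  pr <- linear_fwd(cols, branch$patch)
  tokens <- array(0, c(branch$dim, N + 1L, d[4]))
  tokens[, 1L, ] <- branch$cls
  tokens[, -1L, ] <- pr$out
  tokens <- tokens + as.vector(branch$pe)      # broadcast over batch
  list(tokens = tokens, cols = cols, in_dim = d, n_patch = N)
}

vit_block_fwd <- function(x, p) {
  d <- dim(x)
  n1 <- layernorm_fwd(matrix(x, d[1]), p$ln1)
  a <- msa_fwd(array(n1$out, d), p$msa)
  x2 <- x + a$out
  n2 <- layernorm_fwd(matrix(x2, d[1]), p$ln2)
  f1 <- linear_fwd(n2$out, p$fc1)
  g1 <- gelu_fwd(f1$out)
  f2 <- linear_fwd(g1$out, p$fc2)
  out <- x2 + array(f2$out, d)
  list(out = out, n1 = n1, a = a, n2 = n2, f1 = f1, g1 = g1, f2 = f2, dims = d)
}

vit_block_bwd <- function(dy, p, cache) {
  d <- cache$dims
  dym <- matrix(dy, d[1])
  gf2 <- linear_bwd(dym, p$fc2, cache$f2)
  dg1 <- gelu_bwd(gf2$dx, cache$g1)
  gf1 <- linear_bwd(dg1, p$fc1, cache$f1)
  gn2 <- layernorm_bwd(gf1$dx, p$ln2, cache$n2)
  dx2 <- dy + array(gn2$dx, d)
  ga <- msa_bwd(dx2, p$msa, cache$a)
  gn1 <- layernorm_bwd(matrix(ga$dx, d[1]), p$ln1, cache$n1)
  list(dx = dx2 + array(gn1$dx, d),
       grads = list(ln1 = list(g = gn1$dg, b = gn1$db), msa = ga$grads,
                    ln2 = list(g = gn2$dg, b = gn2$db),
                    fc1 = list(W = gf1$dW, b = gf1$db),
                    fc2 = list(W = gf2$dW, b = gf2$db)))
}

#' Encode tokens and tap `[CLS]` states
#'
#' Runs the encoder stack and captures the `[CLS]` token after each tapped
#' block's output (post-MLP, post-residual).
#'
#' @param tokens `(D, N+1, B)` token array (from [patch_embed()]).
#' @param branch a [vit_branch()] object.
#' @param tap_layers integer vector of 1-based block indices; defaults to the
#'   branch's configured taps.
#' @param full return per-block caches for the backward pass.
#' @return list of taps (each `list(layer_index, vector)` with `vector` a
#'   `B x D` matrix), ordered by ascending layer; with `full = TRUE`, a list
#'   with `taps`, `caches`, and the final token array.
#' @export
encode_with_cls_taps <- function(tokens, branch, tap_layers = branch$tap_layers,
                                 full = FALSE) {
  tap_layers <- sort(as.integer(tap_layers))
  if (length(tap_layers) < 1L) stop("need at least one tap layer")
  if (any(tap_layers < 1L | tap_layers > branch$depth))
    stop("tap layers must lie in [1, ", branch$depth, "]")
  x <- tokens
  caches <- vector("list", branch$depth)
  taps <- list()
  for (l in seq_len(branch$depth)) {
    r <- vit_block_fwd(x, branch$blocks[[l]])
    x <- r$out
    caches[[l]] <- r
    if (l %in% tap_layers) {
      taps[[length(taps) + 1L]] <-
        list(layer_index = l, vector = t(matrix(x[, 1L, ], dim(x)[1])))
    }
  }
  if (!full) return(taps)
  list(taps = taps, caches = caches, out = x, tap_layers = tap_layers)
}

#' Average tapped `[CLS]` tokens into the branch embedding
#'
#' @param taps list of taps from [encode_with_cls_taps()] (or plain `B x D`
#'   matrices).
#' @return `B x D` matrix: the arithmetic mean of the tapped `[CLS]` vectors.
#' @export
fuse_cls_tokens <- function(taps) {
  if (length(taps) < 1L) stop("empty tap list")
  mats <- lapply(taps, function(t) if (is.list(t)) t$vector else t)
  dims <- vapply(mats, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("taps have inconsistent dimensions")
  Reduce(`+`, mats) / length(mats)
}

# Backward through the encoder given gradients on the tapped CLS states
# (list parallel to taps, each B x D) and optionally on the final tokens.
vit_encoder_bwd <- function(branch, enc_cache, dtaps) {
  d <- dim(enc_cache$out)
  dy <- array(0, d)
  grads <- vector("list", branch$depth)
  tap_of_layer <- setNames(seq_along(enc_cache$tap_layers),
                           enc_cache$tap_layers)
  for (l in rev(seq_len(branch$depth))) {
    key <- as.character(l)
    if (!is.na(tap_of_layer[key])) {
      dy[, 1L, ] <- dy[, 1L, ] + t(dtaps[[tap_of_layer[[key]]]])
    }
    r <- vit_block_bwd(dy, branch$blocks[[l]], enc_cache$caches[[l]])
    grads[[l]] <- r$grads
    dy <- r$dx
  }
  list(dtokens = dy, grads = grads)
}

patch_embed_bwd <- function(branch, dtokens, pe_cache) {
  d <- pe_cache$in_dim
  dpe <- rowSums(matrix(dtokens, prod(dim(dtokens)[1:2])))  # sum over batch
  dcls <- rowSums(matrix(dtokens[, 1L, ], dim(dtokens)[1]))
  dpatch_out <- matrix(dtokens[, -1L, ], dim(dtokens)[1])
  g <- linear_bwd(dpatch_out, branch$patch, list(x = pe_cache$cols))
  dimages <- aperm(col2im_cpp(g$dx, 3L, d[1], d[2], d[4], branch$patch_size,
                              branch$patch_size, 0L), c(2, 3, 1, 4))
  list(grads = list(patch = list(W = g$dW, b = g$db), cls = dcls,
                    pe = matrix(dpe, dim(dtokens)[1])),
       dimages = dimages)
}
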