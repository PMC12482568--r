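# Token-aligned multimodal attention (TAMA): the CNN and ViT embeddings are
# aligned into a short token sequence, refined by a plain multi-head
# self-attention stage and a layer-normalized token-alignment (TA) attention
# block, mean-pooled, and classified.
#
# The default sequence has T = 3 tokens: the CNN embedding, the ViT embedding,
# and their joint projection (concatenation reduced back to d), so the
# self-attention stages act on a non-degenerate sequence. A strict
# single-token mode ("single") keeps only the joint projection.

#' Align branch embeddings into a fusion token sequence
#'
#' Concatenates the two `d`-dimensional branch embeddings, projects the
#' `2d`-vector back to `d`, and assembles the fusion sequence.
#'
#' @param z_cnn,z_vit `B x d` embedding matrices.
#' @param params `list(W, b)` with `W` of shape `d x 2d` (the reduction map).
#' @param mode `"triplet"` (default; tokens = CNN, ViT, joint) or `"single"`
#'   (joint token only).
#' @return list with `tokens` (`(d, T, B)` array) and a backward cache.
#' @export
align_tokens <- function(z_cnn, z_vit, params, mode = "triplet") {
  if (!identical(dim(z_cnn), dim(z_vit)))
    stop("branch embeddings disagree: ", paste(dim(z_cnn), collapse = "x"),
         " vs ", paste(dim(z_vit), collapse = "x"))
  d <- ncol(z_cnn); B <- nrow(z_cnn)
  if (ncol(params$W) != 2 * d)
    stop("alignment projection expects 2d = ", ncol(params$W), " inputs")
  zc <- t(z_cnn); zv <- t(z_vit)                 # d x B
  joint_in <- rbind(zc, zv)                      # 2d x B
  pr <- linear_fwd(joint_in, params)
  if (mode == "single") {
    tokens <- array(pr$out, c(nrow(params$W), 1L, B))
  } else {
    tokens <- array(0, c(d, 3L, B))
    tokens[, 1L, ] <- zc
    tokens[, 2L, ] <- zv
    tokens[, 3L, ] <- pr$out
  }
  list(tokens = tokens, pr = pr, mode = mode, d = d, B = B)
}

align_tokens_bwd <- function(dtokens, params, cache) {
  if (cache$mode == "single") {
    dproj <- matrix(dtokens[, 1L, ], nrow(params$W))
    dzc_direct <- 0; dzv_direct <- 0
  } else {
    dproj <- matrix(dtokens[, 3L, ], cache$d)
    dzc_direct <- matrix(dtokens[, 1L, ], cache$d)
    dzv_direct <- matrix(dtokens[, 2L, ], cache$d)
  }
  g <- linear_bwd(dproj, params, cache$pr)
  dzc <- g$dx[seq_len(cache$d), , drop = FALSE] + dzc_direct
  dzv <- g$dx[cache$d + seq_len(cache$d), , drop = FALSE] + dzv_direct
  list(dz_cnn = t(dzc), dz_vit = t(dzv), grads = list(W = g$dW, b = g$db))
}

#' Multi-head self-attention fusion stage
#'
#' Plain multi-head self-attention over the fusion sequence (separate Q/K/V
#' projections, concatenated heads, output projection; no residual or
#' normalization). Per-head attention rows sum to 1.
#'
#' @param seq `(d, T, B)` token array.
#' @param params parameters from `msa_init()` (fields `q`, `k`, `v`, `o`,
#'   `heads`).
#' @return list with `tokens` (same shape) and the backward cache (the cached
#'   attention matrices are in `cache$core$A`).
#' @export
mhsa_stage <- function(seq, params) {
  r <- msa_fwd(seq, params)
  list(tokens = r$out, cache = r)
}

ta_init <- function(d, heads) {
  list(ln = layernorm_init(d), shared = linear_init(d, d, scale = 1),
       o = linear_init(d, d, scale = 1), heads = as.integer(heads))
}

#' Token-alignment attention layer
#'
#' The TA block applies, in order: LayerNorm, a shared linear projection that
#' produces Q = K = V, multi-head attention, and an output projection, wrapped
#' in a residual connection (pre-norm block; the residual can be disabled).
#'
#' @param seq `(d, T, B)` token array.
#' @param params parameters from `ta_init()`.
#' @param residual include the residual connection (default `TRUE`).
#' @return list with `tokens` and the backward cache.
#' @export
ta_layer <- function(seq, params, residual = TRUE) {
  d <- dim(seq)
  n <- layernorm_fwd(matrix(seq, d[1]), params$ln)
  s <- linear_fwd(n$out, params$shared)
  sa <- array(s$out, d)
  core <- attn_core_fwd(sa, sa, sa, params$heads)
  o <- linear3_fwd(core$out, params$o)
  out <- if (residual) seq + o$out else o$out
  list(tokens = out,
       cache = list(n = n, s = s, core = core, o = o, dims = d,
                    residual = residual))
}

ta_layer_bwd <- function(dy, params, cache) {
  d <- cache$dims
  do <- linear3_bwd(dy, params$o, cache$o)
  core <- attn_core_bwd(do$dx, cache$core)
  ds <- matrix(core$dQ + core$dK + core$dV, d[1])
  gs <- linear_bwd(ds, params$shared, cache$s)
  gn <- layernorm_bwd(gs$dx, params$ln, cache$n)
  dx <- array(gn$dx, d)
  if (cache$residual) dx <- dx + dy
  list(dx = dx,
       grads = list(ln = list(g = gn$dg, b = gn$db),
                    shared = list(W = gs$dW, b = gs$db),
                    o = list(W = do$dW, b = do$db)))
}

#' Pool the fusion sequence and classify
#'
#' Mean-pools the tokens, applies the classification head (ReLU, dropout in
#' training mode, linear map) and a row-wise softmax.
#'
#' @param seq `(d, T, B)` token array.
#' @param head `list(W, b)` with `W` of shape `C x d`.
#' @param dropout dropout rate applied after the ReLU in training mode.
#' @param train logical training-mode flag.
#' @return list with `probs` (`B x C`, rows on the simplex), `logits`
#'   (`B x C`) and the backward cache.
#' @export
pool_and_classify <- function(seq, head, dropout = 0, train = FALSE) {
  d <- dim(seq)
  pooled <- matrix(0, d[1], d[3])
  for (t in seq_len(d[2])) pooled <- pooled + matrix(seq[, t, ], d[1])
  pooled <- pooled / d[2]
  r <- relu_fwd(pooled)
  dr <- dropout_fwd(r$out, dropout, train)
  lg <- linear_fwd(dr$out, head)
  logits <- t(lg$out)
  list(probs = softmax_rows(logits), logits = logits,
       cache = list(r = r, dr = dr, lg = lg, dims = d))
}

pool_and_classify_bwd <- function(dlogits, head, cache) {
  g <- linear_bwd(t(dlogits), head, cache$lg)
  dd <- dropout_bwd(g$dx, cache$dr)
  dp <- relu_bwd(dd, cache$r)
  d <- cache$dims
  dseq <- array(rep(dp / d[2], times = d[2]), c(d[1], d[3], d[2]))
  dseq <- aperm(dseq, c(1, 3, 2))
  list(dseq = dseq, grads = list(W = g$dW, b = g$db))
}
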