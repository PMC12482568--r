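# Scaled dot-product multi-head attention on (D, T, B) token arrays, shared by
# the ViT encoder and the fusion module. Per-head scaling uses sqrt(d_k) with
# d_k = D / heads. Attention matrices are cached row-normalized (rows are
# queries), so tests can assert the row-sum invariant directly.

attn_core_fwd <- function(Q, K, V, heads) {
  d <- dim(Q)
  dh <- d[1] %/% heads
  if (dh * heads != d[1]) stop("token dim ", d[1], " not divisible by ", heads,
                               " heads")
  out <- array(0, dim = d)
  A <- vector("list", d[3])
  for (b in seq_len(d[3])) {
    Ab <- vector("list", heads)
    for (h in seq_len(heads)) {
      rows <- ((h - 1) * dh + 1):(h * dh)
      S <- crossprod(matrix(Q[rows, , b], dh, d[2]),
                     matrix(K[rows, , b], dh, d[2])) / sqrt(dh)
      Ah <- softmax_rows(S)
      out[rows, , b] <- matrix(V[rows, , b], dh, d[2]) %*% t(Ah)
      Ab[[h]] <- Ah
    }
    A[[b]] <- Ab
  }
  list(out = out, A = A, Q = Q, K = K, V = V, heads = heads, dh = dh)
}

attn_core_bwd <- function(dout, cache) {
  d <- dim(dout)
  dh <- cache$dh
  dQ <- array(0, d); dK <- array(0, d); dV <- array(0, d)
  for (b in seq_len(d[3])) {
    for (h in seq_len(cache$heads)) {
      rows <- ((h - 1) * dh + 1):(h * dh)
      Ah <- cache$A[[b]][[h]]
      Vh <- matrix(cache$V[rows, , b], dh, d[2])
      dOh <- matrix(dout[rows, , b], dh, d[2])
      dV[rows, , b] <- dOh %*% Ah
      dA <- t(crossprod(Vh, dOh))                      # T x T, rows = queries
      dS <- (dA - rowSums(dA * Ah)) * Ah
      dQ[rows, , b] <- matrix(cache$K[rows, , b], dh, d[2]) %*% t(dS) / sqrt(dh)
      dK[rows, , b] <- matrix(cache$Q[rows, , b], dh, d[2]) %*% dS / sqrt(dh)
    }
  }
  list(dQ = dQ, dK = dK, dV = dV)
}

## ---- standard MSA (separate Q/K/V projections + output projection) ---------

msa_init <- function(d, heads) {
  list(q = linear_init(d, d, scale = 1), k = linear_init(d, d, scale = 1),
       v = linear_init(d, d, scale = 1), o = linear_init(d, d, scale = 1),
       heads = as.integer(heads))
}

# Apply a linear layer to a (D, T, B) array by flattening tokens.
linear3_fwd <- function(x, p) {
  d <- dim(x)
  r <- linear_fwd(matrix(x, d[1]), p)
  list(out = array(r$out, c(nrow(p$W), d[2], d[3])), x = r$x, in_dim = d)
}

linear3_bwd <- function(dy, p, cache) {
  r <- linear_bwd(matrix(dy, dim(dy)[1]), p, cache)
  list(dx = array(r$dx, cache$in_dim), dW = r$dW, db = r$db)
}

msa_fwd <- function(x, p) {
  q <- linear3_fwd(x, p$q); k <- linear3_fwd(x, p$k); v <- linear3_fwd(x, p$v)
  core <- attn_core_fwd(q$out, k$out, v$out, p$heads)
  o <- linear3_fwd(core$out, p$o)
  list(out = o$out, q = q, k = k, v = v, core = core, o = o)
}

msa_bwd <- function(dy, p, cache) {
  do <- linear3_bwd(dy, p$o, cache$o)
  core <- attn_core_bwd(do$dx, cache$core)
  gq <- linear3_bwd(core$dQ, p$q, cache$q)
  gk <- linear3_bwd(core$dK, p$k, cache$k)
  gv <- linear3_bwd(core$dV, p$v, cache$v)
  list(dx = gq$dx + gk$dx + gv$dx,
       grads = list(q = list(W = gq$dW, b = gq$db),
                    k = list(W = gk$dW, b = gk$db),
                    v = list(W = gv$dW, b = gv$db),
                    o = list(W = do$dW, b = do$db)))
}
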