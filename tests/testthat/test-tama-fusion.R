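# Fusion module: alignment projection, both attention stages against written-
# out oracles, the classification head, and whole-model contracts
# (determinism, batch independence, simplex, gradient correctness).

test_that("alignment builds the three-token sequence and checks dimensions", {
  d <- 2
  W <- matrix(c(1, 0, 0, 1, 2, -1, 0.5, 0.25), 2, 4)  # hand-set 2 x 4
  par <- list(W = W, b = c(0.1, -0.1))
  z_cnn <- matrix(c(1, 0), 1)
  z_vit <- matrix(c(0, 1), 1)
  al <- align_tokens(z_cnn, z_vit, par)
  expect_equal(dim(al$tokens), c(2L, 3L, 1L))
  expect_equal(as.numeric(al$tokens[, 1, ]), c(1, 0))
  expect_equal(as.numeric(al$tokens[, 2, ]), c(0, 1))
  expect_equal(as.numeric(al$tokens[, 3, ]),
               as.numeric(W %*% c(1, 0, 0, 1) + c(0.1, -0.1)))
  # zero inputs and zero bias -> all three tokens zero
  al0 <- align_tokens(matrix(0, 1, 2), matrix(0, 1, 2),
                      list(W = W, b = c(0, 0)))
  expect_true(all(al0$tokens == 0))
  expect_error(align_tokens(matrix(0, 1, 2), matrix(0, 1, 3), par),
               "disagree")
  # default config: the joint projection lands in a 768-dim space
  cfg <- histofuse_config("full")
  al768 <- with_seed2(1, histofuse:::linear_init(2 * cfg$model$fusion$dim,
                                                 cfg$model$fusion$dim))
  expect_equal(nrow(al768$W), 768L)
})

test_that("single-token attention is the value path with weight exactly 1", {
  par <- with_seed2(4, histofuse:::msa_init(4, 2))
  x <- array(rnorm(4), c(4, 1, 1))
  r <- mhsa_stage(x, par)
  expect_equal(r$cache$core$A[[1]][[1]], matrix(1, 1, 1))
  v <- par$v$W %*% x[, 1, 1] + par$v$b
  expect_equal(as.numeric(r$tokens[, 1, 1]),
               as.numeric(par$o$W %*% v + par$o$b))
})

test_that("two identical tokens attend with weights exactly one half", {
  par <- with_seed2(5, histofuse:::msa_init(4, 2))
  tok <- rnorm(4)
  x <- array(rep(tok, 2), c(4, 2, 1))
  r <- mhsa_stage(x, par)
  for (h in 1:2)
    expect_equal(r$cache$core$A[[1]][[h]], matrix(0.5, 2, 2))
})

test_that("single-head attention matches a written-out softmax(QK'/sqrt(d))V", {
  d <- 2
  par <- list(q = list(W = matrix(c(1, 0.5, -0.25, 2), 2, 2), b = c(0, 0.1)),
              k = list(W = matrix(c(0.3, -1, 0.7, 0.2), 2, 2), b = c(-0.2, 0)),
              v = list(W = matrix(c(1, 1, 0, -1), 2, 2), b = c(0.05, 0)),
              o = list(W = diag(2), b = c(0, 0)), heads = 1L)
  x <- array(c(0.4, -0.3, 1.1, 0.6), c(2, 2, 1))
  r <- mhsa_stage(x, par)
  X <- matrix(x, 2)
  Q <- par$q$W %*% X + par$q$b
  K <- par$k$W %*% X + par$k$b
  V <- par$v$W %*% X + par$v$b
  S <- t(Q) %*% K / sqrt(2)
  A <- exp(S) / rowSums(exp(S))
  O <- V %*% t(A)
  expect_equal(matrix(r$tokens, 2), O, tolerance = 1e-12)
})

test_that("TA layer degenerates as specified", {
  par <- with_seed2(6, histofuse:::ta_init(4, 2))
  # zero output projection + residual -> identity
  par0 <- par
  par0$o$W[] <- 0; par0$o$b[] <- 0
  x <- array(rnorm(4 * 3 * 2), c(4, 3, 2))
  expect_equal(ta_layer(x, par0, residual = TRUE)$tokens, x)
  # constant token: LayerNorm emits the learned shift (zero at init)
  xc <- array(5, c(4, 1, 1))
  r <- ta_layer(xc, par, residual = FALSE)
  expect_true(all(abs(r$cache$n$out) < 1e-9))
})

test_that("TA layer matches a step-by-step oracle on a 2-token toy", {
  d <- 2
  par <- list(ln = list(g = c(1.5, 0.5), b = c(0.1, -0.2)),
              shared = list(W = matrix(c(0.6, -0.3, 0.2, 1.1), 2, 2),
                            b = c(0, 0.1)),
              o = list(W = matrix(c(0.5, 0.25, -1, 0.75), 2, 2),
                       b = c(0.02, 0)),
              heads = 1L)
  x <- array(c(1, -0.5, 0.25, 2), c(2, 2, 1))
  r <- ta_layer(x, par, residual = TRUE)
  X <- matrix(x, 2)
  mu <- colMeans(X); v <- colMeans(sweep(X, 2, mu)^2)
  Xn <- sweep(sweep(X, 2, mu), 2, 1 / sqrt(v + 1e-5), `*`) *
    par$ln$g + par$ln$b
  S <- par$shared$W %*% Xn + par$shared$b
  At <- t(S) %*% S / sqrt(2)
  A <- exp(At - apply(At, 1, max)); A <- A / rowSums(A)
  O <- S %*% t(A)
  Y <- X + (par$o$W %*% O + par$o$b)
  expect_equal(matrix(r$tokens, 2), Y, tolerance = 1e-10)
})

test_that("the head produces calibrated softmax probabilities", {
  # zero head weights -> uniform probabilities for any input
  seqs <- with_seed2(7, array(rnorm(6 * 3 * 2), c(6, 3, 2)))
  head0 <- list(W = matrix(0, 4, 6), b = numeric(4))
  r <- pool_and_classify(seqs, head0)
  expect_true(all(abs(r$probs - 0.25) < 1e-12))
  # logits (2,0,0,0): class-1 probability is e^2 / (e^2 + 3)
  tok <- array(1, c(2, 1, 1))
  head <- list(W = matrix(0, 4, 2), b = c(2, 0, 0, 0))
  p <- pool_and_classify(tok, head)$probs
  expect_equal(p[1, 1], exp(2) / (exp(2) + 3), tolerance = 1e-12)
  # random inputs stay on the simplex
  r2 <- pool_and_classify(seqs, with_seed2(8, histofuse:::linear_init(6, 5)))
  expect_true(all(abs(rowSums(r2$probs) - 1) < 1e-6))
  expect_true(all(r2$probs >= 0 & r2$probs <= 1))
  # pooled vector is the exact token mean
  expect_equal(r$cache$r$out,
               pmax((seqs[, 1, ] + seqs[, 2, ] + seqs[, 3, ]) / 3, 0))
})

test_that("eval-mode forward is deterministic and batch-independent", {
  mod <- tiny_model()
  img <- tiny_images(2)
  f1 <- histofuse_forward(mod, img)
  f2 <- histofuse_forward(mod, img)
  expect_identical(f1$probs, f2$probs)
  s1 <- histofuse_forward(mod, img[, , , 1, drop = FALSE])$probs
  s2 <- histofuse_forward(mod, img[, , , 2, drop = FALSE])$probs
  expect_equal(rbind(s1, s2), f1$probs, tolerance = 1e-12)
  expect_true(all(abs(rowSums(f1$probs) - 1) < 1e-6))
})

test_that("branch-token permutation leaves the pooled output unchanged", {
  mod <- tiny_model(seed = 9)
  img <- tiny_images(1)
  fw <- histofuse_forward(mod, img, full = TRUE)
  seqs <- fw$cache$align$tokens
  run <- function(s) {
    s <- mhsa_stage(s, mod$fusion$mhsa[[1]])$tokens
    s <- ta_layer(s, mod$fusion$ta[[1]])$tokens
    pool_and_classify(s, mod$head)$probs
  }
  expect_equal(run(seqs), run(seqs[, c(2, 1, 3), , drop = FALSE]),
               tolerance = 1e-12)
})

test_that("ablation arms reproduce the reduced architectures", {
  img <- tiny_images(2)
  # no-TAMA arm classifies from the joint projection
  mod_nt <- histofuse_model(tiny_config(model = list(use_tama = FALSE)), 3)
  fw <- histofuse_forward(mod_nt, img, full = TRUE)
  joint <- fw$cache$align$tokens[, 3, ]
  manual <- histofuse:::pool_and_classify(
    array(joint, c(nrow(joint), 1, ncol(joint))), mod_nt$head)$probs
  expect_equal(fw$probs, manual, tolerance = 1e-12)
  # single-branch arms run end to end with matching shapes
  for (arm in c("cnn", "vit")) {
    m <- histofuse_model(tiny_config(model = list(branches = arm)), 3)
    p <- histofuse_forward(m, img)$probs
    expect_equal(dim(p), c(2L, 3L))
    expect_true(all(abs(rowSums(p) - 1) < 1e-6))
  }
})

test_that("analytic gradients agree with central finite differences", {
  mod <- tiny_model(seed = 13)
  img <- tiny_images(2)
  y <- c(1L, 3L)
  fw <- histofuse_forward(mod, img, full = TRUE)
  bw <- histofuse_backward(mod, fw,
                           histofuse:::cross_entropy_grad(fw$logits, y))
  gflat <- histofuse:::flatten_params(bw$grads)
  pflat <- histofuse:::flatten_params(histofuse:::model_params(mod))
  lossfun <- function(flat) {
    m <- histofuse:::model_set_params(
      mod, histofuse:::unflatten_params(flat, histofuse:::model_params(mod)))
    cross_entropy(histofuse_forward(m, img)$logits, y)
  }
  eps <- 1e-5
  picks <- with_seed2(21, sample(names(pflat), 6))
  for (nm in picks) {
    i <- with_seed2(nchar(nm), sample(length(pflat[[nm]]), 1))
    up <- pflat; up[[nm]][i] <- up[[nm]][i] + eps
    dn <- pflat; dn[[nm]][i] <- dn[[nm]][i] - eps
    num <- (lossfun(up) - lossfun(dn)) / (2 * eps)
    # scale-aware comparison: near-zero gradients are compared absolutely
    expect_lt(abs(num - gflat[[nm]][i]) /
                max(abs(num) + abs(gflat[[nm]][i]), 1e-6), 1e-3)
  }
})

test_that("the loss gradient w.r.t. an input pixel is finite and nonzero", {
  mod <- tiny_model(seed = 17)
  img <- tiny_images(1)
  y <- 2L
  eps <- 1e-4
  up <- img; up[5, 9, 2, 1] <- up[5, 9, 2, 1] + eps
  dn <- img; dn[5, 9, 2, 1] <- dn[5, 9, 2, 1] - eps
  g <- (cross_entropy(histofuse_forward(mod, up)$logits, y) -
          cross_entropy(histofuse_forward(mod, dn)$logits, y)) / (2 * eps)
  expect_true(is.finite(g))
  expect_gt(abs(g), 0)
})
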