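# CNN branch: backbone shape contracts, SE recalibration arithmetic, and the
# projection to the shared embedding.

make_branch <- function(channels = c(4, 6, 8, 8, 12), seed = 1) {
  cfg <- tiny_config(model = list(cnn = list(channels = channels)))
  with_seed2(seed, cnn_branch(cfg))
}

test_that("backbone honours the stride-32 spatial contract", {
  br <- cached("branch128", {
    cfg <- tiny_config(model = list(cnn = list(channels = c(4, 8, 16, 32, 128)),
                                    fusion = list(dim = 16)))
    with_seed2(1, cnn_branch(cfg))
  })
  img <- tiny_images(2, size = 64)
  fm <- extract_local_features(img, br)
  expect_equal(dim(fm), c(128L, 2L, 2L, 2L))   # 64/32 = 2, reduced 128-ch config
  img96 <- tiny_images(1, size = 96)
  expect_equal(dim(extract_local_features(img96, br))[2:3], c(3L, 3L))
  expect_error(extract_local_features(tiny_images(1, size = 48), br),
               "divisible by the backbone stride 32")
})

test_that("an all-zero image with zero biases maps to an all-zero feature map", {
  br <- make_branch()
  zero <- array(0, c(32, 32, 3, 1))
  fm <- extract_local_features(zero, br)
  expect_true(all(fm == 0))
})

test_that("SE gate reproduces hand arithmetic on a 2-channel 2x2 map", {
  # hand-set weights; oracle computed with plain scalar arithmetic below
  x <- array(0, c(2, 2, 2, 1))                # channel-first (C=2, 2x2, B=1)
  x[1, , , 1] <- matrix(c(1, 2, 3, 4), 2)     # channel 1
  x[2, , , 1] <- matrix(c(5, 6, 7, 8), 2)     # channel 2
  gate <- list(fc1 = list(W = matrix(c(0.1, -0.2), 1, 2), b = 0.05),
               fc2 = list(W = matrix(c(0.3, -0.4), 2, 1), b = c(0.01, -0.02)))
  r <- se_recalibrate(x, gate)
  # oracle: GAP -> fc1 -> ReLU -> fc2 -> sigmoid -> channel scaling
  u <- c(mean(x[1, , , 1]), mean(x[2, , , 1]))
  h <- max(0, 0.1 * u[1] - 0.2 * u[2] + 0.05)
  s <- 1 / (1 + exp(-(c(0.3, -0.4) * h + c(0.01, -0.02))))
  expect_equal(as.numeric(r$gate), s)
  expect_equal(r$features[1, , , 1], x[1, , , 1] * s[1])
  expect_equal(r$features[2, , , 1], x[2, , , 1] * s[2])
})

test_that("SE with zero gate parameters halves every channel (sigmoid(0))", {
  x <- tiny_feature_map(8, 3, 2)
  gate <- list(fc1 = list(W = matrix(0, 2, 8), b = numeric(2)),
               fc2 = list(W = matrix(0, 8, 2), b = numeric(8)))
  r <- se_recalibrate(x, gate)
  expect_equal(r$features, 0.5 * x)
  expect_true(all(r$gate == 0.5))
})

test_that("GAP descriptor is exact for constant-per-channel input", {
  ck <- c(2.5, -1, 0.25)
  x <- array(rep(ck, times = 4 * 4), c(3, 4, 4, 1))
  g <- histofuse:::gap_fwd(x)
  expect_equal(as.numeric(g$out), ck)
})

test_that("SE gates stay strictly inside (0,1) and only rescale channels", {
  br <- make_branch(seed = 7)
  for (s in 1:5) {
    x <- with_seed2(s, array(rnorm(12 * 2 * 2 * 2, sd = 2), c(12, 2, 2, 2)))
    r <- se_recalibrate(x, br$se)
    expect_true(all(r$gate > 0 & r$gate < 1))
    expect_equal(dim(r$features), dim(x))
    # channel k of item b is input channel k times one scalar
    for (b in 1:2) for (k in c(1, 12)) {
      ratio <- r$features[k, , , b] / x[k, , , b]
      expect_equal(max(ratio) - min(ratio), 0, tolerance = 1e-12)
    }
    expect_true(all(abs(r$features) <= abs(x) + 1e-12))
  }
})

test_that("a forced all-ones gate reproduces the no-SE branch exactly", {
  mod_se <- tiny_model(seed = 5)
  cfg_no <- tiny_config(model = list(use_se = FALSE))
  mod_no <- histofuse_model(cfg_no, seed = 5)
  img <- tiny_images(2)
  # same weights; only the SE switch differs
  mod_no <- histofuse:::model_set_params(
    mod_no, histofuse:::model_params(mod_se))
  fw_se <- histofuse_forward(mod_se, img, full = TRUE)
  # replace the gate by exactly 1 by scaling features manually
  feats <- fw_se$cache$cnn$feat$out
  g <- histofuse:::gap_fwd(feats)
  z_manual <- t(histofuse:::linear_fwd(g$out, mod_se$cnn$proj)$out)
  fw_no <- histofuse_forward(mod_no, img, full = TRUE)
  expect_equal(fw_no$cache$z_cnn, z_manual, tolerance = 1e-12)
})

test_that("projection equals spatial-mean-then-matrix-multiply", {
  # identity-like projection on a constant map
  v <- 0.75
  x <- array(v, c(4, 2, 2, 1))
  proj <- list(W = diag(4), b = numeric(4))
  expect_equal(as.numeric(project_cnn_embedding(x, proj)), rep(v, 4))
  # zero features -> the projection bias
  proj$b <- c(1, 2, 3, 4)
  expect_equal(as.numeric(project_cnn_embedding(x * 0, proj)), c(1, 2, 3, 4))
  # random 4-channel 2x2 map against a brute-force oracle
  x <- with_seed2(2, array(rnorm(4 * 2 * 2 * 2), c(4, 2, 2, 2)))
  proj <- with_seed2(3, list(W = matrix(rnorm(16), 4, 4), b = rnorm(4)))
  got <- project_cnn_embedding(x, proj)
  for (b in 1:2) {
    mu <- apply(x[, , , b], 1, mean)
    expect_equal(as.numeric(got[b, ]), as.numeric(proj$W %*% mu + proj$b))
  }
  expect_error(project_cnn_embedding(x, list(W = matrix(0, 4, 5), b = numeric(4))),
               "channels")
})
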