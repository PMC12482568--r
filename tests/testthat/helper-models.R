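# Shared tiny configurations and cached fixtures. Everything is generated in
# code at test time; the cache avoids re-deriving the same objects across
# test files within one run.

.test_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.test_cache[[key]])) .test_cache[[key]] <- force(expr)
  .test_cache[[key]]
}

# Tiny dual-branch config: 32 px tiles, 3 classes, every component exercised.
tiny_config <- function(n_classes = 3, model = list()) {
  base <- list(
    cnn = list(channels = c(4, 6, 8, 8, 12)),
    vit = list(patch_size = 8, depth = 2, dim = 16, heads = 2,
               mlp_ratio = 2, tap_layers = c(1, 2), image_size = 32),
    fusion = list(dim = 16, heads = 2, mhsa_blocks = 1, ta_blocks = 1,
                  sequence_mode = "triplet", dropout = 0,
                  ta_residual = TRUE),
    cam_layers = c("stage3", "stage4"))
  histofuse_config("reduced", n_classes = n_classes,
                   model = histofuse:::merge_config(base, model))
}

tiny_model <- function(seed = 3, ...) histofuse_model(tiny_config(...), seed)

tiny_images <- function(n = 2, size = 32, seed = 11) {
  with_seed2(seed, array(runif(size * size * 3 * n), c(size, size, 3, n)))
}

# CNN-only model whose class-1 score is an affine function of the GAP of the
# final feature map: identity projection (d = C) and a one-hot head row make
# the class score y_1 = mean(A_chan1) + const, so alpha = (1/(h*w)) e_1.
linear_cam_model <- function() {
  cfg <- tiny_config(n_classes = 2,
                     model = list(branches = "cnn", use_se = FALSE,
                                  fusion = list(dim = 12, dropout = 0)))
  mod <- histofuse_model(cfg, seed = 1)
  mod$cnn$proj$W <- diag(12)
  mod$cnn$proj$b <- rep(10, 12)        # keeps the head ReLU in its linear range
  mod$head$W <- matrix(0, 2, 12)
  mod$head$W[1, 1] <- 1
  mod$head$b <- c(0, 0)
  mod
}

tiny_feature_map <- function(C, hw, B, seed = 4) {
  with_seed2(seed, array(rnorm(C * hw * hw * B), c(C, hw, hw, B)))
}

# local seed helper for tests (package's with_seed is internal)
with_seed2 <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  force(code)
}
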