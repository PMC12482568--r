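# Loss arithmetic, schedule and early-stopping contracts, metric oracles,
# majority voting, and the paired run-comparison statistics.

test_that("cross-entropy matches hand arithmetic and the batch-mean identity", {
  expect_equal(cross_entropy(matrix(1, 3, 4), rep(2L, 3)), log(4))
  expect_equal(cross_entropy(matrix(c(2, 0, 0, 0), 1), 1L),
               -2 + log(exp(2) + 3))
  logits <- with_seed2(1, matrix(rnorm(20), 5, 4))
  y <- c(1L, 4L, 2L, 2L, 3L)
  per <- vapply(1:5, function(i)
    cross_entropy(logits[i, , drop = FALSE], y[i]), numeric(1))
  expect_equal(cross_entropy(logits, y), mean(per))
  expect_error(cross_entropy(matrix(c(1, Inf), 1), 1L), "non-finite")
})

test_that("the schedule reaches the configured peak at the end of warmup", {
  expect_equal(lr_schedule(5, 2e-4, 50, 5), 2e-4)
  expect_equal(lr_schedule(1, 2e-4, 50, 5), 2e-4 / 5)
  expect_lt(lr_schedule(50, 2e-4, 50, 5), 1e-6)
  rates <- vapply(5:50, lr_schedule, numeric(1), peak = 2e-4, total = 50,
                  warmup = 5)
  expect_true(all(diff(rates) <= 1e-12))     # monotone decay after warmup
})

test_that("training stops after `patience` epochs without val-loss improvement", {
  # ViT-only arm: no batch-norm buffers, so lr = 0 makes the validation loss
  # constant by construction
  mod <- histofuse_model(tiny_config(model = list(branches = "vit")), 1)
  x <- tiny_images(8)
  data <- list(train = list(x = x, y = rep(1:2, 4)),
               val = list(x = x[, , , 1:4, drop = FALSE], y = rep(1:2, 2)))
  res <- train_model(mod, data,
                     recipe = list(lr = 0, epochs = 20, batch_size = 8,
                                   patience = 3, warmup_epochs = 1),
                     seed = 0)
  expect_true(res$stopped_early)
  expect_equal(nrow(res$history), 1L + 3L)
  expect_equal(sd(res$history$val_loss), 0)
})

test_that("training refuses leaking groups", {
  mod <- tiny_model(seed = 1)
  x <- tiny_images(4)
  data <- list(train = list(x = x, y = rep(1:2, 2), group = c("a", "b", "c", "d")),
               val = list(x = x, y = rep(1:2, 2), group = c("d", "e", "f", "g")))
  expect_error(train_model(mod, data, recipe = list(epochs = 1)), "leakage")
})

test_that("the loss decreases on a separable toy problem", {
  mod <- tiny_model(n_classes = 2, seed = 2)
  n <- 16
  x <- array(0.5, c(32, 32, 3, n))
  y <- rep(1:2, each = n / 2)
  x[, , 1, y == 1] <- 0.9                    # class 1: red-shifted tiles
  x[, , 3, y == 2] <- 0.9                    # class 2: blue-shifted tiles
  data <- list(train = list(x = x, y = y), val = list(x = x, y = y))
  res <- train_model(mod, data,
                     recipe = list(epochs = 4, batch_size = 8, lr = 1e-3,
                                   warmup_epochs = 1, patience = 10),
                     seed = 0)
  expect_lt(res$history$train_loss[4], res$history$train_loss[1])
})

test_that("metrics agree with brute-force confusion counting", {
  # binary case TP=8 FP=2 FN=2 TN=8 -> 0.8 across the board
  y <- rep(c(1L, 2L), each = 10)
  pred <- c(rep(1L, 8), 2L, 2L, rep(2L, 8), 1L, 1L)
  probs <- cbind(ifelse(pred == 1, 0.9, 0.1), ifelse(pred == 2, 0.9, 0.1))
  m <- compute_metrics(probs, y)
  expect_equal(m$accuracy, 0.8)
  expect_equal(unname(m$per_class$precision), c(0.8, 0.8))
  expect_equal(unname(m$per_class$recall), c(0.8, 0.8))
  expect_equal(unname(m$per_class$f1), c(0.8, 0.8))
  # perfect predictions
  pp <- diag(3)[c(1, 2, 3, 1), ]
  mp <- compute_metrics(pp, c(1L, 2L, 3L, 1L))
  expect_equal(mp$accuracy, 1)
  expect_true(all(mp$per_class$f1 == 1))
  expect_true(all(mp$auc == 1))
  # random case against an independent counting oracle
  C <- 4
  probs <- with_seed2(3, matrix(runif(200 * C), 200))
  probs <- probs / rowSums(probs)
  y <- with_seed2(4, sample.int(C, 200, replace = TRUE))
  m <- compute_metrics(probs, y)
  pred <- max.col(probs)
  for (k in seq_len(C)) {
    tp <- sum(pred == k & y == k); fp <- sum(pred == k & y != k)
    fn <- sum(pred != k & y == k)
    expect_equal(m$per_class$precision[k], if (tp + fp) tp / (tp + fp) else 0)
    expect_equal(m$per_class$recall[k], tp / (tp + fn))
  }
  expect_equal(m$accuracy, sum(diag(m$confusion)) / sum(m$confusion))
})

test_that("one-vs-rest AUC equals the rank-statistic (Mann-Whitney) oracle", {
  probs <- with_seed2(5, matrix(runif(120 * 3), 120))
  probs <- probs / rowSums(probs)
  y <- with_seed2(6, sample.int(3, 120, replace = TRUE))
  m <- compute_metrics(probs, y)
  for (k in 1:3) {
    pos <- probs[y == k, k]; neg <- probs[y != k, k]
    u <- sum(outer(pos, neg, ">")) + 0.5 * sum(outer(pos, neg, "=="))
    expect_equal(unname(m$auc[k]), u / (length(pos) * length(neg)),
                 tolerance = 1e-10)
  }
})

test_that("majority voting follows modal count with probability tie-breaks", {
  probs4 <- matrix(0.25, 4, 3)
  probs4[cbind(1:4, c(2, 2, 1, 2))] <- 0.9
  v <- majority_vote(rep("img1", 4), probs4)
  expect_equal(v$label, 2)
  expect_equal(majority_vote("solo", matrix(c(0.1, 0.2, 0.7), 1))$label, 3)
  # tie 1-1-2-2 decided by mean probability (0.6 vs 0.55 for class 1)
  tie <- rbind(c(0.55, 0.45), c(0.55, 0.45), c(0.40, 0.60), c(0.40, 0.60))
  expect_equal(majority_vote(rep("t", 4), tie)$label, 2)
  # brute-force oracle over random groups
  probs <- with_seed2(7, matrix(runif(60 * 3), 60))
  probs <- probs / rowSums(probs)
  ids <- rep(sprintf("g%02d", 1:12), each = 5)
  got <- majority_vote(ids, probs)
  pred <- max.col(probs)
  for (i in seq_len(nrow(got))) {
    counts <- tabulate(pred[ids == got$image_id[i]], 3)
    expect_true(got$label[i] %in% which(counts == max(counts)))
  }
  expect_error(majority_vote(character(0), probs[0, , drop = FALSE]), "empty")
})

test_that("paired t and Cohen's d reproduce the three-run hand example", {
  r <- paired_t_and_effect(c(90, 92, 94), c(93, 94, 98), correction = "none")
  expect_equal(r$cohens_d, -3)
  expect_equal(r$t_stat, -3 * sqrt(3), tolerance = 1e-10)
  expect_equal(r$df, 2L)
  expect_equal(r$p_value, 2 * pt(-3 * sqrt(3), df = 2), tolerance = 1e-10)
  expect_equal(r$effect_label, "large")
  # identical runs are degenerate, not NaN
  d <- paired_t_and_effect(c(1, 2, 3), c(1, 2, 3))
  expect_true(d$degenerate)
  expect_equal(d$cohens_d, 0)
  expect_true(is.na(d$t_stat))
})

test_that("family-wise adjusted p-values are monotone in rank order", {
  set.seed(8)
  comps <- lapply(runif(8, 0.001, 0.9), function(p)
    list(p_value = p, adjusted_p = p, correction = "none"))
  adj <- adjust_comparisons(comps, "benjamini_hochberg")
  p <- vapply(comps, `[[`, numeric(1), "p_value")
  a <- vapply(adj, `[[`, numeric(1), "adjusted_p")
  expect_true(all(diff(a[order(p)]) >= -1e-12))
  expect_true(all(a >= p - 1e-12))
  bon <- adjust_comparisons(comps, "bonferroni")
  b <- vapply(bon, `[[`, numeric(1), "adjusted_p")
  expect_equal(b, pmin(1, p * 8))
})
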