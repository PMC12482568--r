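# Loss, AdamW with cosine warmup scheduling, the training loop with early
# stopping and best-checkpoint retention, classification metrics, patch-level
# majority voting, and paired run-comparison statistics.

## ---- loss -------------------------------------------------------------------

#' Multi-class cross-entropy
#'
#' Batch-mean negative log-likelihood of the true classes, computed from
#' logits in the numerically stable log-sum-exp form
#' `-x_y + log(sum_j exp(x_j))`.
#'
#' @param logits `B x C` matrix of unnormalized scores.
#' @param labels integer class ids in `1..C` (length `B`).
#' @return scalar loss (nats). The training loop pairs this with the matching
#'   internal gradient `cross_entropy_grad()`.
#' @export
cross_entropy <- function(logits, labels) {
  if (!all(is.finite(logits))) stop("non-finite logits")
  if (any(labels < 1L | labels > ncol(logits)))
    stop("labels must lie in [1, ", ncol(logits), "]")
  mx <- apply(logits, 1, max)
  lse <- mx + log(rowSums(exp(logits - mx)))
  mean(lse - logits[cbind(seq_along(labels), labels)])
}

# Gradient of the batch-mean cross-entropy w.r.t. the logits: (p - y) / B.
cross_entropy_grad <- function(logits, labels) {
  p <- softmax_rows(logits)
  p[cbind(seq_along(labels), labels)] <-
    p[cbind(seq_along(labels), labels)] - 1
  p / length(labels)
}

## ---- optimizer & schedule ---------------------------------------------------

adamw_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L, beta1 = 0.9, beta2 = 0.999, eps = 1e-8)
}

# Decoupled weight decay: decay applied to weight matrices/arrays only
# (vectors -- biases, norm gains, CLS -- are exempt, standard practice).
adamw_step <- function(params, grads, state, lr, weight_decay) {
  state$t <- state$t + 1L
  bc1 <- 1 - state$beta1^state$t
  bc2 <- 1 - state$beta2^state$t
  for (k in names(params)) {
    g <- grads[[k]]
    if (is.null(g)) next
    state$m[[k]] <- state$beta1 * state$m[[k]] + (1 - state$beta1) * g
    state$v[[k]] <- state$beta2 * state$v[[k]] + (1 - state$beta2) * g^2
    upd <- (state$m[[k]] / bc1) / (sqrt(state$v[[k]] / bc2) + state$eps)
    if (!is.null(dim(params[[k]]))) upd <- upd + weight_decay * params[[k]]
    params[[k]] <- params[[k]] - lr * upd
  }
  list(params = params, state = state)
}

#' Cosine learning-rate schedule with linear warmup
#'
#' Linear ramp from 0 to `peak` over `warmup` epochs, then cosine annealing to
#' zero at `total` epochs. The rate at the end of warmup equals `peak`.
#'
#' @param epoch 1-based epoch index.
#' @param peak peak learning rate.
#' @param total total scheduled epochs.
#' @param warmup warmup epochs.
#' @return the learning rate for `epoch`.
#' @export
lr_schedule <- function(epoch, peak, total, warmup) {
  if (epoch <= warmup) return(peak * epoch / warmup)
  prog <- (epoch - warmup) / max(total - warmup, 1L)
  peak * 0.5 * (1 + cos(pi * min(prog, 1)))
}

## ---- training loop ----------------------------------------------------------

#' Train a model
#'
#' Mini-batch AdamW training with the cosine-warmup schedule, early stopping
#' on stagnant validation loss, and retention of the checkpoint with the best
#' validation accuracy.
#'
#' @param model a [histofuse_model()].
#' @param data list with `train` and `val`, each `list(x, y)` where `x` is an
#'   `(H, W, 3, N)` array and `y` integer labels in `1..C`. Optional `group`
#'   vectors (source image or patient ids) trigger a leakage audit: training
#'   refuses to start if any group appears in both subsets.
#' @param recipe training hyperparameters; defaults from the model's config
#'   (`lr`, `weight_decay`, `epochs`, `batch_size`, `warmup_epochs`,
#'   `patience`). Optional entries: `augment` (`"bach"` or `"breakhis"`
#'   applies that stochastic policy to every training tile) and
#'   `stop_at_val_accuracy`, which halts once the validation accuracy reaches
#'   the given fraction.
#' @param seed RNG seed controlling shuffling and dropout.
#' @param verbose print per-epoch progress.
#' @return list with `model` (best checkpoint), `final_model`, `history`
#'   (data.frame: epoch, lr, train_loss, train_acc, val_loss, val_acc),
#'   `best_epoch`, and `stopped_early`.
#' @export
train_model <- function(model, data, recipe = NULL, seed = 0L,
                        verbose = FALSE) {
  recipe <- merge_config(model$config$train, recipe %||% list())
  if (!is.null(data$train$group) && !is.null(data$val$group)) {
    shared <- intersect(unique(data$train$group), unique(data$val$group))
    if (length(shared))
      stop("leakage audit failed: groups in both train and val: ",
           paste(utils::head(shared, 5), collapse = ", "))
  }
  n <- length(data$train$y)
  best <- list(acc = -Inf, params = NULL, epoch = 0L)
  best_loss <- Inf; stagnant <- 0L; stopped_early <- FALSE
  history <- NULL
  params <- flatten_params(model_params(model))
  opt <- adamw_init(params)
  with_seed(seed, {
    for (epoch in seq_len(recipe$epochs)) {
      lr <- lr_schedule(epoch, recipe$lr, recipe$epochs, recipe$warmup_epochs)
      ord <- sample.int(n)
      tr_loss <- 0; tr_correct <- 0L
      for (i in seq(1L, n, by = recipe$batch_size)) {
        idx <- ord[i:min(i + recipe$batch_size - 1L, n)]
        xb <- data$train$x[, , , idx, drop = FALSE]
        if (!is.null(recipe$augment)) {
          for (j in seq_along(idx))
            xb[, , , j] <- augment(xb[, , , j], recipe$augment)
        }
        yb <- data$train$y[idx]
        fw <- histofuse_forward(model, xb, train = TRUE, full = TRUE)
        model <- fw$model
        loss <- cross_entropy(fw$logits, yb)
        bw <- histofuse_backward(model, fw, cross_entropy_grad(fw$logits, yb))
        gflat <- flatten_params(bw$grads)
        step <- adamw_step(params, gflat, opt, lr, recipe$weight_decay)
        params <- step$params; opt <- step$state
        model <- model_set_params(model,
                                  unflatten_params(params, model_params(model)))
        tr_loss <- tr_loss + loss * length(idx)
        tr_correct <- tr_correct + sum(max.col(fw$probs) == yb)
      }
      vp <- predict_probs(model, data$val$x, recipe$batch_size)
      val_loss <- cross_entropy(log(pmax(vp, 1e-12)), data$val$y)
      val_acc <- mean(max.col(vp) == data$val$y)
      history <- rbind(history, data.frame(
        epoch = epoch, lr = lr, train_loss = tr_loss / n,
        train_acc = tr_correct / n, val_loss = val_loss, val_acc = val_acc))
      if (verbose)
        message(sprintf("epoch %02d lr %.2e train %.4f/%.3f val %.4f/%.3f",
                        epoch, lr, tr_loss / n, tr_correct / n, val_loss,
                        val_acc))
      if (val_acc > best$acc) {
        best <- list(acc = val_acc, params = params, epoch = epoch,
                     buffers = model)
      }
      if (val_loss < best_loss - 1e-8) {
        best_loss <- val_loss; stagnant <- 0L
      } else {
        stagnant <- stagnant + 1L
        if (stagnant >= recipe$patience) { stopped_early <- TRUE; break }
      }
      if (!is.null(recipe$stop_at_val_accuracy) &&
          val_acc >= recipe$stop_at_val_accuracy) break
    }
  })
  best_model <- model_set_params(best$buffers %||% model,
                                 unflatten_params(best$params %||% params,
                                                  model_params(model)))
  list(model = best_model, final_model = model, history = history,
       best_epoch = best$epoch, stopped_early = stopped_early)
}

## ---- metrics ----------------------------------------------------------------

#' Classification metrics report
#'
#' Per-class and macro-averaged precision, recall, F1 and one-vs-rest
#' accuracy, overall accuracy, the confusion matrix, and one-vs-rest ROC AUC
#' per class plus the micro-average, all derived from a single confusion
#' matrix / the probability scores.
#'
#' @param pred_probs `N x C` probability matrix (rows on the simplex).
#' @param labels integer true classes in `1..C`.
#' @param class_names optional class names.
#' @return list with `accuracy`, `confusion`, `per_class` (data.frame),
#'   `macro` (named vector), `auc` (per class) and `micro_auc`.
#' @export
compute_metrics <- function(pred_probs, labels, class_names = NULL) {
  C <- ncol(pred_probs)
  class_names <- class_names %||% paste0("class", seq_len(C))
  pred <- max.col(pred_probs)
  lv <- seq_len(C)
  confusion <- table(factor(labels, lv), factor(pred, lv),
                     dnn = c("true", "pred"))
  tp <- diag(confusion)
  fp <- colSums(confusion) - tp
  fn <- rowSums(confusion) - tp
  tn <- sum(confusion) - tp - fp - fn
  absent <- rowSums(confusion) == 0
  if (any(absent))
    warning("classes absent from labels: ",
            paste(class_names[absent], collapse = ", "),
            "; their recall is reported as 0")
  precision <- ifelse(tp + fp > 0, tp / (tp + fp), 0)
  recall <- ifelse(tp + fn > 0, tp / (tp + fn), 0)
  f1 <- ifelse(precision + recall > 0,
               2 * precision * recall / (precision + recall), 0)
  ovr_acc <- (tp + tn) / sum(confusion)
  auc <- vapply(seq_len(C), function(k) {
    y <- as.integer(labels == k)
    if (length(unique(y)) < 2L) return(NA_real_)
    as.numeric(pROC::auc(pROC::roc(y, pred_probs[, k], quiet = TRUE,
                                   direction = "<", levels = c(0, 1))))
  }, numeric(1))
  micro_auc <- {
    y <- as.integer(as.vector(vapply(lv, function(k) labels == k,
                                     logical(length(labels)))))
    s <- as.vector(pred_probs)
    as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE, direction = "<",
                                   levels = c(0, 1))))
  }
  list(accuracy = mean(pred == labels),
       confusion = unclass(confusion),
       per_class = data.frame(class = class_names, precision = precision,
                              recall = recall, f1 = f1,
                              ovr_accuracy = ovr_acc, auc = auc,
                              row.names = NULL),
       macro = c(precision = mean(precision), recall = mean(recall),
                 f1 = mean(f1)),
       auc = setNames(auc, class_names), micro_auc = micro_auc)
}

#' Patch-to-image majority voting
#'
#' Aggregates patch-level predictions per source image by modal vote; ties are
#' broken by the highest mean softmax probability among the tied classes, then
#' by the lowest class id (fully deterministic).
#'
#' @param image_ids character/factor vector of source-image ids per patch.
#' @param patch_probs `N x C` patch probability matrix.
#' @return data.frame with one row per image: `image_id`, `label` (voted
#'   class), `votes` (patch count).
#' @export
majority_vote <- function(image_ids, patch_probs) {
  if (length(image_ids) == 0L) stop("empty prediction set")
  if (length(image_ids) != nrow(patch_probs))
    stop("image_ids and patch_probs disagree in length")
  pred <- max.col(patch_probs)
  C <- ncol(patch_probs)
  ids <- unique(image_ids)
  out <- lapply(ids, function(id) {
    sel <- image_ids == id
    votes <- tabulate(pred[sel], C)
    top <- which(votes == max(votes))
    if (length(top) > 1L) {
      mp <- colMeans(patch_probs[sel, top, drop = FALSE])
      top <- top[mp == max(mp)]
    }
    data.frame(image_id = id, label = min(top), votes = sum(sel))
  })
  do.call(rbind, out)
}

## ---- run-comparison statistics ----------------------------------------------

#' Paired t-test and Cohen's d between repeated runs
#'
#' Paired t on the per-run differences with Cohen's d for the paired design
#' (`mean(diff) / sd(diff)`). Zero-variance differences are flagged degenerate
#' rather than yielding silent NaNs.
#'
#' @param runs_a,runs_b numeric vectors of equal length (>= 2): one score per
#'   repeated run.
#' @param correction `"benjamini_hochberg"`, `"bonferroni"` or `"none"`; with
#'   `n_comparisons > 1` the p-value is adjusted as one member of that family.
#' @param n_comparisons size of the comparison family for the correction.
#' @return list with `mean_a`, `mean_b`, `sd_a`, `sd_b`, `t_stat`, `df`,
#'   `p_value`, `cohens_d`, `effect_label` (small/medium/large bands at
#'   0.2/0.5/0.8), `adjusted_p`, `correction`, `degenerate`.
#' @export
paired_t_and_effect <- function(runs_a, runs_b,
                                correction = c("benjamini_hochberg",
                                               "bonferroni", "none"),
                                n_comparisons = 1L) {
  correction <- match.arg(correction)
  if (length(runs_a) != length(runs_b)) stop("run vectors differ in length")
  if (length(runs_a) < 2L) stop("need at least two paired runs")
  diffs <- runs_a - runs_b
  degenerate <- isTRUE(all.equal(sd(diffs), 0)) || sd(diffs) == 0
  if (degenerate) {
    t_stat <- NA_real_; p <- NA_real_
    d <- if (mean(diffs) == 0) 0 else NA_real_
  } else {
    tt <- t.test(runs_a, runs_b, paired = TRUE)
    t_stat <- unname(tt$statistic)
    p <- tt$p.value
    d <- mean(diffs) / sd(diffs)
  }
  adj <- if (degenerate) NA_real_ else switch(correction,
    none = p,
    bonferroni = min(1, p * n_comparisons),
    benjamini_hochberg = p)  # single member; family-wise use adjust_comparisons()
  list(mean_a = mean(runs_a), mean_b = mean(runs_b),
       sd_a = sd(runs_a), sd_b = sd(runs_b),
       t_stat = t_stat, df = length(diffs) - 1L, p_value = p,
       cohens_d = d, effect_label = effect_size_label(d),
       adjusted_p = adj, correction = correction, degenerate = degenerate)
}

# Interpretation bands: |d| >= 0.8 large, >= 0.5 medium, >= 0.2 small.
effect_size_label <- function(d) {
  if (is.na(d)) return(NA_character_)
  ad <- abs(d)
  if (ad >= 0.8) "large" else if (ad >= 0.5) "medium"
  else if (ad >= 0.2) "small" else "negligible"
}

#' Adjust a family of run comparisons for multiplicity
#'
#' @param comparisons list of results from [paired_t_and_effect()].
#' @param method `"benjamini_hochberg"` or `"bonferroni"`.
#' @return the list with `adjusted_p` and `correction` rewritten family-wise.
#' @export
adjust_comparisons <- function(comparisons,
                               method = c("benjamini_hochberg", "bonferroni")) {
  method <- match.arg(method)
  p <- vapply(comparisons, `[[`, numeric(1), "p_value")
  adj <- p.adjust(p, method = if (method == "bonferroni") "bonferroni" else "BH")
  for (i in seq_along(comparisons)) {
    comparisons[[i]]$adjusted_p <- adj[i]
    comparisons[[i]]$correction <- method
  }
  comparisons
}
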