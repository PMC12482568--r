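# The packaged desk-scale study: trains the reduced dual-branch model and its
# single-branch ablations on the synthetic fixture task and scores fused
# Grad-CAM localization against the generator's lesion masks. This is the
# reference experiment exercised by the test suite and the acceptance script.

#' Run the desk-scale fixture study
#'
#' Generates the 4-class fixture set (100 tiles per class, 96 px), splits it
#' 70/10/20 at the tile level, trains the reduced dual-branch model plus the
#' CNN-only and ViT-only ablation arms under one shared recipe (AdamW with a
#' toy-scale peak rate of 1e-3, cosine schedule with 2 warmup epochs,
#' flip/right-angle-rotation augmentation, at most `epochs` epochs, training
#' epochs shared by every arm), evaluates all three on the held-out test
#' tiles, and scores fused Grad-CAM lesion localization for the dual-branch
#' model.
#'
#' @param seed seed controlling the generator, split, initialization and
#'   training stochasticity.
#' @param epochs epoch budget shared by all arms.
#' @param tiles_per_class,tile_size fixture dimensions.
#' @param stop_at optional validation-accuracy early-exit threshold
#'   (disabled by default so every arm gets the identical budget).
#' @param arms which model arms to train (`"both"` is the dual-branch model).
#' @param n_cam_tiles test tiles used for the localization score.
#' @param extra_test_per_class freshly generated tiles per class (indices
#'   beyond the training pool, disjoint by construction) used as an enlarged
#'   evaluation set for the arm comparison -- the 80-tile split test set is
#'   too small to resolve close arms.
#' @param verbose print training progress.
#' @return list with the dual-branch training result (`full`), split-test
#'   accuracies (`full_test_acc`, `cnn_test_acc`, `vit_test_acc`), enlarged
#'   evaluation accuracies (`*_ext_acc`), the test-set `metrics` report,
#'   mean fused-CAM lesion IoU (`cam_iou`), and the last scored tile
#'   (`cam_image`, `cam_fused`, `cam_mask`).
#' @export
run_toy_study <- function(seed = 0L, epochs = 30L, tiles_per_class = 100L,
                          tile_size = 96L, stop_at = NULL,
                          arms = c("both", "cnn", "vit"),
                          n_cam_tiles = 12L, extra_test_per_class = 100L,
                          verbose = FALSE) {
  spec <- fixture_spec(n_classes = 4, tiles_per_class = tiles_per_class,
                       tile_size = tile_size, seed = seed)
  tiles <- generate_tiles(spec)
  rec <- data.frame(source_image_id = sprintf("t%04d", seq_along(tiles$y)),
                    label = tiles$y)
  rec <- image_level_split(rec, c(0.7, 0.1, 0.2), seed = seed)
  idx <- split(seq_along(tiles$y), rec$split)
  data <- list(train = list(x = tiles$x[, , , idx$train, drop = FALSE],
                            y = tiles$y[idx$train]),
               val = list(x = tiles$x[, , , idx$val, drop = FALSE],
                          y = tiles$y[idx$val]))
  # toy-scale recipe: higher peak rate and shorter warmup than the full-scale
  # default (appropriate for a ~0.7M-parameter model), geometry-preserving
  # augmentation only (blur would erase the 1.4 px blob-radius cue)
  recipe <- list(epochs = epochs, augment = "geometric", lr = 1e-3,
                 warmup_epochs = 2)
  if (!is.null(stop_at)) recipe$stop_at_val_accuracy <- stop_at
  out <- list(spec = spec, split = rec)
  test_x <- tiles$x[, , , idx$test, drop = FALSE]
  test_y <- tiles$y[idx$test]
  ext_x <- NULL; ext_y <- NULL
  if (extra_test_per_class > 0) {
    S <- spec$tile_size
    n_ext <- 4L * extra_test_per_class
    ext_x <- array(0, c(S, S, 3, n_ext))
    ext_y <- integer(n_ext)
    j <- 0L
    for (k in 1:4) for (i in seq_len(extra_test_per_class)) {
      j <- j + 1L
      ext_x[, , , j] <- generate_tile(spec, k, tiles_per_class + i)$pixels
      ext_y[j] <- k
    }
  }
  for (arm in arms) {
    cfg <- histofuse_config("reduced", n_classes = 4,
                            model = list(branches = arm))
    mod <- histofuse_model(cfg, seed = seed)
    res <- train_model(mod, data, recipe = recipe, seed = seed,
                       verbose = verbose)
    probs <- predict_probs(res$model, test_x)
    acc <- mean(max.col(probs) == test_y)
    ext_acc <- if (is.null(ext_x)) NA_real_ else
      mean(max.col(predict_probs(res$model, ext_x)) == ext_y)
    if (arm == "both") {
      out$full <- res
      out$full_test_acc <- acc
      out$full_ext_acc <- ext_acc
      out$metrics <- compute_metrics(probs, test_y)
    } else {
      out[[paste0(arm, "_test_acc")]] <- acc
      out[[paste0(arm, "_ext_acc")]] <- ext_acc
      out[[paste0(arm, "_history")]] <- res$history
    }
  }
  if (!is.null(out$full) && n_cam_tiles > 0) {
    pick <- idx$test[seq_len(min(n_cam_tiles, length(idx$test)))]
    ious <- numeric(0)
    for (i in pick) {
      ex <- explain_tile(out$full$model, tiles$x[, , , i])
      ious <- c(ious, localization_score(ex$fused, tiles$masks[, , i],
                                         q = 0.2))
      out$cam_image <- tiles$x[, , , i]
      out$cam_fused <- ex$fused
      out$cam_mask <- tiles$masks[, , i]
    }
    out$cam_iou <- mean(ious)
    out$cam_ious <- ious
  }
  out
}
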