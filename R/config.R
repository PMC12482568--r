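#' Model and training configuration
#'
#' Builds the nested configuration list consumed by [histofuse_model()] and
#' [train_model()]. Two presets are provided: `"full"` is the reference
#' architecture (50-layer bottleneck CNN with 2048 final channels, a 12-layer
#' ViT with 768-dimensional tokens and CLS taps at layers 6/9/12, 8-head
#' fusion attention, 768-dimensional shared embedding), while `"reduced"`
#' keeps the same five-stage stride-32 layout and tap pattern at a scale that
#' trains in minutes on one CPU.
#'
#' @param preset `"full"` or `"reduced"`.
#' @param n_classes number of tissue classes (4 for BACH-style, 8 for
#'   BreakHis-style tasks).
#' @param ... named overrides merged into the preset (nested lists are merged
#'   recursively), e.g. `model = list(fusion = list(dropout = 0.2))`.
#' @return a nested list with elements `model` (cnn / vit / fusion / head
#'   settings) and `train` (optimizer recipe).
#' @export
histofuse_config <- function(preset = c("full", "reduced"), n_classes = 4, ...) {
  preset <- match.arg(preset)
  base <- list(
    model = list(
      preset = preset,
      n_classes = n_classes,
      branches = "both",       # "both", "cnn", "vit" (ablation arms)
      use_se = TRUE,
      use_tama = TRUE,
      cnn = list(
        scale = preset,
        # reduced backbone: one residual block per stage, stride 2 each
        channels = c(12, 24, 48, 96, 128),
        se_ratio = 16,
        norm_mean = 0.5,
        norm_sd = 0.5
      ),
      vit = list(patch_size = 16, depth = 12, dim = 768, heads = 12,
                 mlp_ratio = 4, tap_layers = c(6, 9, 12), image_size = 224),
      fusion = list(dim = 768, heads = 8, mhsa_blocks = 1, ta_blocks = 1,
                    sequence_mode = "triplet", dropout = 0.5,
                    ta_residual = TRUE),
      cam_layers = c("stage3.block6", "stage4.block2", "stage4.block3")
    ),
    train = list(lr = 2e-4, weight_decay = 0.01, epochs = 50, batch_size = 32,
                 warmup_epochs = 5, patience = 15)
  )
  if (preset == "reduced") {
    base$model$cnn$se_ratio <- 8
    base$model$vit <- list(patch_size = 12, depth = 4, dim = 64, heads = 4,
                           mlp_ratio = 2, tap_layers = c(2, 3, 4),
                           image_size = 96)
    base$model$fusion <- list(dim = 64, heads = 4, mhsa_blocks = 1,
                              ta_blocks = 1, sequence_mode = "triplet",
                              dropout = 0.1, ta_residual = TRUE)
    base$model$cam_layers <- c("stage1", "stage2", "stage3")
  }
  merge_config(base, list(...))
}

#' Read a configuration from a YAML file
#'
#' The file's entries are merged over the chosen preset, so a config file only
#' needs to name what it changes (keys `model.cnn`, `model.vit`,
#' `model.fusion`, `train`, ...).
#'
#' @param path YAML file path.
#' @param preset preset the file overrides; the file itself may also set
#'   `model.preset`.
#' @return configuration list as from [histofuse_config()].
#' @export
load_config <- function(path, preset = "full") {
  user <- yaml::read_yaml(path)
  if (!is.null(user$model$preset)) preset <- user$model$preset
  n_classes <- user$model$n_classes %||% 4
  merge_config(histofuse_config(preset, n_classes = n_classes), user)
}

# Recursive merge: entries in `over` replace/extend entries in `base`.
merge_config <- function(base, over) {
  for (nm in names(over)) {
    if (is.list(over[[nm]]) && is.list(base[[nm]])) {
      base[[nm]] <- merge_config(base[[nm]], over[[nm]])
    } else {
      base[[nm]] <- over[[nm]]
    }
  }
  base
}
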