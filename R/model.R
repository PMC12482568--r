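# Full dual-branch model: assembly, forward pass, and the explicit backward
# pass used by training and Grad-CAM. Ablation arms (single branch, no SE, no
# fusion attention) are selected through the configuration so the comparison
# architectures share all remaining code paths.

#' Build the dual-branch classifier
#'
#' Assembles the CNN branch, the ViT branch and the fusion module described by
#' `config`, with weights drawn from `seed`. The ablation switches
#' `config$model$branches` (`"both"`, `"cnn"`, `"vit"`), `use_se` and
#' `use_tama` select reduced architectures that reuse the same components.
#'
#' @param config configuration list from [histofuse_config()].
#' @param seed integer seed for weight initialization.
#' @return a `histofuse_model` object.
#' @export
histofuse_model <- function(config, seed = 0L) {
  m <- config$model
  fz <- m$fusion
  if (fz$dim %% fz$heads != 0)
    stop("fusion dim ", fz$dim, " not divisible by ", fz$heads, " heads")
  with_seed(seed, {
    model <- list(config = config)
    if (m$branches != "vit") model$cnn <- cnn_branch(config)
    if (m$branches != "cnn") {
      if (m$branches == "both" && m$vit$dim != fz$dim)
        stop("vit dim must equal the fusion dim for the dual-branch model")
      model$vit <- vit_branch(config)
    }
    if (m$branches == "both") {
      model$fusion <- list(
        align = linear_init(2 * fz$dim, fz$dim, scale = 1),
        mhsa = lapply(seq_len(fz$mhsa_blocks), function(i)
          msa_init(fz$dim, fz$heads)),
        ta = lapply(seq_len(fz$ta_blocks), function(i)
          ta_init(fz$dim, fz$heads)))
    }
    head_dim <- if (m$branches == "both") fz$dim
                else if (m$branches == "cnn") model$cnn$dim else m$vit$dim
    model$head <- linear_init(head_dim, m$n_classes, scale = 1)
    structure(model, class = "histofuse_model")
  })
}

#' @export
print.histofuse_model <- function(x, ...) {
  m <- x$config$model
  np <- sum(vapply(flatten_params(model_params(x)), length, numeric(1)))
  cat("<histofuse_model> preset:", m$preset,
      "| branches:", m$branches,
      "| SE:", m$use_se, "| TAMA:", m$use_tama,
      "| classes:", m$n_classes,
      "| parameters:", format(np, big.mark = ","), "\n")
  invisible(x)
}

# Pure parameter tree (no buffers, no metadata) -- the optimizer's view.
model_params <- function(model) {
  out <- list()
  if (!is.null(model$cnn))
    out$cnn <- list(blocks = lapply(model$cnn$blocks, `[[`, "params"),
                    se = model$cnn$se, proj = model$cnn$proj)
  if (!is.null(model$vit))
    out$vit <- list(patch = model$vit$patch, cls = model$vit$cls,
                    pe = model$vit$pe, blocks = model$vit$blocks)
  if (!is.null(model$fusion)) out$fusion <- model$fusion
  out$head <- model$head
  out
}

model_set_params <- function(model, tree) {
  if (!is.null(tree$cnn)) {
    for (i in seq_along(model$cnn$blocks))
      model$cnn$blocks[[i]]$params <- tree$cnn$blocks[[i]]
    model$cnn$se <- tree$cnn$se
    model$cnn$proj <- tree$cnn$proj
  }
  if (!is.null(tree$vit)) {
    model$vit$patch <- tree$vit$patch
    model$vit$cls <- tree$vit$cls
    model$vit$pe <- tree$vit$pe
    model$vit$blocks <- tree$vit$blocks
  }
  if (!is.null(tree$fusion)) model$fusion <- tree$fusion
  model$head <- tree$head
  model
}

# Normalize raw [0,1] pixels with the configured per-channel mean/sd.
normalize_images <- function(images, config) {
  (images - config$model$cnn$norm_mean) / config$model$cnn$norm_sd
}

#' Forward pass
#'
#' Runs an image batch through the configured architecture. In eval mode
#' (`train = FALSE`) the pass is deterministic given fixed weights.
#'
#' @param model a [histofuse_model()].
#' @param images `(H, W, 3, B)` array of raw pixels in `[0, 1]` (a single
#'   `(H, W, 3)` image is promoted to a batch of one).
#' @param train logical; enables batch statistics and dropout.
#' @param full keep all intermediate caches (needed for a backward pass).
#' @return with `full = FALSE`, a list with `probs` and `logits` (`B x C`);
#'   with `full = TRUE`, additionally all caches, branch activations and the
#'   buffer-updated model.
#' @export
histofuse_forward <- function(model, images, train = FALSE, full = FALSE) {
  if (length(dim(images)) == 3L) dim(images) <- c(dim(images), 1L)
  m <- model$config$model
  x <- normalize_images(images, model$config)
  cache <- list()
  z_cnn <- NULL; z_vit <- NULL
  if (!is.null(model$cnn)) {
    cf <- extract_local_features(x, model$cnn, train = train, full = TRUE)
    model$cnn <- cf$branch          # running statistics updated in train mode
    feats <- cf$out
    if (m$use_se) {
      se <- se_recalibrate(feats, model$cnn$se)
      feats <- se$features
      cache$se <- se
    }
    g <- gap_fwd(feats)
    pr <- linear_fwd(g$out, model$cnn$proj)
    z_cnn <- t(pr$out)
    cache$cnn <- list(feat = cf, gap = g, proj = pr)
  }
  if (!is.null(model$vit)) {
    pe <- patch_embed(x, model$vit)
    enc <- encode_with_cls_taps(pe$tokens, model$vit, full = TRUE)
    z_vit <- fuse_cls_tokens(enc$taps)
    cache$vit <- list(pe = pe, enc = enc, n_taps = length(enc$taps))
  }
  if (m$branches == "both") {
    al <- align_tokens(z_cnn, z_vit, model$fusion$align,
                       mode = m$fusion$sequence_mode)
    seq <- al$tokens
    cache$align <- al
    if (m$use_tama) {
      cache$mhsa <- vector("list", length(model$fusion$mhsa))
      for (i in seq_along(model$fusion$mhsa)) {
        r <- mhsa_stage(seq, model$fusion$mhsa[[i]])
        seq <- r$tokens
        cache$mhsa[[i]] <- r$cache
      }
      cache$ta <- vector("list", length(model$fusion$ta))
      for (i in seq_along(model$fusion$ta)) {
        r <- ta_layer(seq, model$fusion$ta[[i]],
                      residual = m$fusion$ta_residual)
        seq <- r$tokens
        cache$ta[[i]] <- r$cache
      }
    } else {
      # fusion-ablation arm: classify straight from the joint projection
      seq <- array(matrix(al$tokens[, dim(al$tokens)[2], ], dim(al$tokens)[1]),
                   c(dim(al$tokens)[1], 1L, dim(al$tokens)[3]))
    }
  } else if (m$branches == "cnn") {
    seq <- array(t(z_cnn), c(ncol(z_cnn), 1L, nrow(z_cnn)))
  } else {
    seq <- array(t(z_vit), c(ncol(z_vit), 1L, nrow(z_vit)))
  }
  pc <- pool_and_classify(seq, model$head, dropout = m$fusion$dropout,
                          train = train)
  res <- list(probs = pc$probs, logits = pc$logits)
  if (!full) return(res)
  res$cache <- c(cache, list(pc = pc$cache, z_cnn = z_cnn, z_vit = z_vit))
  res$model <- model
  res
}

#' Backward pass
#'
#' Backpropagates a gradient on the logits through the whole architecture,
#' returning parameter gradients shaped like `model_params(model)` and,
#' optionally, gradients of the scalar objective with respect to named CNN
#' block activations (Grad-CAM).
#'
#' @param model the model used for the forward pass.
#' @param fw result of `histofuse_forward(..., full = TRUE)`.
#' @param dlogits `B x C` gradient of the objective w.r.t. the logits.
#' @param capture character vector of CNN block names whose activation
#'   gradients should be captured.
#' @return list with `grads` and `act_grads`.
#' @export
histofuse_backward <- function(model, fw, dlogits, capture = character()) {
  m <- model$config$model
  cache <- fw$cache
  grads <- list()
  pcb <- pool_and_classify_bwd(dlogits, model$head, cache$pc)
  grads$head <- pcb$grads
  dseq <- pcb$dseq
  dz_cnn <- NULL; dz_vit <- NULL
  if (m$branches == "both") {
    if (m$use_tama) {
      for (i in rev(seq_along(model$fusion$ta))) {
        r <- ta_layer_bwd(dseq, model$fusion$ta[[i]], cache$ta[[i]])
        grads$fusion$ta[[i]] <- r$grads
        dseq <- r$dx
      }
      for (i in rev(seq_along(model$fusion$mhsa))) {
        r <- msa_bwd(dseq, model$fusion$mhsa[[i]], cache$mhsa[[i]])
        grads$fusion$mhsa[[i]] <- r$grads
        dseq <- r$dx
      }
    } else {
      dal <- array(0, dim(cache$align$tokens))
      dal[, dim(dal)[2], ] <- dseq[, 1L, ]
      dseq <- dal
    }
    ab <- align_tokens_bwd(dseq, model$fusion$align, cache$align)
    grads$fusion$align <- ab$grads
    dz_cnn <- ab$dz_cnn
    dz_vit <- ab$dz_vit
  } else if (m$branches == "cnn") {
    dz_cnn <- t(matrix(dseq[, 1L, ], dim(dseq)[1]))
  } else {
    dz_vit <- t(matrix(dseq[, 1L, ], dim(dseq)[1]))
  }
  act_grads <- list()
  if (!is.null(model$cnn) && !is.null(dz_cnn)) {
    pb <- linear_bwd(t(dz_cnn), model$cnn$proj, cache$cnn$proj)
    dfeats <- gap_bwd(pb$dx, cache$cnn$gap)
    se_grads <- NULL
    if (m$use_se) {
      sb <- se_bwd(dfeats, model$cnn$se, cache$se$cache)
      dfeats <- sb$dx
      se_grads <- sb$grads
    }
    bb <- cnn_backbone_bwd(model$cnn, dfeats, cache$cnn$feat$caches,
                           capture = capture)
    grads$cnn <- list(blocks = bb$grads, se = se_grads,
                      proj = list(W = pb$dW, b = pb$db))
    act_grads <- bb$act_grads
  }
  if (!is.null(model$vit) && !is.null(dz_vit)) {
    n_taps <- cache$vit$n_taps
    dtaps <- rep(list(dz_vit / n_taps), n_taps)
    eb <- vit_encoder_bwd(model$vit, cache$vit$enc, dtaps)
    pb <- patch_embed_bwd(model$vit, eb$dtokens, cache$vit$pe)
    grads$vit <- list(patch = pb$grads$patch, cls = pb$grads$cls,
                      pe = pb$grads$pe, blocks = eb$grads)
  }
  list(grads = grads, act_grads = act_grads)
}

#' Predict class probabilities
#'
#' Deterministic eval-mode inference in mini-batches.
#'
#' @param model a [histofuse_model()].
#' @param images `(H, W, 3, N)` array.
#' @param batch_size mini-batch size.
#' @return `N x C` matrix of class probabilities.
#' @export
predict_probs <- function(model, images, batch_size = 32L) {
  if (length(dim(images)) == 3L) dim(images) <- c(dim(images), 1L)
  n <- dim(images)[4]
  out <- NULL
  for (i in seq(1L, n, by = batch_size)) {
    idx <- i:min(i + batch_size - 1L, n)
    p <- histofuse_forward(model, images[, , , idx, drop = FALSE])$probs
    out <- rbind(out, p)
  }
  out
}
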