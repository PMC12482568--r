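# Multi-layer Grad-CAM on the CNN branch: per-layer class activation maps
# from gradient-weighted channel sums, cross-layer fusion by resize-and-
# average with min-max normalization, pseudo-color overlays, and quantitative
# localization scoring against binary lesion masks.

#' Per-layer class activation map
#'
#' Computes the Grad-CAM map for one registered CNN block: channel weights are
#' the spatial means of the gradient of the pre-softmax class score w.r.t.
#' that block's activation, and the map is the ReLU of the weighted channel
#' sum.
#'
#' @param model a [histofuse_model()] containing a CNN branch.
#' @param image `(H, W, 3)` array (raw pixels in `[0, 1]`).
#' @param layer_id name of a CNN block (see `model$config$model$cam_layers`);
#'   unknown names raise an error listing the registered blocks.
#' @param class_id 1-based class whose score is explained; default the
#'   predicted class.
#' @return list of class `cam`: `map` (nonnegative `h_k x w_k` matrix),
#'   `layer_id`, `class_id`, `alphas` (channel weights), `probs`.
#' @export
layer_cam <- function(model, image, layer_id, class_id = NULL) {
  if (is.null(model$cnn)) stop("model has no CNN branch to explain")
  registered <- vapply(model$cnn$blocks, `[[`, character(1), "name")
  if (!layer_id %in% registered)
    stop("unknown layer '", layer_id, "'; registered layers: ",
         paste(registered, collapse = ", "))
  fw <- histofuse_forward(model, image, train = FALSE, full = TRUE)
  if (is.null(class_id)) class_id <- which.max(fw$probs[1, ])
  dlogits <- matrix(0, 1, ncol(fw$logits))
  dlogits[1, class_id] <- 1              # d y_c / d logits, pre-softmax score
  bw <- histofuse_backward(model, fw, dlogits, capture = layer_id)
  A <- fw$cache$cnn$feat$activations[[layer_id]]   # (C, h, w, 1)
  dA <- bw$act_grads[[layer_id]]
  d <- dim(A)
  alphas <- rowMeans(matrix(dA, d[1]))
  cam <- matrix(pmax(crossprod(matrix(A, d[1]), alphas), 0), d[2], d[3])
  structure(list(map = cam, layer_id = layer_id, class_id = class_id,
                 alphas = alphas, probs = fw$probs[1, ]),
            class = "cam")
}

#' Fuse class activation maps across layers
#'
#' Each map is bilinearly resized to the target size, the maps are averaged
#' with equal weights, and the result is min-max normalized to `[0, 1]`. A
#' constant (zero-range) fused map normalizes to all zeros with a warning.
#'
#' @param cams list of `cam` objects (or plain matrices).
#' @param target_size `c(H, W)` output size.
#' @return a `cam` object with `map` in `[0, 1]` and `layer_id = "fusion"`.
#' @export
fuse_cams <- function(cams, target_size) {
  if (length(cams) < 1L) stop("need at least one activation map")
  maps <- lapply(cams, function(cm) if (inherits(cm, "cam")) cm$map else cm)
  resized <- lapply(maps, bilinear_resize, out_h = target_size[1],
                    out_w = target_size[2])
  fused <- Reduce(`+`, resized) / length(resized)
  rng <- range(fused)
  if (diff(rng) <= .Machine$double.eps * max(abs(rng), 1)) {
    warning("fused activation map has zero range; returning all zeros")
    fused <- fused * 0
  } else {
    fused <- (fused - rng[1]) / diff(rng)
  }
  cls <- if (inherits(cams[[1]], "cam")) cams[[1]]$class_id else NA_integer_
  structure(list(map = fused, layer_id = "fusion", class_id = cls),
            class = "cam")
}

# Jet-like pseudo-color lookup: value 0 -> blue, 0.35 -> cyan, 0.5 -> green,
# 0.65 -> yellow, 1 -> red; piecewise linear in each channel.
cam_colormap <- function(v) {
  v <- pmin(pmax(v, 0), 1)
  r <- pmin(pmax(4 * v - 2, 0), 1)
  g <- pmin(pmax(2 - abs(4 * v - 2), 0), 1)
  b <- pmin(pmax(2 - 4 * v, 0), 1)
  array(c(r, g, b), c(dim(v) %||% length(v), 3L))
}

#' Overlay a heatmap on an image
#'
#' Pixelwise convex combination `image * (1 - alpha) + heatmap * alpha` of the
#' source image and the pseudo-colored activation map.
#'
#' @param image `(H, W, 3)` array in `[0, 1]`.
#' @param cam a `cam` object (map normalized to `[0, 1]`) or matrix of the
#'   same spatial size as the image.
#' @param alpha blend weight in `[0, 1]`; 0 returns the image, 1 the heatmap.
#' @return `(H, W, 3)` overlay array.
#' @export
overlay_cam <- function(image, cam, alpha = 0.5) {
  m <- if (inherits(cam, "cam")) cam$map else cam
  if (!isTRUE(all.equal(dim(m), dim(image)[1:2])))
    stop("activation map (", paste(dim(m), collapse = "x"),
         ") and image (", paste(dim(image)[1:2], collapse = "x"),
         ") sizes differ")
  if (alpha < 0 || alpha > 1) stop("alpha must lie in [0, 1]")
  heat <- cam_colormap(m)
  image * (1 - alpha) + heat * alpha
}

#' Localization score of an activation map against a lesion mask
#'
#' Intersection-over-union between the top-`q` quantile region of the fused
#' map and a binary lesion mask. For a map that is independent uniform noise
#' and a mask of area fraction `a`, the expected IoU is
#' `q * a / (q + a - q * a)` -- the reference chance baseline.
#'
#' @param cam `cam` object or matrix in `[0, 1]`.
#' @param mask binary matrix of the same size.
#' @param q top-quantile fraction defining the predicted region.
#' @return IoU in `[0, 1]`.
#' @export
localization_score <- function(cam, mask, q = 0.2) {
  m <- if (inherits(cam, "cam")) cam$map else cam
  if (!isTRUE(all.equal(dim(m), dim(mask))))
    stop("map and mask sizes differ")
  if (sum(mask) == 0) stop("empty lesion mask: localization score undefined")
  thr <- quantile(m, 1 - q, names = FALSE)
  region <- m >= thr
  inter <- sum(region & (mask > 0))
  union <- sum(region | (mask > 0))
  inter / union
}

#' Fused multi-layer explanation for one tile
#'
#' Convenience wrapper: per-layer maps for the model's registered CAM layers,
#' fused to the image resolution, with the overlay.
#'
#' @param model a [histofuse_model()].
#' @param image `(H, W, 3)` array.
#' @param class_id class to explain (default: predicted).
#' @param alpha overlay blend weight.
#' @param layers CNN block names; default `model$config$model$cam_layers`.
#' @return list with `fused` (`cam`), `per_layer`, `overlay`, `class_id`,
#'   `probs`.
#' @export
explain_tile <- function(model, image, class_id = NULL, alpha = 0.5,
                         layers = model$config$model$cam_layers) {
  per_layer <- lapply(layers, function(l)
    layer_cam(model, image, l, class_id = class_id))
  fused <- fuse_cams(per_layer, dim(image)[1:2])
  list(fused = fused, per_layer = per_layer,
       overlay = overlay_cam(image, fused, alpha),
       class_id = per_layer[[1]]$class_id, probs = per_layer[[1]]$probs)
}
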