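# Image IO and the small set of deterministic raster operations the pipeline
# needs (bilinear resize, rotation with reflection padding, separable Gaussian
# blur). Interpolation uses the half-pixel-center convention: pixel (i, j)
# sits at continuous coordinate (i - 0.5, j - 0.5), so resizing maps output
# center u to input coordinate u * scale. This convention is pinned so CAM
# fusion and augmentation are bit-reproducible.

#' Read an image file
#'
#' Reads PNG or TIFF into an `(H, W, 3)` array in `[0, 1]`; grayscale images
#' are replicated to 3 channels, alpha channels are dropped.
#'
#' @param path file path (`.png`, `.tif`, `.tiff`).
#' @return numeric `(H, W, 3)` array.
#' @export
load_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported image format: .", ext))
  if (length(dim(img)) == 2L) img <- array(rep(img, 3), c(dim(img), 3L))
  if (dim(img)[3] > 3L) img <- img[, , 1:3, drop = FALSE]
  img
}

#' Write an image file
#'
#' @param img `(H, W)` or `(H, W, 3)` array in `[0, 1]`.
#' @param path output path (`.png`, `.tif`, `.tiff`).
#' @export
save_image <- function(img, path) {
  img <- pmin(pmax(img, 0), 1)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png = png::writePNG(img, path),
    tif = ,
    tiff = tiff::writeTIFF(img, path, bits.per.sample = 8L),
    stop("unsupported image format: .", ext))
  invisible(path)
}

#' Bilinear resize
#'
#' Half-pixel-center bilinear interpolation of a 2-D map or an `(H, W, C)`
#' image; border samples are clamped.
#'
#' @param img matrix or `(H, W, C)` array.
#' @param out_h,out_w output dimensions in pixels.
#' @return resized matrix/array.
#' @export
bilinear_resize <- function(img, out_h, out_w) {
  d <- dim(img)
  h <- d[1]; w <- d[2]
  sy <- h / out_h; sx <- w / out_w
  ys <- (seq_len(out_h) - 0.5) * sy + 0.5
  xs <- (seq_len(out_w) - 0.5) * sx + 0.5
  y0 <- pmin(pmax(floor(ys), 1), h); y1 <- pmin(y0 + 1, h)
  x0 <- pmin(pmax(floor(xs), 1), w); x1 <- pmin(x0 + 1, w)
  fy <- pmin(pmax(ys - y0, 0), 1); fx <- pmin(pmax(xs - x0, 0), 1)
  resize_plane <- function(m) {
    a <- m[y0, x0, drop = FALSE] * (1 - fy) + m[y1, x0, drop = FALSE] * fy
    b <- m[y0, x1, drop = FALSE] * (1 - fy) + m[y1, x1, drop = FALSE] * fy
    sweep(a, 2, 1 - fx, `*`) + sweep(b, 2, fx, `*`)
  }
  if (length(d) == 2L) return(resize_plane(img))
  out <- array(0, c(out_h, out_w, d[3]))
  for (c in seq_len(d[3])) out[, , c] <- resize_plane(img[, , c])
  out
}

# Reflect an out-of-range 1-based index back into [1, n].
reflect_index <- function(i, n) {
  if (n == 1L) return(rep(1L, length(i)))
  p <- 2L * n - 2L
  i <- (i - 1L) %% p
  i <- ifelse(i < 0L, i + p, i)
  as.integer(ifelse(i >= n, p - i, i) + 1L)
}

#' Rotate an image by an arbitrary angle
#'
#' Rotation about the image center with bilinear sampling and reflection
#' padding (used by the small-angle augmentation policy).
#'
#' @param img `(H, W, C)` array or matrix.
#' @param angle_deg rotation angle in degrees (counter-clockwise).
#' @return rotated image, same shape.
#' @export
rotate_bilinear <- function(img, angle_deg) {
  d <- dim(img)
  h <- d[1]; w <- d[2]
  th <- angle_deg * pi / 180
  cy <- (h + 1) / 2; cx <- (w + 1) / 2
  yy <- matrix(seq_len(h), h, w) - cy
  xx <- matrix(seq_len(w), h, w, byrow = TRUE) - cx
  # inverse map: sample source at rotation by -angle
  sy <- cos(th) * yy - sin(th) * xx + cy
  sx <- sin(th) * yy + cos(th) * xx + cx
  y0 <- floor(sy); x0 <- floor(sx)
  fy <- sy - y0; fx <- sx - x0
  iy0 <- reflect_index(as.integer(y0), h); iy1 <- reflect_index(as.integer(y0) + 1L, h)
  ix0 <- reflect_index(as.integer(x0), w); ix1 <- reflect_index(as.integer(x0) + 1L, w)
  sample_plane <- function(m) {
    v00 <- m[cbind(iy0, ix0)]; v10 <- m[cbind(iy1, ix0)]
    v01 <- m[cbind(iy0, ix1)]; v11 <- m[cbind(iy1, ix1)]
    matrix(v00 * (1 - fy) * (1 - fx) + v10 * fy * (1 - fx) +
             v01 * (1 - fy) * fx + v11 * fy * fx, h, w)
  }
  if (length(d) == 2L) return(sample_plane(img))
  out <- img
  for (c in seq_len(d[3])) out[, , c] <- sample_plane(img[, , c])
  out
}

# Rotate by a multiple of 90 degrees (exact, no interpolation).
rotate90 <- function(img, k) {
  k <- ((k %% 4) + 4) %% 4
  if (k == 0) return(img)
  rot1 <- function(m) t(m)[, rev(seq_len(nrow(m))), drop = FALSE] # 90 deg CCW
  f <- function(m) { for (i in seq_len(k)) m <- rot1(m); m }
  if (length(dim(img)) == 2L) return(f(img))
  d <- dim(img)
  first <- f(img[, , 1])
  out <- array(0, c(dim(first), d[3]))
  out[, , 1] <- first
  for (c in seq_len(d[3])[-1]) out[, , c] <- f(img[, , c])
  out
}

#' Separable Gaussian blur
#'
#' @param img matrix or `(H, W, C)` array.
#' @param sigma Gaussian standard deviation in pixels; the kernel truncates at
#'   `ceiling(3 * sigma)` with reflection padding.
#' @return blurred image, same shape.
#' @export
gaussian_blur <- function(img, sigma) {
  if (sigma <= 0) return(img)
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  k <- k / sum(k)
  blur_plane <- function(m) {
    h <- nrow(m); w <- ncol(m)
    padr <- reflect_index(seq(1L - r, h + r), h)
    m3 <- stats::filter(m[padr, , drop = FALSE], k, sides = 2)
    m3 <- m3[(r + 1):(r + h), , drop = FALSE]
    padc <- reflect_index(seq(1L - r, w + r), w)
    m5 <- stats::filter(t(m3[, padc, drop = FALSE]), k, sides = 2)
    t(m5)[, (r + 1):(r + w), drop = FALSE]
  }
  if (length(dim(img)) == 2L) return(blur_plane(img))
  out <- img
  for (c in seq_len(dim(img)[3])) out[, , c] <- blur_plane(img[, , c])
  out
}
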