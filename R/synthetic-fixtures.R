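# Deterministic generator of histology-like labeled tiles. Tiles emulate
# H&E statistics: an eosin-pink low-frequency background, sparse class-
# neutral hematoxylin-purple blobs, and a handful of "lesion" foci --
# compact discs filled with nuclear-like blobs. The class is a factorial
# design of a LOCAL cue (blob density and radius INSIDE the foci) and a
# GLOBAL cue (the spatial arrangement of the foci across the tile), with
# fewer local levels than classes -- so neither in-focus texture alone nor
# arrangement alone separates all classes, and a classifier needs both. The
# binary lesion mask is the union of the foci, so all class-discriminative
# structure lies inside the mask: a faithful explanation of a trained
# classifier should localize it. Every artifact is a pure function of
# (spec, seed, class, index).

fixture_layouts <- c("scattered", "clustered", "ring", "banded")

#' Fixture generator specification
#'
#' @param n_classes 4 or 8. With 4 classes the recipes are 2 local levels x
#'   {scattered, ring} focus arrangements; with 8, 2 local levels x all four
#'   arrangements.
#' @param tiles_per_class tiles generated per class.
#' @param tile_size tile side in pixels (default 96; 224 and 512 presets
#'   mirror common patch sizes).
#' @param seed master seed; every tile is reproducible from
#'   `(spec, class, index)`.
#' @param lesion_fraction_range range of the total lesion (foci) area
#'   fraction.
#' @param n_patients optionally group tiles into this many synthetic
#'   class-pure patients (several tiles per patient) to exercise grouped
#'   k-fold planning.
#' @return a `fixture_spec` list including the per-class `recipes`
#'   (in-focus blob count level, blob radius, focus layout).
#' @export
fixture_spec <- function(n_classes = 4, tiles_per_class = 100, tile_size = 96,
                         seed = 0L, lesion_fraction_range = c(0.12, 0.30),
                         n_patients = NULL) {
  if (!n_classes %in% c(4L, 8L)) stop("n_classes must be 4 or 8")
  layouts <- if (n_classes == 4L) fixture_layouts[c(1, 3)] else fixture_layouts
  area_scale <- (tile_size / 96)^2
  len_scale <- tile_size / 96
  # two local levels: (expected in-focus blobs, blob radius); shared across
  # arrangements by design
  levels <- list(list(density = 14 * area_scale, radius = 2.6 * len_scale),
                 list(density = 34 * area_scale, radius = 4.0 * len_scale))
  recipes <- lapply(seq_len(n_classes), function(k) {
    lev <- levels[[(k - 1) %/% length(layouts) + 1]]
    c(lev, list(layout = layouts[(k - 1) %% length(layouts) + 1]))
  })
  structure(list(n_classes = n_classes, tiles_per_class = tiles_per_class,
                 tile_size = tile_size, seed = as.integer(seed),
                 lesion_fraction_range = lesion_fraction_range,
                 n_patients = n_patients, recipes = recipes,
                 background_density = 6 * area_scale,
                 background_radius = 3.2 * len_scale),
            class = "fixture_spec")
}

tile_seed <- function(spec, class_id, index) {
  (spec$seed %% 9973L) * 200003L + class_id * 30011L + index * 101L
}

# Expected blobs per tile: class-neutral background mean plus the class's
# in-focus level.
expected_blob_count <- function(spec, class_id) {
  spec$background_density + spec$recipes[[class_id]]$density
}

# Focus-center coordinates (n x 2 matrix of (y, x)) for one arrangement.
# Placements guarantee pairwise separation >= 2.1 focus radii and full
# containment, so the mask fraction equals the sampled target up to
# rasterization.
focus_centers <- function(layout, S, rf) {
  jit <- function(n, s) runif(n, -s, s)      # bounded jitter keeps separation
  switch(layout,
    scattered = {
      lo <- rf + 1; hi <- S - rf - 1
      best <- NULL; best_sep <- -Inf
      for (try in 1:300) {
        pos <- cbind(runif(3, lo, hi), runif(3, lo, hi))
        sep <- min(dist(pos))
        if (sep > best_sep) { best <- pos; best_sep <- sep }
        if (sep >= 2.1 * rf) break
      }
      best
    },
    clustered = {
      m <- 2.3 * rf + 1
      c0 <- c(runif(1, m, S - m), runif(1, m, S - m))
      th <- runif(1, 0, 2 * pi) + 2 * pi * (0:2) / 3
      cbind(c0[1] + 1.25 * rf * sin(th), c0[2] + 1.25 * rf * cos(th))
    },
    ring = {
      R <- 0.33 * S
      th <- runif(1, 0, 2 * pi) + pi / 2 * (0:3) + jit(4, 0.12)
      cbind(S / 2 + R * sin(th), S / 2 + R * cos(th))
    },
    banded = {
      yy <- rep(c(S / 3, 2 * S / 3), each = 2) + jit(4, S / 45)
      xx <- rep(c(0.3 * S, 0.7 * S), 2) + jit(4, S / 45)
      cbind(yy, xx)
    },
    stop("unknown layout: ", layout))
}

# Paint one soft-edged rotated ellipse onto (H, W, 3) pixels.
paint_blob <- function(px, cy, cx, ry, rx, phi, col) {
  S <- dim(px)[1]
  r <- max(rx, ry) + 2
  ys <- max(1, floor(cy - r)):min(S, ceiling(cy + r))
  xs <- max(1, floor(cx - r)):min(S, ceiling(cx + r))
  if (!length(ys) || !length(xs)) return(px)
  yy <- matrix(ys - cy, length(ys), length(xs))
  xx <- matrix(xs - cx, length(ys), length(xs), byrow = TRUE)
  u <- (cos(phi) * xx + sin(phi) * yy) / rx
  v <- (-sin(phi) * xx + cos(phi) * yy) / ry
  dist <- sqrt(u^2 + v^2)
  a <- pmin(pmax(1.6 * (1 - dist), 0), 1) * 0.92
  for (ch in 1:3)
    px[ys, xs, ch] <- (1 - a) * px[ys, xs, ch] + a * col[ch]
  px
}

#' Generate one synthetic tile
#'
#' @param spec a [fixture_spec()].
#' @param class_id class in `1..n_classes`.
#' @param index tile index within the class (part of the tile's seed).
#' @return list with `pixels` (`(S, S, 3)` in `[0, 1]`), `mask` (binary
#'   `S x S` lesion mask, the union of the foci), `label`, `n_blobs` and
#'   `lesion_fraction`.
#' @export
generate_tile <- function(spec, class_id, index) {
  if (class_id < 1 || class_id > spec$n_classes)
    stop("class_id must lie in [1, ", spec$n_classes, "]")
  rec <- spec$recipes[[class_id]]
  S <- spec$tile_size
  with_seed(tile_seed(spec, class_id, index), {
    # eosin-like background with low-frequency luminance noise
    base <- c(0.91, 0.78, 0.85) + rnorm(3, sd = 0.015)
    noise <- bilinear_resize(matrix(rnorm(36, sd = 1), 6, 6), S, S) * 0.04
    px <- array(0, c(S, S, 3))
    for (ch in 1:3) px[, , ch] <- base[ch] + noise
    # lesion foci: total area fraction sampled inside the configured range,
    # split over the arrangement's focus count
    fr <- spec$lesion_fraction_range
    f <- runif(1, fr[1] + 0.02, fr[2] - 0.02)
    n_foci <- c(scattered = 3L, clustered = 3L, ring = 4L,
                banded = 4L)[[rec$layout]]
    rf <- S * sqrt(f / (n_foci * pi))
    centers <- focus_centers(rec$layout, S, rf)
    yy <- matrix(seq_len(S), S, S)
    xx <- matrix(seq_len(S), S, S, byrow = TRUE)
    mask <- matrix(0, S, S)
    for (i in seq_len(n_foci)) {
      mask <- mask + ((yy - centers[i, 1])^2 + (xx - centers[i, 2])^2 <= rf^2)
    }
    mask <- (mask > 0) * 1
    # faint chromatic shift inside the foci (lesions are visible structures)
    tint <- c(-0.035, -0.03, 0.01)
    for (ch in 1:3) px[, , ch] <- px[, , ch] + tint[ch] * mask
    # sparse class-neutral background blobs
    n_bg <- rpois(1, spec$background_density)
    if (n_bg > 0) {
      for (i in seq_len(n_bg)) {
        col <- pmin(pmax(c(0.38, 0.25, 0.55) + rnorm(3, sd = 0.04), 0), 1)
        px <- paint_blob(px, runif(1, 1, S), runif(1, 1, S),
                         ry = spec$background_radius * runif(1, 0.8, 1.2),
                         rx = spec$background_radius * runif(1, 0.8, 1.2),
                         phi = runif(1, 0, pi), col = col)
      }
    }
    # class-defining blobs inside the foci: count level split over foci
    n_les <- 0L
    for (i in seq_len(n_foci)) {
      n_i <- rpois(1, rec$density / n_foci)
      n_les <- n_les + n_i
      if (n_i > 0) {
        rr <- (rf - rec$radius) * sqrt(runif(n_i))
        th <- runif(n_i, 0, 2 * pi)
        for (j in seq_len(n_i)) {
          col <- pmin(pmax(c(0.38, 0.25, 0.55) + rnorm(3, sd = 0.04), 0), 1)
          px <- paint_blob(px,
                           cy = centers[i, 1] + rr[j] * sin(th[j]),
                           cx = centers[i, 2] + rr[j] * cos(th[j]),
                           ry = rec$radius * runif(1, 0.75, 1.3),
                           rx = rec$radius * runif(1, 0.75, 1.3),
                           phi = runif(1, 0, pi), col = col)
        }
      }
    }
    list(pixels = pmin(pmax(px, 0), 1), mask = mask, label = class_id,
         n_blobs = n_bg + n_les, lesion_fraction = sum(mask) / S^2)
  })
}

#' Generate an in-memory fixture set
#'
#' @param spec a [fixture_spec()].
#' @param with_masks keep the lesion masks.
#' @return list with `x` (`(S, S, 3, N)`), `y` (labels), `masks`
#'   (`(S, S, N)` or `NULL`), `patient_id` (or `NULL`), `n_blobs`.
#' @export
generate_tiles <- function(spec, with_masks = TRUE) {
  N <- spec$n_classes * spec$tiles_per_class
  S <- spec$tile_size
  x <- array(0, c(S, S, 3, N))
  y <- integer(N); nb <- integer(N)
  masks <- if (with_masks) array(0, c(S, S, N)) else NULL
  i <- 0L
  for (k in seq_len(spec$n_classes)) {
    for (j in seq_len(spec$tiles_per_class)) {
      i <- i + 1L
      tl <- generate_tile(spec, k, j)
      x[, , , i] <- tl$pixels
      if (with_masks) masks[, , i] <- tl$mask
      y[i] <- k; nb[i] <- tl$n_blobs
    }
  }
  pid <- NULL
  if (!is.null(spec$n_patients)) {
    per_class <- max(1L, spec$n_patients %/% spec$n_classes)
    j_within <- rep(seq_len(spec$tiles_per_class), spec$n_classes)
    pid <- sprintf("P%03d", (y - 1L) * per_class +
                     (j_within - 1L) %% per_class + 1L)
  }
  list(x = x, y = y, masks = masks, patient_id = pid, n_blobs = nb)
}

#' Write a fixture dataset to disk
#'
#' Writes tile PNGs, per-tile mask PNGs and a CSV manifest consumable by the
#' data pipeline. Regenerating with the same spec yields identical files.
#'
#' @param spec a [fixture_spec()].
#' @param dir output directory (created if needed).
#' @return the manifest data.frame (invisibly written to
#'   `file.path(dir, "manifest.csv")`).
#' @export
generate_dataset <- function(spec, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- list()
  per_class_pat <- if (!is.null(spec$n_patients))
    max(1L, spec$n_patients %/% spec$n_classes) else NA_integer_
  for (k in seq_len(spec$n_classes)) {
    for (j in seq_len(spec$tiles_per_class)) {
      tl <- generate_tile(spec, k, j)
      img <- sprintf("tile_c%d_i%03d.png", k, j)
      msk <- sprintf("mask_c%d_i%03d.png", k, j)
      save_image(tl$pixels, file.path(dir, img))
      save_image(tl$mask, file.path(dir, msk))
      pid <- if (!is.na(per_class_pat))
        sprintf("P%03d", (k - 1L) * per_class_pat +
                  (j - 1L) %% per_class_pat + 1L) else NA_character_
      rows[[length(rows) + 1L]] <- data.frame(
        image_path = img, mask_path = msk, label = k, patient_id = pid,
        magnification = NA_character_,
        source_image_id = sprintf("c%d_i%03d", k, j),
        patch_row = 0L, patch_col = 0L, split = NA_character_)
    }
  }
  manifest <- do.call(rbind, rows)
  write_manifest(manifest, file.path(dir, "manifest.csv"))
  manifest
}

#' Synthetic patient cohort manifest
#'
#' A pixel-free records table emulating a multi-patient, class-imbalanced
#' cohort (default marginals: 82 patients over 8 subtypes with patient counts
#' 4/10/3/7/38/5/9/6 and image counts 444/1014/453/569/3451/626/792/560,
#' each image carrying one of four magnification tags). Used to exercise
#' patient-grouped k-fold planning and its leakage audit.
#'
#' @param patients_per_class integer vector of patients per class.
#' @param images_per_class integer vector of images per class.
#' @param seed seed for distributing images over patients.
#' @return data.frame with `source_image_id`, `label`, `patient_id`,
#'   `magnification`.
#' @export
synthetic_cohort_manifest <- function(
    patients_per_class = c(4L, 10L, 3L, 7L, 38L, 5L, 9L, 6L),
    images_per_class = c(444L, 1014L, 453L, 569L, 3451L, 626L, 792L, 560L),
    seed = 0L) {
  stopifnot(length(patients_per_class) == length(images_per_class))
  mags <- c("40x", "100x", "200x", "400x")
  with_seed(seed, {
    rows <- list()
    pat0 <- 0L
    for (k in seq_along(patients_per_class)) {
      npat <- patients_per_class[k]
      nimg <- images_per_class[k]
      # distribute images over the class's patients with seeded jitter
      w <- runif(npat, 0.5, 1.5)
      counts <- pmax(1L, round(nimg * w / sum(w)))
      counts[1] <- counts[1] + nimg - sum(counts)
      pid <- rep(sprintf("P%03d", pat0 + seq_len(npat)), counts)
      rows[[k]] <- data.frame(
        source_image_id = sprintf("c%d_img%04d", k, seq_len(nimg)),
        label = k, patient_id = pid,
        magnification = rep_len(mags, nimg))
      pat0 <- pat0 + npat
    }
    do.call(rbind, rows)
  })
}
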