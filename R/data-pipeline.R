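# Patch extraction, stratified image-level splitting, patient-grouped
# stratified k-fold planning with leakage audits, augmentation policies and
# CSV manifest IO.
#
# Coordinates are 0-based (row, col) = (y, x) pixel offsets with half-open
# patch intervals: a patch at origin (r, c) covers rows r..r+size-1.

## ---- patch extraction -------------------------------------------------------

#' Non-overlapping grid patching
#'
#' Cuts `cols x rows` non-overlapping square patches from the top-left corner
#' of an image, origins at multiples of the patch size, listed in row-major
#' order (left-to-right, top-to-bottom).
#'
#' @param image `(H, W, C)` array, or `c(H, W)` dimensions when only the
#'   bookkeeping is needed.
#' @param patch_size patch side length in pixels.
#' @param grid integer `c(cols, rows)`.
#' @param source_image_id id recorded for each patch.
#' @return data.frame with `source_image_id`, `patch_row`, `patch_col`
#'   (0-based origins) and `patch_size`.
#' @export
grid_patch <- function(image, patch_size, grid,
                       source_image_id = "image") {
  d <- if (is.array(image) || is.matrix(image)) dim(image) else image
  cols <- grid[1]; rows <- grid[2]
  if (cols * patch_size > d[2] || rows * patch_size > d[1]) {
    stop("grid ", cols, "x", rows, " of ", patch_size, "px patches exceeds ",
         d[2], "x", d[1], " image; max feasible grid is ",
         d[2] %/% patch_size, "x", d[1] %/% patch_size)
  }
  origins <- expand.grid(patch_col = (seq_len(cols) - 1L) * patch_size,
                         patch_row = (seq_len(rows) - 1L) * patch_size)
  data.frame(source_image_id = source_image_id,
             patch_row = origins$patch_row, patch_col = origins$patch_col,
             patch_size = patch_size)
}

#' Overlapping sliding-window patching
#'
#' Origins at every `(i * stride, j * stride)` that keeps the patch fully
#' inside the image; per axis `floor((dim - patch) / stride) + 1` positions,
#' no partial patches.
#'
#' @inheritParams grid_patch
#' @param stride window stride in pixels.
#' @return data.frame as in [grid_patch()].
#' @export
sliding_window_patch <- function(image, patch_size, stride,
                                 source_image_id = "image") {
  d <- if (is.array(image) || is.matrix(image)) dim(image) else image
  if (patch_size > d[1] || patch_size > d[2])
    stop("image ", d[2], "x", d[1], " is smaller than the ", patch_size,
         "px patch")
  n_r <- (d[1] - patch_size) %/% stride + 1L
  n_c <- (d[2] - patch_size) %/% stride + 1L
  origins <- expand.grid(patch_col = (seq_len(n_c) - 1L) * stride,
                         patch_row = (seq_len(n_r) - 1L) * stride)
  data.frame(source_image_id = source_image_id,
             patch_row = origins$patch_row, patch_col = origins$patch_col,
             patch_size = patch_size)
}

#' Crop one patch
#'
#' @param image `(H, W, C)` array or matrix.
#' @param patch_row,patch_col 0-based origin.
#' @param patch_size side length.
#' @return the cropped patch.
#' @export
extract_patch <- function(image, patch_row, patch_col, patch_size) {
  rows <- (patch_row + 1L):(patch_row + patch_size)
  cols <- (patch_col + 1L):(patch_col + patch_size)
  d <- dim(image)
  if (patch_row + patch_size > d[1] || patch_col + patch_size > d[2])
    stop("patch exceeds image bounds")
  if (length(d) == 2L) image[rows, cols, drop = FALSE]
  else image[rows, cols, , drop = FALSE]
}

## ---- splitting --------------------------------------------------------------

#' Stratified image-level train/val/test split
#'
#' Splits at the source-image level so all patches of one image land in one
#' subset. Within each class, the validation and test counts are the floors
#' of `fraction * class size` and the remainder goes to train; assignment is
#' a seeded permutation, so the same seed reproduces the same split.
#'
#' @param records data.frame with at least `source_image_id` and `label`.
#' @param fractions numeric `c(train, val, test)` summing to 1.
#' @param seed integer seed.
#' @param stratify split within each class (default) or over the pool.
#' @return `records` with a `split` factor column (`train`/`val`/`test`).
#' @export
image_level_split <- function(records, fractions = c(0.7, 0.1, 0.2),
                              seed = 0L, stratify = TRUE) {
  if (abs(sum(fractions) - 1) > 1e-9) stop("fractions must sum to 1")
  imgs <- unique(records[, c("source_image_id", "label")])
  if (anyDuplicated(imgs$source_image_id))
    stop("a source image appears with more than one label")
  strata <- if (stratify) split(imgs, imgs$label) else list(all = imgs)
  n_buckets <- sum(fractions > 0)
  assign <- with_seed(seed, {
    lapply(strata, function(s) {
      n <- nrow(s)
      if (n < n_buckets)
        stop("class '", s$label[1], "' has ", n, " images but the split has ",
             n_buckets, " non-empty buckets")
      n_val <- floor(fractions[2] * n)
      n_test <- floor(fractions[3] * n)
      ord <- sample.int(n)
      lab <- rep("train", n)
      lab[ord[seq_len(n_val)]] <- "val"
      if (n_test > 0) lab[ord[n_val + seq_len(n_test)]] <- "test"
      data.frame(source_image_id = s$source_image_id, split = lab)
    })
  })
  map <- do.call(rbind, assign)
  records$split <- factor(map$split[match(records$source_image_id,
                                          map$source_image_id)],
                          levels = c("train", "val", "test"))
  records
}

# Greedy stratified allocation of groups (rows of `hist`, a group x class
# count matrix) to `length(weights)` bins with target shares `weights`.
# Groups are placed largest-first (seeded shuffle breaks ties); each goes to
# the bin where the resulting weighted class counts deviate least from the
# global class distribution, preferring under-filled bins.
stratified_group_assign <- function(hist, weights, seed = 0L) {
  n_bin <- length(weights)
  totals <- colSums(hist)
  sizes <- rowSums(hist)
  ord <- with_seed(seed, order(-sizes, sample.int(nrow(hist))))
  bin_counts <- matrix(0, n_bin, ncol(hist))
  bin_of <- integer(nrow(hist))
  for (g in ord) {
    best <- NA_integer_; best_cost <- Inf
    for (b in seq_len(n_bin)) {
      trial <- bin_counts
      trial[b, ] <- trial[b, ] + hist[g, ]
      # deviation of each bin's class counts from its target share
      cost <- sum((sweep(trial, 2, totals * 1, `/`) - weights)^2) +
        0.01 * (sum(trial[b, ]) / (weights[b] * sum(totals)))
      if (cost < best_cost) { best_cost <- cost; best <- b }
    }
    bin_counts[best, ] <- bin_counts[best, ] + hist[g, ]
    bin_of[g] <- best
  }
  bin_of
}

#' Patient-grouped stratified k-fold plan
#'
#' Two-stage plan: patients are first allocated to `k` folds (stratified by
#' label, every patient wholly in one fold); then, for each fold used as the
#' test set, the remaining patients are split into train and validation
#' subsets, again stratified and patient-grouped.
#'
#' @param records data.frame with `patient_id` and `label` (one row per item).
#' @param k number of folds.
#' @param seed integer seed.
#' @param val_fraction share of the non-test portion assigned to validation.
#' @return a `fold_plan` list: `k`, `patient_fold` (named integer), `roles`
#'   (per fold, named character train/val over non-test patients),
#'   `seed`.
#' @export
patient_grouped_kfold <- function(records, k, seed = 0L, val_fraction = 0.2) {
  if (is.null(records$patient_id) || any(is.na(records$patient_id)))
    stop("every record needs a patient_id; for cohorts without patient ids ",
         "use image_level_split()")
  pats <- unique(records$patient_id)
  if (k > length(pats)) stop("k = ", k, " exceeds ", length(pats), " patients")
  hist <- as.matrix(table(records$patient_id, records$label))
  hist <- hist[match(pats, rownames(hist)), , drop = FALSE]
  fold_of <- stratified_group_assign(hist, rep(1 / k, k), seed = seed)
  names(fold_of) <- pats
  roles <- vector("list", k)
  for (f in seq_len(k)) {
    rest <- pats[fold_of != f]
    h <- hist[match(rest, pats), , drop = FALSE]
    r <- stratified_group_assign(h, c(1 - val_fraction, val_fraction),
                                 seed = seed + f)
    roles[[f]] <- setNames(c("train", "val")[r], rest)
  }
  structure(list(k = k, patient_fold = fold_of, roles = roles, seed = seed),
            class = "fold_plan")
}

#' Materialize one fold of a plan
#'
#' @param plan a [patient_grouped_kfold()] plan.
#' @param records the records the plan was built from.
#' @param fold fold index in `1..k` to use as the test set.
#' @return `records` with a `split` column (`train`/`val`/`test`).
#' @export
fold_records <- function(plan, records, fold) {
  role <- plan$roles[[fold]]
  split <- ifelse(plan$patient_fold[records$patient_id] == fold, "test",
                  role[records$patient_id])
  records$split <- factor(unname(split), levels = c("train", "val", "test"))
  records
}

#' Audit a fold plan for patient leakage and stratification
#'
#' @param plan a [patient_grouped_kfold()] plan.
#' @param records the records the plan was built from.
#' @return list with `shared_patients` (`k x k` matrix of patients shared
#'   between fold pairs; the invariant is all zeros off-diagonal),
#'   `max_shared`, `fold_class_proportions`, `global_proportions`, and
#'   `max_proportion_deviation`.
#' @export
audit_fold_plan <- function(plan, records) {
  k <- plan$k
  shared <- matrix(0L, k, k)
  pats_by_fold <- lapply(seq_len(k), function(f)
    names(plan$patient_fold)[plan$patient_fold == f])
  for (i in seq_len(k)) for (j in seq_len(k)) if (i != j)
    shared[i, j] <- length(intersect(pats_by_fold[[i]], pats_by_fold[[j]]))
  fold_of_rec <- plan$patient_fold[records$patient_id]
  tab <- table(fold_of_rec, records$label)
  props <- prop.table(tab, 1)
  global <- prop.table(table(records$label))
  dev <- max(abs(sweep(props, 2, as.numeric(global))))
  list(shared_patients = shared, max_shared = max(shared),
       fold_class_proportions = props, global_proportions = global,
       max_proportion_deviation = dev)
}

## ---- augmentation -----------------------------------------------------------

#' Stochastic tile augmentation
#'
#' Training-time augmentation following one of two policies. `"bach"`:
#' random horizontal/vertical flips, rotations by multiples of 90 degrees,
#' brightness and contrast jitter (+-20%), Gaussian blur (sigma drawn from
#' 0.1-1.0). `"breakhis"`: random horizontal/vertical flips and
#' small-angle rotations within +-10 degrees (bilinear, reflection padding).
#' Each transform fires independently with probability 0.5; results are
#' deterministic given the RNG state.
#'
#' @param tile `(H, W, C)` array in `[0, 1]`.
#' @param policy `"bach"` or `"breakhis"`.
#' @return augmented tile, same shape.
#' @export
augment <- function(tile, policy = c("bach", "breakhis", "geometric")) {
  apply_augment(tile, augment_params(policy))
}

# Sample the stochastic transform parameters of one augmentation draw
# (separated from application so the sampling distribution is auditable).
augment_params <- function(policy = c("bach", "breakhis", "geometric")) {
  policy <- match.arg(policy)
  p <- list(policy = policy,
            flip_h = runif(1) < 0.5,
            flip_v = runif(1) < 0.5)
  if (policy == "geometric") {
    p$rot90 <- if (runif(1) < 0.5) sample(1:3, 1) else 0L
  } else if (policy == "bach") {
    p$rot90 <- if (runif(1) < 0.5) sample(1:3, 1) else 0L
    if (runif(1) < 0.5) {
      p$contrast <- runif(1, 0.8, 1.2)
      p$brightness <- runif(1, -0.2, 0.2)
    }
    if (runif(1) < 0.5) p$blur_sigma <- runif(1, 0.1, 1.0)
  } else {
    p$angle <- if (runif(1) < 0.5) runif(1, -10, 10) else 0
  }
  p
}

apply_augment <- function(tile, p) {
  if (p$flip_h) tile <- tile[, rev(seq_len(dim(tile)[2])), , drop = FALSE]
  if (p$flip_v) tile <- tile[rev(seq_len(dim(tile)[1])), , , drop = FALSE]
  if (p$policy == "geometric") {
    if (p$rot90 > 0) tile <- rotate90(tile, p$rot90)
  } else if (p$policy == "bach") {
    if (p$rot90 > 0) tile <- rotate90(tile, p$rot90)
    if (!is.null(p$contrast))
      tile <- pmin(pmax((tile - 0.5) * p$contrast + 0.5 + p$brightness, 0), 1)
    if (!is.null(p$blur_sigma)) tile <- gaussian_blur(tile, p$blur_sigma)
  } else if (!identical(p$angle, 0)) {
    tile <- rotate_bilinear(tile, p$angle)
  }
  tile
}

## ---- manifests --------------------------------------------------------------

manifest_columns <- c("image_path", "label", "patient_id", "magnification",
                      "source_image_id", "patch_row", "patch_col", "split")

#' Read/write tile manifests
#'
#' CSV manifests with columns `image_path`, `label`, `patient_id`,
#' `magnification`, `source_image_id`, `patch_row`, `patch_col`, `split`
#' (missing optional columns are filled with `NA`).
#'
#' @param path CSV path.
#' @return data.frame manifest.
#' @export
read_manifest <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  for (col in manifest_columns) if (is.null(df[[col]])) df[[col]] <- NA
  df
}

#' @rdname read_manifest
#' @param manifest data.frame to write.
#' @export
write_manifest <- function(manifest, path) {
  write.csv(manifest, path, row.names = FALSE)
  invisible(path)
}
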