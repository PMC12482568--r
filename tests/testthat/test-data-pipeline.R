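# Patch bookkeeping, stratified splitting, patient-grouped k-fold planning
# with leakage audits, augmentation, and manifest IO.

test_that("grid patching produces the exact non-overlapping tiling", {
  # 2048 x 1536 slide, 4 x 3 grid of 512 px
  g <- grid_patch(c(1536, 2048), 512, c(4, 3))
  expect_equal(nrow(g), 12L)
  expect_equal(sort(unique(g$patch_col)), c(0, 512, 1024, 1536))
  expect_equal(sort(unique(g$patch_row)), c(0, 512, 1024))
  # row-major order: first row of the grid first
  expect_equal(g$patch_row[1:4], rep(0L, 4))
  expect_equal(g$patch_col[1:4], c(0L, 512L, 1024L, 1536L))
  expect_equal(nrow(grid_patch(c(512, 512), 512, c(1, 1))), 1L)
  g2 <- grid_patch(c(512, 1024), 512, c(2, 1))
  expect_equal(g2[, c("patch_row", "patch_col")],
               data.frame(patch_row = c(0L, 0L), patch_col = c(0L, 512L)))
  expect_error(grid_patch(c(512, 1024), 512, c(3, 1)), "max feasible grid")
})

test_that("sliding-window origins follow the floor((dim-patch)/stride)+1 rule", {
  s <- sliding_window_patch(c(460, 700), 224, 112)
  expect_equal(nrow(s), 15L)                  # 5 columns x 3 rows
  expect_equal(length(unique(s$patch_col)), 5L)
  expect_equal(length(unique(s$patch_row)), 3L)
  expect_true(all(s$patch_row + 224 <= 460 & s$patch_col + 224 <= 700))
  expect_equal(nrow(sliding_window_patch(c(224, 224), 224, 112)), 1L)
  expect_equal(nrow(sliding_window_patch(c(224, 336), 224, 112)), 2L)
  expect_error(sliding_window_patch(c(200, 300), 224, 112), "smaller")
})

test_that("grid patches reassemble the cropped source region pixel-exactly", {
  img <- with_seed2(10, array(runif(64 * 96 * 3), c(64, 96, 3)))
  g <- grid_patch(img, 32, c(3, 2))
  rebuilt <- array(NA_real_, c(64, 96, 3))
  for (i in seq_len(nrow(g))) {
    p <- extract_patch(img, g$patch_row[i], g$patch_col[i], 32)
    rebuilt[g$patch_row[i] + 1:32, g$patch_col[i] + 1:32, ] <- p
  }
  expect_identical(rebuilt, img)
})

test_that("stratified image-level split reproduces the 70/10/20 counts", {
  rec <- data.frame(source_image_id = sprintf("img%03d", 1:800),
                    label = rep(1:4, each = 200))
  sp <- image_level_split(rec, c(0.7, 0.1, 0.2), seed = 1)
  expect_equal(as.numeric(table(sp$split)), c(560, 80, 160))
  tab <- table(sp$label, sp$split)
  expect_true(all(tab[, "train"] == 140))
  expect_true(all(tab[, "val"] == 20))
  expect_true(all(tab[, "test"] == 40))
  # 10 one-class items -> 7/1/2 (floors to val/test, remainder to train)
  rec10 <- data.frame(source_image_id = letters[1:10], label = 1)
  expect_equal(as.numeric(table(image_level_split(rec10, seed = 2)$split)),
               c(7, 1, 2))
})

test_that("splits are deterministic in the seed and keep source images whole", {
  rec <- data.frame(source_image_id = rep(sprintf("img%02d", 1:40), each = 12),
                    label = rep(rep(1:2, each = 20), each = 12))
  a <- image_level_split(rec, seed = 5)
  b <- image_level_split(rec, seed = 5)
  expect_identical(a$split, b$split)
  c <- image_level_split(rec, seed = 6)
  expect_false(identical(a$split, c$split))
  expect_equal(as.numeric(table(c$split)), as.numeric(table(a$split)))
  # all 12 patches of each source image share one subset
  per_img <- tapply(as.character(a$split), a$source_image_id,
                    function(s) length(unique(s)))
  expect_true(all(per_img == 1L))
  # a class smaller than the bucket count is rejected
  tiny <- data.frame(source_image_id = c("a", "b", "x", "y", "z"),
                     label = c(9, 9, 1, 1, 1))
  expect_error(image_level_split(tiny, c(0.7, 0.1, 0.2), seed = 1),
               "buckets")
})

test_that("patient-grouped k-fold never splits a patient and stratifies labels", {
  # one patient per fold when k equals the patient count
  rec5 <- data.frame(patient_id = rep(paste0("P", 1:5), each = 3), label = 1)
  plan5 <- patient_grouped_kfold(rec5, k = 5, seed = 1)
  expect_equal(sort(as.integer(table(plan5$patient_fold))), rep(1L, 5))
  # 20 patients, 2 balanced classes: per-fold proportions near global
  rec <- data.frame(patient_id = rep(sprintf("Q%02d", 1:20), each = 10),
                    label = rep(rep(1:2, 10), each = 10))
  plan <- patient_grouped_kfold(rec, k = 5, seed = 3)
  audit <- audit_fold_plan(plan, rec)
  expect_equal(audit$max_shared, 0L)
  expect_lt(audit$max_proportion_deviation, 0.15)
  # two-stage split keeps patients whole and near the 80/20 sub-split
  fr <- fold_records(plan, rec, fold = 2)
  per_pat <- tapply(as.character(fr$split), fr$patient_id,
                    function(s) length(unique(s)))
  expect_true(all(per_pat == 1L))
  expect_true(all(c("train", "val", "test") %in% fr$split))
  expect_error(patient_grouped_kfold(data.frame(label = 1:3), k = 2),
               "image_level_split")
})

test_that("augmentation transforms are bounded, involutive and reproducible", {
  tile <- with_seed2(12, array(runif(32 * 32 * 3), c(32, 32, 3)))
  # horizontal flip applied twice is the identity
  flip_h <- function(t) t[, rev(seq_len(dim(t)[2])), , drop = FALSE]
  expect_identical(flip_h(flip_h(tile)), tile)
  # small-angle policy stays within +-10 degrees
  angles <- with_seed2(13, replicate(200, {
    p <- histofuse:::augment_params("breakhis")
    p$angle
  }))
  expect_true(all(abs(angles) <= 10))
  expect_gt(max(abs(angles)), 1)             # rotations actually fire
  # fixed RNG state reproduces the augmented pixels exactly
  a1 <- with_seed2(14, augment(tile, "bach"))
  a2 <- with_seed2(14, augment(tile, "bach"))
  expect_identical(a1, a2)
  expect_equal(dim(a1), dim(tile))
  expect_error(histofuse:::augment_params("nope"))
})

test_that("manifests round-trip through CSV with the canonical columns", {
  m <- data.frame(image_path = c("a.png", "b.png"), label = 1:2,
                  patient_id = c("P1", NA), magnification = c("40x", NA),
                  source_image_id = c("s1", "s2"), patch_row = c(0L, 512L),
                  patch_col = c(0L, 0L), split = c("train", NA))
  f <- tempfile(fileext = ".csv")
  write_manifest(m, f)
  back <- read_manifest(f)
  expect_equal(back$image_path, m$image_path)
  expect_equal(back$patch_row, m$patch_row)
  expect_equal(back$patient_id, m$patient_id)
  unlink(f)
})
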