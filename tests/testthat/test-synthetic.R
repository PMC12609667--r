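# Synthetic fiber generator, annotation pipeline and dataset protocol.

test_that("generation is a pure function of the configuration", {
  cfg <- synthetic_config(image_size = c(64L, 64L), seed = 42L)
  s1 <- generate_sample(cfg)
  s2 <- generate_sample(cfg)
  expect_identical(s1$image, s2$image)
  expect_identical(s1$mask, s2$mask)
  s3 <- generate_sample(synthetic_config(image_size = c(64L, 64L), seed = 43L))
  expect_false(identical(s1$image, s3$image))
  # generation does not disturb the caller's RNG stream
  set.seed(1); r1 <- rnorm(1)
  set.seed(1); invisible(generate_sample(cfg)); r2 <- rnorm(1)
  expect_identical(r1, r2)
})

test_that("an empty scene is pure background", {
  s <- generate_sample(synthetic_config(image_size = c(32L, 32L),
                                        n_wires = 0L, noise_sd = 0,
                                        illumination_gradient = 0, seed = 1L))
  expect_true(all(s$mask == 0L))
  expect_true(all(s$image == 170))
})

test_that("configuration contracts are enforced", {
  expect_error(synthetic_config(wire_level = 200, background_level = 100),
               "darker")
  expect_error(generate_sample(synthetic_config(image_size = c(16L, 16L),
                                                wire_width_px = c(20, 24))),
               "exceeds")
})

test_that("foreground fraction sits in the analytic band", {
  # n wires of width w and mean length ~ 0.85 * max(H, W) cover about
  # n * w * len / (H * W) of the frame; allow +/- 50% for curvature, overlap
  # and boundary clipping, averaged over seeds
  fracs <- vapply(1:20, function(s) {
    smp <- generate_sample(synthetic_config(
      image_size = c(256L, 256L), n_wires = c(3L, 3L),
      wire_width_px = c(4, 6), seed = s))
    mean(smp$mask)
  }, numeric(1))
  expected <- 3 * 5 * (0.85 * 256) / (256 * 256)
  expect_gt(mean(fracs), expected * 0.5)
  expect_lt(mean(fracs), expected * 1.5)
  expect_true(all(fracs > 0 & fracs < 0.5))
})

test_that("thresholds act literally on the HSV channels", {
  # uniformly bright: V = 200 >= 90 everywhere -> empty mask
  bright <- matrix(200, 16, 16)
  expect_true(all(annotate_mask(bright) == 0L))
  # uniformly dark: V = 50 < 90, S = 0 < 40 -> all foreground, and the
  # morphology leaves a uniform mask unchanged
  dark <- matrix(50, 16, 16)
  expect_true(all(annotate_mask(dark) == 1L))
  # V just below / at the threshold
  expect_true(all(annotate_mask(matrix(89, 8, 8)) == 1L))
  expect_true(all(annotate_mask(matrix(90, 8, 8)) == 0L))
})

test_that("stripe fixture reproduces the hand-stepped morphology oracle", {
  # 2-px dark stripe anchored at the left edge plus one isolated dark pixel
  img <- matrix(200, 16, 16)
  img[, 1:2] <- 60
  img[8, 8] <- 60
  # the 3x3 median removes the isolated pixel before thresholding; to test
  # the morphology itself, step the oracle from the post-median threshold mask
  med <- matrix(0, 16, 16)
  for (i in 1:16) for (j in 1:16) {
    v <- as.vector(img[pmin(pmax(i + (-1:1), 1), 16),   # replicate-edge
                       pmin(pmax(j + (-1:1), 1), 16)])  # 3x3 neighbourhood
    med[i, j] <- sort(v)[5]
  }
  m0 <- matrix(as.integer(med < 90), 16, 16)
  expected <- oracle_opening(m0)
  expected <- oracle_closing(oracle_closing(expected))
  expected <- oracle_dilate(expected)
  got <- annotate_mask(img)
  expect_identical(got, expected)
  # the stripe survives and widens by one pixel; the isolated pixel is gone
  expect_true(all(got[, 1:3] == 1L))
  expect_true(all(got[, 5:16] == 0L))
  expect_equal(got[8, 8], 0L)
})

test_that("morphology matches the nested-loop oracle on random grids", {
  set.seed(99)
  for (rep in 1:100) {
    m <- matrix(sample(0:1, 64, TRUE, prob = c(0.6, 0.4)), 8, 8)
    expect_identical(unname(binary_opening(m)), oracle_opening(m))
    expect_identical(unname(binary_closing(m)), oracle_closing(m))
    expect_identical(unname(binary_dilate(m)), oracle_dilate(m))
    expect_identical(unname(binary_erode(m)), oracle_erode(m))
  }
})

test_that("annotation recovers generated masks under low noise", {
  ious <- vapply(1:20, function(s) {
    smp <- generate_sample(synthetic_config(
      image_size = c(128L, 128L), n_wires = c(3L, 5L),
      wire_width_px = c(4, 6), blur_sigma = 1.0, noise_sd = 5, seed = 100 + s))
    ann <- annotate_mask(smp$image)
    inter <- sum(ann == 1L & smp$mask == 1L)
    union <- sum(ann == 1L | smp$mask == 1L)
    if (union == 0) 1 else inter / union
  }, numeric(1))
  expect_true(all(ious >= 0.7))
})

test_that("splitting is leakage-free and cropping is a clean grid", {
  samples <- lapply(1:10, function(s)
    generate_sample(synthetic_config(image_size = c(64L, 64L), seed = s,
                                     n_wires = c(2L, 3L),
                                     wire_width_px = c(3, 4))))
  ds <- split_and_crop(samples, ratio = c(7, 2, 1), patch = 32L, seed = 5L)
  # 10 source images -> 7 / 2 / 1, each giving four 32x32 patches
  expect_length(ds$train, 28)
  expect_length(ds$val, 8)
  expect_length(ds$test, 4)
  # no source image contributes to two splits
  src_split <- unique(ds$manifest[c("source", "split")])
  expect_false(any(duplicated(src_split$source)))
  # a 1024-grid example in miniature: one 64x64 image, patch 32 -> 4 patches
  one <- split_and_crop(samples[1], ratio = c(1, 0, 0), patch = 32L)
  expect_length(one$train, 4)
  # patch exceeding the image is rejected
  expect_error(split_and_crop(samples, patch = 128L), "exceeds")
})

test_that("datasets round-trip through PNG + manifest bitwise", {
  dir <- file.path(tempdir(), "wbs_ds_test")
  unlink(dir, recursive = TRUE)
  samples <- lapply(1:5, function(s)
    generate_sample(synthetic_config(image_size = c(32L, 32L), seed = s,
                                     n_wires = c(1L, 2L),
                                     wire_width_px = c(3, 4))))
  ds <- split_and_crop(samples, patch = 32L, seed = 1L)
  write_dataset(ds, dir)
  back <- read_dataset(dir)
  for (split in c("train", "val", "test")) {
    expect_length(back[[split]], length(ds[[split]]))
    for (i in seq_along(ds[[split]])) {
      expect_identical(back[[split]][[i]]$image, ds[[split]][[i]]$image)
      expect_identical(back[[split]][[i]]$mask, ds[[split]][[i]]$mask)
    }
  }
  # manifest entries match the files on disk
  n_files <- length(list.files(dir, pattern = "^img_", recursive = TRUE))
  expect_equal(n_files, nrow(ds$manifest))
  # a corrupted mask fails integrity checking, naming the file
  msk <- list.files(dir, pattern = "^mask_", recursive = TRUE,
                    full.names = TRUE)[1]
  png::writePNG(matrix(0.37, 4, 4), msk)
  expect_error(read_dataset(dir), basename(msk))
  unlink(dir, recursive = TRUE)
})
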