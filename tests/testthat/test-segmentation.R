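test_that("TIFF stacks round-trip through read_stack", {
  td <- withr::local_tempdir()
  p <- file.path(td, "zeros.tif")
  st <- image_stack(array(0, c(10, 64, 64)), c(0.24, 0.05, 0.05))
  write_stack(st, p, bits = 8L)
  back <- read_stack(p, c(0.24, 0.05, 0.05))
  expect_identical(dim(back$voxels), c(10L, 64L, 64L))
  expect_true(all(back$voxels == 0))

  set.seed(1)
  st2 <- image_stack(array(sample(0:255, 5 * 16 * 16, TRUE), c(5, 16, 16)),
                     c(0.24, 0.05, 0.05))
  p2 <- file.path(td, "rand.tif")
  write_stack(st2, p2, bits = 8L)
  back2 <- read_stack(p2, c(0.24, 0.05, 0.05))
  expect_equal(back2$voxels, st2$voxels, ignore_attr = TRUE)
})

test_that("multi-channel TIFFs require a channel selector", {
  td <- withr::local_tempdir()
  p <- file.path(td, "rgb.tif")
  tiff::writeTIFF(array(runif(16 * 16 * 3), c(16, 16, 3)), p)
  expect_error(read_stack(p, c(1, 1, 1)), "channel")
  st <- read_stack(p, c(1, 1, 1), channel = 2L)
  expect_identical(dim(st$voxels), c(1L, 16L, 16L))
})

test_that("black-pixel repair follows the 8-neighbor rule", {
  sl <- array(10, c(1, 3, 3))
  sl[1, 2, 2] <- 0
  fixed <- fix_black_pixels(image_stack(sl, c(1, 1, 1)))
  expect_equal(fixed$voxels[1, 2, 2], 10)

  sl2 <- array(10, c(1, 3, 3))
  sl2[1, 2, 2] <- 0
  sl2[1, 1, 1] <- 0   # one neighbor is itself black
  fixed2 <- fix_black_pixels(image_stack(sl2, c(1, 1, 1)))
  expect_equal(fixed2$voxels[1, 2, 2], 0)
})

test_that("black-pixel repair matches the brute-force per-pixel rule", {
  set.seed(7)
  vox <- array(sample(c(0, 0, 1:20), 2 * 32 * 32, TRUE), c(2, 32, 32))
  fixed <- fix_black_pixels(image_stack(vox, c(1, 1, 1)))$voxels
  # brute force on the original values
  expected <- vox
  for (s in 1:2) for (i in 2:31) for (j in 2:31) {
    if (vox[s, i, j] != 0) next
    nb <- vox[s, (i - 1):(i + 1), (j - 1):(j + 1)][-5]
    if (all(nb > 0)) expected[s, i, j] <- mean(nb)
  }
  expect_equal(fixed, expected)
  # only zeros change, and the zero count never increases
  changed <- which(fixed != vox)
  expect_true(all(vox[changed] == 0))
  expect_lte(sum(fixed == 0), sum(vox == 0))
})

test_that("segmentation defaults match the study parameters", {
  cfg <- segmentation_config()
  expect_equal(cfg$mu_smooth, 1L)
  expect_equal(cfg$lambda1, 1)
  expect_equal(cfg$lambda2, 9)
  expect_equal(cfg$iterations, 100L)
  expect_identical(cfg$init, "otsu")
})

test_that("constant stacks yield an empty flagged mask, not an error", {
  st <- image_stack(array(0, c(4, 8, 8)), c(1, 1, 1))
  seg <- segment_acwe(st)
  expect_false(any(seg$mask))
  expect_match(seg$warning_flag, "constant")
})

test_that("a bright sphere is segmented accurately", {
  mask <- ball_mask(0.5, c(0.05, 0.05, 0.05), margin = 4)
  img <- array(0, dim(mask))
  img[mask] <- 200
  set.seed(2)
  img <- img + abs(rnorm(length(img), 0, 20))   # SNR 10 background noise
  st <- image_stack(img, c(0.05, 0.05, 0.05))
  seg <- segment_acwe(st, segmentation_config(iterations = 50L))
  expect_gte(dice_coefficient(seg$mask, mask), 0.90)
})

test_that("ACWE with Otsu init is invariant to affine intensity rescaling", {
  mask <- ball_mask(0.4, c(0.1, 0.1, 0.1), margin = 3)
  img <- array(0, dim(mask)); img[mask] <- 150
  set.seed(3)
  img <- img + abs(rnorm(length(img), 0, 15))
  st <- image_stack(img, c(0.1, 0.1, 0.1))
  st2 <- image_stack(3.7 * img + 42, c(0.1, 0.1, 0.1))
  cfg <- segmentation_config(iterations = 25L)
  expect_identical(segment_acwe(st, cfg)$mask, segment_acwe(st2, cfg)$mask)
})

test_that("isosurface extraction recovers ball geometry", {
  expect_error(mesh_from_volume(array(FALSE, c(4, 4, 4))), "empty mask")

  mask <- ball_mask(1, c(0.05, 0.05, 0.05), margin = 3)
  m <- mesh_from_volume(mask, spacing = c(0.05, 0.05, 0.05))
  expect_true(integrity(m)$is_watertight)
  expect_equal(feature_volume(m), 4 * pi / 3, tolerance = 0.05)

  # anisotropic spacing on a correspondingly squashed mask: physical box
  # within 5% of 2 um per axis
  mask2 <- ball_mask(1, c(0.24, 0.05, 0.05), margin = 3)
  m2 <- mesh_from_volume(mask2, spacing = c(0.24, 0.05, 0.05))
  box <- apply(m2$vertices, 2, function(v) diff(range(v)))
  expect_equal(unname(box), c(2, 2, 2), tolerance = 0.05)
})

test_that("foreground touching the boundary is padded with a warning", {
  mask <- array(TRUE, c(4, 4, 4))
  expect_warning(m <- mesh_from_volume(mask, c(0.1, 0.1, 0.1)), "padding")
  expect_true(integrity(m)$is_watertight)
})

test_that("isosurfaces of random blobs are watertight", {
  set.seed(11)
  for (rep in 1:3) {
    vol <- array(stats::rnorm(12^3), c(12, 12, 12))
    sm <- spinemorph:::gaussian_blur3(vol, c(2, 2, 2))
    mask <- sm > stats::quantile(sm, 0.8)
    m <- suppressWarnings(mesh_from_volume(mask, c(0.1, 0.1, 0.1)))
    expect_true(integrity(m)$is_watertight)
  }
})
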