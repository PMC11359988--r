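# Volume data model, NIfTI/CSV I/O and preprocessing.

test_that("NIfTI write/read round-trips voxels, spacing and origin exactly", {
  set.seed(11)
  v <- volume(array(rnorm(4 * 3 * 2), c(4, 3, 2)), spacing = c(1, 2, 3),
              origin = c(5, -4, 10))
  f <- tempfile(fileext = ".nii.gz")
  write_volume(v, f)
  v2 <- read_volume(f)
  expect_identical(dim(v2$voxels), dim(v$voxels))
  expect_equal(max(abs(v2$voxels - v$voxels)), 0)   # bit-exact (float64 storage)
  expect_equal(v2$spacing, v$spacing)
  expect_equal(v2$origin, v$origin)

  # phantom-style anisotropic spacing survives the header round trip
  p <- volume(array(0, c(8, 8, 4)), spacing = c(1, 1, 3))
  f2 <- tempfile(fileext = ".nii.gz")
  write_volume(p, f2)
  expect_equal(read_volume(f2)$spacing, c(1, 1, 3))
})

test_that("reading rejects missing files, 4D images and non-finite voxels", {
  expect_error(read_volume(tempfile()), "not found")
  f <- tempfile(fileext = ".nii")
  RNifti::writeNifti(RNifti::asNifti(array(0, c(3, 3, 3, 2))), f)
  expect_error(read_volume(f), "3 spatial axes")
  expect_error(volume(array(c(NA, rep(0, 7)), c(2, 2, 2))), "non-finite")
  expect_error(volume(array(0, c(2, 2)), c(1, 1, 1)), "3 spatial axes")
  expect_error(volume(array(0, c(2, 2, 2)), spacing = c(1, 0, 1)), "positive")
})

test_that("landmark CSV round trip preserves names, regions and coordinates", {
  lms <- landmarks(c("a", "b"), c("head", "neck"),
                   rbind(c(1.5, -2, 3), c(0, 10, 20)))
  f <- tempfile(fileext = ".csv")
  write_landmarks(lms, f)
  l2 <- read_landmarks(f)
  expect_equal(l2$name, lms$name)
  expect_equal(l2$region, lms$region)
  expect_equal(lm_xyz(l2), lm_xyz(lms), ignore_attr = TRUE)
  expect_error(landmarks("a", "torso", rbind(c(0, 0, 0))), "head")
})

test_that("resampling preserves identity, constants and linear ramps", {
  v <- volume(array(rnorm(16 * 12 * 8), c(16, 12, 8)), spacing = c(2, 2, 4))
  expect_identical(resample_volume(v, c(2, 2, 4))$voxels, v$voxels)

  cv <- volume(array(7, c(10, 10, 6)), spacing = c(2, 2, 2))
  r <- resample_volume(cv, c(1.3, 1.7, 0.9))
  expect_true(all(abs(r$voxels - 7) < 1e-12))

  # linear ramp along x: trilinear interpolation reproduces the analytic ramp
  sh <- c(17, 5, 5)
  px <- (seq_len(sh[1]) - 1) * 2
  ramp <- volume(array(rep(px, times = sh[2] * sh[3]), sh), spacing = c(2, 2, 2))
  r2 <- resample_volume(ramp, c(1, 2, 2))
  px2 <- (seq_len(dim(r2$voxels)[1]) - 1) * 1
  expect_lt(max(abs(r2$voxels - array(rep(px2, times = prod(dim(r2$voxels)[2:3])),
                                      dim(r2$voxels)))), 1e-6)
  # physical extent preserved within one voxel
  old_ext <- (sh - 1) * c(2, 2, 2)
  new_ext <- (dim(r2$voxels) - 1) * c(1, 2, 2)
  expect_true(all(abs(old_ext - new_ext) <= c(1, 2, 2)))
  expect_error(resample_volume(v, c(0, 1, 1)), "positive")
})

test_that("crop_or_pad hits the target shape, fills background and is inverse-consistent", {
  v <- volume(array(rnorm(10 * 10 * 10), c(10, 10, 10)), spacing = c(1, 1, 3))
  expect_identical(crop_or_pad(v, c(10, 10, 10))$voxels, v$voxels)

  padded <- crop_or_pad(v, c(16, 16, 16), fill = -1000)
  expect_equal(dim(padded$voxels), c(16, 16, 16))
  expect_equal(padded$voxels[1, 1, 1], -1000)
  expect_equal(padded$voxels[4:13, 4:13, 4:13], v$voxels)
  # physical coordinates of retained voxels unchanged: origin shifted back
  expect_equal(padded$origin, v$origin + c(-3, -3, -3) * v$spacing)

  big <- volume(array(rnorm(27e3), c(30, 30, 30)), spacing = c(1, 1, 1))
  cropped <- crop_or_pad(big, c(24, 24, 6))
  expect_equal(dim(cropped$voxels), c(24, 24, 6))
  back <- crop_or_pad(cropped, c(30, 30, 30), center = (dim(cropped$voxels) - 1) / 2)
  ctr <- crop_or_pad(back, c(24, 24, 6))
  expect_equal(ctr$voxels, cropped$voxels)

  s <- segmentation(array(sample(0:2, 8, TRUE), c(2, 2, 2)), c("a", "b"))
  expect_equal(dim(crop_or_pad(s, c(4, 4, 4))$labels), c(4, 4, 4))
})

test_that("intensity normalization maps to [0,1] and guards constants", {
  v <- volume(array(seq(-1000, 1000, length.out = 64), c(4, 4, 4)))
  n <- normalize_intensity(v, "minmax")
  expect_equal(range(n$voxels), c(0, 1))
  w <- normalize_intensity(volume(array(300, c(2, 2, 2))), "window",
                           window = c(-200, 800))
  expect_equal(w$voxels[1, 1, 1], 0.5)
  expect_warning(cn <- normalize_intensity(volume(array(5, c(2, 2, 2))), "minmax"),
                 "constant")
  expect_true(all(cn$voxels == 0))
})

test_that("segmentation labels are validated and resampled nearest-neighbour", {
  expect_error(segmentation(array(3, c(2, 2, 2)), c("a", "b")), "0..2")
  s <- segmentation(array(sample(0:3, 12 * 12 * 6, TRUE), c(12, 12, 6)),
                    c("a", "b", "c"), spacing = c(2, 2, 2))
  r <- resample_segmentation(s, c(1.5, 1.5, 1.5))
  expect_true(all(unique(as.vector(r$labels)) %in% 0:3))
})
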