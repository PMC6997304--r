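test_that("volume constructors validate their input", {
  arr <- array(runif(27), c(3, 3, 3))
  v <- voxel_volume(arr, 6)
  expect_s3_class(v, "voxel_volume")
  expect_identical(dim(v), c(3L, 3L, 3L))
  expect_error(voxel_volume(arr[, , 1], 6), "3D")
  expect_error(voxel_volume(arr, -1), "positive")
  expect_error(voxel_volume(array(c(NA, runif(26)), c(3, 3, 3)), 6),
               "finite")
  expect_error(label_volume(array(-1L, c(2, 2, 2)), 6), "non-negative")
  m <- binary_mask(array(c(0, 1), c(2, 2, 2)), 6)
  expect_type(m$data, "logical")
})

test_that("voxels_to_mm3 converts pitch cubed", {
  expect_equal(voxels_to_mm3(1, 100), 1e-3)
  expect_equal(voxels_to_mm3(8, 50), 1e-3)
  expect_equal(voxels_to_mm3(0, 10), 0)
  expect_error(voxels_to_mm3(-1, 10), ">= 0")
  # a 1 mm^3 cube of 10 um voxels
  expect_equal(voxels_to_mm3(100^3, 10), 1)
})

test_that("mask and grayscale TIFF round-trips are lossless", {
  arr <- array(runif(4 * 5 * 3) > 0.5, c(4, 5, 3))
  m <- binary_mask(arr, 12)
  f <- tempfile(fileext = ".tif")
  write_stack(m, f)
  back <- read_mask(f, 12)
  expect_identical(back$data, arr)

  g <- voxel_volume(array(runif(60), c(4, 5, 3)), 12)
  f2 <- tempfile(fileext = ".tif")
  write_stack(g, f2)
  gb <- read_stack(f2, 12)
  expect_equal(gb$data, g$data, tolerance = 1e-6)
  unlink(c(f, f2))
})

test_that("label TIFF round-trips and overflow is an explicit error", {
  arr <- array(sample(0:7, 60, replace = TRUE), c(4, 5, 3))
  lv <- label_volume(arr, 12)
  f <- tempfile(fileext = ".tif")
  write_stack(lv, f)
  back <- read_labels(f, 12)
  expect_identical(back$data, lv$data)
  unlink(f)

  big <- label_volume(array(70000L, c(2, 2, 2)), 12)
  expect_error(write_stack(big, tempfile(fileext = ".tif")), "16-bit")
})

test_that("read_stack reads a slice directory in sorted order", {
  dirp <- tempfile()
  dir.create(dirp)
  arr <- array(runif(4 * 5 * 3), c(4, 5, 3))
  for (k in 1:3) {
    sl <- t(arr[, , k])
    tiff::writeTIFF(sl, file.path(dirp, sprintf("slice_%02d.tif", k)),
                    bits.per.sample = 32)
  }
  v <- read_stack(dirp, 6)
  expect_equal(dim(v$data), c(4L, 5L, 3L))
  expect_equal(v$data, arr, tolerance = 1e-6)
  unlink(dirp, recursive = TRUE)
})

test_that("mismatched slice shapes are rejected", {
  dirp <- tempfile()
  dir.create(dirp)
  tiff::writeTIFF(matrix(0.5, 4, 4), file.path(dirp, "a.tif"),
                  bits.per.sample = 32)
  tiff::writeTIFF(matrix(0.5, 5, 4), file.path(dirp, "b.tif"),
                  bits.per.sample = 32)
  expect_error(read_stack(dirp, 6), "mismatched")
  unlink(dirp, recursive = TRUE)
})
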