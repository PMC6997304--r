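# Low-level C++ kernels against brute-force oracles and analytic values.

test_that("squared EDT matches the exhaustive oracle", {
  set.seed(5)
  arr <- array(runif(11 * 9 * 8) > 0.6, c(11, 9, 8))
  got <- pelletscan:::.edt_sq_cpp(as.logical(arr), dim(arr))
  expect_equal(array(got, dim(arr)), oracle_edt_sq(arr))
})

test_that("EDT of a padded ball and slab hit analytic maxima", {
  ball <- make_ball(8)
  e <- pelletscan:::edt(pelletscan:::pad_array(ball, 1L))
  expect_equal(max(e), sqrt(65), tolerance = 1e-12)  # 8 inside + diag offset
  slab <- array(TRUE, c(9, 15, 15))
  es <- pelletscan:::edt(pelletscan:::pad_array(slab, 1L))
  expect_equal(max(es), 5)  # central plane of a 9-thick slab
})

test_that("connected component labelling distinguishes 6 and 26 connectivity", {
  arr <- array(FALSE, c(4, 4, 4))
  arr[1, 1, 1] <- TRUE
  arr[2, 2, 2] <- TRUE  # diagonal touch only
  l6 <- pelletscan:::label_array(arr, 6L)
  l26 <- pelletscan:::label_array(arr, 26L)
  expect_identical(attr(l6, "n_labels"), 2L)
  expect_identical(attr(l26, "n_labels"), 1L)
})

test_that("grayscale reconstruction: h-maxima flattens shallow peaks", {
  # two peaks (heights 10 and 3) on a flat background
  arr <- array(0, c(30, 7, 7))
  arr[8, 4, 4] <- 10
  arr[22, 4, 4] <- 3
  sm <- array(pelletscan:::.gaussian_blur_cpp(as.numeric(arr), dim(arr), 1.5),
              dim = dim(arr))
  h <- max(sm) * 0.5
  rec <- array(pelletscan:::.reconstruct_gray_cpp(as.numeric(sm) - h,
                                                  as.numeric(sm), dim(sm)),
               dim = dim(sm))
  resid <- sm - rec
  # the tall peak survives suppression as a strict maximum of rec...
  expect_gt(resid[8, 4, 4], 1e-3)
  expect_gt(rec[8, 4, 4], rec[14, 4, 4] + 1e-6)
  # ...while the shallow peak is flattened to the surrounding plateau
  expect_lt(abs(rec[22, 4, 4] - rec[21, 4, 4]), 1e-9)
  expect_lt(abs(rec[22, 4, 4] - rec[25, 4, 4]), 1e-9)
  # reconstruction never exceeds the mask image, residual never exceeds h
  expect_true(all(rec <= sm + 1e-12))
  expect_true(all(resid <= h + 1e-12))
})

test_that("watershed is deterministic and conserves the mask", {
  tb <- make_touching_balls(6)
  mask <- binary_mask(tb$mask, 6)
  dm <- distance_map(mask)
  mk <- generate_markers(dm, mask)
  expect_identical(max(mk$data), 2L)
  l1 <- watershed_split(mask, mk, dist = dm)
  l2 <- watershed_split(mask, mk, dist = dm)
  expect_identical(l1$data, l2$data)
  # assign_nearest policy: every mask voxel gets a label, background none
  expect_identical(l1$data > 0L, mask$data)
  expect_identical(max(l1$data), 2L)
})

test_that("local thickness of slab and ball", {
  slab <- array(TRUE, c(9, 21, 21))
  th <- local_thickness(binary_mask(slab, 1))
  # central plane carries the full slab thickness (approximately 9)
  expect_equal(max(th), 9, tolerance = 0.12)
  ball <- make_ball(8)
  thb <- local_thickness(binary_mask(ball, 1))
  expect_equal(max(thb), 16, tolerance = 0.15)
})

test_that("marching-cubes area of a smoothed ball is near analytic", {
  r <- 8
  a <- surface_area(binary_mask(make_ball(r), 1))
  expect_equal(a, 4 * pi * r^2, tolerance = 0.035)
  # scales with pitch squared
  a10 <- surface_area(binary_mask(make_ball(r), 10))
  expect_equal(a10, a * 100)
})

test_that("median filter removes isolated speckle exactly", {
  arr <- array(0, c(7, 7, 7))
  arr[4, 4, 4] <- 1
  f <- pelletscan:::.median_filter_cpp(as.numeric(arr), dim(arr), 1L)
  expect_equal(max(f), 0)
})

test_that("trilinear interpolation reproduces a linear field", {
  d <- c(6L, 6L, 6L)
  vol <- array(0, d)
  for (k in 1:6) for (j in 1:6) for (i in 1:6)
    vol[i, j, k] <- 2 * (i - 1) + 3 * (j - 1) - (k - 1)
  pts <- rbind(c(1.25, 2.5, 3.75), c(0, 0, 0), c(4.9, 4.9, 4.9))
  got <- pelletscan:::.trilinear_cpp(as.numeric(vol), d, pts)
  expect_equal(got, 2 * pts[, 1] + 3 * pts[, 2] - pts[, 3])
})
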