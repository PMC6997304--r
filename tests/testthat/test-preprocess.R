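test_that("automatic threshold matches the exhaustive-scan oracle", {
  set.seed(42)
  v <- c(rnorm(4000, 0.2, 0.03), rnorm(4000, 0.8, 0.03))
  vol <- voxel_volume(array(v, c(20, 20, 20)), 6)
  thr <- threshold_histogram(vol)
  expect_gt(thr, 0.35)
  expect_lt(thr, 0.65)
  expect_equal(thr, oracle_otsu(v), tolerance = 0.02)
})

test_that("thresholding a constant volume is an error", {
  vol <- voxel_volume(array(0.5, c(5, 5, 5)), 6)
  expect_error(threshold_histogram(vol), "constant")
})

test_that("binarize separates a noisy two-phase volume", {
  set.seed(7)
  truth <- make_ball(6)
  noisy <- array(0.2 + 0.6 * truth + rnorm(length(truth), 0, 0.05),
                 dim = dim(truth))
  vol <- voxel_volume(noisy, 6)
  m <- binarize(vol, preprocess_params())
  expect_gt(mean(m$data == truth), 0.99)
  expect_true(is.numeric(m$threshold))
})

test_that("median smoothing preserves edges better than its input noise", {
  set.seed(11)
  truth <- make_ball(6)
  noisy <- array(0.2 + 0.6 * truth + rnorm(length(truth), 0, 0.1),
                 dim = dim(truth))
  vol <- voxel_volume(noisy, 6)
  sm <- smooth_edge_preserving(vol, 1)
  clean <- 0.2 + 0.6 * truth
  expect_lt(mean((sm$data - clean)^2), mean((vol$data - clean)^2) / 2)
  # strength 0 is the identity
  expect_identical(smooth_edge_preserving(vol, 0)$data, vol$data)
})

test_that("clean_binary removes speckles, keeps the object, and is idempotent", {
  set.seed(3)
  arr <- make_ball(7, dims = c(41, 25, 25), center = c(13, 13, 13))
  # fifty 1-voxel speckles away from the ball
  bg <- which(!arr & seq_along(arr) %% 7 == 0)
  arr[sample(bg, 50)] <- TRUE
  m <- binary_mask(arr, 6)
  pp <- preprocess_params(min_object_voxels = 50)
  cl <- clean_binary(m, pp)
  lab <- pelletscan:::label_array(cl$data, pp$connectivity)
  expect_identical(attr(lab, "n_labels"), 1L)
  expect_identical(clean_binary(cl, pp)$data, cl$data)
})

test_that("clean_binary fills small enclosed holes", {
  arr <- make_ball(8)
  center <- (dim(arr) + 1) / 2
  arr[center[1], center[2], center[3]] <- FALSE  # 1-voxel internal hole
  cl <- clean_binary(binary_mask(arr, 6), preprocess_params())
  expect_true(cl$data[center[1], center[2], center[3]])
})

test_that("degrade is deterministic per seed and leaves RNG state alone", {
  vol <- voxel_volume(array(runif(8000), c(20, 20, 20)), 6)
  set.seed(123)
  before <- .Random.seed
  d1 <- degrade(vol, blur_sigma_um = 6, noise_sd = 0.05, seed = 9)
  expect_identical(.Random.seed, before)
  d2 <- degrade(vol, blur_sigma_um = 6, noise_sd = 0.05, seed = 9)
  expect_identical(d1$data, d2$data)
  d3 <- degrade(vol, blur_sigma_um = 6, noise_sd = 0.05, seed = 10)
  expect_false(identical(d1$data, d3$data))
})

test_that("binarized phantom sphere volume is within 2% of analytic", {
  r <- 10
  truth <- make_ball(r)
  vol <- voxel_volume(0.2 + 0.6 * truth, 6)
  m <- binarize(vol, preprocess_params(smooth_strength = 0))
  expect_equal(sum(m$data), 4 / 3 * pi * r^3, tolerance = 0.02)
})
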