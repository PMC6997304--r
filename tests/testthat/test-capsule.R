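test_that("partition_from_counts reproduces the conservation identities", {
  p <- partition_from_counts(n_cs_roi = 1000, n_cs = 100, n_cp_roi = 500,
                             n_cp = 420, voxel_size_um = 1000)
  # 1000 um pitch: 1 voxel = 1 mm^3, so counts equal volumes
  expect_equal(p$V_CS_InV, 900)
  expect_equal(p$V_CS_Poros, 400)
  expect_equal(p$V_CP_Poros, 80)
  expect_equal(p$V_CS_ROI, p$V_CS + p$V_CS_InV)
  expect_equal(p$V_CS_InV, p$V_CS_Poros + p$V_CP_ROI)
  expect_equal(p$V_CP_ROI, p$V_CP + p$V_CP_Poros)
  expect_equal(p$filled_volume_pct, 100 * 500 / 900)
})

test_that("containment violations raise a consistency error", {
  expect_error(partition_from_counts(100, 150, 10, 5, 10), "containment")
  expect_error(partition_from_counts(100, 10, 95, 5, 10), "containment")
  expect_error(partition_from_counts(100, 10, 50, 60, 10), "containment")
})

test_that("fill_height_ratio arithmetic", {
  expect_equal(fill_height_ratio(16.09, 16.78), 95.89, tolerance = 1e-4)
  expect_error(fill_height_ratio(1, 0), "positive")
})

test_that("population_roi fills a porous ball to its envelope", {
  arr <- make_ball(9)
  porous <- arr
  cen <- (dim(arr) + 1) / 2
  # carve a 2-voxel-radius pore off-center
  pore <- make_ball(2, dim(arr), cen + c(3, 0, 0))
  porous <- porous & !pore
  roi <- population_roi(binary_mask(porous, 6))
  expect_identical(roi$data | arr, roi$data)  # superset of the envelope
  expect_equal(sum(roi$data), sum(arr), tolerance = 0.02)
})

test_that("population_roi keeps well-separated balls disjoint", {
  dims <- c(50L, 21L, 21L)
  two <- make_ball(6, dims, c(11, 11, 11)) | make_ball(6, dims, c(39, 11, 11))
  roi <- population_roi(binary_mask(two, 6), closing_radius_um = 2 * 6)
  lab <- pelletscan:::label_array(roi$data, 26L)
  expect_identical(attr(lab, "n_labels"), 2L)
})

test_that("feret_3d of a ball matches its diameter", {
  fer <- feret_3d(binary_mask(make_ball(8), 10))
  expect_equal(fer$max_um, 170, tolerance = 0.03)  # (2r + 1) voxels * 10 um
  # off-axis calipers of a digital ball run up to ~1 voxel short
  expect_equal(fer$min_um, 170, tolerance = 0.07)
  expect_lte(fer$min_um, fer$max_um)
})

test_that("axial profile conserves per-slice areas and finds the fill height", {
  # synthetic: shell tube along z, pellets fill the lower 60%
  dims <- c(30L, 30L, 50L)
  shell <- array(FALSE, dims)
  rho <- outer((1:30 - 15.5)^2, (1:30 - 15.5)^2, "+")
  for (k in 3:48) shell[, , k] <- rho <= 14^2 & rho > 12^2
  shell[, , 2] <- rho <= 14^2
  shell[, , 49] <- rho <= 14^2
  inner <- array(FALSE, dims)
  for (k in 3:48) inner[, , k] <- rho <= 12^2
  pel <- array(FALSE, dims)
  for (k in 3:29) pel[, , k] <- rho <= 11^2
  u <- 100
  prof <- axial_profile(binary_mask(shell, u), binary_mask(pel, u),
                        binary_mask(pel, u))
  df <- prof$data
  expect_true(all(abs(df$area_CP_mm2 + df$area_CP_Poros_mm2 +
                        df$area_CS_Poros_mm2 - df$area_InV_mm2) < 1e-9))
  expect_equal(prof$fill_height_ratio_pct,
               100 * 27 / 46, tolerance = 0.05)
})

test_that("split_capsule_phases separates shell from pellets", {
  dims <- c(40L, 40L, 60L)
  rho <- outer((1:40 - 20.5)^2, (1:40 - 20.5)^2, "+")
  arr <- array(FALSE, dims)
  for (k in 5:55) arr[, , k] <- rho <= 18^2 & rho > 16^2
  arr <- arr | make_ball(5, dims, c(20, 20, 20)) |
    make_ball(5, dims, c(20, 20, 35))
  ph <- split_capsule_phases(binary_mask(arr, 10))
  expect_equal(sum(ph$shell$data) + sum(ph$pellets$data), sum(arr))
  lab <- pelletscan:::label_array(ph$pellets$data, 26L)
  expect_identical(attr(lab, "n_labels"), 2L)
  # a single-component mask errors
  expect_error(split_capsule_phases(binary_mask(make_ball(5), 10)),
               "separate components")
})
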