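# a small, quick-to-rasterize capsule used by most phantom tests
small_spec <- function(n_pellets = 12L, ...) {
  phantom_spec(voxel_size_um = 20, capsule_inner_diameter_um = 1600,
               capsule_length_um = 3200, wall_thickness_um = 100,
               n_pellets = n_pellets, pellet_diameter_mean_um = 350,
               pellet_diameter_sd_um = 80,
               pellet_diameter_range_um = c(240, 500),
               pore_diameter_range_um = c(60, 120),
               broken_fraction = 0.25, ...)
}

test_that("phantoms are a pure function of (spec, seed) and restore the RNG", {
  sp <- small_spec()
  set.seed(999)
  before <- .Random.seed
  p1 <- generate_capsule(sp, seed = 5L)
  expect_identical(.Random.seed, before)  # global RNG untouched
  p2 <- generate_capsule(sp, seed = 5L)
  expect_identical(p1$volume$data, p2$volume$data)
  expect_identical(p1$labels$data, p2$labels$data)
  expect_identical(p1$truth, p2$truth)
  p3 <- generate_capsule(sp, seed = 6L)
  expect_false(identical(p1$truth$center_x_vox, p3$truth$center_x_vox))
})

test_that("truth table is consistent with the label volume", {
  ph <- generate_capsule(small_spec(), seed = 5L, degraded = FALSE)
  expect_identical(ph$n_placed, 12L)
  expect_identical(ph$n_broken, 3L)  # round(0.25 * 12)
  expect_identical(sum(ph$truth$broken), 3L)
  counts <- tabulate(ph$labels$data[ph$labels$data > 0L], max(ph$truth$id))
  expect_identical(counts[ph$truth$id], ph$truth$solid_voxels)
  expect_identical(sum(ph$truth$solid_voxels), ph$solid_voxels_total)
  expect_gte(min(ph$truth$envelope_voxels - ph$truth$solid_voxels), 0L)
  # shell and pellets occupy disjoint voxels
  expect_false(any(ph$shell$data & ph$labels$data > 0L))
  # undegraded volume carries exactly the three phase intensities
  expect_setequal(unique(as.numeric(ph$volume$data)),
                  unname(ph$spec$intensities))
})

test_that("undegraded intensities reproduce the truth counts exactly", {
  ph <- generate_capsule(small_spec(), seed = 8L, degraded = FALSE)
  ints <- ph$spec$intensities
  thr <- (ints[["shell"]] + ints[["pellet"]]) / 2
  expect_identical(sum(ph$volume$data > thr), ph$solid_voxels_total)
  expect_identical(sum(ph$volume$data == ints[["shell"]]),
                   sum(ph$shell$data))
})

test_that("equivalent-sphere diameters of intact pellets match the truth", {
  ph <- generate_capsule(small_spec(void_fraction = 0), seed = 5L,
                         degraded = FALSE)
  u <- ph$volume$voxel_size_um
  intact <- ph$truth[!ph$truth$broken, ]
  d_meas <- (6 * intact$solid_voxels * u^3 / pi)^(1 / 3)
  expect_lt(max(abs(d_meas - intact$diameter_um) / intact$diameter_um), 0.04)
})

test_that("an empty capsule is shell-only", {
  ph <- generate_capsule(small_spec(n_pellets = 0L), seed = 1L,
                         degraded = FALSE)
  expect_identical(nrow(ph$truth), 0L)
  expect_identical(max(ph$labels$data), 0L)
  expect_gt(sum(ph$shell$data), 0)
})

test_that("impossible packing stops with the achieved count", {
  sp <- phantom_spec(voxel_size_um = 20, capsule_inner_diameter_um = 800,
                     capsule_length_um = 2000, wall_thickness_um = 100,
                     n_pellets = 3L, pellet_diameter_mean_um = 700,
                     pellet_diameter_sd_um = 10,
                     pellet_diameter_range_um = c(650, 750))
  expect_error(generate_capsule(sp, seed = 1L), "packing failure: placed 0")
})

test_that("diameter sampling respects the truncation range", {
  set.seed(61)
  d <- pelletscan:::sample_diameters(500, 450, 120, c(300, 900))
  expect_gte(min(d), 300)
  expect_lte(max(d), 900)
  expect_equal(mean(d), 450, tolerance = 0.1)
  expect_error(pelletscan:::sample_diameters(10, 450, 10, c(5000, 6000)),
               "truncation range")
})

test_that("blur closes internal pores and inflates measured solidity", {
  ph <- generate_capsule(small_spec(void_fraction = 0.06), seed = 5L,
                         degraded = FALSE)
  u <- ph$volume$voxel_size_um
  # crop the pellet with the most pores
  i <- which.max(ph$truth$n_pores)
  expect_gt(ph$truth$n_pores[i], 0)
  cen <- round(c(ph$truth$center_x_vox[i], ph$truth$center_y_vox[i],
                 ph$truth$center_z_vox[i]))
  hw <- ceiling(ph$truth$diameter_um[i] / 2 / u) + 3
  ix <- (cen[1] - hw):(cen[1] + hw)
  iy <- (cen[2] - hw):(cen[2] + hw)
  iz <- (cen[3] - hw):(cen[3] + hw)
  crop <- voxel_volume(ph$volume$data[ix, iy, iz], u)
  sv_of <- function(sigma_um) {
    g <- degrade(crop, blur_sigma_um = sigma_um, noise_sd = 0, seed = 1)
    m <- binary_mask(g$data > 0.5, u)
    roi <- population_roi(m)
    sum(m$data) / sum(roi$data)
  }
  expect_gt(sv_of(1.5 * u), sv_of(0))
})
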