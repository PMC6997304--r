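test_that("distance_map sees background beyond the array border", {
  arr <- array(TRUE, c(9, 9, 9))
  dm <- distance_map(binary_mask(arr, 6))
  expect_equal(max(dm), 5)  # center of a 9-cube fully inside the frame
  expect_equal(dm[1, 1, 1], 1)
})

test_that("marker count is monotone non-increasing in marker_h", {
  set.seed(13)
  tb <- make_touching_balls(6)
  arr <- tb$mask
  mask <- binary_mask(arr, 6)
  dm <- distance_map(mask)
  counts <- vapply(c(0, 0.5, 1, 2, 4), function(h) {
    mk <- generate_markers(dm, mask, watershed_params(marker_h = h))
    max(mk$data)
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
  expect_identical(counts[3], 2)  # h = 1 resolves both balls
  expect_identical(counts[5], 1)  # h = 4 exceeds the saddle depth: merged
})

test_that("two touching balls split into two equal-ish regions", {
  tb <- make_touching_balls(7)
  mask <- binary_mask(tb$mask, 6)
  lab <- segment_pellets(mask)
  expect_identical(max(lab$data), 2L)
  sz <- tabulate(lab$data[lab$data > 0L], 2L)
  expect_lt(abs(sz[1] - sz[2]) / max(sz), 0.1)
  # label count equals marker count; mask conserved
  expect_identical(lab$data > 0L, mask$data)
})

test_that("watershed line policy 'exclude' zeroes one-voxel boundaries", {
  tb <- make_touching_balls(7)
  mask <- binary_mask(tb$mask, 6)
  wp <- watershed_params(line_policy = "exclude")
  dm <- distance_map(mask)
  mk <- generate_markers(dm, mask, wp)
  lab <- watershed_split(mask, mk, wp, dist = dm)
  expect_gt(sum(mask$data) - sum(lab$data > 0L), 0)
  # lines are thin: much smaller than either region
  expect_lt(sum(mask$data) - sum(lab$data > 0L), 0.05 * sum(mask$data))
})

test_that("markers outside the mask and empty markers are errors", {
  mask <- binary_mask(make_ball(5), 6)
  bad <- label_volume(array(0L, dim(mask$data)), 6)
  expect_error(watershed_split(mask, bad), "no markers")
  bad$data[1, 1, 1] <- 1L
  expect_error(watershed_split(mask, bad), "inside the mask")
})

test_that("empty mask yields a warning and zero markers", {
  mask <- binary_mask(array(FALSE, c(5, 5, 5)), 6)
  dm <- distance_map(mask)
  expect_warning(mk <- generate_markers(dm, mask), "empty")
  expect_identical(max(mk$data), 0L)
})

test_that("segment_pellets is robust to internal porosity", {
  # porous touching balls: pores would fracture the EDT without filling
  tb <- make_touching_balls(8)
  arr <- tb$mask
  for (cen in list(tb$centers[1, ], tb$centers[2, ])) {
    arr <- arr & !make_ball(2, dim(tb$mask), cen + c(2, 1, 0))
    arr <- arr & !make_ball(2, dim(tb$mask), cen - c(3, 2, 0))
  }
  mask <- binary_mask(arr, 6)
  lab <- segment_pellets(mask)
  expect_identical(max(lab$data), 2L)
  expect_identical(lab$data > 0L, mask$data)
})

test_that("extract_pellets records carry filled envelopes and centroids", {
  tb <- make_touching_balls(7)
  mask <- binary_mask(tb$mask, 6)
  lab <- segment_pellets(mask)
  recs <- extract_pellets(lab)
  expect_length(recs, 2L)
  for (r in recs) {
    expect_s3_class(r, "pellet_record")
    expect_gte(sum(r$mask_V_ROI$data), sum(r$mask_V$data))
  }
  # centroids near the generating centers (0-based, in um)
  cents <- t(vapply(recs, `[[`, numeric(3), "centroid_um")) / 6 + 1
  d1 <- min(sqrt(rowSums(sweep(cents, 2, tb$centers[1, ])^2)))
  expect_lt(d1, 1)
})
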