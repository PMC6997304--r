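test_that("sample_conditions builds a de-duplicated grid with a reference row", {
  g <- sample_conditions(blur_sigma_vox = c(0, 1, 1), threshold_offset = c(0, 0.05),
                         smooth_strength = 0)
  expect_identical(g$condition[1], 0L)
  expect_true(all(g[1, -1] == 0))
  expect_false(any(duplicated(g[, -1])))
  # 2 blur x 2 offset = 4 combinations, reference appears once
  expect_identical(nrow(g), 4L)
  expect_warning(g0 <- sample_conditions(blur_sigma_vox = numeric(0)), "empty")
  expect_identical(nrow(g0), 1L)
})

test_that("sensitivity screen: reference condition gives zero residuals", {
  set.seed(41)
  dims <- c(48L, 30L, 30L)
  arr <- array(0.15, dims)
  arr[make_ball(7, dims, c(13, 15, 15))] <- 0.85
  arr[make_ball(6, dims, c(34, 15, 15))] <- 0.85
  vol <- degrade(voxel_volume(arr, 10), blur_sigma_um = 5, noise_sd = 0.01,
                 seed = 3)
  mask <- binarize(vol)
  lab <- segment_pellets(mask)
  recs <- extract_pellets(lab)
  conds <- sample_conditions(blur_sigma_vox = c(0, 1), threshold_offset = 0,
                             smooth_strength = 0)
  rep <- run_sensitivity(vol, recs, conds)
  expect_s3_class(rep, "sensitivity_report")
  # reference condition (column 1) reproduces the reference features exactly
  ref_res <- rep$residuals[, 1, ]
  expect_true(all(ref_res[is.finite(ref_res)] < 1e-9))
  # residual array dimensions: features x conditions x pellets
  expect_identical(dim(rep$residuals),
                   c(nrow(feature_registry()), nrow(conds), length(recs)))
  # volume under 1-voxel blur moves, but the pellet is not lost
  expect_false(rep$lost[2, 1])
  expect_lt(rep$residuals["V_V_um3", 2, 1], 50)
})

test_that("robust_subset is monotone in the threshold", {
  set.seed(42)
  dims <- c(40L, 28L, 28L)
  arr <- array(0.15, dims)
  arr[make_ball(7, dims, c(20, 14, 14))] <- 0.85
  vol <- degrade(voxel_volume(arr, 10), blur_sigma_um = 5, noise_sd = 0.01,
                 seed = 5)
  mask <- binarize(vol)
  recs <- extract_pellets(segment_pellets(mask))
  conds <- sample_conditions(blur_sigma_vox = c(0, 2),
                             threshold_offset = c(0, 0.05),
                             smooth_strength = 0)
  rep <- run_sensitivity(vol, recs, conds)
  s5 <- robust_subset(rep, 5)
  s10 <- robust_subset(rep, 10)
  s50 <- robust_subset(rep, 50)
  expect_true(all(s5 %in% s10))
  expect_true(all(s10 %in% s50))
  # strictly-greater residuals excluded at exactly the threshold
  rmax <- rep$report$max_residual_pct
  expect_identical(sort(s10), sort(rep$report$feature[rmax <= 10]))
})

test_that("a lost pellet contributes 100% residuals", {
  set.seed(43)
  dims <- c(30L, 24L, 24L)
  arr <- array(0.15, dims)
  arr[make_ball(4, dims, c(15, 12, 12))] <- 0.60  # faint object
  vol <- voxel_volume(arr, 10)
  mask <- binary_mask(arr > 0.4, 10)
  recs <- extract_pellets(segment_pellets(mask))
  # a +40% threshold offset pushes the faint pellet below threshold
  conds <- data.frame(condition = 0:1, blur_sigma_vox = 0,
                      threshold_offset = c(0, 0.4),
                      smooth_strength = 0, noise_sd = 0)
  rep <- run_sensitivity(vol, recs, conds, ref_threshold = 0.4)
  expect_true(rep$lost[2, 1])
  expect_true(all(rep$residuals[, 2, 1] == 100))
})
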