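# ---------------------------------------------------------------------------
# Feature-robustness screen: re-measure a small pellet subset under a grid
# of image-quality and processing conditions and flag features whose
# residual relative to the reference condition exceeds a variability
# threshold.

#' Build the sensitivity sampling grid
#'
#' Cartesian product of the declared degradation and processing levels.
#' Condition 0 is always the reference (no degradation, reference
#' parameters). Duplicate level combinations are de-duplicated with stable
#' order. The default grid targets the noise-reduction and binarization
#' steps: blur sigma 0-3 voxels, threshold offset -5/0/+5% of the dynamic
#' range, smoothing strength 0/1/2.
#'
#' @param blur_sigma_vox Gaussian blur sigmas, in voxels.
#' @param threshold_offset Additive threshold offsets (fraction of the
#'   intensity range).
#' @param smooth_strength Median-filter strengths.
#' @param noise_sd Additive noise standard deviations.
#' @return A data.frame of conditions; row 1 is the reference.
#' @export
sample_conditions <- function(blur_sigma_vox = c(0, 1, 2, 3),
                              threshold_offset = c(-0.05, 0, 0.05),
                              smooth_strength = c(0, 1, 2),
                              noise_sd = 0) {
  if (!length(blur_sigma_vox) || !length(threshold_offset) ||
      !length(smooth_strength) || !length(noise_sd)) {
    warning("empty grid: reference condition only", call. = FALSE)
    blur_sigma_vox <- 0; threshold_offset <- 0
    smooth_strength <- 0; noise_sd <- 0
  }
  g <- expand.grid(blur_sigma_vox = blur_sigma_vox,
                   threshold_offset = threshold_offset,
                   smooth_strength = smooth_strength,
                   noise_sd = noise_sd,
                   KEEP.OUT.ATTRS = FALSE)
  g <- g[!duplicated(g), , drop = FALSE]
  ref <- data.frame(blur_sigma_vox = 0, threshold_offset = 0,
                    smooth_strength = 0, noise_sd = 0)
  g <- g[!(g$blur_sigma_vox == 0 & g$threshold_offset == 0 &
             g$smooth_strength == 0 & g$noise_sd == 0), , drop = FALSE]
  out <- rbind(ref, g)
  out$condition <- seq_len(nrow(out)) - 1L
  rownames(out) <- NULL
  out[, c("condition", "blur_sigma_vox", "threshold_offset",
          "smooth_strength", "noise_sd")]
}

# Re-measure one pellet under one condition. The pellet's padded bounding
# box is cut from the grayscale volume, degraded, re-binarized (reference
# threshold + offset), cleaned, and the component with maximum overlap with
# the reference solid mask becomes the new V.
remeasure_pellet <- function(vol, record, cond, ref_threshold,
                             params = preprocess_params(),
                             capsule_axis = c(0, 0, 1), seed = 1L) {
  bb <- record$bbox
  sub <- vol$data[bb[1]:bb[2], bb[3]:bb[4], bb[5]:bb[6], drop = FALSE]
  sv <- voxel_volume(sub, vol$voxel_size_um)
  sv <- degrade(sv, blur_sigma_um = cond$blur_sigma_vox * vol$voxel_size_um,
                noise_sd = cond$noise_sd, seed = seed)
  if (cond$smooth_strength > 0)
    sv <- smooth_edge_preserving(sv, cond$smooth_strength)
  thr <- ref_threshold + cond$threshold_offset
  m <- binary_mask(sv$data >= thr, vol$voxel_size_um)
  m <- clean_binary(m, params)
  lab <- label_array(m$data, params$connectivity)
  n <- attr(lab, "n_labels")
  if (n == 0L) return(NULL)
  refm <- record$mask_V$data
  ov <- vapply(seq_len(n), function(l) sum(lab == l & refm), numeric(1))
  best <- which.max(ov)
  if (ov[best] == 0) return(NULL)
  mv <- binary_mask(array(lab == best, dim = dim(lab)), vol$voxel_size_um)
  roi <- population_roi(mv, closing_radius_um = 2 * vol$voxel_size_um)
  rec <- list(mask_V = mv, mask_V_ROI = roi, label = record$label)
  feature_battery(rec, capsule_axis = capsule_axis)
}

#' Run the sensitivity screen
#'
#' Re-runs degradation, binarization, cleanup, re-segmentation (within each
#' pellet's bounding box) and the full feature battery for every condition
#' and pellet, then aggregates per-feature residuals relative to the
#' reference condition: `residual = |f_cond - f_ref| / |f_ref|`. Features
#' with a zero reference value use the absolute residual scaled by the
#' feature's inter-quartile range over the pellet subset (flagged). A
#' pellet lost under a condition contributes a 100% residual for all
#' features ("object lost").
#'
#' @param vol The grayscale [voxel_volume()] the pellets came from.
#' @param records Pellet subset (typically 5 per class) from
#'   [extract_pellets()] at the reference condition.
#' @param conditions Condition grid from [sample_conditions()].
#' @param params [preprocess_params()] used at reference.
#' @param ref_threshold Reference binarization threshold; recomputed from
#'   `vol` when NULL.
#' @param capsule_axis Capsule axis for orientation features.
#' @param seed Seed for the noise draws.
#' @return A `sensitivity_report`: data.frame with per-feature
#'   `max_residual_pct`, `mean_residual_pct`, `robust` flag (threshold 10%),
#'   `zero_reference` flag; plus the per-condition residual array in
#'   `residuals` (features x conditions x pellets).
#' @export
run_sensitivity <- function(vol, records, conditions = sample_conditions(),
                            params = preprocess_params(),
                            ref_threshold = NULL,
                            capsule_axis = c(0, 0, 1), seed = 1L) {
  stopifnot(inherits(vol, "voxel_volume"), length(records) >= 1)
  if (is.null(ref_threshold)) ref_threshold <- threshold_histogram(vol)
  reg <- feature_registry()
  nf <- nrow(reg)
  np <- length(records)
  nc <- nrow(conditions)

  ref_feats <- vapply(records, function(r)
    feature_battery(r, capsule_axis = capsule_axis), numeric(nf))
  # per-feature IQR over the subset (scale for zero-reference residuals)
  iqr <- apply(ref_feats, 1, function(v)
    diff(quantile(v, c(0.25, 0.75), na.rm = TRUE)))

  res <- array(NA_real_, dim = c(nf, nc, np),
               dimnames = list(reg$name, NULL, NULL))
  lost <- matrix(FALSE, nc, np)
  for (ci in seq_len(nc)) {
    cond <- conditions[ci, ]
    for (pi in seq_len(np)) {
      f <- remeasure_pellet(vol, records[[pi]], cond, ref_threshold, params,
                            capsule_axis, seed = seed + 1000L * ci + pi)
      fr <- ref_feats[, pi]
      if (is.null(f)) {
        res[, ci, pi] <- 100
        lost[ci, pi] <- TRUE
        next
      }
      zero_ref <- !is.na(fr) & fr == 0
      r <- abs(f - fr) / abs(fr) * 100
      r[zero_ref] <- ifelse(iqr[zero_ref] > 0,
                            abs(f[zero_ref]) / iqr[zero_ref] * 100,
                            ifelse(f[zero_ref] == 0, 0, 100))
      res[, ci, pi] <- r
    }
  }
  max_res <- apply(res, 1, max, na.rm = TRUE)
  mean_res <- apply(res, 1, mean, na.rm = TRUE)
  report <- data.frame(
    feature = reg$name, category = reg$category, source = reg$source,
    max_residual_pct = max_res, mean_residual_pct = mean_res,
    robust = max_res <= 10,
    zero_reference = apply(ref_feats, 1, function(v)
      any(!is.na(v) & v == 0)))
  structure(list(report = report, residuals = res, lost = lost,
                 conditions = conditions, threshold_pct = 10),
            class = "sensitivity_report")
}

#' @export
print.sensitivity_report <- function(x, ...) {
  cat(sprintf("<sensitivity_report> %d features, %d conditions, %d pellets\n",
              nrow(x$report), nrow(x$conditions), dim(x$residuals)[3]))
  cat(sprintf("  robust (max residual <= %g%%): %d; fragile: %d\n",
              x$threshold_pct, sum(x$report$robust),
              sum(!x$report$robust)))
  invisible(x)
}

#' Robust feature subset
#'
#' Names of the features whose maximum residual does not exceed the
#' variability threshold (strictly-greater residuals are excluded), in
#' registry order. Monotone in the threshold.
#'
#' @param report A `sensitivity_report`.
#' @param threshold_pct Variability threshold in percent.
#' @return Character vector of feature names.
#' @export
robust_subset <- function(report, threshold_pct = 10) {
  stopifnot(inherits(report, "sensitivity_report"))
  rep <- report$report
  rep$feature[rep$max_residual_pct <= threshold_pct]
}
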