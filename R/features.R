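# ---------------------------------------------------------------------------
# The per-pellet feature battery: fills all 206 registry features from the
# 3D masks and the three invariant cross-sections.

#' Algebraic least-squares ellipsoid fit
#'
#' Fits the general quadric `x'Qx + b'x = 1` to a point cloud by linear
#' least squares and extracts center and semi-axes. Falls back to the
#' moment-matched (covariance) ellipsoid when the fitted quadric is not an
#' ellipsoid, and reports which route produced the result.
#'
#' @param pts n x 3 matrix of surface points.
#' @param fallback_cov Covariance matrix for the moment-ellipsoid fallback
#'   (semi-axes `sqrt(5 * eigenvalues)`); required if the fit can fail.
#' @return List with `radii` (descending), `center`, `method`
#'   (`"fit"` or `"moments"`).
#' @export
fit_ellipsoid <- function(pts, fallback_cov = NULL) {
  stopifnot(is.matrix(pts), ncol(pts) == 3)
  ok <- FALSE
  if (nrow(pts) >= 9) {
    x <- pts[, 1]; y <- pts[, 2]; z <- pts[, 3]
    D <- cbind(x^2, y^2, z^2, x * y, x * z, y * z, x, y, z)
    theta <- tryCatch(qr.solve(D, rep(1, nrow(pts))),
                      error = function(e) NULL)
    if (!is.null(theta)) {
      Q <- matrix(c(theta[1], theta[4] / 2, theta[5] / 2,
                    theta[4] / 2, theta[2], theta[6] / 2,
                    theta[5] / 2, theta[6] / 2, theta[3]), 3, 3)
      b <- theta[7:9]
      eg <- eigen(Q, symmetric = TRUE)
      if (all(eg$values > 0)) {
        cen <- -solve(2 * Q, b)
        # recentering x = c + q turns the quadric into q'Qq = s
        s <- 1 - sum(b * cen) - as.numeric(t(cen) %*% Q %*% cen)
        if (s > 0) {
          radii <- sort(sqrt(s / eg$values), decreasing = TRUE)
          return(list(radii = radii, center = cen, method = "fit"))
        }
      }
    }
  }
  if (is.null(fallback_cov)) {
    cen <- colMeans(pts)
    fallback_cov <- stats::cov(pts) * (nrow(pts) - 1) / nrow(pts)
  } else {
    cen <- colMeans(pts)
  }
  ev <- sort(pmax(eigen(fallback_cov, symmetric = TRUE,
                        only.values = TRUE)$values, 0), decreasing = TRUE)
  list(radii = sqrt(5 * ev), center = cen, method = "moments")
}

#' Compute the full 206-feature battery for one pellet
#'
#' Fills every registry feature from the pellet's solid mask (`V`), filled
#' envelope (`V_ROI`) and the three invariant cross-sections. Individual
#' feature failures (degenerate sections, empty pore phase) are recorded as
#' `NA` with a reason, never silently zeroed.
#'
#' @param record A `pellet_record` (from [extract_pellets()]), or a list
#'   with `mask_V` and `mask_V_ROI`.
#' @param frame Optional precomputed `eigen_frame`.
#' @param sections Optional precomputed [iev_sections()].
#' @param capsule_axis Unit vector of the capsule axis for orientation
#'   angles.
#' @param micro_pore_um Local-thickness bound (micrometers) below which
#'   porosity counts as micro-porosity.
#' @return Named numeric vector of length 206 in registry order, with a
#'   `reasons` attribute naming failed features.
#' @export
feature_battery <- function(record, frame = NULL, sections = NULL,
                            capsule_axis = c(0, 0, 1), micro_pore_um = 25) {
  mask_V <- record$mask_V
  mask_R <- record$mask_V_ROI
  stopifnot(inherits(mask_V, "binary_mask"), inherits(mask_R, "binary_mask"))
  u <- mask_V$voxel_size_um
  reg <- feature_registry()
  vals <- setNames(rep(NA_real_, nrow(reg)), reg$name)
  reasons <- character(0)

  momR <- compute_moments(mask_R)
  if (is.null(frame)) frame <- orientation_frame(momR)
  if (is.null(sections)) sections <- iev_sections(mask_V, mask_R, frame)

  nV <- sum(mask_V$data); nR <- sum(mask_R$data)
  volV <- nV * u^3; volR <- nR * u^3
  fer <- feret_3d(mask_R)
  aR <- surface_area(mask_R)
  aV <- surface_area(mask_V)

  bpts <- .boundary_voxels_cpp(as.logical(mask_R$data), as_dim(mask_R$data))
  efit <- fit_ellipsoid(bpts * u, fallback_cov = momR$cov * u^2)
  r123 <- efit$radii

  d <- dim(mask_R$data)
  bbox_vol <- prod(apply(arrayInd(which(mask_R$data), d), 2,
                         function(v) diff(range(v)) + 1)) * u^3
  cen <- momR$centroid
  rad3 <- sqrt(rowSums((bpts - matrix(cen, nrow(bpts), 3, byrow = TRUE))^2)) + 0.5

  vals["V_V_um3"] <- volV
  vals["V_V_ROI_um3"] <- volR
  vals["d_eqSph_V"] <- (6 * volV / pi)^(1 / 3)
  vals["d_eqSph_V_ROI"] <- (6 * volR / pi)^(1 / 3)
  vals["F_max_3d_V_ROI"] <- fer$max_um
  vals["F_min_3d_V_ROI"] <- fer$min_um
  vals["F_mean_3d_V_ROI"] <- fer$mean_um
  vals["SF_Elps_SA_r1_V_ROI"] <- r123[1]
  vals["SF_Elps_SA_r2_V_ROI"] <- r123[2]
  vals["SF_Elps_SA_r3_V_ROI"] <- r123[3]

  vals["Psi_gl_V_ROI"] <- pi^(1 / 3) * (6 * volR)^(2 / 3) / aR
  vals["SF_maxFeretSph_F_V_ROI"] <- volR / (pi / 6 * fer$max_um^3)
  vals["SF_maxFeretSph_F_V"] <- volV / (pi / 6 * fer$max_um^3)
  vals["Elps_AR_r1r2"] <- r123[1] / r123[2]
  vals["Elps_AR_r1r3"] <- r123[1] / r123[3]
  vals["Elps_AR_r2r3"] <- r123[2] / r123[3]
  vals["Elps_fill_V_ROI"] <- volR / (4 / 3 * pi * prod(r123))
  vals["Extent3d_V_ROI"] <- volR / bbox_vol
  vals["Compact3d_V_ROI"] <- aR^1.5 / (6 * sqrt(pi) * volR)
  vals["FeretAR_3d_V_ROI"] <- fer$min_um / fer$max_um
  vals["SphFeret_V_ROI"] <- vals["d_eqSph_V_ROI"] / fer$max_um
  ev <- frame$values
  vals["EigenIso_V_ROI"] <- if (sum(ev) > 0)
    3 * prod(pmax(ev, 1e-12))^(1 / 3) / sum(ev) else NA_real_
  vals["rCV3d_V_ROI"] <- sd(rad3) / mean(rad3)
  vals["SphFeret_V"] <- vals["d_eqSph_V"] / fer$max_um

  vals["A_Sf_V_ROI"] <- aR
  vals["A_Sf_V"] <- aV
  vals["SSA_V_ROI"] <- aR / volR
  vals["SSA_V"] <- if (volV > 0) aV / volV else NA_real_
  vals["Sauter_d32_V_ROI"] <- 6 * volR / aR
  a_elps <- ellipsoid_surface_area(r123)
  vals["SurfRatio_Elps_V_ROI"] <- aR / a_elps

  # porosity
  pores <- mask_R$data & !mask_V$data
  vals["SV"] <- nV / nR
  vals["V_P_Poros_um3"] <- sum(pores) * u^3
  if (any(pores)) {
    plab <- label_array(pores, 26L)
    vals["N_Pores"] <- attr(plab, "n_labels")
    pth <- local_thickness(binary_mask(pores, u))
    pv <- pth[pores]
    vals["PoreTh_mean_um"] <- mean(pv)
    vals["PoreFrac_lt25um"] <- mean(pv < micro_pore_um)
  } else {
    vals["N_Pores"] <- 0
    vals["PoreTh_mean_um"] <- 0
    vals["PoreFrac_lt25um"] <- 0
    reasons["PoreTh_mean_um"] <- "no pore phase"
  }

  ax <- capsule_axis / sqrt(sum(capsule_axis^2))
  ang <- function(v) {
    c <- abs(sum(v * ax)) / sqrt(sum(v^2))
    acos(pmin(1, c)) * 180 / pi
  }
  vals["Ang_e1_axis_deg"] <- ang(frame$vectors[, 1])
  vals["Ang_e2_axis_deg"] <- ang(frame$vectors[, 2])
  vals["Ang_e3_axis_deg"] <- ang(frame$vectors[, 3])
  vals["Lambda1_um2"] <- ev[1] * u^2
  vals["Lambda2_um2"] <- ev[2] * u^2
  vals["Lambda3_um2"] <- ev[3] * u^2
  vals["EigRatio_l2l1"] <- if (ev[1] > 0) ev[2] / ev[1] else NA_real_
  vals["EigRatio_l3l1"] <- if (ev[1] > 0) ev[3] / ev[1] else NA_real_
  vals["Aniso3d"] <- if (ev[1] > 0) 1 - ev[3] / ev[1] else NA_real_

  for (k in 1:3) {
    sk <- paste0("IEV", k)
    sf <- section_features(sections$V[[sk]], sections$ROI[[sk]], u)
    if (is.null(sf)) {
      reasons[paste0("section_", sk)] <- "degenerate (empty) section"
      next
    }
    names(sf) <- paste0(names(sf), "_", sk)
    common <- intersect(names(sf), names(vals))
    vals[common] <- sf[common]
  }

  failed <- names(vals)[is.na(vals)]
  for (f in failed) if (!f %in% names(reasons)) reasons[f] <- "not computable"
  attr(vals, "reasons") <- reasons
  vals
}

# Knud Thomsen approximation (max error ~1.06%)
ellipsoid_surface_area <- function(r) {
  p <- 1.6075
  4 * pi * ((r[1]^p * r[2]^p + r[1]^p * r[3]^p + r[2]^p * r[3]^p) / 3)^(1 / p)
}

#' Build a feature table for a list of pellets
#'
#' Runs [feature_battery()] on every record and assembles the pellets x 206
#' feature table.
#'
#' @param records List of `pellet_record`s.
#' @param capsule_axis Capsule axis for orientation features.
#' @param capsule_id Optional capsule identifier column.
#' @param verbose Print progress?
#' @return A data.frame with columns `label`, `capsule`, then the 206
#'   registry features.
#' @export
feature_table <- function(records, capsule_axis = c(0, 0, 1),
                          capsule_id = "C0", verbose = FALSE) {
  reg <- feature_registry()
  rows <- lapply(seq_along(records), function(i) {
    if (verbose && i %% 25 == 0)
      message(sprintf("  features: pellet %d / %d", i, length(records)))
    feature_battery(records[[i]], capsule_axis = capsule_axis)
  })
  tab <- as.data.frame(do.call(rbind, rows))
  stopifnot(identical(names(tab), reg$name))
  cbind(data.frame(label = vapply(records, `[[`, integer(1), "label"),
                   capsule = capsule_id),
        tab)
}

#' Write a feature table to CSV
#'
#' @param tab Feature table from [feature_table()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(tab, path) {
  write.csv(tab, path, row.names = FALSE)
  invisible(path)
}
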