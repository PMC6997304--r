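# ---------------------------------------------------------------------------
# Image moments, the orientation eigenframe, and the translation- and
# rotation-invariant cross-sections (IEV1-IEV3) obtained by re-slicing a
# pellet normal to its moment eigenvectors.

#' Image moments of a binary mask (orders 0-2)
#'
#' Raw moments `M_pqr = sum x^p y^q z^r` over foreground voxel centers
#' (0-based coordinates) and central moments about the centroid. The zeroth
#' moment is the voxel volume; the first-order raw moments give the
#' centroid; the second-order central moments carry orientation.
#'
#' @param mask A non-empty [binary_mask()] (or logical array).
#' @return A `moment_set` list: `M` (named raw moments), `mu` (named central
#'   moments), `volume` (voxels), `centroid` (0-based voxel coordinates),
#'   `cov` (3x3 second-order central moment matrix divided by volume).
#' @export
compute_moments <- function(mask) {
  arr <- if (inherits(mask, "binary_mask")) mask$data else mask
  idx <- which(arr)
  if (!length(idx)) stop("empty mask has no moments", call. = FALSE)
  co <- arrayInd(idx, dim(arr)) - 1
  x <- co[, 1]; y <- co[, 2]; z <- co[, 3]
  n <- length(idx)
  M <- c(M000 = n,
         M100 = sum(x), M010 = sum(y), M001 = sum(z),
         M200 = sum(x^2), M020 = sum(y^2), M002 = sum(z^2),
         M110 = sum(x * y), M101 = sum(x * z), M011 = sum(y * z))
  cen <- c(M[["M100"]], M[["M010"]], M[["M001"]]) / n
  xc <- x - cen[1]; yc <- y - cen[2]; zc <- z - cen[3]
  mu <- c(mu000 = n, mu100 = 0, mu010 = 0, mu001 = 0,
          mu200 = sum(xc^2), mu020 = sum(yc^2), mu002 = sum(zc^2),
          mu110 = sum(xc * yc), mu101 = sum(xc * zc), mu011 = sum(yc * zc))
  covm <- matrix(c(mu[["mu200"]], mu[["mu110"]], mu[["mu101"]],
                   mu[["mu110"]], mu[["mu020"]], mu[["mu011"]],
                   mu[["mu101"]], mu[["mu011"]], mu[["mu002"]]),
                 3, 3) / n
  structure(list(M = M, mu = mu, volume = n, centroid = cen, cov = covm),
            class = "moment_set")
}

#' Orientation eigenframe from second-order moments
#'
#' Eigen-decomposition of the 3x3 covariance (second central moment /
#' volume) matrix. Eigenvalues are sorted descending; each eigenvector's
#' sign is fixed so its largest-magnitude component is positive (axis-order
#' tie-break), and the frame is made right-handed by flipping the third
#' vector if needed. A frame whose eigenvalues agree within 2% is flagged
#' isotropic (orientation is then not meaningful).
#'
#' @param moments A `moment_set` from [compute_moments()].
#' @return An `eigen_frame` list: `values` (descending), `vectors` (columns
#'   e1, e2, e3), `isotropic` flag.
#' @export
orientation_frame <- function(moments) {
  stopifnot(inherits(moments, "moment_set"))
  if (moments$volume <= 0) stop("zero-volume moment set", call. = FALSE)
  if (moments$volume == 1) {
    return(structure(list(values = c(0, 0, 0), vectors = diag(3),
                          isotropic = TRUE), class = "eigen_frame"))
  }
  eg <- eigen(moments$cov, symmetric = TRUE)
  ord <- order(eg$values, decreasing = TRUE)
  vals <- pmax(eg$values[ord], 0)
  vecs <- eg$vectors[, ord, drop = FALSE]
  for (j in 1:3) {
    k <- which.max(abs(vecs[, j]))
    if (vecs[k, j] < 0) vecs[, j] <- -vecs[, j]
  }
  if (det(vecs) < 0) vecs[, 3] <- -vecs[, 3]
  iso <- vals[1] > 0 && (vals[1] - vals[3]) / vals[1] < 0.02
  structure(list(values = vals, vectors = vecs, isotropic = iso),
            class = "eigen_frame")
}

# Sample one central cross-section of a mask: plane through `center` with
# in-plane axes u, v (unit, orthogonal), trilinear interpolation of the
# binary indicator thresholded at 0.5. Grid extent covers `half_extent`
# voxels in each in-plane direction at native pitch.
sample_section <- function(arr, center, u, v, half_extent) {
  n <- as.integer(ceiling(half_extent))
  g <- seq(-n, n)
  gu <- matrix(g, length(g), length(g))
  gv <- t(gu)
  pts <- cbind(center[1] + as.numeric(gu) * u[1] + as.numeric(gv) * v[1],
               center[2] + as.numeric(gu) * u[2] + as.numeric(gv) * v[2],
               center[3] + as.numeric(gu) * u[3] + as.numeric(gv) * v[3])
  vals <- .trilinear_cpp(as.numeric(arr), as.integer(dim(arr)), pts)
  matrix(vals >= 0.5, length(g), length(g))
}

#' Invariant cross-sections (IEV1-IEV3)
#'
#' Re-slices a pellet along the three planes through its `V_ROI` centroid
#' normal to the moment eigenvectors. Because centroid and eigenframe move
#' rigidly with the object, the sections are translation- and
#' rotation-invariant up to interpolation error. Sections are sampled at
#' native pitch; in-plane axes are the remaining two eigenvectors in
#' eigenvalue order. Section IEVk is normal to eigenvector `e_k`.
#'
#' @param mask_V Solid-phase [binary_mask()] of one pellet.
#' @param mask_V_ROI Filled-envelope [binary_mask()] of the same pellet.
#' @param frame An `eigen_frame` (computed from `V_ROI` when NULL).
#' @param extent_factor Section half-extent = `extent_factor` x bounding
#'   sphere radius of `V_ROI`.
#' @return An `iev_sections` list: `V` and `ROI`, each a list of three
#'   logical matrices (IEV1-IEV3); `pitch_um`; `frame`.
#' @export
iev_sections <- function(mask_V, mask_V_ROI, frame = NULL,
                         extent_factor = 1.2) {
  stopifnot(inherits(mask_V, "binary_mask"),
            inherits(mask_V_ROI, "binary_mask"))
  mom <- compute_moments(mask_V_ROI)
  if (is.null(frame)) frame <- orientation_frame(mom)
  cen <- mom$centroid
  idx <- which(mask_V_ROI$data)
  co <- arrayInd(idx, dim(mask_V_ROI$data)) - 1
  r_bound <- sqrt(max(rowSums((co - matrix(cen, nrow(co), 3,
                                           byrow = TRUE))^2))) + 1
  half <- extent_factor * r_bound
  vecs <- frame$vectors
  sec_of <- function(arr) {
    lapply(1:3, function(k) {
      inplane <- setdiff(1:3, k)
      sample_section(arr, cen, vecs[, inplane[1]], vecs[, inplane[2]], half)
    })
  }
  structure(list(V = setNames(sec_of(mask_V$data * 1.0),
                              c("IEV1", "IEV2", "IEV3")),
                 ROI = setNames(sec_of(mask_V_ROI$data * 1.0),
                                c("IEV1", "IEV2", "IEV3")),
                 pitch_um = mask_V$voxel_size_um,
                 frame = frame),
            class = "iev_sections")
}
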