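# ---------------------------------------------------------------------------
# 2D descriptors of the invariant cross-sections. Sections are logical
# pixel matrices at native pitch; areas use pixel counts, perimeters use
# the sub-pixel 0.5 contour of the indicator, convex hulls are taken over
# pixel corners (so hull area >= pixel area for convex shapes and
# hull-solidity stays <= ~1).

sec_pixel_coords <- function(mat) {
  idx <- which(mat)
  if (!length(idx)) return(NULL)
  arrayInd(idx, dim(mat))  # 1-based (row, col) = pixel centers
}

sec_corner_points <- function(mat) {
  co <- sec_pixel_coords(mat)
  if (is.null(co)) return(NULL)
  rbind(cbind(co[, 1] - 0.5, co[, 2] - 0.5),
        cbind(co[, 1] + 0.5, co[, 2] - 0.5),
        cbind(co[, 1] - 0.5, co[, 2] + 0.5),
        cbind(co[, 1] + 0.5, co[, 2] + 0.5))
}

polygon_area <- function(p) {
  x <- p[, 1]; y <- p[, 2]
  n <- nrow(p)
  abs(sum(x * y[c(2:n, 1)] - x[c(2:n, 1)] * y)) / 2
}

polygon_perimeter <- function(p) {
  d <- p[c(2:nrow(p), 1), ] - p
  sum(sqrt(rowSums(d^2)))
}

sec_hull <- function(mat) {
  pts <- sec_corner_points(mat)
  if (is.null(pts) || nrow(pts) < 3) return(NULL)
  h <- grDevices::chull(pts)
  hp <- pts[h, , drop = FALSE]
  if (nrow(hp) < 3) return(NULL)
  list(area = polygon_area(hp), perimeter = polygon_perimeter(hp))
}

# total contour length of the 0.5 level set (includes pore boundaries)
sec_perimeter <- function(mat) {
  m <- matrix(0, nrow(mat) + 2L, ncol(mat) + 2L)
  m[2:(nrow(mat) + 1L), 2:(ncol(mat) + 1L)] <- mat * 1.0
  cl <- grDevices::contourLines(x = seq_len(nrow(m)), y = seq_len(ncol(m)),
                                z = m, levels = 0.5)
  if (!length(cl)) return(0)
  sum(vapply(cl, function(cc) {
    dx <- diff(cc$x); dy <- diff(cc$y)
    sum(sqrt(dx^2 + dy^2))
  }, numeric(1)))
}

sec_feret <- function(mat, step_deg = 2) {
  pts <- sec_corner_points(mat)
  if (is.null(pts)) return(c(max = NA_real_, min = NA_real_, mean = NA_real_))
  ang <- seq(0, 180 - step_deg, by = step_deg) * pi / 180
  dirs <- cbind(cos(ang), sin(ang))
  pr <- pts %*% t(dirs)
  ext <- apply(pr, 2, function(v) max(v) - min(v))
  c(max = max(ext), min = min(ext), mean = mean(ext))
}

sec_moments2d <- function(mat) {
  co <- sec_pixel_coords(mat)
  if (is.null(co)) return(NULL)
  n <- nrow(co)
  cen <- colMeans(co)
  xc <- co[, 1] - cen[1]; yc <- co[, 2] - cen[2]
  mu20 <- sum(xc^2) / n; mu02 <- sum(yc^2) / n; mu11 <- sum(xc * yc) / n
  tr <- mu20 + mu02
  det2 <- mu20 * mu02 - mu11^2
  disc <- sqrt(max(0, tr^2 / 4 - det2))
  l1 <- tr / 2 + disc; l2 <- max(0, tr / 2 - disc)
  theta <- 0.5 * atan2(2 * mu11, mu20 - mu02)
  if (theta < 0) theta <- theta + pi
  list(n = n, centroid = cen, mu20 = mu20, mu02 = mu02, mu11 = mu11,
       l1 = l1, l2 = l2, theta = theta)
}

# Hu's seven invariant moments from normalized central moments
sec_hu <- function(mat) {
  co <- sec_pixel_coords(mat)
  if (is.null(co)) return(rep(NA_real_, 7))
  n <- nrow(co)
  cen <- colMeans(co)
  x <- co[, 1] - cen[1]; y <- co[, 2] - cen[2]
  m <- function(p, q) sum(x^p * y^q)
  eta <- function(p, q) m(p, q) / n^(1 + (p + q) / 2)
  n20 <- eta(2, 0); n02 <- eta(0, 2); n11 <- eta(1, 1)
  n30 <- eta(3, 0); n03 <- eta(0, 3); n21 <- eta(2, 1); n12 <- eta(1, 2)
  h1 <- n20 + n02
  h2 <- (n20 - n02)^2 + 4 * n11^2
  h3 <- (n30 - 3 * n12)^2 + (3 * n21 - n03)^2
  h4 <- (n30 + n12)^2 + (n21 + n03)^2
  h5 <- (n30 - 3 * n12) * (n30 + n12) *
    ((n30 + n12)^2 - 3 * (n21 + n03)^2) +
    (3 * n21 - n03) * (n21 + n03) *
    (3 * (n30 + n12)^2 - (n21 + n03)^2)
  h6 <- (n20 - n02) * ((n30 + n12)^2 - (n21 + n03)^2) +
    4 * n11 * (n30 + n12) * (n21 + n03)
  h7 <- (3 * n21 - n03) * (n30 + n12) *
    ((n30 + n12)^2 - 3 * (n21 + n03)^2) -
    (n30 - 3 * n12) * (n21 + n03) *
    (3 * (n30 + n12)^2 - (n21 + n03)^2)
  c(h1, h2, h3, h4, h5, h6, h7)
}

# radial signature: boundary-pixel distances to the section centroid
sec_radial <- function(mat) {
  co <- sec_pixel_coords(mat)
  if (is.null(co)) return(NULL)
  d <- dim(mat)
  bnd <- logical(nrow(co))
  m <- mat
  is_bg <- function(r, c) r < 1 | r > d[1] | c < 1 | c > d[2] |
    !m[cbind(pmin(pmax(r, 1), d[1]), pmin(pmax(c, 1), d[2]))]
  bnd <- is_bg(co[, 1] - 1, co[, 2]) | is_bg(co[, 1] + 1, co[, 2]) |
    is_bg(co[, 1], co[, 2] - 1) | is_bg(co[, 1], co[, 2] + 1)
  bp <- co[bnd, , drop = FALSE]
  if (!nrow(bp)) bp <- co
  cen <- colMeans(co)
  sqrt((bp[, 1] - cen[1])^2 + (bp[, 2] - cen[2])^2) + 0.5
}

# All 54 per-section features; `u` is the pixel pitch in micrometers.
section_features <- function(secV, secROI, u) {
  out <- numeric(0)
  nV <- sum(secV); nR <- sum(secROI)
  if (nR == 0L) return(NULL)   # degenerate section: caller records a reason
  aV <- nV * u^2; aR <- nR * u^2
  pV <- sec_perimeter(secV) * u
  pR <- sec_perimeter(secROI) * u
  fer <- sec_feret(secROI) * u
  ferV <- sec_feret(secV) * u
  hullR <- sec_hull(secROI)
  hullV <- sec_hull(secV)
  aCH <- if (!is.null(hullR)) hullR$area * u^2 else NA_real_
  pCH <- if (!is.null(hullR)) hullR$perimeter * u else NA_real_
  coR <- sec_pixel_coords(secROI)
  bb <- c(diff(range(coR[, 1])) + 1, diff(range(coR[, 2])) + 1) * u
  rad <- sec_radial(secROI) * u
  momR <- sec_moments2d(secROI)
  momV <- sec_moments2d(secV)
  safe_ratio <- function(a, b) if (is.na(b) || b == 0) NA_real_ else a / b

  size <- c(
    A_V = aV, A_V_ROI = aR,
    d_eqC_V = 2 * sqrt(aV / pi), d_eqC_V_ROI = 2 * sqrt(aR / pi),
    P_V = pV, P_V_ROI = pR,
    F_max_V_ROI = fer[["max"]], F_min_V_ROI = fer[["min"]],
    F_mean_V_ROI = fer[["mean"]],
    A_CH_V_ROI = aCH, P_CH_V_ROI = pCH,
    BBw_V_ROI = bb[1], BBh_V_ROI = bb[2],
    r_mean_V_ROI = mean(rad), r_max_V_ROI = max(rad),
    r_min_V_ROI = min(rad),
    d_eqC_CH_V_ROI = if (is.na(aCH)) NA_real_ else 2 * sqrt(aCH / pi))

  eccV <- if (!is.null(momV) && momV$l1 > 0)
    sqrt(1 - momV$l2 / momV$l1) else NA_real_
  eccR <- if (momR$l1 > 0) sqrt(1 - momR$l2 / momR$l1) else NA_real_
  shape <- c(
    Circ_V = if (pV > 0) 4 * pi * aV / pV^2 else NA_real_,
    Circ_V_ROI = if (pR > 0) 4 * pi * aR / pR^2 else NA_real_,
    AR_V_ROI = safe_ratio(fer[["max"]], fer[["min"]]),
    AR_V = safe_ratio(ferV[["max"]], ferV[["min"]]),
    Ecc_V_ROI = eccR, Ecc_V = eccV,
    Elong_V_ROI = if (momR$l1 > 0) 1 - momR$l2 / momR$l1 else NA_real_,
    Extent_V_ROI = aR / (bb[1] * bb[2]),
    Extent_V = aV / (bb[1] * bb[2]),
    Conv_V_ROI = safe_ratio(pCH, pR),
    setNames(sec_hu(secROI), paste0("Hu", 1:7, "_V_ROI")),
    setNames(sec_hu(secV), paste0("Hu", 1:7, "_V")),
    rCV_V_ROI = sd(rad) / mean(rad),
    rMinMax_V_ROI = min(rad) / max(rad),
    Circ_CH_V_ROI = if (!is.null(hullR))
      4 * pi * aCH / pCH^2 else NA_real_,
    Compact_V_ROI = if (aR > 0) pR^2 / aR else NA_real_,
    Compact_V = if (aV > 0) pV^2 / aV else NA_real_,
    Rnd_V_ROI = 4 * aR / (pi * fer[["max"]]^2))

  surface <- c(
    SV_CH_V_ROI = safe_ratio(aR, aCH),
    Rgh_V_ROI = safe_ratio(pR, pCH))

  porosity <- c(
    SV_CH_V = if (!is.null(hullV)) safe_ratio(aV, hullV$area * u^2)
    else NA_real_,
    SV_sec = safe_ratio(aV, aR),
    A_Poros = aR - aV)

  orient <- c(
    Theta_V_ROI = momR$theta,
    OrientAniso_V_ROI = if (momR$l1 + momR$l2 > 0)
      (momR$l1 - momR$l2) / (momR$l1 + momR$l2) else NA_real_)

  c(size, shape, surface, porosity, orient)
}
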