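# ---------------------------------------------------------------------------
# Global capsule analysis: ROI construction, voxel-exact volume partition,
# axial profiles and capsule measurements.

#' Build a filled region-of-interest around a solid mask
#'
#' Iterates morphological closing (Euclidean ball) followed by filling of
#' enclosed background components until a fixed point: the output is a
#' superset of the input whose background is a single border-connected
#' component. Applied to a porous pellet it returns the filled envelope
#' `V_ROI`; applied per population it yields `V_CP_ROI`.
#'
#' @param solid_mask A non-empty [binary_mask()].
#' @param closing_radius_um Closing ball radius in micrometers (>= 1 voxel).
#' @param max_iter Safety bound on the fixed-point loop.
#' @return A [binary_mask()] containing `solid_mask`.
#' @export
population_roi <- function(solid_mask, closing_radius_um = NULL,
                           max_iter = 10L) {
  stopifnot(inherits(solid_mask, "binary_mask"))
  if (!any(solid_mask$data)) stop("solid mask is empty", call. = FALSE)
  pitch <- solid_mask$voxel_size_um
  if (is.null(closing_radius_um)) closing_radius_um <- 2 * pitch
  r_vox <- closing_radius_um / pitch
  if (r_vox < 1) stop("closing radius must be at least 1 voxel", call. = FALSE)
  arr <- solid_mask$data
  for (i in seq_len(max_iter)) {
    nxt <- close_ball(arr, r_vox)
    nxt <- fill_enclosed_background(nxt)
    if (identical(nxt, arr)) break
    arr <- nxt
  }
  out <- solid_mask
  out$data <- arr | solid_mask$data
  out$name <- paste0(solid_mask$name, "_ROI")
  out
}

#' Split a capsule foreground mask into shell and pellet phases
#'
#' Separates the binarized capsule into the shell wall and the pellet
#' population by connected components: the shell is the component with the
#' largest bounding box (it encloses everything else); all other components
#' are pellets. Requires the shell to be disconnected from the pellet bed
#' (pellets resting against the wall merge the phases and raise an error).
#'
#' @param mask Cleaned foreground [binary_mask()] (shell + pellets).
#' @param connectivity Component connectivity (6 or 26).
#' @return List with `shell` and `pellets` ([binary_mask()]s).
#' @export
split_capsule_phases <- function(mask, connectivity = 26L) {
  stopifnot(inherits(mask, "binary_mask"))
  lab <- label_array(mask$data, connectivity)
  n <- attr(lab, "n_labels")
  if (n < 2)
    stop("expected the shell and at least one pellet as separate components",
         call. = FALSE)
  d <- dim(lab)
  co <- arrayInd(which(lab > 0L), d)
  lv <- lab[lab > 0L]
  bbvol <- vapply(seq_len(n), function(l) {
    p <- co[lv == l, , drop = FALSE]
    prod(apply(p, 2, function(v) diff(range(v)) + 1))
  }, numeric(1))
  shell_id <- which.max(bbvol)
  pitch <- mask$voxel_size_um
  list(shell = binary_mask(array(lab == shell_id, dim = d), pitch,
                           name = "shell"),
       pellets = binary_mask(array(lab > 0L & lab != shell_id, dim = d),
                             pitch, name = "pellets"))
}

#' Volume partition from voxel counts
#'
#' The voxel-arithmetic core of the capsule summary: given the voxel counts
#' of the filled shell envelope, the shell wall, the pellet-population ROI
#' and the pellet solid phase, derives the internal volume, the inter-pellet
#' void and the intra-pellet porosity. The three conservation identities
#' (`V_CS_ROI = V_CS + V_CS_InV`, `V_CS_InV = V_CS_Poros + V_CP_ROI`,
#' `V_CP_ROI = V_CP + V_CP_Poros`) hold voxel-exactly before unit
#' conversion.
#'
#' @param n_cs_roi,n_cs,n_cp_roi,n_cp Voxel counts of the filled shell
#'   envelope, shell wall, pellet ROI and pellet solid phase.
#' @param voxel_size_um Voxel pitch in micrometers.
#' @return A list of volumes in cubic millimeters (`V_CS_ROI`, `V_CS`,
#'   `V_CS_InV`, `V_CS_Poros`, `V_CP_ROI`, `V_CP`, `V_CP_Poros`), the raw
#'   voxel counts, and the filled-volume ratio `V_CP_ROI / V_CS_InV` (in
#'   percent).
#' @export
partition_from_counts <- function(n_cs_roi, n_cs, n_cp_roi, n_cp,
                                  voxel_size_um) {
  counts <- c(n_cs_roi = n_cs_roi, n_cs = n_cs, n_cp_roi = n_cp_roi,
              n_cp = n_cp)
  if (any(counts < 0)) stop("voxel counts must be >= 0", call. = FALSE)
  n_inv <- n_cs_roi - n_cs
  n_cs_poros <- n_inv - n_cp_roi
  n_cp_poros <- n_cp_roi - n_cp
  if (n_inv < 0 || n_cs_poros < 0 || n_cp_poros < 0)
    stop(sprintf(paste0("containment violated: V_CS_InV=%g, V_CS_Poros=%g, ",
                        "V_CP_Poros=%g voxels"),
                 n_inv, n_cs_poros, n_cp_poros), call. = FALSE)
  vols <- lapply(list(V_CS_ROI = n_cs_roi, V_CS = n_cs, V_CS_InV = n_inv,
                      V_CS_Poros = n_cs_poros, V_CP_ROI = n_cp_roi,
                      V_CP = n_cp, V_CP_Poros = n_cp_poros),
                 voxels_to_mm3, voxel_size_um = voxel_size_um)
  vols$filled_volume_pct <- if (n_inv > 0) 100 * n_cp_roi / n_inv else 0
  vols$voxel_counts <- c(counts, n_cs_inv = n_inv, n_cs_poros = n_cs_poros,
                         n_cp_poros = n_cp_poros)
  vols
}

#' Partition the capsule volume
#'
#' Splits the capsule into shell wall, inter-pellet void and intra-pellet
#' porosity by voxel arithmetic on the supplied masks. The filled shell
#' envelope (`V_CS_ROI`) is constructed with [population_roi()] on the
#' shell mask.
#'
#' @param shell_mask Shell-wall [binary_mask()].
#' @param pellet_solid_mask Pellet solid-phase [binary_mask()].
#' @param pellet_roi Pellet-population ROI [binary_mask()] (from
#'   [population_roi()] per pellet or population).
#' @param shell_roi Optional precomputed filled shell envelope.
#' @param closing_radius_um Closing radius for the shell envelope (defaults
#'   to 10 voxels; the envelope closing must bridge the capsule opening if
#'   any, it does not affect conservation).
#' @return A capsule partition list as in [partition_from_counts()].
#' @export
capsule_partition <- function(shell_mask, pellet_solid_mask, pellet_roi,
                              shell_roi = NULL, closing_radius_um = NULL) {
  stopifnot(inherits(shell_mask, "binary_mask"),
            inherits(pellet_solid_mask, "binary_mask"),
            inherits(pellet_roi, "binary_mask"))
  pitch <- shell_mask$voxel_size_um
  if (is.null(closing_radius_um)) closing_radius_um <- 10 * pitch
  if (is.null(shell_roi))
    shell_roi <- population_roi(shell_mask, closing_radius_um)
  n_solid_outside <- sum(pellet_solid_mask$data & !pellet_roi$data)
  if (n_solid_outside > 0)
    stop(sprintf("pellet solid mask has %d voxels outside the pellet ROI",
                 n_solid_outside), call. = FALSE)
  n_roi_outside <- sum(pellet_roi$data & !(shell_roi$data & !shell_mask$data))
  if (n_roi_outside > 0)
    stop(sprintf("pellet ROI has %d voxels outside the shell interior",
                 n_roi_outside), call. = FALSE)
  out <- partition_from_counts(sum(shell_roi$data), sum(shell_mask$data),
                               sum(pellet_roi$data),
                               sum(pellet_solid_mask$data), pitch)
  out$shell_roi <- shell_roi
  out
}

#' Axial cross-section profile of the capsule partition
#'
#' Projects the partition masks onto the capsule axis and reports per-slice
#' cross-section areas of the pellet solid phase, the intra-pellet porosity
#' and the inter-pellet void. Works for an arbitrary axis by binning voxel
#' centers on their axial coordinate (bin width = one voxel pitch), so the
#' per-slice identity `area_CP + area_CP_Poros + area_CS_Poros =
#' area(V_CS_InV)` holds by construction.
#'
#' @param shell_mask,pellet_solid_mask,pellet_roi,shell_roi Partition masks
#'   (see [capsule_partition()]).
#' @param axis Unit 3-vector of the capsule axis (default z).
#' @param noise_floor_frac Fraction of the median filled-slice `V_CP` area
#'   below which a slice does not count as filled.
#' @return A list with `data` (data.frame: `pos_mm`, `area_CP_mm2`,
#'   `area_CP_Poros_mm2`, `area_CS_Poros_mm2`, `area_InV_mm2`),
#'   `slice_pitch_mm`, `filled_height_mm`, `body_length_mm` and
#'   `fill_height_ratio_pct`.
#' @export
axial_profile <- function(shell_mask, pellet_solid_mask, pellet_roi,
                          shell_roi = NULL, axis = c(0, 0, 1),
                          noise_floor_frac = 0.01) {
  stopifnot(inherits(shell_mask, "binary_mask"))
  pitch <- shell_mask$voxel_size_um
  if (is.null(shell_roi)) shell_roi <- population_roi(shell_mask, 10 * pitch)
  axis <- axis / sqrt(sum(axis^2))
  inv <- shell_roi$data & !shell_mask$data
  cp <- pellet_solid_mask$data
  cp_poros <- pellet_roi$data & !cp
  cs_poros <- inv & !pellet_roi$data

  proj <- function(arr) {
    idx <- which(arr)
    if (!length(idx)) return(numeric(0))
    co <- arrayInd(idx, dim(arr)) - 1
    as.numeric(co %*% axis)
  }
  t_inv <- proj(inv)
  if (!length(t_inv)) stop("empty capsule interior", call. = FALSE)
  t0 <- min(t_inv)
  brk <- function(tv) if (length(tv)) floor(tv - t0) + 1L else integer(0)
  nb <- max(brk(t_inv))
  cnt <- function(tv) tabulate(brk(tv), nbins = nb)
  a_scale <- (pitch * 1e-3)^2  # voxel count per unit-pitch bin -> mm^2
  df <- data.frame(
    pos_mm = (seq_len(nb) - 0.5) * pitch * 1e-3,
    area_CP_mm2 = cnt(proj(cp)) * a_scale,
    area_CP_Poros_mm2 = cnt(proj(cp_poros)) * a_scale,
    area_CS_Poros_mm2 = cnt(proj(cs_poros)) * a_scale,
    area_InV_mm2 = cnt(t_inv) * a_scale
  )
  filled <- df$area_CP_mm2 > 0
  floor_area <- if (any(filled))
    noise_floor_frac * median(df$area_CP_mm2[filled]) else 0
  top <- if (any(df$area_CP_mm2 > floor_area))
    max(which(df$area_CP_mm2 > floor_area)) else 0L
  filled_height_mm <- top * pitch * 1e-3
  body_length_mm <- nb * pitch * 1e-3
  list(data = df,
       slice_pitch_mm = pitch * 1e-3,
       filled_height_mm = filled_height_mm,
       body_length_mm = body_length_mm,
       fill_height_ratio_pct = fill_height_ratio(filled_height_mm,
                                                 body_length_mm))
}

#' Filling-height ratio
#'
#' @param filled_height_mm Height reached by the pellet bed.
#' @param body_length_mm Internal capsule body length.
#' @return The ratio in percent.
#' @export
#' @examples
#' fill_height_ratio(16.09, 16.78)  # 95.89
fill_height_ratio <- function(filled_height_mm, body_length_mm) {
  if (body_length_mm <= 0) stop("body length must be positive", call. = FALSE)
  100 * filled_height_mm / body_length_mm
}

#' Maximum Feret (caliper) diameter of a mask
#'
#' Maximum caliper extent over a systematic direction grid on the hemisphere
#' (default 3 degree angular step; the sampling makes this a lower bound
#' within ~0.2% of the exact maximum for convex bodies). Calipers are
#' measured on boundary voxels inflated by half a voxel.
#'
#' @param mask A [binary_mask()].
#' @param step_deg Angular sampling step in degrees.
#' @return List with `max_um`, `min_um` (minimum directional caliper over
#'   the same grid) and `mean_um`.
#' @export
feret_3d <- function(mask, step_deg = 3) {
  stopifnot(inherits(mask, "binary_mask"))
  pts <- .boundary_voxels_cpp(as.logical(mask$data), as_dim(mask$data))
  if (nrow(pts) == 0L) stop("empty mask", call. = FALSE)
  dirs <- hemisphere_directions(step_deg)
  n <- nrow(pts)
  ext <- numeric(nrow(dirs))
  chunk <- max(1L, floor(4e6 / n))
  for (s in seq(1, nrow(dirs), by = chunk)) {
    e <- min(nrow(dirs), s + chunk - 1L)
    pr <- pts %*% t(dirs[s:e, , drop = FALSE])
    ext[s:e] <- apply(pr, 2, function(v) max(v) - min(v))
  }
  ext <- ext + 1  # voxel extent: centers span + one voxel
  pitch <- mask$voxel_size_um
  list(max_um = max(ext) * pitch, min_um = min(ext) * pitch,
       mean_um = mean(ext) * pitch)
}

hemisphere_directions <- function(step_deg = 3) {
  az <- seq(0, 180 - step_deg, by = step_deg) * pi / 180
  el <- seq(-90, 90, by = step_deg) * pi / 180
  g <- expand.grid(az = az, el = el)
  cbind(cos(g$el) * cos(g$az), cos(g$el) * sin(g$az), sin(g$el))
}

#' Local thickness of a binary phase
#'
#' Per-voxel diameter of the largest inscribed sphere containing the voxel
#' (Hildebrand-style, computed from the distance ridge), in micrometers.
#'
#' @param mask A [binary_mask()].
#' @return 3D numeric array of thicknesses in micrometers (0 on background).
#' @export
local_thickness <- function(mask) {
  stopifnot(inherits(mask, "binary_mask"))
  if (!any(mask$data))
    return(array(0, dim = dim(mask$data)))
  d <- dim(mask$data)
  m <- pad_array(mask$data, 1L)
  th <- .local_thickness_cpp(as.logical(m), as.integer(dim(m)))
  th <- array(th, dim = dim(m))
  unpad_array(th, 1L, d) * mask$voxel_size_um
}

#' Triangulated iso-surface area of a mask
#'
#' Marching-cubes area of the 0.5 level set after light Gaussian smoothing
#' (sigma 0.8 voxels) of the binary indicator; the smoothing removes the
#' voxelization staircase so that a digital ball measures within ~2% of
#' `4*pi*r^2`.
#'
#' @param mask A [binary_mask()].
#' @param smooth_sigma Pre-smoothing sigma in voxels (0 disables).
#' @return Surface area in square micrometers.
#' @export
surface_area <- function(mask, smooth_sigma = 0.8) {
  stopifnot(inherits(mask, "binary_mask"))
  if (!any(mask$data)) return(0)
  d <- dim(mask$data)
  pad <- as.integer(ceiling(3 * smooth_sigma) + 1L)
  arr <- pad_array(mask$data, pad) * 1.0
  if (smooth_sigma > 0)
    arr <- array(.gaussian_blur_cpp(as.numeric(arr), as.integer(dim(arr)),
                                    smooth_sigma), dim = dim(arr))
  a_vox <- .mc_area_cpp(as.numeric(arr), as.integer(dim(arr)), 0.5)
  a_vox * mask$voxel_size_um^2
}

#' Capsule shell measurements
#'
#' Computes the maximum Feret length of the filled shell envelope, the
#' per-slice equivalent-circle diameter of the cylindrical body region
#' (`d_c`, mean and sd; the body region is the axial span where the slice
#' area varies by less than 5% of its median), the wall-thickness
#' distribution (`s_c`, local thickness of the shell mask) and the surface
#' areas of the shell envelope and, optionally, the pellet ROI.
#'
#' @param shell_mask Shell-wall [binary_mask()].
#' @param shell_roi Filled shell envelope (from [population_roi()]).
#' @param pellet_roi Optional pellet-population ROI for its surface area.
#' @param axis Capsule axis unit vector.
#' @return List with `max_length_feret_mm`, `d_c_mm` (c(mean, sd)),
#'   `s_c_um` (c(mean, sd)), `A_S_V_CS_ROI_mm2`, `A_S_V_CP_ROI_mm2` (NA if
#'   no pellet ROI given).
#' @export
capsule_measurements <- function(shell_mask, shell_roi, pellet_roi = NULL,
                                 axis = c(0, 0, 1)) {
  stopifnot(inherits(shell_mask, "binary_mask"),
            inherits(shell_roi, "binary_mask"))
  pitch <- shell_mask$voxel_size_um
  fer <- feret_3d(shell_roi)
  axis <- axis / sqrt(sum(axis^2))
  idx <- which(shell_roi$data)
  co <- arrayInd(idx, dim(shell_roi$data)) - 1
  tpos <- as.numeric(co %*% axis)
  bin <- floor(tpos - min(tpos)) + 1L
  area <- tabulate(bin, nbins = max(bin))
  med <- median(area[area > 0])
  body <- which(abs(area - med) < 0.05 * med)
  d_eq <- 2 * sqrt(area[body] / pi) * pitch * 1e-3
  th <- local_thickness(shell_mask)
  thv <- th[shell_mask$data]
  list(
    max_length_feret_mm = fer$max_um * 1e-3,
    d_c_mm = c(mean = mean(d_eq), sd = sd(d_eq)),
    s_c_um = c(mean = mean(thv), sd = sd(thv)),
    A_S_V_CS_ROI_mm2 = surface_area(shell_roi) * 1e-6,
    A_S_V_CP_ROI_mm2 = if (!is.null(pellet_roi))
      surface_area(pellet_roi) * 1e-6 else NA_real_
  )
}
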