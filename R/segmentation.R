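# ---------------------------------------------------------------------------
# Marker-controlled watershed segmentation of the touching pellet population.
#
# The binary population mask is transformed into a Euclidean distance map;
# markers are placed at its regional maxima after h-maxima suppression (the
# standard guard against over-segmentation), and a priority flood from the
# markers partitions the mask, growing regions from high distance values
# downwards so boundaries form at the distance-map saddles (the necks
# between touching pellets).

#' Watershed parameters
#'
#' @param marker_h h-maxima suppression depth in voxels (the main over- vs.
#'   under-segmentation dial): a regional maximum must rise at least
#'   `marker_h` above its surrounding saddle to seed a region.
#' @param distance_smooth_sigma Gaussian sigma (voxels) applied to the
#'   distance map before marker detection.
#' @param connectivity Marker labelling connectivity (6 or 26).
#' @param line_policy `"assign_nearest"` assigns every foreground voxel to a
#'   region (voxel-exact volume conservation); `"exclude"` zeroes one-voxel
#'   watershed lines between regions for visualization.
#' @return A `watershed_params` list.
#' @export
watershed_params <- function(marker_h = 2,
                             distance_smooth_sigma = 1,
                             connectivity = 26L,
                             line_policy = c("assign_nearest", "exclude")) {
  if (marker_h < 0) stop("marker_h must be >= 0", call. = FALSE)
  if (distance_smooth_sigma < 0)
    stop("distance_smooth_sigma must be >= 0", call. = FALSE)
  line_policy <- match.arg(line_policy)
  structure(list(marker_h = marker_h,
                 distance_smooth_sigma = distance_smooth_sigma,
                 connectivity = as.integer(connectivity),
                 line_policy = line_policy),
            class = "watershed_params")
}

#' Euclidean distance map
#'
#' Per-voxel Euclidean distance (in voxels) to the nearest background voxel;
#' 0 on background. Exact (squared-distance lower-envelope transform).
#'
#' @param mask A [binary_mask()].
#' @return A 3D numeric array of distances.
#' @export
distance_map <- function(mask) {
  stopifnot(inherits(mask, "binary_mask"))
  # pad so that foreground touching the array border still sees background
  d <- dim(mask$data)
  m <- pad_array(mask$data, 1L)
  dist <- edt(m)
  unpad_array(dist, 1L, d)
}

#' Generate watershed markers
#'
#' Smooths the distance map, suppresses shallow maxima by grayscale
#' reconstruction (h-maxima), and labels the surviving regional maxima.
#' Marker count is monotone non-increasing in `marker_h`.
#'
#' @param dist Distance map from [distance_map()].
#' @param mask The [binary_mask()] the map was computed from.
#' @param params A [watershed_params()].
#' @return A [label_volume()] of markers (0 outside markers).
#' @export
generate_markers <- function(dist, mask, params = watershed_params()) {
  stopifnot(inherits(mask, "binary_mask"))
  if (!any(mask$data)) {
    warning("empty mask: no markers generated", call. = FALSE)
    return(label_volume(array(0L, dim = dim(mask$data)), mask$voxel_size_um))
  }
  dm <- dist
  if (params$distance_smooth_sigma > 0) {
    dm <- array(.gaussian_blur_cpp(as.numeric(dm), as_dim(dm),
                                   params$distance_smooth_sigma),
                dim = dim(dm))
  }
  dims <- as_dim(dm)
  if (params$marker_h > 0) {
    dm <- array(.reconstruct_gray_cpp(as.numeric(dm) - params$marker_h,
                                      as.numeric(dm), dims),
                dim = dim(dm))
  }
  eps <- 1e-3
  rec <- array(.reconstruct_gray_cpp(as.numeric(dm) - eps, as.numeric(dm),
                                     dims),
               dim = dim(dm))
  maxima <- (dm - rec) > eps / 2 & mask$data
  lab <- label_array(maxima, params$connectivity)
  label_volume(array(lab, dim = dim(maxima)), mask$voxel_size_um,
               name = "markers")
}

#' Marker-supported watershed split
#'
#' Partitions the mask into one connected region per marker by priority
#' flooding of the distance map (flooded from high values downwards, ties
#' broken deterministically by voxel index).
#'
#' @param mask A [binary_mask()].
#' @param markers A marker [label_volume()] (from [generate_markers()]).
#' @param params A [watershed_params()].
#' @param dist Optional precomputed distance map.
#' @return A [label_volume()] with `max(markers)` labels.
#' @export
watershed_split <- function(mask, markers, params = watershed_params(),
                            dist = NULL) {
  stopifnot(inherits(mask, "binary_mask"), inherits(markers, "label_volume"))
  if (n_labels(markers) == 0L)
    stop("no markers supplied", call. = FALSE)
  if (any(markers$data > 0L & !mask$data))
    stop("markers must lie inside the mask", call. = FALSE)
  if (is.null(dist)) dist <- distance_map(mask)
  out <- .watershed_cpp(as.numeric(dist), as.integer(markers$data),
                        as.logical(mask$data), as_dim(mask$data))
  arr <- array(as.integer(out), dim = dim(mask$data))
  if (params$line_policy == "exclude") {
    arr <- zero_watershed_lines(arr)
  }
  label_volume(arr, mask$voxel_size_um, name = "watershed")
}

# One-voxel watershed lines: a voxel is zeroed when a 6-neighbour carries a
# smaller non-zero label (one-sided rule, keeps lines one voxel thick).
zero_watershed_lines <- function(arr) {
  d <- dim(arr)
  line <- array(FALSE, dim = d)
  shift_cmp <- function(a, b) a > 0L & b > 0L & a > b
  line[-1, , ] <- line[-1, , ] | shift_cmp(arr[-1, , ], arr[-d[1], , ])
  line[-d[1], , ] <- line[-d[1], , ] | shift_cmp(arr[-d[1], , ], arr[-1, , ])
  line[, -1, ] <- line[, -1, ] | shift_cmp(arr[, -1, ], arr[, -d[2], ])
  line[, -d[2], ] <- line[, -d[2], ] | shift_cmp(arr[, -d[2], ], arr[, -1, ])
  line[, , -1] <- line[, , -1] | shift_cmp(arr[, , -1], arr[, , -d[3]])
  line[, , -d[3]] <- line[, , -d[3]] | shift_cmp(arr[, , -d[3]], arr[, , -1])
  arr[line] <- 0L
  arr
}

#' Segment a pellet population mask into labelled pellets
#'
#' High-level wrapper around the watershed pieces that is robust to
#' intra-pellet porosity: enclosed pores are filled before the distance
#' map is computed (open pores would fracture the map into shallow maxima
#' and merge touching pellets under h-maxima suppression), markers are
#' detected on the filled map, the watershed partitions the filled mask,
#' and the resulting labels are finally restricted to the original solid
#' phase.
#'
#' @param mask Pellet-population [binary_mask()] (solid phase).
#' @param params A [watershed_params()].
#' @return A [label_volume()]; labels cover exactly the input mask.
#' @export
segment_pellets <- function(mask, params = watershed_params()) {
  stopifnot(inherits(mask, "binary_mask"))
  filled <- mask
  filled$data <- fill_enclosed_background(mask$data)
  dm <- distance_map(filled)
  mk <- generate_markers(dm, filled, params)
  lab <- watershed_split(filled, mk, params, dist = dm)
  lab$data[!mask$data] <- 0L
  lab
}

#' Extract per-pellet records from a label volume
#'
#' For each label the solid-phase mask (`mask_V`), the filled single-pellet
#' envelope (`mask_V_ROI`, via [population_roi()] which closes the surface
#' and fills enclosed porosity) and the centroid are extracted. Records are
#' sorted by label.
#'
#' @param labels A [label_volume()] from [watershed_split()].
#' @param closing_radius_um Ball radius for the per-pellet ROI closing.
#' @param pad Bounding-box padding in voxels.
#' @return A list of `pellet_record` objects with elements `label`, `bbox`
#'   (xmin, xmax, ymin, ymax, zmin, zmax; 1-based), `mask_V`, `mask_V_ROI`
#'   (cropped to the padded bbox), `centroid_um`, `features` (NULL until
#'   [feature_battery()] is run).
#' @export
extract_pellets <- function(labels, closing_radius_um = NULL, pad = 4L) {
  stopifnot(inherits(labels, "label_volume"))
  n <- n_labels(labels)
  if (n == 0L) return(list())
  pitch <- labels$voxel_size_um
  if (is.null(closing_radius_um)) closing_radius_um <- 2 * pitch
  arr <- labels$data
  d <- dim(arr)
  idx <- which(arr > 0L)
  lab <- arr[idx]
  co <- arrayInd(idx, d)
  ord <- order(lab)
  lab <- lab[ord]; co <- co[ord, , drop = FALSE]
  splits <- split(seq_along(lab), lab)
  records <- vector("list", n)
  for (li in seq_len(n)) {
    rows <- splits[[as.character(li)]]
    if (is.null(rows) || !length(rows)) next
    pc <- co[rows, , drop = FALSE]
    bb <- c(range(pc[, 1]), range(pc[, 2]), range(pc[, 3]))
    lo <- pmax(1L, c(bb[1], bb[3], bb[5]) - pad)
    hi <- pmin(d, c(bb[2], bb[4], bb[6]) + pad)
    sub <- arr[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
    mv <- array(sub == li, dim = dim(sub))
    mask_v <- binary_mask(mv, pitch, name = sprintf("pellet_%03d_V", li))
    roi <- population_roi(mask_v, closing_radius_um = closing_radius_um)
    centroid_vox <- colMeans(pc) - 1  # 0-based voxel center coordinates
    records[[li]] <- structure(
      list(label = li,
           bbox = c(lo[1], hi[1], lo[2], hi[2], lo[3], hi[3]),
           mask_V = mask_v,
           mask_V_ROI = roi,
           centroid_um = centroid_vox * pitch,
           features = NULL),
      class = "pellet_record")
  }
  records[!vapply(records, is.null, logical(1))]
}

#' @export
print.pellet_record <- function(x, ...) {
  cat(sprintf("<pellet_record> label %d, |V| = %d vox, |V_ROI| = %d vox\n",
              x$label, sum(x$mask_V$data), sum(x$mask_V_ROI$data)))
  invisible(x)
}
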