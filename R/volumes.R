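#' @useDynLib pelletscan, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats median quantile rnorm runif sd setNames t.test var
#' @importFrom utils head read.csv write.csv
NULL

# ---------------------------------------------------------------------------
# Volumetric containers.
#
# Coordinate convention (asserted throughout the package): arrays are indexed
# [x, y, z] (column, row, slice in image terms), 0-based voxel coordinates
# refer to voxel centers, and voxels are isotropic with pitch `voxel_size_um`.

new_volume <- function(data, voxel_size_um, name, class) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3D array", call. = FALSE)
  if (any(dim(data) < 1L))
    stop("all three dimensions must be >= 1", call. = FALSE)
  if (!is.numeric(voxel_size_um) || length(voxel_size_um) != 1L ||
      !is.finite(voxel_size_um) || voxel_size_um <= 0)
    stop("`voxel_size_um` must be a single positive number", call. = FALSE)
  structure(
    list(data = data, voxel_size_um = as.numeric(voxel_size_um), name = name),
    class = c(class, "ps_volume")
  )
}

#' Grayscale voxel volume
#'
#' A 3D grid of scalar intensities with isotropic voxel pitch. Intensities
#' are stored as doubles; [read_stack()] normalizes integer input to
#' \[0, 1\].
#'
#' @param data 3D numeric array, indexed \[x, y, z\].
#' @param voxel_size_um Isotropic voxel pitch in micrometers.
#' @param name Optional free-text label.
#' @return A `voxel_volume` object.
#' @export
voxel_volume <- function(data, voxel_size_um, name = "") {
  storage.mode(data) <- "double"
  if (anyNA(data) || any(!is.finite(data)))
    stop("intensities must be finite", call. = FALSE)
  new_volume(data, voxel_size_um, name, "voxel_volume")
}

#' Binary mask volume
#'
#' @inheritParams voxel_volume
#' @param data 3D logical array.
#' @return A `binary_mask` object.
#' @export
binary_mask <- function(data, voxel_size_um, name = "") {
  if (!is.logical(data)) {
    if (anyNA(data)) stop("mask must not contain NA", call. = FALSE)
    data <- array(data != 0, dim = dim(data))
  }
  if (anyNA(data)) stop("mask must not contain NA", call. = FALSE)
  new_volume(data, voxel_size_um, name, "binary_mask")
}

#' Integer label volume
#'
#' Voxel value 0 is background; objects are labelled 1..N.
#'
#' @inheritParams voxel_volume
#' @param data 3D array of non-negative integers.
#' @return A `label_volume` object.
#' @export
label_volume <- function(data, voxel_size_um, name = "") {
  storage.mode(data) <- "integer"
  if (anyNA(data) || any(data < 0L))
    stop("labels must be non-negative integers", call. = FALSE)
  new_volume(data, voxel_size_um, name, "label_volume")
}

#' @export
print.ps_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<%s> %d x %d x %d voxels @ %.3g um%s\n",
              class(x)[1], d[1], d[2], d[3], x$voxel_size_um,
              if (nzchar(x$name)) paste0("  '", x$name, "'") else ""))
  invisible(x)
}

#' @export
dim.ps_volume <- function(x) dim(x$data)

n_labels <- function(lv) {
  stopifnot(inherits(lv, "label_volume"))
  max(0L, max(lv$data))
}

#' Convert a voxel count to cubic millimeters
#'
#' One voxel occupies `(voxel_size_um * 1e-3)^3` cubic millimeters; this is
#' the conversion behind every reported absolute volume.
#'
#' @param count Non-negative voxel count.
#' @param voxel_size_um Isotropic voxel pitch in micrometers.
#' @return Volume in cubic millimeters.
#' @export
#' @examples
#' voxels_to_mm3(1, 100)   # 0.001
#' voxels_to_mm3(8, 50)    # 0.001
voxels_to_mm3 <- function(count, voxel_size_um) {
  if (any(count < 0)) stop("voxel count must be >= 0", call. = FALSE)
  if (voxel_size_um <= 0) stop("voxel pitch must be positive", call. = FALSE)
  count * (voxel_size_um * 1e-3)^3
}

# ---------------------------------------------------------------------------
# Stack I/O (multipage TIFF, or a directory of 2D slice images)

#' Read a volumetric image stack
#'
#' Reads either a multipage TIFF or a directory of equally sized 2D slice
#' images (sorted lexicographically). Slices are stacked along the third
#' array axis. Integer input is normalized to \[0, 1\] by its bit depth when
#' `normalize = TRUE`.
#'
#' @param path Path to a multipage TIFF file or a slice directory.
#' @param voxel_size_um Isotropic voxel pitch in micrometers (not parsed from
#'   vendor metadata).
#' @param normalize Normalize integer intensities to \[0, 1\] by their bit
#'   depth (default)? With `FALSE`, integer samples are restored to their
#'   raw values (bit-exact); float samples are returned verbatim either
#'   way.
#' @return A [voxel_volume()] (or integer array wrapped as `voxel_volume`
#'   when `normalize = FALSE`).
#' @export
read_stack <- function(path, voxel_size_um, normalize = TRUE) {
  if (!file.exists(path))
    stop(sprintf("path not found: %s", path), call. = FALSE)
  if (dir.exists(path)) {
    files <- sort(list.files(path, full.names = TRUE,
                             pattern = "\\.(tif|tiff|png)$", ignore.case = TRUE))
    if (length(files) == 0L)
      stop("no slice images found in directory", call. = FALSE)
    slices <- lapply(files, function(f) {
      if (grepl("\\.png$", f, ignore.case = TRUE)) {
        if (!requireNamespace("png", quietly = TRUE))
          stop("the 'png' package is needed for PNG slices", call. = FALSE)
        m <- png::readPNG(f)
        if (length(dim(m)) == 3L) m <- m[, , 1]
        attr(m, "sample.format") <- "uint"
        attr(m, "bits.per.sample") <- 8L
        m
      } else {
        tiff::readTIFF(f, info = TRUE)
      }
    })
  } else {
    slices <- tiff::readTIFF(path, all = TRUE, info = TRUE)
    if (!is.list(slices)) slices <- list(slices)
  }
  shp <- dim(slices[[1]])
  ok <- vapply(slices, function(s) identical(dim(s), shp), logical(1))
  if (!all(ok))
    stop("slice images have mismatched shapes", call. = FALSE)
  # readTIFF returns float samples verbatim and integer samples scaled to
  # [0, 1]; the sample format and bit depth come from the TIFF tags
  fmt <- attr(slices[[1]], "sample.format")
  int_source <- is.null(fmt) || identical(fmt, "uint") || identical(fmt, "int")
  bits <- attr(slices[[1]], "bits.per.sample")
  if (is.null(bits)) bits <- 8L
  # slice matrices are (row, col); store as [x = col, y = row, z = slice]
  arr <- array(0, dim = c(shp[2], shp[1], length(slices)))
  for (k in seq_along(slices)) arr[, , k] <- t(slices[[k]])
  if (!normalize && int_source)
    arr <- round(arr * (2^bits - 1))
  vol <- voxel_volume(arr, voxel_size_um, name = basename(path))
  vol$integer_source <- int_source
  vol
}

#' Write a volume to a multipage TIFF
#'
#' Grayscale volumes are written as 32-bit float, binary masks as 8-bit and
#' label volumes as 16-bit integers. Round-trips through [read_stack()] are
#' lossless; a label count that exceeds the 16-bit range is an error, never
#' a silent truncation.
#'
#' @param vol A [voxel_volume()], [binary_mask()] or [label_volume()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_stack <- function(vol, path) {
  stopifnot(inherits(vol, "ps_volume"))
  arr <- vol$data
  nz <- dim(arr)[3]
  if (inherits(vol, "binary_mask")) {
    slices <- lapply(seq_len(nz), function(k) t(arr[, , k]) * 1.0)
    tiff::writeTIFF(slices, path, bits.per.sample = 8)
  } else if (inherits(vol, "label_volume")) {
    mx <- max(arr)
    if (mx > 65535L)
      stop(sprintf("label count %d exceeds 16-bit TIFF capacity", mx),
           call. = FALSE)
    slices <- lapply(seq_len(nz), function(k) t(arr[, , k]) / 65535)
    tiff::writeTIFF(slices, path, bits.per.sample = 16)
  } else {
    slices <- lapply(seq_len(nz), function(k) t(arr[, , k]))
    tiff::writeTIFF(slices, path, bits.per.sample = 32)
  }
  invisible(path)
}

#' Read a label volume written by [write_stack()]
#'
#' @param path Multipage TIFF path.
#' @param voxel_size_um Voxel pitch in micrometers.
#' @return A [label_volume()].
#' @export
read_labels <- function(path, voxel_size_um) {
  raw <- read_stack(path, voxel_size_um, normalize = FALSE)
  label_volume(raw$data, voxel_size_um, name = basename(path))
}

#' Read a binary mask written by [write_stack()]
#'
#' @inheritParams read_labels
#' @return A [binary_mask()].
#' @export
read_mask <- function(path, voxel_size_um) {
  raw <- read_stack(path, voxel_size_um, normalize = FALSE)
  binary_mask(raw$data > 0, voxel_size_um, name = basename(path))
}

# internal helpers -----------------------------------------------------------

as_dim <- function(x) as.integer(dim(x))

edt <- function(mask_arr) {
  d <- .edt_sq_cpp(as.logical(mask_arr), as.integer(dim(mask_arr)))
  array(sqrt(d), dim = dim(mask_arr))
}

label_array <- function(mask_arr, connectivity = 26L) {
  stopifnot(connectivity %in% c(6L, 26L))
  v <- .label_components_cpp(as.logical(mask_arr), as.integer(dim(mask_arr)),
                             as.integer(connectivity))
  n <- attr(v, "n_labels")
  out <- array(as.integer(v), dim = dim(mask_arr))
  attr(out, "n_labels") <- n
  out
}

pad_array <- function(arr, pad, value = FALSE) {
  d <- dim(arr)
  out <- array(value, dim = d + 2L * pad)
  out[pad + seq_len(d[1]), pad + seq_len(d[2]), pad + seq_len(d[3])] <- arr
  out
}

unpad_array <- function(arr, pad, d) {
  arr[pad + seq_len(d[1]), pad + seq_len(d[2]), pad + seq_len(d[3])]
}

# Morphological dilation/erosion/closing with a Euclidean ball, realised on
# the distance transform (exact for a ball structuring element).
dilate_ball <- function(mask_arr, r_vox) {
  if (r_vox <= 0) return(mask_arr)
  dist_to_fg <- .edt_sq_cpp(as.logical(!mask_arr), as.integer(dim(mask_arr)))
  array(dist_to_fg <= r_vox^2, dim = dim(mask_arr))
}

erode_ball <- function(mask_arr, r_vox) {
  if (r_vox <= 0) return(mask_arr)
  dist_to_bg <- .edt_sq_cpp(as.logical(mask_arr), as.integer(dim(mask_arr)))
  array(dist_to_bg > r_vox^2, dim = dim(mask_arr))
}

close_ball <- function(mask_arr, r_vox) {
  if (r_vox <= 0) return(mask_arr)
  pad <- as.integer(ceiling(r_vox) + 1L)
  d <- dim(mask_arr)
  m <- pad_array(mask_arr, pad)
  m <- erode_ball(dilate_ball(m, r_vox), r_vox)
  unpad_array(m, pad, d)
}

open_ball <- function(mask_arr, r_vox) {
  if (r_vox <= 0) return(mask_arr)
  dilate_ball(erode_ball(mask_arr, r_vox), r_vox)
}

# Fill background components not connected to the array border.
fill_enclosed_background <- function(mask_arr) {
  lab <- label_array(!mask_arr, connectivity = 6L)
  n <- attr(lab, "n_labels")
  if (n == 0L) return(mask_arr)
  border <- unique(c(lab[1, , ], lab[dim(lab)[1], , ],
                     lab[, 1, ], lab[, dim(lab)[2], ],
                     lab[, , 1], lab[, , dim(lab)[3]]))
  border <- border[border > 0L]
  enclosed <- setdiff(seq_len(n), border)
  if (length(enclosed)) mask_arr[lab %in% enclosed] <- TRUE
  mask_arr
}
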