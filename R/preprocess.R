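# ---------------------------------------------------------------------------
# Grayscale preprocessing, histogram binarization, binary cleanup and the
# controlled image-degradation operator used by the sensitivity screen.

#' Preprocessing parameters
#'
#' @param smooth_strength Non-negative smoothing strength; mapped to the
#'   radius of the edge-preserving 3D median filter
#'   (`radius = round(strength)`, 0 = no smoothing).
#' @param threshold_mode `"auto"` (between-class-variance maximizer over a
#'   256-bin histogram) or `"fixed"`.
#' @param threshold_value Threshold in \[0, 1\]; required iff
#'   `threshold_mode = "fixed"`.
#' @param min_object_voxels Connected components (and enclosed background
#'   holes) smaller than this are removed during cleanup.
#' @param connectivity Foreground connectivity, 6 or 26.
#' @return A `preprocess_params` list.
#' @export
preprocess_params <- function(smooth_strength = 1,
                              threshold_mode = c("auto", "fixed"),
                              threshold_value = NULL,
                              min_object_voxels = 50L,
                              connectivity = 26L) {
  threshold_mode <- match.arg(threshold_mode)
  if (smooth_strength < 0) stop("smooth_strength must be >= 0", call. = FALSE)
  if (threshold_mode == "fixed") {
    if (is.null(threshold_value) || threshold_value < 0 || threshold_value > 1)
      stop("fixed mode requires threshold_value in [0, 1]", call. = FALSE)
  } else if (!is.null(threshold_value)) {
    stop("threshold_value is only used in fixed mode", call. = FALSE)
  }
  if (!connectivity %in% c(6L, 26L))
    stop("connectivity must be 6 or 26", call. = FALSE)
  structure(list(smooth_strength = smooth_strength,
                 threshold_mode = threshold_mode,
                 threshold_value = threshold_value,
                 min_object_voxels = as.integer(min_object_voxels),
                 connectivity = as.integer(connectivity)),
            class = "preprocess_params")
}

#' Edge-preserving smoothing
#'
#' Reduces random grayscale noise with a 3D median filter, the classic
#' parameter-light edge-preserving choice: step edges keep their position
#' and most of their contrast while speckle noise is suppressed.
#'
#' @param vol A [voxel_volume()].
#' @param strength Non-negative strength; the filter radius is
#'   `round(strength)` voxels, so `strength = 0` is the identity.
#' @return A smoothed [voxel_volume()].
#' @export
smooth_edge_preserving <- function(vol, strength = 1) {
  stopifnot(inherits(vol, "voxel_volume"))
  if (strength < 0) stop("strength must be >= 0", call. = FALSE)
  rad <- as.integer(round(strength))
  if (rad == 0L) return(vol)
  sm <- .median_filter_cpp(as.numeric(vol$data), as_dim(vol$data), rad)
  out <- vol
  out$data <- array(sm, dim = dim(vol$data))
  out
}

#' Histogram-based binarization threshold
#'
#' Returns the threshold that maximizes the between-class variance of the
#' volume's 256-bin intensity histogram (Otsu's criterion). The search is an
#' explicit scan over all 255 candidate cuts.
#'
#' @param vol A [voxel_volume()] with at least two distinct intensities.
#' @param nbins Number of histogram bins.
#' @return Threshold on the intensity scale of `vol`.
#' @export
threshold_histogram <- function(vol, nbins = 256L) {
  stopifnot(inherits(vol, "voxel_volume"))
  x <- as.numeric(vol$data)
  rng <- range(x)
  if (rng[1] == rng[2])
    stop("degenerate histogram: volume is constant", call. = FALSE)
  h <- tabulate(pmin(nbins, 1L + floor((x - rng[1]) / diff(rng) * nbins)),
                nbins = nbins)
  p <- h / sum(h)
  # class means/weights for every cut after bin t
  omega <- cumsum(p)
  mids <- rng[1] + (seq_len(nbins) - 0.5) / nbins * diff(rng)
  mu <- cumsum(p * mids)
  mu_t <- mu[nbins]
  t_range <- seq_len(nbins - 1L)
  w0 <- omega[t_range]
  valid <- w0 > 0 & w0 < 1
  sigma_b <- rep(-Inf, nbins - 1L)
  sigma_b[valid] <- (mu_t * w0[valid] - mu[t_range][valid])^2 /
    (w0[valid] * (1 - w0[valid]))
  # well-separated modes leave a plateau of equivalent cuts across the
  # empty gap; take its center rather than the first argmax
  mx <- max(sigma_b)
  ties <- which(sigma_b >= mx - abs(mx) * 1e-10)
  t_best <- mean(ties)
  # threshold at the upper edge of the best cut bin
  rng[1] + t_best / nbins * diff(rng)
}

#' Binarize a grayscale volume
#'
#' @param vol A [voxel_volume()].
#' @param params A [preprocess_params()] (controls threshold mode).
#' @param verbose Log the foreground fraction?
#' @return A [binary_mask()]; the applied threshold is stored in the
#'   `threshold` element.
#' @export
binarize <- function(vol, params = preprocess_params(), verbose = FALSE) {
  stopifnot(inherits(vol, "voxel_volume"))
  thr <- if (params$threshold_mode == "fixed") params$threshold_value
         else threshold_histogram(vol)
  m <- binary_mask(vol$data >= thr, vol$voxel_size_um, name = vol$name)
  m$threshold <- thr
  frac <- mean(m$data)
  if (verbose)
    message(sprintf("binarize: threshold %.4f, foreground %.2f%%",
                    thr, 100 * frac))
  if (frac == 0) warning("binarize produced an empty mask", call. = FALSE)
  m
}

#' Clean a binary mask
#'
#' Removes foreground connected components smaller than
#' `min_object_voxels` (at `params$connectivity`) and fills enclosed
#' background holes smaller than the same bound (at the dual background
#' connectivity, 6 when foreground is 26 and vice versa). Idempotent; real
#' intra-pellet porosity above the bound is preserved because it is measured
#' downstream.
#'
#' @param mask A [binary_mask()].
#' @param params A [preprocess_params()].
#' @return A cleaned [binary_mask()].
#' @export
clean_binary <- function(mask, params = preprocess_params()) {
  stopifnot(inherits(mask, "binary_mask"))
  minv <- params$min_object_voxels
  if (minv <= 0L) return(mask)
  arr <- mask$data
  lab <- label_array(arr, params$connectivity)
  n <- attr(lab, "n_labels")
  if (n > 0L) {
    sz <- tabulate(lab[lab > 0L], nbins = n)
    drop <- which(sz < minv)
    if (length(drop)) arr[lab %in% drop] <- FALSE
  }
  bg_conn <- if (params$connectivity == 26L) 6L else 26L
  labb <- label_array(!arr, bg_conn)
  nb <- attr(labb, "n_labels")
  if (nb > 0L) {
    szb <- tabulate(labb[labb > 0L], nbins = nb)
    border <- unique(c(labb[1, , ], labb[dim(labb)[1], , ],
                       labb[, 1, ], labb[, dim(labb)[2], ],
                       labb[, , 1], labb[, , dim(labb)[3]]))
    fill <- setdiff(which(szb < minv), border[border > 0L])
    if (length(fill)) arr[labb %in% fill] <- TRUE
  }
  out <- mask
  out$data <- arr
  out
}

#' Degrade a volume to emulate reduced acquisition quality
#'
#' Applies a Gaussian blur whose standard deviation is given in micrometers
#' (converted to voxels via the pitch), then additive Gaussian intensity
#' noise. Deterministic for a fixed seed.
#'
#' @param vol A [voxel_volume()].
#' @param blur_sigma_um Blur standard deviation in micrometers (>= 0).
#' @param noise_sd Standard deviation of additive Gaussian noise on the
#'   intensity scale (>= 0).
#' @param seed Integer seed for the noise.
#' @return A degraded [voxel_volume()].
#' @export
degrade <- function(vol, blur_sigma_um = 0, noise_sd = 0, seed = 1L) {
  stopifnot(inherits(vol, "voxel_volume"))
  if (blur_sigma_um < 0 || noise_sd < 0)
    stop("blur_sigma_um and noise_sd must be >= 0", call. = FALSE)
  arr <- vol$data
  sig_vox <- blur_sigma_um / vol$voxel_size_um
  if (sig_vox > 0) {
    arr <- array(.gaussian_blur_cpp(as.numeric(arr), as_dim(arr), sig_vox),
                 dim = dim(arr))
  }
  if (noise_sd > 0) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    set.seed(as.integer(seed))
    arr <- arr + array(rnorm(length(arr), sd = noise_sd), dim = dim(arr))
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  }
  out <- vol
  out$data <- arr
  out
}
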