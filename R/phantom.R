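# ---------------------------------------------------------------------------
# Synthetic ground-truth capsules: a hollow spherocylinder shell filled with
# spherical pellets (internal pores, a small broken fraction), rasterized at
# isotropic pitch with known per-pellet truth, then optionally degraded with
# blur and noise. Everything is a deterministic function of the spec and the
# seed.

#' Phantom generation parameters
#'
#' Defaults describe the reference acquisition this package models: 6 um
#' voxels, a size-00 style capsule (6.55 mm internal diameter, 16.78 mm
#' long, 112 um wall), about 300 pellets with a lognormal diameter
#' distribution truncated to 90-1408 um, filling 95.89% of the internal
#' height, and 7/300 broken pellets. At this pitch the full grid is far
#' larger than small-memory test machines allow; [scaled_phantom_spec()]
#' provides a geometrically similar problem size for tests.
#'
#' @param voxel_size_um Isotropic voxel pitch (um).
#' @param capsule_inner_diameter_um Internal shell diameter (um).
#' @param capsule_length_um Outer capsule length along the axis (um).
#' @param wall_thickness_um Shell wall thickness (um).
#' @param n_pellets Number of pellets to place (0 gives a shell-only
#'   phantom).
#' @param pellet_diameter_mean_um,pellet_diameter_sd_um Mean and standard
#'   deviation of the lognormal pellet diameter distribution (um).
#' @param pellet_diameter_range_um Truncation bounds on the diameters (um).
#' @param void_fraction Target intra-pellet void (pore) volume fraction.
#' @param pore_diameter_range_um Min/max internal pore diameter (um).
#' @param broken_fraction Fraction of pellets turned into fragments.
#' @param fragment_model `"sphere_cap"` (random cut plane, keep one side)
#'   or `"eroded"` (sphere cap additionally eroded by one voxel, modelling
#'   attrition-smoothed edges).
#' @param fill_ratio Filled height as a fraction of the internal height.
#' @param max_overlap_frac Contact tolerance: neighboring pellet centers
#'   may approach up to this fraction of the radius sum closer than
#'   touching, so necks form and the watershed is exercised.
#' @param wall_clearance_vox Minimum pellet clearance from the shell wall,
#'   in voxels.
#' @param intensities Named intensities for `air`, `shell`, `pellet`.
#' @param blur_sigma_um Degradation blur sigma (um); 0 disables.
#' @param noise_sd Additive Gaussian noise standard deviation.
#' @param margin_vox Empty voxels padded around the capsule.
#' @return A `phantom_spec` list.
#' @export
phantom_spec <- function(voxel_size_um = 6,
                         capsule_inner_diameter_um = 6550,
                         capsule_length_um = 16780,
                         wall_thickness_um = 112,
                         n_pellets = 300L,
                         pellet_diameter_mean_um = 500,
                         pellet_diameter_sd_um = 250,
                         pellet_diameter_range_um = c(90, 1408),
                         void_fraction = 0.04,
                         pore_diameter_range_um = c(12, 50),
                         broken_fraction = 7 / 300,
                         fragment_model = c("sphere_cap", "eroded"),
                         fill_ratio = 0.9589,
                         max_overlap_frac = 0.05,
                         wall_clearance_vox = 2.5,
                         intensities = c(air = 0.15, shell = 0.75,
                                         pellet = 0.85),
                         blur_sigma_um = NULL,
                         noise_sd = 0.02,
                         margin_vox = 4L) {
  if (is.null(blur_sigma_um)) blur_sigma_um <- 0.5 * voxel_size_um
  fragment_model <- match.arg(fragment_model)
  stopifnot(voxel_size_um > 0, capsule_inner_diameter_um > 0,
            wall_thickness_um > 0, n_pellets >= 0,
            pellet_diameter_mean_um > 0, pellet_diameter_sd_um > 0,
            length(pellet_diameter_range_um) == 2,
            diff(pellet_diameter_range_um) >= 0,
            void_fraction >= 0, void_fraction < 1,
            broken_fraction >= 0, broken_fraction < 0.5,
            fill_ratio > 0, fill_ratio <= 1,
            max_overlap_frac >= 0, max_overlap_frac < 1,
            all(c("air", "shell", "pellet") %in% names(intensities)))
  if (capsule_length_um < capsule_inner_diameter_um + 2 * wall_thickness_um)
    stop("capsule too short for its diameter (no spherocylinder exists)",
         call. = FALSE)
  structure(list(
    voxel_size_um = voxel_size_um,
    capsule_inner_diameter_um = capsule_inner_diameter_um,
    capsule_length_um = capsule_length_um,
    wall_thickness_um = wall_thickness_um,
    n_pellets = as.integer(n_pellets),
    pellet_diameter_mean_um = pellet_diameter_mean_um,
    pellet_diameter_sd_um = pellet_diameter_sd_um,
    pellet_diameter_range_um = pellet_diameter_range_um,
    void_fraction = void_fraction,
    pore_diameter_range_um = pore_diameter_range_um,
    broken_fraction = broken_fraction,
    fragment_model = fragment_model,
    fill_ratio = fill_ratio,
    max_overlap_frac = max_overlap_frac,
    wall_clearance_vox = wall_clearance_vox,
    intensities = intensities,
    blur_sigma_um = blur_sigma_um,
    noise_sd = noise_sd,
    margin_vox = as.integer(margin_vox)),
    class = "phantom_spec")
}

#' Scaled phantom for test problem sizes
#'
#' Geometrically similar to [phantom_spec()] but a smaller capsule
#' rasterized at a coarser pitch, so a full phantom fits comfortably in a
#' test-machine memory budget. At the default 15 um pitch pellets span
#' 20-60 voxels in diameter and the grid is about 39 million voxels.
#'
#' @param n_pellets Number of pellets.
#' @param voxel_size_um Voxel pitch (um).
#' @param ... Overrides passed to [phantom_spec()].
#' @return A `phantom_spec`.
#' @export
scaled_phantom_spec <- function(n_pellets = 300L, voxel_size_um = 15, ...) {
  phantom_spec(voxel_size_um = voxel_size_um,
               capsule_inner_diameter_um = 3600,
               capsule_length_um = 8000,
               wall_thickness_um = 120,
               n_pellets = n_pellets,
               pellet_diameter_mean_um = 450,
               pellet_diameter_sd_um = 120,
               pellet_diameter_range_um = c(300, 900),
               pore_diameter_range_um = c(60, 120),
               ...)
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf("<phantom_spec> %g um pitch, d_c %g mm, L %g mm, %d pellets (%.0f-%.0f um), %.2f%% broken\n",
              x$voxel_size_um, x$capsule_inner_diameter_um / 1000,
              x$capsule_length_um / 1000, x$n_pellets,
              x$pellet_diameter_range_um[1], x$pellet_diameter_range_um[2],
              100 * x$broken_fraction))
  invisible(x)
}

# truncated lognormal diameters with the requested arithmetic mean/sd
sample_diameters <- function(n, mean_um, sd_um, range_um) {
  if (n == 0L) return(numeric(0))
  sdlog <- sqrt(log(1 + (sd_um / mean_um)^2))
  meanlog <- log(mean_um) - sdlog^2 / 2
  out <- numeric(0)
  for (it in 1:100) {
    d <- stats::rlnorm(2L * n, meanlog, sdlog)
    out <- c(out, d[d >= range_um[1] & d <= range_um[2]])
    if (length(out) >= n) break
  }
  if (length(out) < n)
    stop("diameter distribution barely intersects the truncation range",
         call. = FALSE)
  out[seq_len(n)]
}

#' Generate a synthetic capsule volume with known truth
#'
#' Rasterizes the shell, packs pellets by sequential rejection sampling
#' (largest first; up to `max_overlap_frac` center overlap permitted so
#' neighbors touch; wall clearance enforced), carves spherical pores until
#' each pellet reaches the target void fraction, converts the selected
#' broken pellets into fragments by a random cut plane, and records
#' per-pellet truth from the pre-degradation voxel counts. The grayscale
#' volume is then degraded (blur + noise) unless `degraded = FALSE`.
#'
#' @param spec A [phantom_spec()].
#' @param seed Integer seed; the phantom is a pure function of
#'   `(spec, seed)`.
#' @param degraded Apply the blur/noise degradation?
#' @return A `phantom` list: `volume` ([voxel_volume()]), `labels`
#'   ([label_volume()] of true pellet ids, pre-degradation), `shell`
#'   (binary mask of the shell), `truth` (per-pellet data.frame: `id`,
#'   `diameter_um`, `center_*_vox`, `solid_voxels`, `envelope_voxels`,
#'   `n_pores`, `broken`), `spec`, `seed`, and summary counts.
#' @export
generate_capsule <- function(spec = scaled_phantom_spec(), seed = 1L,
                             degraded = TRUE) {
  stopifnot(inherits(spec, "phantom_spec"))
  u <- spec$voxel_size_um
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                   envir = globalenv())
  }, add = TRUE)
  set.seed(seed)

  r_in <- spec$capsule_inner_diameter_um / 2
  r_out <- r_in + spec$wall_thickness_um
  L <- spec$capsule_length_um
  m <- spec$margin_vox
  nx <- as.integer(ceiling(2 * r_out / u)) + 2L * m
  ny <- nx
  nz <- as.integer(ceiling(L / u)) + 2L * m
  cx <- nx / 2 * u; cy <- ny / 2 * u

  # shell/cavity slice-wise from the 2D squared radial distance (memory-lean)
  xs <- (seq_len(nx) - 0.5) * u
  ys <- (seq_len(ny) - 0.5) * u
  zs <- (seq_len(nz) - 0.5) * u
  rho2 <- outer((xs - cx)^2, (ys - cy)^2, "+")
  z0 <- m * u; z1 <- z0 + L
  az_out <- z0 + r_out; bz_out <- z1 - r_out
  az_in <- z0 + spec$wall_thickness_um + r_in
  bz_in <- z1 - spec$wall_thickness_um - r_in
  shell <- array(FALSE, dim = c(nx, ny, nz))
  cavity_vox <- 0
  for (k in seq_len(nz)) {
    dz_out <- pmax(0, az_out - zs[k], zs[k] - bz_out)
    dz_in <- pmax(0, az_in - zs[k], zs[k] - bz_in)
    out_k <- rho2 + dz_out^2 <= r_out^2
    in_k <- rho2 + dz_in^2 <= r_in^2
    shell[, , k] <- out_k & !in_k
    cavity_vox <- cavity_vox + sum(in_k)
  }

  # ---- pellet packing -------------------------------------------------
  diam <- sample_diameters(spec$n_pellets, spec$pellet_diameter_mean_um,
                           spec$pellet_diameter_sd_um,
                           spec$pellet_diameter_range_um)
  diam <- sort(diam, decreasing = TRUE)  # place large pellets first
  rad <- diam / 2
  clearance <- spec$wall_clearance_vox * u

  # fill height: pellets allowed up to fill_ratio of the internal height
  z_cav0 <- z0 + spec$wall_thickness_um
  z_cav1 <- z1 - spec$wall_thickness_um
  z_top <- z_cav0 + spec$fill_ratio * (z_cav1 - z_cav0)

  centers <- matrix(NA_real_, max(1L, spec$n_pellets), 3)
  placed <- logical(spec$n_pellets)
  for (i in seq_len(spec$n_pellets)) {
    r <- rad[i]
    for (att in seq_len(20000L)) {
      p <- c(cx + runif(1, -r_in, r_in), cy + runif(1, -r_in, r_in),
             runif(1, z_cav0 + r, z_top - r))
      # inside the cavity with wall clearance
      zz <- pmin(pmax(p[3], az_in), bz_in)
      dwall <- sqrt((p[1] - cx)^2 + (p[2] - cy)^2 + (p[3] - zz)^2)
      if (dwall > r_in - r - clearance) next
      if (p[3] + r > z_top) next
      ok <- TRUE
      if (any(placed)) {
        pc <- centers[placed, , drop = FALSE]
        dd <- sqrt(rowSums(sweep(pc, 2, p)^2))
        lim <- (rad[placed] + r) * (1 - spec$max_overlap_frac)
        if (any(dd < lim)) ok <- FALSE
      }
      if (ok) { centers[i, ] <- p; placed[i] <- TRUE; break }
    }
    if (!placed[i])
      stop(sprintf("packing failure: placed %d of %d pellets at fill height",
                   sum(placed), spec$n_pellets), call. = FALSE)
  }
  keep <- which(placed)

  # ---- choice of broken pellets and pore layout (before rasterizing) --
  n_broken <- round(spec$broken_fraction * length(keep))
  broken_ids <- if (n_broken > 0) sort(sample(keep, n_broken)) else integer(0)

  labels <- array(0L, dim = c(nx, ny, nz))
  truth <- vector("list", length(keep))
  pr <- spec$pore_diameter_range_um / 2

  next_id <- 0L
  for (i in keep) {
    next_id <- next_id + 1L
    r <- rad[i]; p <- centers[i, ]
    lo <- pmax(1L, floor((p - r) / u - 1))
    hi <- pmin(c(nx, ny, nz), ceiling((p + r) / u + 1))
    ix <- lo[1]:hi[1]; iy <- lo[2]:hi[2]; iz <- lo[3]:hi[3]
    gx <- (ix - 0.5) * u; gy <- (iy - 0.5) * u; gz <- (iz - 0.5) * u
    dx2 <- (gx - p[1])^2; dy2 <- (gy - p[2])^2; dz2 <- (gz - p[3])^2
    D2xy <- outer(dx2, dy2, "+")
    env <- array(FALSE, dim = c(length(ix), length(iy), length(iz)))
    for (k in seq_along(iz)) env[, , k] <- D2xy + dz2[k] <= r^2

    broken <- i %in% broken_ids
    if (broken) {
      # random cut plane through an off-center point; keep one cap
      nvec <- rnorm(3); nvec <- nvec / sqrt(sum(nvec^2))
      off <- runif(1, -0.3, 0.3) * r
      PLxy <- outer((gx - p[1]) * nvec[1], (gy - p[2]) * nvec[2], "+")
      for (k in seq_along(iz))
        env[, , k] <- env[, , k] & (PLxy + (gz[k] - p[3]) * nvec[3] <= off)
      if (spec$fragment_model == "eroded" && any(env))
        env <- erode_ball(env, 1)  # attrition-smoothed fragment edges
      if (!any(env)) next  # degenerate cut: drop the fragment entirely
    }

    # carve pores until the target void fraction is reached
    sol <- env
    n_env <- sum(env)
    pores_made <- 0L
    if (spec$void_fraction > 0 && r > 2 * pr[2] + 2 * u) {
      target <- spec$void_fraction * n_env
      for (q in seq_len(200L)) {
        if (n_env - sum(sol) >= target) break
        rp <- runif(1, pr[1], pr[2])
        # pore fully interior so the envelope stays intact
        dirv <- rnorm(3); dirv <- dirv / sqrt(sum(dirv^2))
        rc <- runif(1, 0, max(0, r - rp - 1.5 * u))
        pc <- p + rc * dirv
        Dpxy <- outer((gx - pc[1])^2, (gy - pc[2])^2, "+")
        pore <- array(FALSE, dim = dim(env))
        for (k in seq_along(iz))
          pore[, , k] <- Dpxy + (gz[k] - pc[3])^2 <= rp^2
        pore <- pore & env
        if (any(pore & sol)) {
          sol <- sol & !pore
          pores_made <- pores_made + 1L
        }
      }
    }

    # rasterize into the global label array (first-come id wins in overlaps)
    sub_lab <- labels[ix, iy, iz]
    write_mask <- sol & sub_lab == 0L
    sub_lab[write_mask] <- next_id
    labels[ix, iy, iz] <- sub_lab

    truth[[next_id]] <- data.frame(
      id = next_id, diameter_um = diam[i],
      center_x_vox = p[1] / u, center_y_vox = p[2] / u,
      center_z_vox = p[3] / u,
      solid_voxels = sum(write_mask), envelope_voxels = sum(env),
      n_pores = pores_made, broken = broken)
  }
  truth <- if (next_id > 0) do.call(rbind, truth[seq_len(next_id)])
  else data.frame(id = integer(0), diameter_um = numeric(0),
                  center_x_vox = numeric(0), center_y_vox = numeric(0),
                  center_z_vox = numeric(0), solid_voxels = integer(0),
                  envelope_voxels = integer(0), n_pores = integer(0),
                  broken = logical(0))
  truth <- truth[truth$solid_voxels > 0, , drop = FALSE]

  # ---- intensities ----------------------------------------------------
  inten <- spec$intensities
  vol <- array(inten[["air"]], dim = c(nx, ny, nz))
  vol[shell] <- inten[["shell"]]
  vol[labels > 0L] <- inten[["pellet"]]
  v <- voxel_volume(vol, u, name = sprintf("phantom seed %d", seed))
  rm(vol)
  if (degraded)
    v <- degrade(v, blur_sigma_um = spec$blur_sigma_um,
                 noise_sd = spec$noise_sd, seed = seed + 1L)

  structure(list(
    volume = v,
    labels = label_volume(labels, u, name = "true pellet ids"),
    shell = binary_mask(shell, u, name = "true shell"),
    truth = truth,
    spec = spec, seed = seed,
    n_placed = nrow(truth),
    n_broken = sum(truth$broken),
    solid_voxels_total = sum(truth$solid_voxels),
    cavity_voxels = cavity_vox),
    class = "phantom")
}

#' @export
print.phantom <- function(x, ...) {
  d <- dim(x$volume$data)
  cat(sprintf("<phantom> %d x %d x %d @ %g um; %d pellets (%d broken), seed %d\n",
              d[1], d[2], d[3], x$volume$voxel_size_um,
              x$n_placed, x$n_broken, x$seed))
  invisible(x)
}

#' Generate a synthetic labelled feature dataset
#'
#' Draws a class-imbalanced feature table mimicking the statistical
#' structure of a measured pellet population: the broken class differs from
#' the intact class in hull solidity (intact `SV_CH` concentrated near
#' 0.989 with sd 0.002, broken shifted low and widened), sphericity and
#' max-Feret shape factor; remaining features are shared-noise columns.
#' Setting `effect_size = 0` makes the classes indistinguishable. Used to
#' exercise ranking and classification without a full phantom segmentation.
#'
#' @param n_non_broken Intact pellet count.
#' @param n_broken Broken pellet count (default gives ~1:37 imbalance).
#' @param n_noise_features Number of uninformative extra features.
#' @param effect_size Interpolates the class mean separation and spread
#'   difference (1 = full-magnitude effects, 0 = identical class
#'   distributions, hence no class signal).
#' @param seed Integer seed.
#' @return List with `x` (matrix), `labels` (`"non_broken"` / `"broken"`),
#'   `informative` (names of the discriminating features).
#' @export
generate_feature_dataset <- function(n_non_broken = 854L, n_broken = 23L,
                                     n_noise_features = 20L,
                                     effect_size = 1, seed = 1L) {
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                   envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  n <- n_non_broken + n_broken
  labels <- c(rep("non_broken", n_non_broken), rep("broken", n_broken))
  shift <- function(mu_nb, mu_b) mu_nb - effect_size * (mu_nb - mu_b)
  # effect_size interpolates both moments, so 0 gives identical classes
  sprd <- function(sd_nb, sd_b) sd_nb + effect_size * (sd_b - sd_nb)
  svch <- c(rnorm(n_non_broken, 0.989, 0.002),
            rnorm(n_broken, shift(0.989, 0.94), sprd(0.002, 0.02)))
  psi <- c(rnorm(n_non_broken, 0.92, 0.02),
           rnorm(n_broken, shift(0.92, 0.78), sprd(0.02, 0.05)))
  sfm <- c(rnorm(n_non_broken, 0.93, 0.03),
           rnorm(n_broken, shift(0.93, 0.55), sprd(0.03, 0.08)))
  x <- cbind(SV_CH_V_ROI_IEV1 = pmin(svch, 1),
             Psi_gl_V_ROI = pmin(psi, 1),
             SF_maxFeretSph_F_V_ROI = pmin(sfm, 1))
  if (n_noise_features > 0) {
    noise <- matrix(rnorm(n * n_noise_features), n, n_noise_features)
    colnames(noise) <- paste0("noise_", seq_len(n_noise_features))
    x <- cbind(x, noise)
  }
  perm <- sample(n)
  list(x = x[perm, , drop = FALSE], labels = labels[perm],
       informative = c("SV_CH_V_ROI_IEV1", "Psi_gl_V_ROI",
                       "SF_maxFeretSph_F_V_ROI"))
}

#' @importFrom stats rlnorm rnorm
NULL
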