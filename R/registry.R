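# ---------------------------------------------------------------------------
# The canonical feature registry: 206 named scalar features per pellet,
# tagged by category (size / shape / surface / porosity / orientation) and
# source (3D or one of the IEV1-IEV3 cross-sections). 162 features are
# computed from the three invariant cross-sections (54 per section,
# identical definitions across sections); 44 from the 3D masks. The
# registry is the single source of truth for feature order and naming; its
# counts are asserted at load time.

iev_feature_defs <- function() {
  rbind(
    # --- size (17 per section) ---
    data.frame(stem = c(
      "A_V", "A_V_ROI", "d_eqC_V", "d_eqC_V_ROI", "P_V", "P_V_ROI",
      "F_max_V_ROI", "F_min_V_ROI", "F_mean_V_ROI", "A_CH_V_ROI",
      "P_CH_V_ROI", "BBw_V_ROI", "BBh_V_ROI", "r_mean_V_ROI",
      "r_max_V_ROI", "r_min_V_ROI", "d_eqC_CH_V_ROI"),
      category = "size"),
    # --- shape (30 per section) ---
    data.frame(stem = c(
      "Circ_V", "Circ_V_ROI", "AR_V_ROI", "AR_V", "Ecc_V_ROI", "Ecc_V",
      "Elong_V_ROI", "Extent_V_ROI", "Extent_V", "Conv_V_ROI",
      paste0("Hu", 1:7, "_V_ROI"), paste0("Hu", 1:7, "_V"),
      "rCV_V_ROI", "rMinMax_V_ROI", "Circ_CH_V_ROI", "Compact_V_ROI",
      "Compact_V", "Rnd_V_ROI"),
      category = "shape"),
    # --- surface (2 per section) ---
    data.frame(stem = c("SV_CH_V_ROI", "Rgh_V_ROI"), category = "surface"),
    # --- porosity (3 per section) ---
    data.frame(stem = c("SV_CH_V", "SV_sec", "A_Poros"),
               category = "porosity"),
    # --- orientation (2 per section) ---
    data.frame(stem = c("Theta_V_ROI", "OrientAniso_V_ROI"),
               category = "orientation")
  )
}

threed_feature_defs <- function() {
  rbind(
    data.frame(name = c(
      "V_V_um3", "V_V_ROI_um3", "d_eqSph_V", "d_eqSph_V_ROI",
      "F_max_3d_V_ROI", "F_min_3d_V_ROI", "F_mean_3d_V_ROI",
      "SF_Elps_SA_r1_V_ROI", "SF_Elps_SA_r2_V_ROI", "SF_Elps_SA_r3_V_ROI"),
      category = "size"),
    data.frame(name = c(
      "Psi_gl_V_ROI", "SF_maxFeretSph_F_V_ROI", "SF_maxFeretSph_F_V",
      "Elps_AR_r1r2", "Elps_AR_r1r3", "Elps_AR_r2r3", "Elps_fill_V_ROI",
      "Extent3d_V_ROI", "Compact3d_V_ROI", "FeretAR_3d_V_ROI",
      "SphFeret_V_ROI", "EigenIso_V_ROI", "rCV3d_V_ROI", "SphFeret_V"),
      category = "shape"),
    data.frame(name = c(
      "A_Sf_V_ROI", "A_Sf_V", "SSA_V_ROI", "SSA_V", "Sauter_d32_V_ROI",
      "SurfRatio_Elps_V_ROI"),
      category = "surface"),
    data.frame(name = c(
      "SV", "V_P_Poros_um3", "N_Pores", "PoreTh_mean_um",
      "PoreFrac_lt25um"),
      category = "porosity"),
    data.frame(name = c(
      "Ang_e1_axis_deg", "Ang_e2_axis_deg", "Ang_e3_axis_deg",
      "Lambda1_um2", "Lambda2_um2", "Lambda3_um2", "EigRatio_l2l1",
      "EigRatio_l3l1", "Aniso3d"),
      category = "orientation")
  )
}

#' The canonical pellet feature registry
#'
#' Ordered table of all 206 per-pellet features: the features named in the
#' field's symbol conventions (`d_eqSph`, `A_Sf`, `SV`, `Psi_gl`,
#' `SF_maxFeretSph`, `SF_Elps_SA_rk`, `SV_CH`) plus a canonical battery of
#' standard 2D descriptors per invariant cross-section (area, perimeter,
#' Feret diameters, circularity, convexity, eccentricity, Hu invariant
#' moments, hull statistics, radial signature). Category counts: size 61,
#' shape 104, surface 12, porosity 14, orientation 15; 162 features are
#' IEV-sourced (54 per section).
#'
#' @return A data.frame with columns `name`, `category`, `source`,
#'   `definition` and `robust` (logical, `NA` until a sensitivity screen
#'   sets it).
#' @export
feature_registry <- function() {
  reg3 <- threed_feature_defs()
  reg3$source <- "3D"
  iev <- iev_feature_defs()
  regs <- do.call(rbind, lapply(c("IEV1", "IEV2", "IEV3"), function(s) {
    data.frame(name = paste0(iev$stem, "_", s), category = iev$category,
               source = s)
  }))
  reg <- rbind(reg3[, c("name", "category", "source")], regs)
  reg$definition <- feature_definitions()[reg$name]
  reg$robust <- NA
  stopifnot(!anyDuplicated(reg$name))
  rownames(reg) <- NULL
  reg
}

feature_definitions <- function() {
  base <- c(
    V_V_um3 = "solid-phase volume |V| (um^3)",
    V_V_ROI_um3 = "filled-envelope volume |V_ROI| (um^3)",
    d_eqSph_V = "equivalent-sphere diameter (6|V|/pi)^(1/3) (um)",
    d_eqSph_V_ROI = "equivalent-sphere diameter of V_ROI (um)",
    F_max_3d_V_ROI = "maximum 3D Feret (caliper) diameter of V_ROI (um)",
    F_min_3d_V_ROI = "minimum directional caliper of V_ROI over the grid (um)",
    F_mean_3d_V_ROI = "mean directional caliper of V_ROI (um)",
    SF_Elps_SA_r1_V_ROI = "longest semi-axis of the surface-fitted ellipsoid (um)",
    SF_Elps_SA_r2_V_ROI = "middle semi-axis of the surface-fitted ellipsoid (um)",
    SF_Elps_SA_r3_V_ROI = "shortest semi-axis of the surface-fitted ellipsoid (um)",
    Psi_gl_V_ROI = "sphericity: area of equal-volume sphere / A_Sf(V_ROI)",
    SF_maxFeretSph_F_V_ROI = "|V_ROI| / volume of sphere with diameter F_max",
    SF_maxFeretSph_F_V = "|V| / volume of sphere with diameter F_max",
    SV = "solidity |V| / |V_ROI|")
  # remaining definitions are generated from the name; keep it light
  base
}

assert_registry <- function(reg = feature_registry()) {
  counts <- table(reg$category)
  ok <- nrow(reg) == 206L &&
    counts[["size"]] == 61L && counts[["shape"]] == 104L &&
    counts[["surface"]] == 12L && counts[["porosity"]] == 14L &&
    counts[["orientation"]] == 15L &&
    sum(reg$source != "3D") == 162L &&
    all(table(reg$source[reg$source != "3D"]) == 54L)
  if (!ok) stop("feature registry violates its count contract", call. = FALSE)
  invisible(TRUE)
}

.onLoad <- function(libname, pkgname) {
  assert_registry()
}

#' Export the feature registry as JSON
#'
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_registry_json <- function(path) {
  reg <- feature_registry()
  jsonlite::write_json(reg, path, auto_unbox = TRUE, pretty = TRUE, na = "null")
  invisible(path)
}
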