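#' Analysis parameters
#'
#' Collects every tunable quantitation parameter with the defaults used
#' throughout the package. Intensity thresholds are raw detector counts on
#' whatever bit depth the images carry; the defaults (250 units for the
#' graft label, 100 units for the vessel reporter) and the 100 um^3 minimum
#' object volume correspond to the standard xenograft quantitation
#' workflow, and both filters are inclusive (`>=`).
#'
#' @param graft_min_intensity Minimum graft-channel intensity, detector
#'   units (default 250).
#' @param graft_min_volume Minimum graft object volume, um^3 (default 100).
#' @param vessel_min_intensity Minimum vessel-channel intensity (default 100).
#' @param vessel_min_volume Minimum vessel object volume, um^3 (default 100).
#' @param macrophage_min_intensity Minimum macrophage-channel intensity
#'   (default 100).
#' @param macrophage_min_volume Minimum macrophage object volume, um^3
#'   (default 10; macrophage somata are far smaller than grafts or vessels).
#' @param angiogenic_radius Radius of the scoring disc centred on the
#'   vessel tip, um (default 10).
#' @param control_offset Centre-to-centre distance from the angiogenic to
#'   the control region, um (default 25).
#' @param contact_radius Macrophage-to-tip distance defining contact for
#'   track analysis, um (default equal to `angiogenic_radius`).
#' @param tipcell_min_duration Minimum tip-contact duration for the
#'   tip-cell classification, minutes (default 40, inclusive).
#' @param connectivity Voxel connectivity for 3D components: 6, 18 or 26
#'   (default 26).
#' @param aoi_mode `"bounding_box"` (default) or `"mask"`; how the vessel
#'   area of interest is built from the graft objects.
#' @param alpha_gate Significance level for the normality and variance
#'   gates of the statistical decision tree (default 0.05).
#' @return A list of class `analysis_config`.
#' @export
analysis_config <- function(graft_min_intensity = 250,
                            graft_min_volume = 100,
                            vessel_min_intensity = 100,
                            vessel_min_volume = 100,
                            macrophage_min_intensity = 100,
                            macrophage_min_volume = 10,
                            angiogenic_radius = 10,
                            control_offset = 25,
                            contact_radius = angiogenic_radius,
                            tipcell_min_duration = 40,
                            connectivity = 26,
                            aoi_mode = c("bounding_box", "mask"),
                            alpha_gate = 0.05) {
  aoi_mode <- match.arg(aoi_mode)
  num <- c(graft_min_intensity = graft_min_intensity,
           graft_min_volume = graft_min_volume,
           vessel_min_intensity = vessel_min_intensity,
           vessel_min_volume = vessel_min_volume,
           macrophage_min_intensity = macrophage_min_intensity,
           macrophage_min_volume = macrophage_min_volume,
           angiogenic_radius = angiogenic_radius,
           control_offset = control_offset,
           contact_radius = contact_radius,
           tipcell_min_duration = tipcell_min_duration)
  if (any(!is.finite(num)) || any(num <= 0))
    xv_stop("xv_bad_config",
            "all thresholds, radii and durations must be strictly positive")
  if (!connectivity %in% c(6L, 18L, 26L))
    xv_stop("xv_bad_config", "connectivity must be 6, 18 or 26")
  if (!is.finite(alpha_gate) || alpha_gate <= 0 || alpha_gate >= 1)
    xv_stop("xv_bad_config", "alpha_gate must be in (0, 1)")
  structure(
    list(graft_min_intensity = graft_min_intensity,
         graft_min_volume = graft_min_volume,
         vessel_min_intensity = vessel_min_intensity,
         vessel_min_volume = vessel_min_volume,
         macrophage_min_intensity = macrophage_min_intensity,
         macrophage_min_volume = macrophage_min_volume,
         angiogenic_radius = angiogenic_radius,
         control_offset = control_offset,
         contact_radius = contact_radius,
         tipcell_min_duration = tipcell_min_duration,
         connectivity = as.integer(connectivity),
         aoi_mode = aoi_mode,
         alpha_gate = alpha_gate),
    class = "analysis_config")
}

#' Fingerprint a configuration
#'
#' A short md5 digest of the canonical JSON form of a configuration, used
#' to stamp output tables so results can be traced to the exact parameters
#' that produced them.
#'
#' @param config An `analysis_config` (or any list of scalars).
#' @return A character md5 string.
#' @export
config_fingerprint <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(unclass(config), tmp, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}
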