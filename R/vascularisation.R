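#' Percentage graft vascularisation
#'
#' Totals the graft object volumes to give the graft volume, totals the
#' vessel object volumes (detected inside the graft area of interest) to
#' give the graft-associated vessel volume, and reports
#' `100 * vessel_volume / graft_volume`. With a bounding-box AOI the
#' percentage can exceed 100 when vessels fill more volume than the graft
#' itself; this is flagged with a warning and never clipped.
#'
#' @param graft `object_set` of graft objects; must be non-empty.
#' @param vessels `object_set` of vessel objects from the same grid.
#' @return List of class `graft_metrics` with `graft_volume_um3`,
#'   `vessel_volume_um3`, `percent_vascularisation`.
#' @export
percent_vascularisation <- function(graft, vessels) {
  if (!identical(dim(graft$labels), dim(vessels$labels)))
    xv_stop("xv_geometry_mismatch", "graft and vessel grids differ")
  if (!n_objects(graft))
    xv_stop("xv_empty_graft",
            "graft object set is empty; percentage vascularisation undefined")
  gv <- sum(graft$table$volume_um3)
  vv <- sum(vessels$table$volume_um3)
  pct <- 100 * vv / gv
  if (pct > 100)
    xv_warn("xv_percent_over_100",
            "vessel volume exceeds graft volume (%.1f%%); bounding-box AOI can include extra-graft vessels",
            pct)
  structure(list(graft_volume_um3 = gv, vessel_volume_um3 = vv,
                 percent_vascularisation = pct),
            class = "graft_metrics")
}

#' @export
print.graft_metrics <- function(x, ...) {
  cat(sprintf("<graft_metrics> graft %.4g um^3, vessels %.4g um^3, vascularisation %.2f%%\n",
              x$graft_volume_um3, x$vessel_volume_um3,
              x$percent_vascularisation))
  invisible(x)
}

#' Regional vascularisation relative to the CCV
#'
#' Splits the graft into three equal sections by volume along the common
#' cardinal vein (CCV) axis and reports the vessel percentage in each.
#' Every graft voxel gets the scalar projection
#' `s = (position - ccv_point) . ccv_axis`; voxels are sorted ascending
#' by `s` (ties by z, y, x index) and cut into three consecutive runs
#' whose sizes differ by at most one voxel, remainder voxels going to the
#' proximal-most runs first. The run nearest the CCV (smallest `s`) is
#' the proximal region. Only vessel voxels inside the graft mask count
#' towards regional percentages; they inherit the region of the graft
#' voxel they occupy.
#'
#' @param graft_mask Logical 3D array of graft voxels.
#' @param vessel_mask Logical 3D array of vessel voxels, same grid.
#' @param ccv An [annotation_set()] (or list with `ccv_point`,
#'   `ccv_axis`).
#' @param voxel_size `(dz, dy, dx)` um.
#' @return List of class `regional_metrics`: `percent` (named numeric:
#'   proximal, middle, distal), `graft_voxels`, `vessel_voxels`,
#'   `graft_volume_um3` per region, and `region` (integer array, 0 =
#'   outside graft, 1/2/3 = proximal/middle/distal).
#' @export
regional_vascularisation <- function(graft_mask, vessel_mask, ccv,
                                     voxel_size) {
  if (!identical(dim(graft_mask), dim(vessel_mask)))
    xv_stop("xv_geometry_mismatch", "graft and vessel masks differ in shape")
  check_voxel_size(voxel_size)
  dims <- dim(graft_mask)
  idx <- which(graft_mask)
  if (!length(idx)) xv_stop("xv_empty_graft", "graft mask is empty")
  axis <- ccv$ccv_axis / sqrt(sum(ccv$ccv_axis^2))
  zyx <- arrayInd(idx, dims)
  pos <- sweep(zyx - 0.5, 2, voxel_size, `*`)
  s <- (pos[, 1] - ccv$ccv_point[1]) * axis[1] +
       (pos[, 2] - ccv$ccv_point[2]) * axis[2] +
       (pos[, 3] - ccv$ccv_point[3]) * axis[3]
  ord <- order(s, zyx[, 1], zyx[, 2], zyx[, 3])
  n <- length(idx)
  base <- n %/% 3L; r <- n %% 3L
  sizes <- base + c(r >= 1L, r >= 2L, 0L)
  region_of_rank <- rep.int(1:3, sizes)
  region <- array(0L, dims)
  region[idx[ord]] <- region_of_rank

  g_count <- tabulate(region_of_rank, 3L)
  v_idx <- which(vessel_mask & graft_mask)
  v_count <- tabulate(region[v_idx], 3L)
  pct <- 100 * v_count / g_count
  names(pct) <- names(g_count) <- names(v_count) <-
    c("proximal", "middle", "distal")
  structure(list(percent = pct,
                 graft_voxels = g_count,
                 vessel_voxels = v_count,
                 graft_volume_um3 = g_count * prod(voxel_size),
                 region = region),
            class = "regional_metrics")
}

#' Count graft-associated macrophages
#'
#' A macrophage is graft-associated when its centroid lies inside the
#' graft area of interest (inclusive at the AOI boundary). The count is
#' normalised per 1e5 um^3 of graft volume so grafts of different sizes
#' are comparable.
#'
#' @param macrophage_objects `object_set` of detected macrophages.
#' @param graft_aoi [build_aoi()] result on the same grid.
#' @param graft_volume Graft volume in um^3, > 0.
#' @return List with `count` and `per_1e5_um3`.
#' @export
count_macrophages <- function(macrophage_objects, graft_aoi, graft_volume) {
  if (!identical(dim(macrophage_objects$labels), graft_aoi$dim))
    xv_stop("xv_geometry_mismatch", "macrophage grid does not match the AOI")
  if (!is.finite(graft_volume) || graft_volume <= 0)
    xv_stop("xv_zero_graft_volume", "graft volume must be > 0")
  tab <- macrophage_objects$table
  if (!nrow(tab)) {
    inside <- logical(0)
  } else if (graft_aoi$mode == "bounding_box") {
    e <- graft_aoi$extent
    d <- graft_aoi$voxel_size
    lo <- (e[, "lo"] - 1) * d   # physical box spanned by the voxels
    hi <- e[, "hi"] * d
    inside <- tab$centroid_z_um >= lo[1] & tab$centroid_z_um <= hi[1] &
              tab$centroid_y_um >= lo[2] & tab$centroid_y_um <= hi[2] &
              tab$centroid_x_um >= lo[3] & tab$centroid_x_um <= hi[3]
  } else {
    d <- graft_aoi$voxel_size
    iz <- pmin(pmax(floor(tab$centroid_z_um / d[1]) + 1, 1), graft_aoi$dim[1])
    iy <- pmin(pmax(floor(tab$centroid_y_um / d[2]) + 1, 1), graft_aoi$dim[2])
    ix <- pmin(pmax(floor(tab$centroid_x_um / d[3]) + 1, 1), graft_aoi$dim[3])
    inside <- graft_aoi$extent[cbind(iz, iy, ix)]
  }
  n <- sum(inside)
  list(count = n, per_1e5_um3 = n * 1e5 / graft_volume)
}

#' VEGFA secretion index
#'
#' Secreted VEGFA concentration divided by total protein content, per
#' well; replicate wells are summarised by the mean of the per-well
#' indices (not the index of the means, which differs whenever protein
#' content differs between wells).
#'
#' @param vegfa_pg_ml VEGFA concentration(s), pg/ml.
#' @param protein_ug Total protein content(s), ug; strictly positive.
#' @return Numeric vector of per-well indices, same length as the inputs.
#' @examples
#' secretion_index(100, 50)               # 2
#' mean(secretion_index(c(100, 80), c(50, 40)))  # replicate summary
#' @export
secretion_index <- function(vegfa_pg_ml, protein_ug) {
  if (any(!is.finite(protein_ug)) || any(protein_ug <= 0))
    xv_stop("xv_bad_protein", "total protein must be strictly positive")
  vegfa_pg_ml / protein_ug
}
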