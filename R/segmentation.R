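#' Detect fluorescent objects by threshold and minimum volume
#'
#' Voxels with intensity `>= min_intensity` (inclusive) are foreground;
#' 3D connected components are computed under the requested connectivity
#' and components with volume `< min_volume` um^3 are discarded (the
#' filter is inclusive at exactly `min_volume`). Surviving objects are
#' labelled `1..K` in decreasing volume order, ties broken by smallest
#' centroid z, then y, then x. Volume is voxel count times voxel volume,
#' with no sub-voxel interpolation; anisotropy enters only through the
#' voxel volume.
#'
#' @param stack A [volumetric_stack()].
#' @param role Channel role to segment (`"graft"`, `"vessel"`,
#'   `"macrophage"`).
#' @param min_intensity Inclusive intensity threshold, detector units.
#' @param min_volume Inclusive minimum object volume, um^3.
#' @param connectivity 6, 18 or 26 (default 26: diagonal-touching voxels
#'   are connected, as in common commercial 3D object counters).
#' @param restrict_mask Optional logical array of the stack's grid; when
#'   given, only voxels inside the mask can be foreground (objects are
#'   clipped at its boundary).
#' @return An `object_set`: list with `labels` (integer array, 0 =
#'   background), `table` (data.frame: `id`, `n_voxels`, `volume_um3`,
#'   `centroid_z_um`, `centroid_y_um`, `centroid_x_um`), `source_channel`,
#'   `thresholds`, `voxel_size`.
#' @examples
#' vx <- array(0, c(4, 10, 10, 1))
#' vx[2:3, 3:6, 3:6, 1] <- 300
#' s <- volumetric_stack(vx, c(graft = 1), c(5, 0.5, 0.5))
#' threshold_objects(s, "graft", 250, 30)$table
#' @export
threshold_objects <- function(stack, role, min_intensity, min_volume,
                              connectivity = 26L, restrict_mask = NULL) {
  ch <- get_channel(stack, role)
  if (!length(ch)) xv_stop("xv_empty_stack", "stack has no voxels")
  if (min_intensity <= 0 || min_volume <= 0)
    xv_stop("xv_bad_config", "thresholds must be strictly positive")
  fg <- ch >= min_intensity
  if (!is.null(restrict_mask)) {
    if (!identical(dim(restrict_mask), dim(ch)))
      xv_stop("xv_geometry_mismatch", "restrict_mask does not match the grid")
    fg <- fg & restrict_mask
  }
  object_set_from_mask(fg, stack$voxel_size, role,
                       list(min_intensity = min_intensity,
                            min_volume = min_volume,
                            connectivity = as.integer(connectivity)))
}

# Label a foreground mask and apply the volume filter / canonical ordering.
object_set_from_mask <- function(fg, voxel_size, role, thresholds) {
  dims <- dim(fg)
  vv <- prod(voxel_size)
  labels <- label_components_cpp(as.logical(fg), as.integer(dims),
                                 thresholds$connectivity)
  nlab <- max(labels)
  if (nlab > 0L) {
    counts <- tabulate(labels[labels > 0L], nbins = nlab)
    keep <- which(counts * vv >= thresholds$min_volume)
  } else keep <- integer(0)

  if (!length(keep)) {
    tab <- data.frame(id = integer(0), n_voxels = integer(0),
                      volume_um3 = numeric(0), centroid_z_um = numeric(0),
                      centroid_y_um = numeric(0), centroid_x_um = numeric(0))
    out_labels <- array(0L, dims)
  } else {
    idx <- which(array(labels %in% keep, dims))
    lab_at <- labels[idx]
    zyx <- arrayInd(idx, dims)
    pos <- sweep(zyx - 0.5, 2, voxel_size, `*`)  # voxel-centre um
    cz <- tapply(pos[, 1], lab_at, mean)
    cy <- tapply(pos[, 2], lab_at, mean)
    cx <- tapply(pos[, 3], lab_at, mean)
    nvox <- tapply(lab_at, lab_at, length)
    old_ids <- as.integer(names(nvox))
    ord <- order(-nvox, cz, cy, cx)
    new_of_old <- integer(nlab)
    new_of_old[old_ids[ord]] <- seq_along(ord)
    out_labels <- array(0L, dims)
    out_labels[idx] <- new_of_old[lab_at]
    tab <- data.frame(id = seq_along(ord),
                      n_voxels = as.integer(nvox[ord]),
                      volume_um3 = as.numeric(nvox[ord]) * vv,
                      centroid_z_um = as.numeric(cz[ord]),
                      centroid_y_um = as.numeric(cy[ord]),
                      centroid_x_um = as.numeric(cx[ord]))
  }
  structure(list(labels = out_labels, table = tab, source_channel = role,
                 thresholds = thresholds, voxel_size = as.numeric(voxel_size)),
            class = "object_set")
}

#' @rdname threshold_objects
#' @param objects An `object_set`.
#' @export
n_objects <- function(objects) nrow(objects$table)

#' @export
print.object_set <- function(x, ...) {
  cat(sprintf("<object_set> %d object(s) from '%s' channel (>= %g units, >= %g um^3, conn %d)\n",
              n_objects(x), x$source_channel, x$thresholds$min_intensity,
              x$thresholds$min_volume, x$thresholds$connectivity))
  if (n_objects(x)) print(utils::head(x$table, 10))
  invisible(x)
}

#' Build the 3D area of interest around detected objects
#'
#' The vessel quantitation region is derived from the graft objects,
#' either as the minimal axis-aligned bounding box containing every graft
#' voxel (`"bounding_box"`, the default, mirroring the interactive AOI
#' workflow) or as the exact union of graft voxels (`"mask"`, stricter).
#'
#' @param objects An `object_set` (typically graft objects).
#' @param mode `"bounding_box"` or `"mask"`.
#' @return A list of class `aoi` with `mode`, `extent` (for
#'   `bounding_box`: integer matrix of inclusive voxel bounds, rows
#'   z/y/x, columns lo/hi; for `mask`: logical array), `volume_um3`,
#'   `dim`, `voxel_size`.
#' @export
build_aoi <- function(objects, mode = c("bounding_box", "mask")) {
  mode <- match.arg(mode)
  dims <- dim(objects$labels)
  vv <- prod(objects$voxel_size)
  if (mode == "bounding_box") {
    if (!n_objects(objects))
      xv_stop("xv_empty_objects",
              "cannot build a bounding-box AOI from an empty object set")
    idx <- which(objects$labels > 0L)
    zyx <- arrayInd(idx, dims)
    extent <- rbind(z = range(zyx[, 1]), y = range(zyx[, 2]),
                    x = range(zyx[, 3]))
    colnames(extent) <- c("lo", "hi")
    vol <- prod(extent[, "hi"] - extent[, "lo"] + 1) * vv
  } else {
    extent <- objects$labels > 0L
    vol <- sum(extent) * vv
  }
  structure(list(mode = mode, extent = extent, volume_um3 = vol,
                 dim = dims, voxel_size = objects$voxel_size),
            class = "aoi")
}

# Logical inclusion mask of an AOI on its grid.
aoi_mask <- function(aoi) {
  if (aoi$mode == "mask") return(aoi$extent)
  m <- array(FALSE, aoi$dim)
  e <- aoi$extent
  m[e["z", "lo"]:e["z", "hi"],
    e["y", "lo"]:e["y", "hi"],
    e["x", "lo"]:e["x", "hi"]] <- TRUE
  m
}

#' Detect vessel objects inside an area of interest
#'
#' Same algorithm as [threshold_objects()], restricted to voxels inside
#' the AOI before component labelling: objects are clipped at the AOI
#' boundary and the volume filter applies to the clipped objects.
#'
#' @inheritParams threshold_objects
#' @param aoi An [build_aoi()] result on the same grid.
#' @export
vessels_in_aoi <- function(stack, aoi, min_intensity, min_volume,
                           connectivity = 26L) {
  if (!identical(aoi$dim, stack_dim(stack)))
    xv_stop("xv_geometry_mismatch", "AOI grid does not match the stack")
  threshold_objects(stack, "vessel", min_intensity, min_volume,
                    connectivity, restrict_mask = aoi_mask(aoi))
}
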