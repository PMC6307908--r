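# Disc footprint helper: matrix (iy, ix) of pixel indices whose centre
# lies within `radius` um of centre_yx (um), plus the centre distances.
disc_pixels <- function(centre_yx, radius, dims, voxel_size) {
  dy <- voxel_size[2]; dx <- voxel_size[3]
  iy_rng <- max(1L, floor((centre_yx[1] - radius) / dy)) :
            min(dims[2], ceiling((centre_yx[1] + radius) / dy + 1))
  ix_rng <- max(1L, floor((centre_yx[2] - radius) / dx)) :
            min(dims[3], ceiling((centre_yx[2] + radius) / dx + 1))
  g <- expand.grid(iy = iy_rng, ix = ix_rng)
  py <- (g$iy - 0.5) * dy; px <- (g$ix - 0.5) * dx
  d <- sqrt((py - centre_yx[1])^2 + (px - centre_yx[2])^2)
  keep <- d <= radius
  list(iy = g$iy[keep], ix = g$ix[keep], dist = d[keep])
}

#' Define the angiogenic scoring region at a vessel tip
#'
#' A disc of given radius in the xy plane centred on the tip of the
#' growing vessel, replicated over the z-sections occupied by that vessel
#' under the disc (at minimum the tip's own z-section). The z-section set
#' implements the rule that a macrophage only scores when it shares an
#' optical section with the vessel.
#'
#' @param tip Length-3 numeric, tip position (z, y, x) in um.
#' @param vessel_objects `object_set` of vessel objects in the frame.
#' @param radius Disc radius, um (default 10).
#' @return List of class `region_spec`: `centre_yx_um`, `radius_um`,
#'   `z_slices` (integer), `kind`.
#' @export
angiogenic_region <- function(tip, vessel_objects, radius = 10) {
  dims <- dim(vessel_objects$labels)
  d <- vessel_objects$voxel_size
  lims <- dims * d
  if (any(tip < 0) || any(tip > lims))
    xv_stop("xv_tip_out_of_bounds",
            "tip position (%s) um lies outside the stack (%s) um",
            paste(format(tip), collapse = ", "),
            paste(format(lims), collapse = ", "))
  tip_z_slice <- min(max(floor(tip[1] / d[1]) + 1, 1), dims[1])
  disc <- disc_pixels(tip[2:3], radius, dims, d)
  z_slices <- tip_z_slice
  if (length(disc$iy)) {
    # vessel voxels under the disc footprint, any z
    nz <- dims[1]
    lin <- rep(seq_len(nz), times = length(disc$iy)) +
      nz * rep((disc$iy - 1L), each = nz) +
      nz * dims[2] * rep((disc$ix - 1L), each = nz)
    lab <- vessel_objects$labels[lin]
    hit <- lab > 0L
    if (any(hit)) {
      zz <- rep(seq_len(nz), times = length(disc$iy))[hit]
      yy <- rep(disc$iy, each = nz)[hit]
      xx <- rep(disc$ix, each = nz)[hit]
      labs <- lab[hit]
      pz <- (zz - 0.5) * d[1]; py <- (yy - 0.5) * d[2]; px <- (xx - 0.5) * d[3]
      dist3 <- sqrt((pz - tip[1])^2 + (py - tip[2])^2 + (px - tip[3])^2)
      nearest <- labs[which.min(dist3)]
      z_slices <- sort(unique(c(tip_z_slice, zz[labs == nearest])))
    }
  }
  structure(list(centre_yx_um = as.numeric(tip[2:3]), radius_um = radius,
                 z_slices = as.integer(z_slices), kind = "angiogenic"),
            class = "region_spec")
}

#' Place the matched control region
#'
#' Candidate centres sit at the given centre-to-centre offset from the
#' angiogenic region, at xy angles 0, 15, ..., 345 degrees
#' (`y = cy + offset * sin(a)`, `x = cx + offset * cos(a)`). A candidate
#' is admissible when its whole disc lies inside the graft mask on every
#' z-section of the angiogenic region. Among admissible candidates the
#' one farthest from any vessel voxel (2D distance on those z-sections)
#' is chosen; ties go to the smallest angle, so placement is
#' deterministic. The control shares the angiogenic region's radius and
#' z-sections.
#'
#' @param angio [angiogenic_region()] result.
#' @param graft_mask Logical 3D array of graft voxels.
#' @param vessel_mask Logical 3D array of vessel voxels.
#' @param offset Centre-to-centre distance, um (default 25).
#' @param voxel_size `(dz, dy, dx)` um.
#' @return A `region_spec` with `kind = "control"` and the chosen
#'   `angle_deg`.
#' @export
place_control_region <- function(angio, graft_mask, vessel_mask,
                                 offset = 25, voxel_size) {
  if (offset <= 0) xv_stop("xv_bad_config", "offset must be > 0")
  dims <- dim(graft_mask)
  angles <- seq(0, 345, by = 15)
  rad <- angles * pi / 180
  zs <- angio$z_slices
  v_idx <- which(vessel_mask[zs, , , drop = FALSE],
                 arr.ind = TRUE)
  have_vessel <- nrow(v_idx) > 0
  if (have_vessel) {
    vy <- (v_idx[, 2] - 0.5) * voxel_size[2]
    vx <- (v_idx[, 3] - 0.5) * voxel_size[3]
  }
  best <- NULL
  for (k in seq_along(angles)) {
    cen <- c(angio$centre_yx_um[1] + offset * sin(rad[k]),
             angio$centre_yx_um[2] + offset * cos(rad[k]))
    disc <- disc_pixels(cen, angio$radius_um, dims, voxel_size)
    if (!length(disc$iy)) next
    # full containment: every disc pixel must exist in-grid and be graft
    # on every z-section of the angiogenic region
    n_expect <- n_disc_pixels(cen, angio$radius_um, voxel_size)
    if (length(disc$iy) < n_expect) next    # disc clipped by the grid
    ok <- TRUE
    for (z in zs) {
      if (!all(graft_mask[cbind(z, disc$iy, disc$ix)])) { ok <- FALSE; break }
    }
    if (!ok) next
    score <- if (have_vessel)
      min(sqrt((vy - cen[1])^2 + (vx - cen[2])^2)) else Inf
    if (is.null(best) || score > best$score + 1e-9)
      best <- list(score = score, angle = angles[k], centre = cen)
  }
  if (is.null(best))
    xv_stop("xv_no_control_position",
            "no admissible control position at offset %g um; use a larger graft or a smaller offset",
            offset)
  structure(list(centre_yx_um = best$centre, radius_um = angio$radius_um,
                 z_slices = angio$z_slices, kind = "control",
                 angle_deg = best$angle),
            class = "region_spec")
}

# Number of pixel centres within `radius` of a centre on an unbounded
# grid with the same pixel phase (used to detect grid clipping).
n_disc_pixels <- function(centre_yx, radius, voxel_size) {
  dy <- voxel_size[2]; dx <- voxel_size[3]
  iy <- floor((centre_yx[1] - radius) / dy):ceiling((centre_yx[1] + radius) / dy + 1)
  ix <- floor((centre_yx[2] - radius) / dx):ceiling((centre_yx[2] + radius) / dx + 1)
  g <- expand.grid(py = (iy - 0.5) * dy, px = (ix - 0.5) * dx)
  sum(sqrt((g$py - centre_yx[1])^2 + (g$px - centre_yx[2])^2) <= radius)
}

#' Score macrophage presence in a region for one frame
#'
#' A macrophage is counted when its centroid's (y, x) lies within the
#' region disc (distance <= radius, inclusive) and its object occupies at
#' least one z-section of the region (the same-optical-section rule).
#'
#' @param macrophage_objects `object_set` of macrophages in the frame.
#' @param region A `region_spec`.
#' @param frame Frame index to record (default `NA`).
#' @return One-row data.frame: `frame`, `region_kind`, `present`, `count`.
#' @export
score_frame <- function(macrophage_objects, region, frame = NA_integer_) {
  tab <- macrophage_objects$table
  count <- 0L
  if (nrow(tab)) {
    d2 <- sqrt((tab$centroid_y_um - region$centre_yx_um[1])^2 +
               (tab$centroid_x_um - region$centre_yx_um[2])^2)
    in_disc <- which(d2 <= region$radius_um)
    for (id in tab$id[in_disc]) {
      obj_z <- unique(arrayInd(which(macrophage_objects$labels == id),
                               dim(macrophage_objects$labels))[, 1])
      if (any(obj_z %in% region$z_slices)) count <- count + 1L
    }
  }
  data.frame(frame = frame, region_kind = region$kind,
             present = count >= 1L, count = count)
}

#' Summarise association scores per region kind
#'
#' @param scores Data.frame of [score_frame()] rows.
#' @return Data.frame with one row per region kind: `region_kind`,
#'   `n_frames`, `percent_frames_present`, `mean_count`.
#' @export
association_summary <- function(scores) {
  if (!nrow(scores))
    xv_stop("xv_empty_scores", "no frame scores to summarise")
  kinds <- unique(scores$region_kind)
  out <- lapply(kinds, function(k) {
    s <- scores[scores$region_kind == k, , drop = FALSE]
    data.frame(region_kind = k, n_frames = nrow(s),
               percent_frames_present = 100 * mean(s$present),
               mean_count = mean(s$count))
  })
  do.call(rbind, out)
}
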