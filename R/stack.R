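#' Construct a multichannel 3D volumetric stack
#'
#' A `volumetric_stack` holds one multichannel 3D intensity grid together
#' with its acquisition geometry. Axis order is (z, y, x): the voxel array
#' has `dim = c(nz, ny, nx, n_channels)`. Physical positions are voxel
#' centres, `pos_um = (index - 0.5) * voxel_size`, so the stack occupies
#' `[0, dim * voxel_size]` micrometres along each axis.
#'
#' @param voxels Numeric array of dimension `c(nz, ny, nx, n_channels)`
#'   (a 3D array is promoted to a single channel). Intensities must be
#'   non-negative.
#' @param channel_roles Named integer vector mapping roles (a subset of
#'   `"graft"`, `"vessel"`, `"macrophage"`) to 1-based channel indices.
#'   The mapping must be injective.
#' @param voxel_size Numeric length-3, voxel spacing `(dz, dy, dx)` in
#'   micrometres, each strictly positive.
#' @return An object of class `volumetric_stack`.
#' @examples
#' vx <- array(0, dim = c(4, 8, 8, 2))
#' s <- volumetric_stack(vx, c(graft = 1, vessel = 2), c(5, 0.6, 0.6))
#' voxel_volume(s)  # 1.8 um^3
#' @export
volumetric_stack <- function(voxels, channel_roles, voxel_size) {
  if (length(dim(voxels)) == 3L) dim(voxels) <- c(dim(voxels), 1L)
  if (length(dim(voxels)) != 4L)
    xv_stop("xv_bad_stack", "voxels must be a (z, y, x, channel) array")
  if (any(voxels < 0, na.rm = TRUE))
    xv_stop("xv_bad_stack", "intensities must be non-negative")
  check_voxel_size(voxel_size)
  nch <- dim(voxels)[4]
  check_channel_roles(channel_roles, nch)
  structure(
    list(voxels = voxels,
         channel_roles = channel_roles,
         voxel_size = as.numeric(voxel_size)),
    class = "volumetric_stack")
}

check_voxel_size <- function(voxel_size) {
  if (length(voxel_size) != 3L || !is.numeric(voxel_size) ||
      any(!is.finite(voxel_size)) || any(voxel_size <= 0))
    xv_stop("xv_bad_voxel_size",
            "voxel_size must be three strictly positive numbers (dz, dy, dx)")
  invisible(voxel_size)
}

check_channel_roles <- function(channel_roles, n_channels) {
  if (is.null(names(channel_roles)) || any(names(channel_roles) == ""))
    xv_stop("xv_bad_roles", "channel_roles must be a named vector")
  bad <- setdiff(names(channel_roles), c("graft", "vessel", "macrophage"))
  if (length(bad))
    xv_stop("xv_bad_roles", "unknown channel role(s): %s",
            paste(bad, collapse = ", "))
  idx <- as.integer(channel_roles)
  if (any(is.na(idx)) || any(idx < 1L) || any(idx > n_channels))
    xv_stop("xv_channel_mismatch",
            "channel_roles index outside the file's %d channel(s)", n_channels)
  if (anyDuplicated(idx))
    xv_stop("xv_bad_roles", "channel_roles must be injective")
  invisible(channel_roles)
}

#' @rdname volumetric_stack
#' @param stack A `volumetric_stack`.
#' @export
voxel_volume <- function(stack) prod(stack$voxel_size)

#' @rdname volumetric_stack
#' @export
stack_dim <- function(stack) dim(stack$voxels)[1:3]

#' Extract one channel of a stack by role
#'
#' @param stack A `volumetric_stack`.
#' @param role One of `"graft"`, `"vessel"`, `"macrophage"`.
#' @return 3D numeric array `(nz, ny, nx)`.
#' @export
get_channel <- function(stack, role) {
  if (!role %in% names(stack$channel_roles))
    xv_stop("xv_unknown_role", "stack has no channel for role '%s'", role)
  stack$voxels[, , , stack$channel_roles[[role]], drop = TRUE]
}

#' @export
print.volumetric_stack <- function(x, ...) {
  d <- stack_dim(x)
  cat(sprintf("<volumetric_stack> %d z x %d y x %d x voxels, %d channel(s)\n",
              d[1], d[2], d[3], dim(x$voxels)[4]))
  cat(sprintf("  voxel size (dz,dy,dx): %s um; voxel volume %.4g um^3\n",
              paste(format(x$voxel_size), collapse = " x "), voxel_volume(x)))
  cat(sprintf("  roles: %s\n",
              paste(sprintf("%s=%d", names(x$channel_roles),
                            x$channel_roles), collapse = ", ")))
  invisible(x)
}

#' Construct a time-lapse stack
#'
#' An ordered sequence of [volumetric_stack()] frames sharing geometry,
#' acquired at a fixed frame interval. Frame `f` is at time
#' `(f - 1) * frame_interval` minutes.
#'
#' @param frames List of `volumetric_stack` objects with identical
#'   dimensions, voxel size and channel roles.
#' @param frame_interval Minutes between frames, > 0.
#' @return An object of class `timelapse_stack`.
#' @export
timelapse_stack <- function(frames, frame_interval) {
  if (!length(frames))
    xv_stop("xv_bad_stack", "a timelapse_stack needs at least one frame")
  if (!is.numeric(frame_interval) || length(frame_interval) != 1L ||
      !is.finite(frame_interval) || frame_interval <= 0)
    xv_stop("xv_bad_frame_interval", "frame_interval must be > 0 minutes")
  ref <- frames[[1]]
  for (f in frames) {
    if (!inherits(f, "volumetric_stack"))
      xv_stop("xv_bad_stack", "all frames must be volumetric_stack objects")
    if (!identical(dim(f$voxels), dim(ref$voxels)) ||
        !identical(f$voxel_size, ref$voxel_size) ||
        !identical(f$channel_roles, ref$channel_roles))
      xv_stop("xv_bad_stack", "all frames must share geometry and roles")
  }
  structure(list(frames = frames, frame_interval = frame_interval),
            class = "timelapse_stack")
}

#' @export
print.timelapse_stack <- function(x, ...) {
  cat(sprintf("<timelapse_stack> %d frames every %g min\n",
              length(x$frames), x$frame_interval))
  print(x$frames[[1]])
  invisible(x)
}

#' @rdname timelapse_stack
#' @param stack A `timelapse_stack`.
#' @export
n_frames <- function(stack) length(stack$frames)
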