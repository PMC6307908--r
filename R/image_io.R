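#' Read and write multichannel z-stacks as multipage TIFF
#'
#' Stacks are stored as plain multipage greyscale TIFF, one page per
#' z-slice per channel, channel-major: page `(c - 1) * nz + z` holds slice
#' `z` of channel `c`. A time-lapse file appends frames outermost, i.e.
#' page `((f - 1) * n_channels + (c - 1)) * nz + z`. Intensities are
#' written as 16-bit unsigned integers, so round-trips are bit exact for
#' integer intensities in `[0, 65535]`.
#'
#' Geometry metadata (voxel size, channel roles) is supplied explicitly by
#' the caller and always overrides anything in the file headers; nothing
#' is inferred silently.
#'
#' @param path TIFF file path.
#' @param channel_roles Named integer vector, see [volumetric_stack()].
#' @param voxel_size `(dz, dy, dx)` in micrometres.
#' @param n_channels Number of channels stored in the file; defaults to
#'   the largest index in `channel_roles`.
#' @return [read_stack()] returns a `volumetric_stack`; [write_stack()]
#'   returns `path` invisibly.
#' @examples
#' \donttest{
#' p <- tempfile(fileext = ".tif")
#' s <- volumetric_stack(array(rpois(4 * 16 * 16 * 2, 50), c(4, 16, 16, 2)),
#'                       c(graft = 1, vessel = 2), c(5, 0.6, 0.6))
#' write_stack(s, p)
#' s2 <- read_stack(p, c(graft = 1, vessel = 2), c(5, 0.6, 0.6))
#' stopifnot(identical(s$voxels, s2$voxels))
#' }
#' @export
read_stack <- function(path, channel_roles, voxel_size,
                       n_channels = max(as.integer(channel_roles))) {
  if (!file.exists(path))
    xv_stop("xv_missing_file", "no such file: %s", path)
  check_voxel_size(voxel_size)
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  if (length(pages) %% n_channels != 0L)
    xv_stop("xv_channel_mismatch",
            "%d pages are not divisible into %d channel(s)",
            length(pages), n_channels)
  nz <- length(pages) %/% n_channels
  ny <- nrow(pages[[1]]); nx <- ncol(pages[[1]])
  vox <- array(0, dim = c(nz, ny, nx, n_channels))
  for (ch in seq_len(n_channels))
    for (z in seq_len(nz))
      vox[z, , , ch] <- pages[[(ch - 1L) * nz + z]]
  volumetric_stack(vox, channel_roles, voxel_size)
}

#' @rdname read_stack
#' @param stack A `volumetric_stack` (or, for the timelapse variants, a
#'   `timelapse_stack`).
#' @export
write_stack <- function(stack, path) {
  vox <- stack$voxels
  if (max(vox) > 65535 || any(vox != round(vox)))
    xv_stop("xv_bad_stack",
            "write_stack stores 16-bit integers; intensities must be integers in [0, 65535]")
  nz <- dim(vox)[1]; nch <- dim(vox)[4]
  pages <- vector("list", nz * nch)
  for (ch in seq_len(nch))
    for (z in seq_len(nz))
      pages[[(ch - 1L) * nz + z]] <- vox[z, , , ch] / 65535
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  invisible(path)
}

#' @rdname read_stack
#' @param frame_interval Minutes between frames.
#' @export
read_timelapse <- function(path, channel_roles, voxel_size, n_channels,
                           nz, frame_interval) {
  if (!file.exists(path))
    xv_stop("xv_missing_file", "no such file: %s", path)
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  per_frame <- n_channels * nz
  if (length(pages) %% per_frame != 0L)
    xv_stop("xv_channel_mismatch",
            "%d pages are not divisible into frames of %d channel(s) x %d slices",
            length(pages), n_channels, nz)
  nf <- length(pages) %/% per_frame
  frames <- vector("list", nf)
  ny <- nrow(pages[[1]]); nx <- ncol(pages[[1]])
  for (f in seq_len(nf)) {
    vox <- array(0, dim = c(nz, ny, nx, n_channels))
    for (ch in seq_len(n_channels))
      for (z in seq_len(nz))
        vox[z, , , ch] <- pages[[(f - 1L) * per_frame + (ch - 1L) * nz + z]]
    frames[[f]] <- volumetric_stack(vox, channel_roles, voxel_size)
  }
  timelapse_stack(frames, frame_interval)
}

#' @rdname read_stack
#' @export
write_timelapse <- function(stack, path) {
  nz <- stack_dim(stack$frames[[1]])[1]
  nch <- dim(stack$frames[[1]]$voxels)[4]
  pages <- vector("list", length(stack$frames) * nch * nz)
  k <- 0L
  for (fr in stack$frames) {
    vox <- fr$voxels
    if (max(vox) > 65535 || any(vox != round(vox)))
      xv_stop("xv_bad_stack",
              "write_timelapse stores 16-bit integers; intensities must be integers in [0, 65535]")
    for (ch in seq_len(nch))
      for (z in seq_len(nz)) {
        k <- k + 1L
        pages[[k]] <- vox[z, , , ch] / 65535
      }
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  invisible(path)
}

#' Read manually curated annotations
#'
#' Annotations carry the inputs that are selected by eye in the original
#' workflow: the common cardinal vein (CCV) reference point and axis used
#' for the proximal/middle/distal split, and the per-frame trajectory of
#' the analysed vessel tip with the time-lapse analysis window.
#'
#' The file is JSON with fields `ccv_point` (length-3, um, (z, y, x)),
#' `ccv_axis` (length-3, direction of increasing distance from the CCV;
#' renormalised to unit length on read), and optionally `analysis_window`
#' (`[first_frame, last_frame]`, 1-based) plus `tip_trajectory`, an array
#' of records `{frame, z_um, y_um, x_um, tip_id?}` (`tip_id` defaults
#' to 1). Trajectory rows are sorted by frame; the trajectory must cover
#' every frame of the analysis window with no gaps.
#'
#' @param path JSON annotation file.
#' @return A list of class `annotation_set` with elements `ccv_point`,
#'   `ccv_axis`, `analysis_window` (or `NULL`) and `tip_trajectory` (a
#'   data.frame or `NULL`).
#' @export
read_annotations <- function(path) {
  if (!file.exists(path))
    xv_stop("xv_missing_file", "no such file: %s", path)
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  annotation_set(ccv_point = as.numeric(raw$ccv_point),
                 ccv_axis = as.numeric(raw$ccv_axis),
                 analysis_window = if (!is.null(raw$analysis_window))
                   as.integer(raw$analysis_window),
                 tip_trajectory = if (!is.null(raw$tip_trajectory))
                   as.data.frame(raw$tip_trajectory))
}

#' @rdname read_annotations
#' @param ccv_point Length-3 numeric, um, (z, y, x).
#' @param ccv_axis Length-3 numeric; renormalised to unit length.
#' @param analysis_window Optional `c(first_frame, last_frame)`, 1-based.
#' @param tip_trajectory Optional data.frame with columns `frame`, `z_um`,
#'   `y_um`, `x_um` and optionally `tip_id`.
#' @export
annotation_set <- function(ccv_point, ccv_axis, analysis_window = NULL,
                           tip_trajectory = NULL) {
  if (length(ccv_point) != 3L || any(!is.finite(ccv_point)))
    xv_stop("xv_bad_annotation", "ccv_point must be three finite numbers")
  nrm <- sqrt(sum(ccv_axis^2))
  if (length(ccv_axis) != 3L || !is.finite(nrm) || nrm < 1e-12)
    xv_stop("xv_zero_axis", "ccv_axis must have non-zero length")
  ccv_axis <- ccv_axis / nrm
  if (!is.null(tip_trajectory)) {
    need <- c("frame", "z_um", "y_um", "x_um")
    if (!all(need %in% names(tip_trajectory)))
      xv_stop("xv_bad_annotation", "tip_trajectory needs columns %s",
              paste(need, collapse = ", "))
    if (is.null(tip_trajectory$tip_id)) tip_trajectory$tip_id <- 1L
    tip_trajectory <- tip_trajectory[order(tip_trajectory$tip_id,
                                           tip_trajectory$frame), , drop = FALSE]
    rownames(tip_trajectory) <- NULL
    if (anyDuplicated(tip_trajectory[c("tip_id", "frame")]))
      xv_stop("xv_bad_annotation", "duplicate (tip_id, frame) rows in trajectory")
  }
  if (!is.null(analysis_window)) {
    if (length(analysis_window) != 2L || analysis_window[1] > analysis_window[2])
      xv_stop("xv_bad_annotation", "analysis_window must be (first, last)")
    if (is.null(tip_trajectory))
      xv_stop("xv_trajectory_gap",
              "analysis_window given but no tip trajectory")
    want <- seq(analysis_window[1], analysis_window[2])
    for (id in unique(tip_trajectory$tip_id)) {
      have <- tip_trajectory$frame[tip_trajectory$tip_id == id]
      miss <- setdiff(want, have)
      if (length(miss))
        xv_stop("xv_trajectory_gap",
                "tip %s trajectory missing frame(s) %s inside analysis window",
                id, paste(miss, collapse = ", "))
    }
  }
  structure(list(ccv_point = as.numeric(ccv_point),
                 ccv_axis = ccv_axis,
                 analysis_window = analysis_window,
                 tip_trajectory = tip_trajectory),
            class = "annotation_set")
}

#' @rdname read_annotations
#' @param annotations An `annotation_set`.
#' @export
write_annotations <- function(annotations, path) {
  jsonlite::write_json(
    list(ccv_point = annotations$ccv_point,
         ccv_axis = annotations$ccv_axis,
         analysis_window = annotations$analysis_window,
         tip_trajectory = annotations$tip_trajectory),
    path, auto_unbox = FALSE, digits = NA, null = "null", dataframe = "rows")
  invisible(path)
}

#' Write and read metric tables
#'
#' Plain CSV with a header row; numbers keep full double precision (15
#' significant digits), so write-then-read reproduces values to within
#' 1e-6 relative comfortably.
#'
#' @param records A data.frame of metric records.
#' @param path Output CSV path.
#' @return [write_metrics()] returns `path` invisibly; [read_metrics()]
#'   a data.frame.
#' @export
write_metrics <- function(records, path) {
  if (!is.data.frame(records))
    xv_stop("xv_bad_records", "records must be a data.frame")
  ok <- tryCatch({
    utils::write.csv(records, path, row.names = FALSE)
    TRUE
  }, error = function(e) FALSE)
  if (!ok)
    xv_stop("xv_unwritable", "cannot write metrics to %s", path)
  invisible(path)
}

#' @rdname write_metrics
#' @export
read_metrics <- function(path) {
  if (!file.exists(path))
    xv_stop("xv_missing_file", "no such file: %s", path)
  utils::read.csv(path)
}
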