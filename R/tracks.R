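#' Link per-frame detections into tracks
#'
#' Frame-to-frame linking by an exact minimum-cost assignment between the
#' tracks open at frame `f` and the detections at frame `f + 1`: among
#' matchings of maximal cardinality whose link distances do not exceed
#' `max_step`, the one of minimal total displacement is chosen (solved by
#' a linear assignment on a cost matrix augmented with birth/death
#' entries). Unmatched detections start new tracks; a track with no match
#' is closed, so tracks never contain frame gaps. The procedure is
#' deterministic.
#'
#' Automatic linking exists mainly for synthetic data; manually curated
#' tracks in the same layout can be fed to the downstream functions
#' directly.
#'
#' @param detections Data.frame with columns `frame`, `z_um`, `y_um`,
#'   `x_um` (one row per detected centroid).
#' @param max_step Maximum allowed frame-to-frame displacement, um.
#' @return Data.frame `track_id`, `frame`, `z_um`, `y_um`, `x_um`,
#'   ordered by track then frame.
#' @export
link_tracks <- function(detections, max_step) {
  if (!is.finite(max_step) || max_step <= 0)
    xv_stop("xv_bad_config", "max_step must be > 0")
  need <- c("frame", "z_um", "y_um", "x_um")
  if (!all(need %in% names(detections)))
    xv_stop("xv_bad_records", "detections need columns %s",
            paste(need, collapse = ", "))
  detections <- detections[order(detections$frame, detections$z_um,
                                 detections$y_um, detections$x_um), ,
                           drop = FALSE]
  if (!nrow(detections))
    return(data.frame(track_id = integer(0), frame = integer(0),
                      z_um = numeric(0), y_um = numeric(0),
                      x_um = numeric(0)))
  frames <- sort(unique(detections$frame))
  next_id <- 0L
  open <- NULL  # data.frame track_id, z_um, y_um, x_um (position at prev frame)
  rows <- list()
  prev_f <- NULL
  for (f in frames) {
    det <- detections[detections$frame == f, , drop = FALSE]
    if (is.null(prev_f) || (f - prev_f) != 1) {
      open <- NULL  # a gap in the frame sequence closes all tracks
    }
    assigned <- rep(NA_integer_, nrow(det))
    if (!is.null(open) && nrow(open)) {
      n1 <- nrow(open); n2 <- nrow(det)
      D <- outer(seq_len(n1), seq_len(n2), function(i, j)
        sqrt((open$z_um[i] - det$z_um[j])^2 +
             (open$y_um[i] - det$y_um[j])^2 +
             (open$x_um[i] - det$x_um[j])^2))
      B <- (min(n1, n2) + 1) * max_step       # cost of a birth/death slot
      FORB <- 4 * B * (n1 + n2 + 1)           # forbidden (finite for LAP)
      C <- matrix(FORB, n1 + n2, n1 + n2)
      Dq <- D; Dq[Dq > max_step] <- FORB
      C[1:n1, 1:n2] <- Dq
      for (i in 1:n1) C[i, n2 + i] <- B       # track i ends
      for (j in 1:n2) C[n1 + j, j] <- B       # detection j starts a track
      C[(n1 + 1):(n1 + n2), (n2 + 1):(n2 + n1)] <- 0
      sol <- solve_lap_cpp(C)
      for (i in 1:n1) {
        j <- sol[i]
        if (j <= n2 && D[i, j] <= max_step) assigned[j] <- open$track_id[i]
      }
    }
    new_mask <- is.na(assigned)
    if (any(new_mask)) {
      ids <- next_id + seq_len(sum(new_mask))
      next_id <- next_id + sum(new_mask)
      assigned[new_mask] <- ids
    }
    rows[[length(rows) + 1L]] <-
      data.frame(track_id = assigned, frame = f, z_um = det$z_um,
                 y_um = det$y_um, x_um = det$x_um)
    open <- data.frame(track_id = assigned, z_um = det$z_um,
                       y_um = det$y_um, x_um = det$x_um)
    prev_f <- f
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$track_id, out$frame), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Contact intervals between a macrophage track and a vessel tip
#'
#' A track point is in contact at a frame when its 3D distance to the tip
#' position at that frame is at most `contact_radius` (inclusive).
#' Maximal runs of consecutive contact frames become intervals; runs
#' separated by even one non-contact frame are never merged. Duration is
#' the time spanned between the first and last contact frame,
#' `(run length - 1) * frame_interval`, so a single-frame sighting has
#' duration 0 and a tip-cell classification at 40 min with 10-min frames
#' requires 5 consecutive contact frames. The classification is
#' inclusive: exactly 40 min is a tip cell.
#'
#' @param track Data.frame for one track: `frame`, `z_um`, `y_um`, `x_um`
#'   (and optionally `track_id`, carried through).
#' @param tip_trajectory Data.frame `frame`, `z_um`, `y_um`, `x_um`,
#'   optionally `tip_id` (default 1); multiple tips are scored
#'   independently.
#' @param contact_radius Contact distance, um (default 10, the
#'   angiogenic-region radius).
#' @param frame_interval Minutes per frame (default 10).
#' @param tipcell_min_duration Minutes, inclusive tip-cell threshold
#'   (default 40).
#' @return Data.frame `track_id`, `tip_id`, `start_frame`, `end_frame`,
#'   `n_frames`, `duration_min`, `is_tipcell` (zero rows when there is no
#'   contact).
#' @export
contact_intervals <- function(track, tip_trajectory, contact_radius = 10,
                              frame_interval = 10,
                              tipcell_min_duration = 40) {
  tid <- if (!is.null(track$track_id)) track$track_id[1] else NA_integer_
  if (is.null(tip_trajectory$tip_id)) tip_trajectory$tip_id <- 1L
  out <- list()
  for (id in unique(tip_trajectory$tip_id)) {
    tip <- tip_trajectory[tip_trajectory$tip_id == id, , drop = FALSE]
    m <- merge(track[c("frame", "z_um", "y_um", "x_um")],
               tip[c("frame", "z_um", "y_um", "x_um")],
               by = "frame", suffixes = c("", ".tip"))
    if (!nrow(m)) next
    m <- m[order(m$frame), , drop = FALSE]
    contact <- sqrt((m$z_um - m$z_um.tip)^2 + (m$y_um - m$y_um.tip)^2 +
                    (m$x_um - m$x_um.tip)^2) <= contact_radius
    # maximal runs of consecutive contact frames (frame numbers must be
    # consecutive too, not merely consecutive rows)
    if (!any(contact)) next
    cf <- m$frame[contact]
    brk <- c(TRUE, diff(cf) != 1)
    run <- cumsum(brk)
    for (rn in unique(run)) {
      fr <- cf[run == rn]
      out[[length(out) + 1L]] <- data.frame(
        track_id = tid, tip_id = id,
        start_frame = fr[1], end_frame = fr[length(fr)],
        n_frames = length(fr),
        duration_min = (length(fr) - 1) * frame_interval)
    }
  }
  if (!length(out)) {
    if (!length(intersect(track$frame, tip_trajectory$frame)))
      xv_stop("xv_no_overlap",
              "track and tip trajectory share no frames")
    res <- data.frame(track_id = integer(0), tip_id = integer(0),
                      start_frame = integer(0), end_frame = integer(0),
                      n_frames = integer(0), duration_min = numeric(0))
  } else {
    res <- do.call(rbind, out)
    res <- res[order(res$tip_id, res$start_frame), , drop = FALSE]
    rownames(res) <- NULL
  }
  res$is_tipcell <- res$duration_min >= tipcell_min_duration
  res
}

#' Migration speed during versus after tip contact
#'
#' Mean path speed over the contact interval and over an equally long
#' window immediately after it. When fewer post-contact frames are
#' available than the contact lasted, both windows are truncated to the
#' same number of steps (the during-window keeps its latest frames).
#' Speed is the summed 3D point-to-point displacement divided by the
#' window duration, in um/min; it is invariant under rigid motions of the
#' coordinate frame.
#'
#' @param track Data.frame for one track (`frame`, `z_um`, `y_um`,
#'   `x_um`), consecutive frames.
#' @param interval One row of [contact_intervals()] (needs `start_frame`,
#'   `end_frame`).
#' @param frame_interval Minutes per frame (default 10).
#' @return One-row data.frame: `track_id`, `speed_during_um_min`,
#'   `speed_after_um_min`, `window_min`, `n_steps`.
#' @export
speed_comparison <- function(track, interval, frame_interval = 10) {
  track <- track[order(track$frame), , drop = FALSE]
  n_steps <- interval$end_frame - interval$start_frame
  avail <- max(track$frame) - interval$end_frame
  n_used <- min(n_steps, avail)
  if (n_used < 1)
    xv_stop("xv_zero_window",
            "no usable window: contact spans %d step(s), %d post-contact step(s) available",
            n_steps, avail)
  during <- seq(interval$end_frame - n_used, interval$end_frame)
  after <- seq(interval$end_frame, interval$end_frame + n_used)
  path_len <- function(frames) {
    p <- track[match(frames, track$frame), c("z_um", "y_um", "x_um")]
    if (anyNA(p[[1]]))
      xv_stop("xv_zero_window", "track does not cover frames %d..%d",
              frames[1], frames[length(frames)])
    sum(sqrt(diff(p$z_um)^2 + diff(p$y_um)^2 + diff(p$x_um)^2))
  }
  dur_min <- n_used * frame_interval
  data.frame(
    track_id = if (!is.null(track$track_id)) track$track_id[1] else NA_integer_,
    speed_during_um_min = path_len(during) / dur_min,
    speed_after_um_min = path_len(after) / dur_min,
    window_min = dur_min,
    n_steps = n_used)
}

#' Fraction of tip-cell macrophages that revisit another tip
#'
#' Among tracks with at least one tip-cell interval (contact of at least
#' the tip-cell duration), the fraction whose contact intervals touch two
#' or more distinct tip identities.
#'
#' @param intervals Data.frame of [contact_intervals()] rows across
#'   tracks (needs `track_id`, `tip_id`, `is_tipcell`).
#' @return List with `n_tipcell`, `n_revisit`, `fraction`.
#' @export
revisit_fraction <- function(intervals) {
  tip_tracks <- unique(intervals$track_id[intervals$is_tipcell])
  if (!length(tip_tracks))
    xv_stop("xv_no_tipcells", "no tip-cell tracks in the interval table")
  nrev <- sum(vapply(tip_tracks, function(tr) {
    length(unique(intervals$tip_id[intervals$track_id == tr])) >= 2
  }, logical(1)))
  list(n_tipcell = length(tip_tracks), n_revisit = nrev,
       fraction = nrev / length(tip_tracks))
}
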