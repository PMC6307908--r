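#' End-to-end static quantitation of one or more stacks
#'
#' For each input stack: segment graft objects, build the area of
#' interest, segment vessels inside it, compute percentage
#' vascularisation, optionally regional percentages (when annotations
#' supply a CCV point/axis) and macrophage counts (when the stack has a
#' macrophage channel). Results are written as one CSV row per stack plus
#' a JSON summary; both are stamped with the configuration fingerprint,
#' and re-running with identical inputs reproduces them byte for byte
#' (outputs carry no timestamps).
#'
#' @param stacks A [volumetric_stack()] or list of them (optionally
#'   named; names become the `id` column).
#' @param config An [analysis_config()].
#' @param annotations Optional [annotation_set()] (or list of them, one
#'   per stack) supplying the CCV reference for regional percentages.
#' @param out_dir Optional output directory; when given, writes
#'   `graft_metrics.csv` and `summary.json` there.
#' @param group Optional character vector, one label per stack; when
#'   present and there are >= 2 groups with n >= 3, a group comparison of
#'   percentage vascularisation is run through the statistical decision
#'   tree and included in the summary.
#' @return Invisibly, a list with `metrics` (data.frame), `comparison`
#'   (an `xv_test_result` or `NULL`) and `fingerprint`.
#' @export
run_static <- function(stacks, config = analysis_config(),
                       annotations = NULL, out_dir = NULL, group = NULL) {
  if (inherits(stacks, "volumetric_stack")) stacks <- list(stacks)
  if (inherits(annotations, "annotation_set"))
    annotations <- rep(list(annotations), length(stacks))
  ids <- names(stacks)
  if (is.null(ids)) ids <- sprintf("stack%03d", seq_along(stacks))
  fp <- config_fingerprint(config)
  rows <- vector("list", length(stacks))
  for (i in seq_along(stacks)) {
    s <- stacks[[i]]
    res <- tryCatch(
      quantify_stack(s, config, annotations[[i]]),
      error = function(e) {
        xv_stop("xv_stage_failed", "stack '%s': %s", ids[i],
                conditionMessage(e))
      })
    rows[[i]] <- cbind(data.frame(id = ids[i]), res,
                       data.frame(config_fingerprint = fp))
  }
  metrics <- do.call(rbind, rows)
  comparison <- NULL
  if (!is.null(group) && length(unique(group)) >= 2) {
    samples <- split(metrics$percent_vascularisation, group)
    if (all(lengths(samples) >= 3)) {
      comparison <- if (length(samples) == 2)
        compare_two(samples[[1]], samples[[2]], config$alpha_gate)
      else
        compare_many(samples, control_index = 1,
                     alpha_gate = config$alpha_gate)
    }
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_metrics(metrics, file.path(out_dir, "graft_metrics.csv"))
    summ <- list(n_stacks = length(stacks),
                 config = unclass(config),
                 config_fingerprint = fp,
                 mean_percent_vascularisation =
                   mean(metrics$percent_vascularisation),
                 comparison = if (!is.null(comparison))
                   list(test = comparison$test_name,
                        statistic = comparison$statistic,
                        p_value = comparison$p_value))
    jsonlite::write_json(summ, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  invisible(list(metrics = metrics, comparison = comparison,
                 fingerprint = fp))
}

# One stack -> one row of graft metrics.
quantify_stack <- function(stack, config, annot = NULL) {
  if (!"graft" %in% names(stack$channel_roles))
    xv_stop("xv_unknown_role", "stack has no graft channel")
  graft <- threshold_objects(stack, "graft", config$graft_min_intensity,
                             config$graft_min_volume, config$connectivity)
  if (!n_objects(graft))
    xv_stop("xv_empty_graft", "no graft objects detected")
  aoi <- build_aoi(graft, config$aoi_mode)
  vessels <- if ("vessel" %in% names(stack$channel_roles))
    vessels_in_aoi(stack, aoi, config$vessel_min_intensity,
                   config$vessel_min_volume, config$connectivity)
  pm <- if (!is.null(vessels)) percent_vascularisation(graft, vessels)
  out <- data.frame(
    graft_volume_um3 = sum(graft$table$volume_um3),
    vessel_volume_um3 = if (!is.null(pm)) pm$vessel_volume_um3 else NA_real_,
    percent_vascularisation = if (!is.null(pm))
      pm$percent_vascularisation else NA_real_)
  out$percent_proximal <- out$percent_middle <- out$percent_distal <- NA_real_
  if (!is.null(annot) && !is.null(vessels)) {
    reg <- regional_vascularisation(graft$labels > 0L, vessels$labels > 0L,
                                    annot, stack$voxel_size)
    out$percent_proximal <- reg$percent[["proximal"]]
    out$percent_middle <- reg$percent[["middle"]]
    out$percent_distal <- reg$percent[["distal"]]
  }
  out$macrophage_count <- NA_integer_
  out$macrophages_per_1e5_um3 <- NA_real_
  if ("macrophage" %in% names(stack$channel_roles)) {
    mac <- threshold_objects(stack, "macrophage",
                             config$macrophage_min_intensity,
                             config$macrophage_min_volume,
                             config$connectivity)
    cm <- count_macrophages(mac, aoi, out$graft_volume_um3)
    out$macrophage_count <- cm$count
    out$macrophages_per_1e5_um3 <- cm$per_1e5_um3
  }
  out
}

#' End-to-end time-lapse association and tip-cell analysis
#'
#' For every frame of the analysis window: segment the vessel and
#' macrophage channels, build the angiogenic region at the annotated tip
#' and the matched control region inside the graft, and score macrophage
#' presence in both. Macrophage centroids are then linked into tracks,
#' contact intervals against the tip trajectory are classified
#' (tip-cell at >= `tipcell_min_duration`), and migration speed during
#' versus after each tip-cell contact is compared.
#'
#' @param movie A [timelapse_stack()].
#' @param annotations An [annotation_set()] with `tip_trajectory` and
#'   `analysis_window`.
#' @param config An [analysis_config()].
#' @param out_dir Optional output directory for `frame_scores.csv`,
#'   `association_summary.csv`, `tracks.csv`, `contact_intervals.csv`,
#'   `speed_comparison.csv` and `summary.json`.
#' @param max_step Maximum frame-to-frame displacement for track linking,
#'   um (default 25).
#' @return Invisibly, a list with `frame_scores`, `summary` (per region
#'   kind), `tracks`, `intervals`, `speeds`, `fingerprint`.
#' @export
run_timelapse <- function(movie, annotations, config = analysis_config(),
                          out_dir = NULL, max_step = 25) {
  if (is.null(annotations$tip_trajectory))
    xv_stop("xv_bad_annotation",
            "time-lapse analysis needs a tip trajectory annotation")
  win <- annotations$analysis_window
  if (is.null(win)) win <- range(annotations$tip_trajectory$frame)
  frames <- seq(win[1], win[2])
  if (any(frames < 1) || any(frames > n_frames(movie)))
    xv_stop("xv_bad_annotation", "analysis window outside the movie")
  fp <- config_fingerprint(config)
  traj <- annotations$tip_trajectory

  # graft geometry is static; take the mask from the first analysed frame
  f1 <- movie$frames[[frames[1]]]
  graft_mask <- threshold_objects(f1, "graft", config$graft_min_intensity,
                                  config$graft_min_volume,
                                  config$connectivity)$labels > 0L

  scores <- list()
  detections <- list()
  for (f in frames) {
    fr <- movie$frames[[f]]
    vess <- threshold_objects(fr, "vessel", config$vessel_min_intensity,
                              config$vessel_min_volume, config$connectivity)
    mac <- threshold_objects(fr, "macrophage",
                             config$macrophage_min_intensity,
                             config$macrophage_min_volume,
                             config$connectivity)
    tip_row <- traj[traj$frame == f, ][1, ]
    tip <- c(tip_row$z_um, tip_row$y_um, tip_row$x_um)
    angio <- angiogenic_region(tip, vess, config$angiogenic_radius)
    ctrl <- place_control_region(angio, graft_mask, vess$labels > 0L,
                                 config$control_offset, fr$voxel_size)
    scores[[length(scores) + 1L]] <- rbind(
      score_frame(mac, angio, f), score_frame(mac, ctrl, f))
    if (n_objects(mac))
      detections[[length(detections) + 1L]] <-
        data.frame(frame = f, z_um = mac$table$centroid_z_um,
                   y_um = mac$table$centroid_y_um,
                   x_um = mac$table$centroid_x_um)
  }
  frame_scores <- do.call(rbind, scores)
  summary_tab <- association_summary(frame_scores)

  tracks <- link_tracks(do.call(rbind, detections), max_step)
  intervals <- list()
  speeds <- list()
  for (tr in unique(tracks$track_id)) {
    tk <- tracks[tracks$track_id == tr, , drop = FALSE]
    iv <- tryCatch(
      contact_intervals(tk, traj, config$contact_radius,
                        movie$frame_interval, config$tipcell_min_duration),
      xv_no_overlap = function(e) NULL)
    if (is.null(iv) || !nrow(iv)) next
    intervals[[length(intervals) + 1L]] <- iv
    for (r in which(iv$is_tipcell)) {
      sp <- tryCatch(speed_comparison(tk, iv[r, ], movie$frame_interval),
                     xv_zero_window = function(e) NULL)
      if (!is.null(sp)) speeds[[length(speeds) + 1L]] <- sp
    }
  }
  intervals <- if (length(intervals)) do.call(rbind, intervals) else NULL
  speeds <- if (length(speeds)) do.call(rbind, speeds) else NULL

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    frame_scores$config_fingerprint <- fp
    summary_tab$config_fingerprint <- fp
    write_metrics(frame_scores, file.path(out_dir, "frame_scores.csv"))
    write_metrics(summary_tab, file.path(out_dir, "association_summary.csv"))
    write_metrics(tracks, file.path(out_dir, "tracks.csv"))
    if (!is.null(intervals))
      write_metrics(intervals, file.path(out_dir, "contact_intervals.csv"))
    if (!is.null(speeds))
      write_metrics(speeds, file.path(out_dir, "speed_comparison.csv"))
    jsonlite::write_json(
      list(config = unclass(config), config_fingerprint = fp,
           n_frames_analysed = length(frames),
           association = summary_tab[
             c("region_kind", "n_frames", "percent_frames_present",
               "mean_count")],
           n_tracks = length(unique(tracks$track_id)),
           n_tipcell_intervals = if (!is.null(intervals))
             sum(intervals$is_tipcell) else 0L),
      file.path(out_dir, "summary.json"), auto_unbox = TRUE, digits = NA,
      null = "null")
  }
  invisible(list(frame_scores = frame_scores, summary = summary_tab,
                 tracks = tracks, intervals = intervals, speeds = speeds,
                 fingerprint = fp))
}
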