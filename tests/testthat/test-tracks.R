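test_that("drifting and stationary detections link into the expected tracks", {
  det <- data.frame(frame = 1:6, z_um = 0, y_um = 0, x_um = (0:5) * 2)
  tr <- link_tracks(det, max_step = 10)
  expect_equal(length(unique(tr$track_id)), 1)
  expect_equal(tr$frame, 1:6)
  # two stationary, well-separated cells: two tracks, no identity switches
  det2 <- rbind(data.frame(frame = rep(1:5, each = 1), z_um = 0, y_um = 0,
                           x_um = 0),
                data.frame(frame = 1:5, z_um = 0, y_um = 50, x_um = 0))
  tr2 <- link_tracks(det2, max_step = 10)
  expect_equal(length(unique(tr2$track_id)), 2)
  for (id in unique(tr2$track_id))
    expect_equal(length(unique(tr2$y_um[tr2$track_id == id])), 1)
  # a jump beyond max_step starts a new track
  det3 <- data.frame(frame = 1:4, z_um = 0, y_um = 0, x_um = c(0, 2, 40, 42))
  tr3 <- link_tracks(det3, max_step = 10)
  expect_equal(length(unique(tr3$track_id)), 2)
})

test_that("crossing paths resolve to the minimal-total-displacement matching", {
  # two cells crossing in x; the greedy-from-first pairing would swap them
  det <- rbind(
    data.frame(frame = 1, z_um = 0, y_um = c(0, 1), x_um = c(0, 10)),
    data.frame(frame = 2, z_um = 0, y_um = c(0, 1), x_um = c(4, 6)),
    data.frame(frame = 3, z_um = 0, y_um = c(0, 1), x_um = c(8, 2)))
  tr <- link_tracks(det, max_step = 12)
  expect_equal(length(unique(tr$track_id)), 2)
  # oracle: enumerate both possible matchings per frame pair and keep the
  # cheaper; verify the produced assignment attains that cost
  cost_pair <- function(a, b) {
    d <- as.matrix(dist(rbind(a, b)))[1:2, 3:4]
    min(d[1, 1] + d[2, 2], d[1, 2] + d[2, 1])
  }
  f1 <- det[det$frame == 1, c("y_um", "x_um")]
  f2 <- det[det$frame == 2, c("y_um", "x_um")]
  f3 <- det[det$frame == 3, c("y_um", "x_um")]
  want <- cost_pair(f1, f2) + cost_pair(f2, f3)
  got <- 0
  for (id in unique(tr$track_id)) {
    tk <- tr[tr$track_id == id, ]
    got <- got + sum(sqrt(diff(tk$y_um)^2 + diff(tk$x_um)^2))
  }
  expect_equal(got, want)
})

tip_line <- function(n, step = 1) {
  data.frame(frame = 1:n, z_um = 0, y_um = 0, x_um = (0:(n - 1)) * step,
             tip_id = 1L)
}

test_that("contact runs become intervals with span-based durations", {
  # track touching the tip on frames 3..7 (5 frames) -> 40 min -> tip cell
  tk <- data.frame(track_id = 1L, frame = 1:10, z_um = 0, y_um = 0,
                   x_um = c(50, 50, 2, 3, 4, 5, 6, 50, 50, 50))
  tip <- tip_line(10)
  iv <- contact_intervals(tk, tip, contact_radius = 10, frame_interval = 10,
                          tipcell_min_duration = 40)
  expect_equal(nrow(iv), 1)
  expect_equal(iv$start_frame, 3)
  expect_equal(iv$end_frame, 7)
  expect_equal(iv$duration_min, 40)
  expect_true(iv$is_tipcell)
  # 4 consecutive contact frames -> 30 min -> not a tip cell
  tk4 <- tk; tk4$x_um[7] <- 50
  iv4 <- contact_intervals(tk4, tip, 10, 10, 40)
  expect_equal(iv4$duration_min, 30)
  expect_false(iv4$is_tipcell)
  # two runs separated by one non-contact frame are never merged
  tk2 <- data.frame(track_id = 2L, frame = 1:10, z_um = 0, y_um = 0,
                    x_um = c(2, 3, 50, 4, 5, 6, 7, 8, 50, 50))
  iv2 <- contact_intervals(tk2, tip, 10, 10, 40)
  expect_equal(nrow(iv2), 2)
  expect_equal(iv2$duration_min, c(10, 40))
  expect_equal(iv2$is_tipcell, c(FALSE, TRUE))
  # no shared frames at all is an error
  expect_error(
    contact_intervals(data.frame(track_id = 3L, frame = 20:25, z_um = 0,
                                 y_um = 0, x_um = 0), tip, 10, 10, 40),
    class = "xv_no_overlap")
})

test_that("speed comparison uses equal windows and plain path arithmetic", {
  # stationary during contact (frames 1..5), then 3 um per 10-min step
  tk <- data.frame(track_id = 1L, frame = 1:9, z_um = 0, y_um = 0,
                   x_um = c(0, 0, 0, 0, 0, 3, 6, 9, 12))
  iv <- data.frame(start_frame = 1, end_frame = 5)
  sp <- speed_comparison(tk, iv, frame_interval = 10)
  expect_equal(sp$speed_during_um_min, 0)
  expect_equal(sp$speed_after_um_min, 0.3)
  expect_equal(sp$window_min, 40)
  # equal stepping before and after gives equal speeds
  tk2 <- data.frame(track_id = 1L, frame = 1:9, z_um = 0, y_um = (1:9) * 2,
                    x_um = 0)
  expect_equal(with(speed_comparison(tk2, iv, 10),
                    speed_during_um_min - speed_after_um_min), 0)
  # speeds are invariant under rigid rotation + translation
  th <- 0.7
  rot <- function(df) {
    y <- df$y_um * cos(th) - df$x_um * sin(th) + 11
    x <- df$y_um * sin(th) + df$x_um * cos(th) - 4
    transform(df, y_um = y, x_um = x)
  }
  sp_r <- speed_comparison(rot(tk), iv, 10)
  expect_equal(sp_r$speed_during_um_min, sp$speed_during_um_min)
  expect_equal(sp_r$speed_after_um_min, sp$speed_after_um_min)
  # short post-contact tails truncate both windows equally
  tk3 <- tk[tk$frame <= 7, ]
  sp3 <- speed_comparison(tk3, iv, 10)
  expect_equal(sp3$n_steps, 2)
  expect_equal(sp3$window_min, 20)
  expect_error(speed_comparison(tk[tk$frame <= 5, ], iv, 10),
               class = "xv_zero_window")
})

test_that("revisit fraction counts tip-cell tracks touching several tips", {
  iv <- data.frame(track_id = c(1, 1, 2, 3, 4),
                   tip_id = c(1, 2, 1, 1, 2),
                   is_tipcell = c(TRUE, FALSE, TRUE, TRUE, TRUE))
  rf <- revisit_fraction(iv)
  expect_equal(rf$n_tipcell, 4)
  expect_equal(rf$n_revisit, 1)
  expect_equal(rf$fraction, 0.25)
  expect_error(revisit_fraction(transform(iv, is_tipcell = FALSE)),
               class = "xv_no_tipcells")
})

test_that("planted dwell durations are recovered from generator movies", {
  p <- generator_params("timelapse", dwell_prob = 1)
  g <- generate_timelapse(p, seed = 17)
  ev <- g$truth$dwell_events
  ev <- ev[!ev$truncated, , drop = FALSE]
  expect_gt(nrow(ev), 0)
  traj <- g$truth$annotations$tip_trajectory
  for (r in seq_len(nrow(ev))) {
    tk <- g$truth$tracks[g$truth$tracks$track_id == ev$track_id[r], ]
    iv <- contact_intervals(tk, traj, contact_radius = 10,
                            frame_interval = p$frame_interval,
                            tipcell_min_duration = 40)
    hit <- iv[iv$start_frame <= ev$start_frame[r] &
                iv$end_frame >= ev$end_frame[r] - 1, , drop = FALSE]
    expect_gte(nrow(hit), 1)
    expect_lte(abs(hit$duration_min[1] - ev$duration_min[r]),
               p$frame_interval)
  }
})
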