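vs8 <- c(8, 0.5, 0.5)

vessel_set <- function(v, voxel_size = vs8) {
  s <- make_stack3(array(0, dim(v)), v, array(0, dim(v)), voxel_size)
  threshold_objects(s, "vessel", 100, 1)
}

mac_set <- function(m, voxel_size = vs8) {
  s <- make_stack3(array(0, dim(m)), array(0, dim(m)), m, voxel_size)
  threshold_objects(s, "macrophage", 100, 1)
}

test_that("the angiogenic region takes the vessel's z-sections under the disc", {
  v <- array(0, c(6, 80, 80))
  v[2:4, 38:42, 38:42] <- 300            # vessel spanning z-sections 2..4
  vo <- vessel_set(v)
  tip <- c(2.5 * 8, 20, 20)              # tip on z-section 3, at (y,x)=(20,20)
  r <- angiogenic_region(tip, vo, radius = 10)
  expect_equal(r$z_slices, 2:4)
  expect_equal(r$centre_yx_um, c(20, 20))
  # no vessel voxel within the disc -> fall back to the tip's own section
  far <- c(2.5 * 8, 5, 5)
  r2 <- angiogenic_region(far, vo, radius = 3)
  expect_equal(r2$z_slices, 3L)
  expect_error(angiogenic_region(c(100, 20, 20), vo, 10),
               class = "xv_tip_out_of_bounds")
})

test_that("disc membership matches a brute-force pixel scan", {
  v <- array(0, c(4, 60, 60)); v[2, 28:32, 28:32] <- 300
  vo <- vessel_set(v)
  tip <- c(12, 15.2, 14.9)
  r <- angiogenic_region(tip, vo, radius = 10)
  disc <- xenovasc:::disc_pixels(r$centre_yx_um, 10, c(4, 60, 60), vs8)
  # oracle: scan every pixel of the plane
  cnt <- 0L
  for (iy in 1:60) for (ix in 1:60) {
    d <- sqrt(((iy - 0.5) * 0.5 - 15.2)^2 + ((ix - 0.5) * 0.5 - 14.9)^2)
    if (d <= 10) cnt <- cnt + 1L
  }
  expect_equal(length(disc$iy), cnt)
})

test_that("control placement is admissible, vessel-avoiding and deterministic", {
  dims <- c(6, 160, 160)                 # 80 x 80 um field
  graft <- array(TRUE, dims)             # graft covers the whole field
  v <- array(0, dims); v[3, 79:81, 79:81] <- 300
  vo <- vessel_set(v)
  tip <- c(20, 40, 40)
  angio <- angiogenic_region(tip, vo, radius = 10)
  vmask <- v >= 100
  ctrl <- place_control_region(angio, graft, vmask, offset = 25, vs8)
  expect_equal(ctrl$kind, "control")
  expect_equal(ctrl$radius_um, angio$radius_um)
  expect_equal(ctrl$z_slices, angio$z_slices)
  expect_equal(sqrt(sum((ctrl$centre_yx_um - angio$centre_yx_um)^2)), 25)
  # re-run: identical (tie-break by smallest angle is deterministic)
  ctrl2 <- place_control_region(angio, graft, vmask, offset = 25, vs8)
  expect_identical(ctrl$centre_yx_um, ctrl2$centre_yx_um)
  # with no vessels at all, ties resolve to angle 0
  ctrl3 <- place_control_region(angio, graft, array(FALSE, dims), 25, vs8)
  expect_equal(ctrl3$angle_deg, 0)
  # clip the graft so only one angle remains admissible
  graft2 <- array(FALSE, dims)
  # keep discs around the angiogenic region and the angle-90 candidate
  # (y = 40 + 25)
  yy <- ((1:160) - 0.5) * 0.5; xx <- yy
  for (iy in 1:160) for (ix in 1:160)
    if (sqrt((yy[iy] - 65)^2 + (xx[ix] - 40)^2) <= 11 ||
        sqrt((yy[iy] - 40)^2 + (xx[ix] - 40)^2) <= 11)
      graft2[, iy, ix] <- TRUE
  ctrl4 <- place_control_region(angio, graft2, vmask, 25, vs8)
  expect_equal(ctrl4$angle_deg, 90)
  # an impossible offset raises the named error
  expect_error(place_control_region(angio, graft2, vmask, 55, vs8),
               class = "xv_no_control_position")
})

test_that("scoring enforces both the disc radius and the z-section rule", {
  dims <- c(6, 80, 80)
  region <- structure(list(centre_yx_um = c(20, 20), radius_um = 10,
                           z_slices = 2:3, kind = "angiogenic"),
                      class = "region_spec")
  m <- array(0, dims)
  m[2, 55:57, 55:57] <- 350    # centroid ~ (12, 28, 28): 9.9+ um away? compute
  mo <- mac_set(m)
  # macrophage at distance <= radius on an in-set section is counted
  m1 <- array(0, dims); m1[2, 40:42, 40:42] <- 350   # centroid (y,x)=(20.5,20.5)
  expect_equal(score_frame(mac_set(m1), region, 1)$count, 1)
  # same xy but only on an out-of-set z-section is not counted
  m2 <- array(0, dims); m2[5, 40:42, 40:42] <- 350
  expect_equal(score_frame(mac_set(m2), region, 1)$count, 0)
  # centroid just beyond the radius is not counted
  m3 <- array(0, dims); m3[2, 40:42, 61:63] <- 350   # x ~ 31, dist ~ 11
  expect_equal(score_frame(mac_set(m3), region, 1)$count, 0)
  # counts equal a brute-force all-pairs containment check
  set.seed(41)
  m4 <- array(0, dims)
  pts <- cbind(sample(1:6, 12, TRUE), sample(5:76, 12, TRUE),
               sample(5:76, 12, TRUE))
  for (i in 1:12) m4[pts[i, 1], pts[i, 2], pts[i, 3]] <- 350
  mo4 <- mac_set(m4)
  sc <- score_frame(mo4, region, 1)
  tab <- mo4$table
  want <- 0L
  for (i in seq_len(nrow(tab))) {
    d <- sqrt((tab$centroid_y_um[i] - 20)^2 + (tab$centroid_x_um[i] - 20)^2)
    zslice <- round(tab$centroid_z_um[i] / 8 + 0.5)
    if (d <= 10 && zslice %in% 2:3) want <- want + 1L
  }
  expect_equal(sc$count, want)
})

test_that("association summaries aggregate presence and counts per region", {
  sc <- data.frame(frame = rep(1:4, 2),
                   region_kind = rep(c("angiogenic", "control"), each = 4),
                   present = c(TRUE, TRUE, FALSE, FALSE,
                               FALSE, FALSE, FALSE, TRUE),
                   count = c(0L, 1L, 2L, 1L, 0L, 0L, 0L, 1L))
  su <- association_summary(sc)
  expect_equal(su$percent_frames_present[su$region_kind == "angiogenic"], 50)
  expect_equal(su$mean_count[su$region_kind == "angiogenic"], 1)
  expect_equal(su$percent_frames_present[su$region_kind == "control"], 25)
  expect_error(association_summary(sc[0, ]), class = "xv_empty_scores")
})
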