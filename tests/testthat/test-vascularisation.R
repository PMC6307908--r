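ccv_x <- function(point = c(0, 0, 0)) {
  annotation_set(ccv_point = point, ccv_axis = c(0, 0, 1))
}

test_that("percentage vascularisation follows the volume ratio", {
  g <- array(0, c(10, 20, 20)); g[2:9, 3:18, 3:18] <- 400
  m0 <- array(0, c(10, 20, 20))
  s <- make_stack3(g, m0, m0, voxel_size = c(5, 0.5, 0.5))
  graft <- threshold_objects(s, "graft", 250, 100)
  # empty vessels -> 0%
  ves0 <- threshold_objects(s, "vessel", 100, 100)
  expect_equal(percent_vascularisation(graft, ves0)$percent_vascularisation, 0)
  # vessels identical to the graft mask -> 100%
  s2 <- make_stack3(g, g, m0, voxel_size = c(5, 0.5, 0.5))
  ves1 <- threshold_objects(s2, "vessel", 100, 100)
  expect_equal(percent_vascularisation(graft, ves1)$percent_vascularisation,
               100)
  # empty graft is an error
  s3 <- make_stack3(m0, g, m0, voxel_size = c(5, 0.5, 0.5))
  expect_error(
    percent_vascularisation(threshold_objects(s3, "graft", 250, 100), ves1),
    class = "xv_empty_graft")
})

test_that("planted vessel volume inside the AOI is recovered exactly", {
  g <- array(0, c(10, 24, 24)); g[1:10, 3:22, 3:22] <- 400  # 4000 voxels
  v <- array(0, c(10, 24, 24)); v[3:7, 6:15, 6:15] <- 300   # 500 voxels
  s <- make_stack3(g, v, array(0, dim(g)), voxel_size = c(5, 0.5, 0.5))
  graft <- threshold_objects(s, "graft", 250, 100)
  ves <- vessels_in_aoi(s, build_aoi(graft), 100, 100)
  pm <- percent_vascularisation(graft, ves)
  expect_equal(pm$percent_vascularisation, 100 * 500 / 4000)
})

test_that("regional thirds are disjoint, exhaustive and balanced", {
  set.seed(31)
  for (rep in 1:5) {
    dims <- c(6, 15, 15)
    g <- array(runif(prod(dims)) < 0.4, dims)
    if (!any(g)) next
    v <- g & array(runif(prod(dims)) < 0.3, dims)
    reg <- regional_vascularisation(g, v, ccv_x(), c(5, 0.6, 0.6))
    N <- sum(g)
    expect_equal(sum(reg$graft_voxels), N)
    expect_true(all(abs(reg$graft_voxels - N / 3) <= 1))
    expect_equal(sum(reg$region > 0), N)        # regions only on graft voxels
    expect_true(all(reg$region[!g] == 0))
    # permuting input memory layout cannot change the deterministic split
    reg2 <- regional_vascularisation(g, v, ccv_x(), c(5, 0.6, 0.6))
    expect_identical(reg$region, reg2$region)
  }
})

test_that("regional assignment matches an independent rank-based oracle", {
  set.seed(32)
  dims <- c(4, 8, 8)
  g <- array(runif(prod(dims)) < 0.5, dims)
  v <- g & array(runif(prod(dims)) < 0.5, dims)
  vs <- c(5, 0.7, 0.7)
  point <- c(3, 1, 0); axis <- c(0.2, 0.3, 0.9); axis <- axis / sqrt(sum(axis^2))
  ann <- annotation_set(point, axis)
  reg <- regional_vascularisation(g, v, ann, vs)
  # oracle: explicit loop over voxels, rank by projection, thirds with
  # remainder to proximal-most regions
  idx <- which(g); zyx <- arrayInd(idx, dims)
  s <- numeric(length(idx))
  for (i in seq_along(idx)) {
    pos <- (zyx[i, ] - 0.5) * vs
    s[i] <- sum((pos - point) * axis)
  }
  ord <- order(s, zyx[, 1], zyx[, 2], zyx[, 3])
  N <- length(idx); base <- N %/% 3; r <- N %% 3
  sizes <- base + c(r >= 1, r >= 2, 0)
  expect_equal(unname(reg$graft_voxels), sizes)
  want <- integer(N); want[ord] <- rep(1:3, sizes)
  expect_equal(reg$region[idx], want)
})

test_that("uniform vessels give equal regional percentages; proximal-only vessels score (x, 0, 0)", {
  g <- array(FALSE, c(6, 12, 12)); g[2:5, 3:10, 3:10] <- TRUE
  reg <- regional_vascularisation(g, g, ccv_x(), c(5, 0.6, 0.6))
  expect_equal(unname(reg$percent), c(100, 100, 100))
  # vessels only in the third nearest the CCV (smallest x)
  v <- g & array(rep(rep(c(TRUE, FALSE), c(4, 8)), each = 6 * 12),
                 c(6, 12, 12))
  reg2 <- regional_vascularisation(g, v, ccv_x(), c(5, 0.6, 0.6))
  expect_gt(reg2$percent[["proximal"]], 0)
  expect_equal(reg2$percent[["middle"]], 0)
  expect_equal(reg2$percent[["distal"]], 0)
})

test_that("macrophage counting uses inclusive AOI bounds and normalises per volume", {
  g <- array(0, c(10, 40, 40)); g[2:9, 5:36, 5:36] <- 400
  s <- make_stack3(g, array(0, dim(g)), array(0, dim(g)),
                   voxel_size = c(5, 0.5, 0.5))
  aoi <- build_aoi(threshold_objects(s, "graft", 250, 100))
  # synthetic object table against a point-in-box oracle
  set.seed(33)
  n <- 40
  cent <- data.frame(id = 1:n, n_voxels = 10L, volume_um3 = 12.5,
                     centroid_z_um = runif(n, 0, 50),
                     centroid_y_um = runif(n, 0, 20),
                     centroid_x_um = runif(n, 0, 20))
  fake <- structure(list(labels = array(0L, dim(g)), table = cent,
                         source_channel = "macrophage",
                         thresholds = list(min_intensity = 100,
                                           min_volume = 10,
                                           connectivity = 26L),
                         voxel_size = c(5, 0.5, 0.5)),
                    class = "object_set")
  got <- count_macrophages(fake, aoi, 2e5)
  lo <- (aoi$extent[, "lo"] - 1) * c(5, 0.5, 0.5)
  hi <- aoi$extent[, "hi"] * c(5, 0.5, 0.5)
  want <- sum(cent$centroid_z_um >= lo[1] & cent$centroid_z_um <= hi[1] &
              cent$centroid_y_um >= lo[2] & cent$centroid_y_um <= hi[2] &
              cent$centroid_x_um >= lo[3] & cent$centroid_x_um <= hi[3])
  expect_equal(got$count, want)
  expect_equal(got$per_1e5_um3, want * 1e5 / 2e5)
  # centroid exactly on a boundary face is counted
  cent2 <- cent[1, ]; cent2$centroid_z_um <- lo[1]
  cent2$centroid_y_um <- mean(c(lo[2], hi[2]))
  cent2$centroid_x_um <- mean(c(lo[3], hi[3]))
  fake2 <- fake; fake2$table <- cent2
  expect_equal(count_macrophages(fake2, aoi, 2e5)$count, 1)
  expect_error(count_macrophages(fake, aoi, 0), class = "xv_zero_graft_volume")
})

test_that("secretion index is concentration per protein, per well", {
  expect_equal(secretion_index(100, 50), 2)
  expect_equal(secretion_index(0, 50), 0)
  expect_error(secretion_index(100, 0), class = "xv_bad_protein")
  # replicate mean of indices differs from index of means when protein differs
  v <- c(100, 80); p <- c(50, 20)
  expect_false(isTRUE(all.equal(mean(secretion_index(v, p)),
                                sum(v) / sum(p))))
  # ... but matches when protein content is equal
  p2 <- c(40, 40)
  expect_equal(mean(secretion_index(v, p2)), mean(v) / 40)
})
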