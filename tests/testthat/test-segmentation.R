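test_that("empty and all-background channels give zero objects", {
  s <- make_stack(array(0, c(6, 12, 12)))
  o <- threshold_objects(s, "graft", 250, 100)
  expect_equal(n_objects(o), 0)
  expect_equal(sum(o$labels), 0)
  expect_error(threshold_objects(s, "vessel", 100, 100),
               class = "xv_unknown_role")
})

test_that("the minimum-volume filter is inclusive and exact in um^3", {
  # voxel volume 1.25 um^3: 79 voxels = 98.75 um^3 rejected,
  # 80 voxels = 100 um^3 retained under the 100 um^3 minimum
  arr <- array(0, c(6, 20, 20))
  arr[2, 2:10, 2:10] <- 300; arr[2, 10, 10] <- 0   # 80-voxel blob
  arr[5, 2:10, 2:10] <- 300                        # 81 voxels...
  arr[5, 10, 9:10] <- 0                            # -> 79-voxel blob
  expect_equal(sum(arr[2, , ] > 0), 80)
  expect_equal(sum(arr[5, , ] > 0), 79)
  s <- make_stack(arr, voxel_size = c(5, 0.5, 0.5))
  o <- threshold_objects(s, "graft", 250, 100)
  expect_equal(n_objects(o), 1)
  expect_equal(o$table$volume_um3, 100)
  expect_equal(o$table$n_voxels, 80)
})

test_that("component labelling matches the brute-force flood fill", {
  set.seed(21)
  for (rep in 1:25) {
    dims <- sample(4:12, 3, replace = TRUE)
    conn <- sample(c(6L, 18L, 26L), 1)
    mask <- array(runif(prod(dims)) < 0.35, dims)
    arr <- array(0, dims); arr[mask] <- 300
    s <- make_stack(arr, voxel_size = c(1, 1, 1))
    o <- threshold_objects(s, "graft", 1, 1, connectivity = conn)
    ref <- oracle_label(mask, conn)
    expect_true(same_partition(o$labels, ref))
    # per-object voxel counts agree as multisets
    expect_equal(sort(o$table$n_voxels),
                 sort(as.integer(table(ref[ref > 0]))))
  }
})

test_that("objects are ordered by decreasing volume with spatial tie-breaks", {
  arr <- array(0, c(4, 12, 12))
  arr[1, 1:2, 1:2] <- 300   # 4 voxels
  arr[3, 5:7, 5:7] <- 300   # 9 voxels
  arr[1, 10:11, 10:11] <- 300  # 4 voxels, larger z? same z, larger y
  s <- make_stack(arr, voxel_size = c(1, 1, 1))
  o <- threshold_objects(s, "graft", 1, 1)
  expect_equal(o$table$n_voxels, c(9L, 4L, 4L))
  # ties: the 4-voxel object with the smaller centroid y comes first
  expect_lt(o$table$centroid_y_um[2], o$table$centroid_y_um[3])
})

test_that("raising thresholds never increases retained volume or count", {
  set.seed(22)
  arr <- array(sample(0:400, 6 * 16 * 16, TRUE), c(6, 16, 16))
  s <- make_stack(arr, voxel_size = c(2, 1, 1))
  vol_at <- function(int, mv) {
    o <- threshold_objects(s, "graft", int, mv)
    c(sum(o$table$volume_um3), n_objects(o))
  }
  v1 <- vol_at(100, 2); v2 <- vol_at(200, 2); v3 <- vol_at(300, 2)
  expect_true(v1[1] >= v2[1] && v2[1] >= v3[1])
  c1 <- vol_at(150, 2)[2]; c2 <- vol_at(150, 8)[2]; c3 <- vol_at(150, 20)[2]
  expect_true(c1 >= c2 && c2 >= c3)
})

test_that("bounding-box AOI is minimal and mask AOI conserves volume", {
  arr <- array(0, c(6, 24, 12))
  arr[3:5, 11:21, 6] <- 300
  s <- make_stack(arr, voxel_size = c(5, 0.5, 0.5))
  o <- threshold_objects(s, "graft", 250, 1)
  box <- build_aoi(o, "bounding_box")
  expect_equal(unname(box$extent["z", ]), c(3, 5))
  expect_equal(unname(box$extent["y", ]), c(11, 21))
  expect_equal(unname(box$extent["x", ]), c(6, 6))
  expect_equal(box$volume_um3, 3 * 11 * 1 * 1.25)
  msk <- build_aoi(o, "mask")
  expect_equal(msk$volume_um3, sum(o$table$volume_um3))
  # empty set cannot give a box
  empty <- threshold_objects(make_stack(array(0, c(2, 2, 2))), "graft", 250, 1)
  expect_error(build_aoi(empty, "bounding_box"), class = "xv_empty_objects")
})

test_that("vessels are clipped at the AOI boundary before labelling", {
  g <- array(0, c(4, 20, 20)); g[2:3, 5:10, 5:10] <- 400
  v <- array(0, c(4, 20, 20)); v[2, 5:10, 3:14] <- 300  # tube sticking out
  s <- make_stack3(g, v, array(0, c(4, 20, 20)), voxel_size = c(5, 1, 1))
  graft <- threshold_objects(s, "graft", 250, 1)
  aoi <- build_aoi(graft, "bounding_box")
  ves <- vessels_in_aoi(s, aoi, 100, 1)
  # only x 5..10 survive inside the box
  expect_equal(sum(ves$table$n_voxels), 6 * 6)
  # oracle: mask then flood
  inc <- array(FALSE, c(4, 20, 20)); inc[2:3, 5:10, 5:10] <- TRUE
  ref <- oracle_label((v >= 100) & inc, 26)
  expect_true(same_partition(ves$labels, ref))
  # all-zero vessel channel
  s0 <- make_stack3(g, array(0, c(4, 20, 20)), array(0, c(4, 20, 20)),
                    voxel_size = c(5, 1, 1))
  expect_equal(n_objects(vessels_in_aoi(s0, aoi, 100, 1)), 0)
})
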