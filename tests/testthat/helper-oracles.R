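# Independent reference implementations used as oracles.

# Brute-force flood fill over a logical 3D mask: grow each component by
# repeated whole-neighbourhood expansion until it stops changing.
# Independent of the package's scan-order labelling.
oracle_label <- function(mask, connectivity = 26) {
  dims <- dim(mask)
  offs <- expand.grid(dz = -1:1, dy = -1:1, dx = -1:1)
  m <- abs(offs$dz) + abs(offs$dy) + abs(offs$dx)
  keep <- m > 0 & ((connectivity == 26) | (connectivity == 18 & m <= 2) |
                     (connectivity == 6 & m <= 1))
  offs <- as.matrix(offs[keep, ])
  labels <- array(0L, dims)
  lab <- 0L
  for (seed in which(mask)) {
    if (labels[seed] != 0L) next
    lab <- lab + 1L
    comp <- array(FALSE, dims)
    comp[seed] <- TRUE
    repeat {
      cur <- which(comp)
      zyx <- arrayInd(cur, dims)
      grown <- comp
      for (k in seq_len(nrow(offs))) {
        nb <- zyx + rep(offs[k, ], each = nrow(zyx))
        ok <- nb[, 1] >= 1 & nb[, 1] <= dims[1] &
              nb[, 2] >= 1 & nb[, 2] <= dims[2] &
              nb[, 3] >= 1 & nb[, 3] <= dims[3]
        if (any(ok)) grown[nb[ok, , drop = FALSE]] <- TRUE
      }
      grown <- grown & mask
      if (identical(grown, comp)) break
      comp <- grown
    }
    labels[comp] <- lab
  }
  labels
}

# Two labelings induce the same partition of the foreground?
same_partition <- function(l1, l2) {
  idx <- which(l1 > 0)
  if (!identical(idx, which(l2 > 0))) return(FALSE)
  a <- l1[idx]; b <- l2[idx]
  length(unique(a)) == length(unique(paste(a, b))) &&
    length(unique(b)) == length(unique(paste(a, b)))
}

# Single-channel stack from a 3D intensity array.
make_stack <- function(arr, voxel_size = c(5, 0.6, 0.6), role = "graft") {
  roles <- stats::setNames(1L, role)
  volumetric_stack(array(arr, c(dim(arr), 1L)), roles, voxel_size)
}

# Three-channel stack from graft/vessel/macrophage arrays.
make_stack3 <- function(g, v, m, voxel_size = c(5, 0.6, 0.6)) {
  vox <- array(0, c(dim(g), 3L))
  vox[, , , 1] <- g; vox[, , , 2] <- v; vox[, , , 3] <- m
  volumetric_stack(vox, c(graft = 1L, vessel = 2L, macrophage = 3L),
                   voxel_size)
}
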