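# Rendering helpers ---------------------------------------------------------

# Paint all voxels whose centre lies within `radius` um of the segment
# p0 -> p1 (positions in um, (z, y, x)) with at least `value`.
paint_capsule <- function(arr, p0, p1, radius, voxel_size, value) {
  dims <- dim(arr)
  lo <- pmin(p0, p1) - radius; hi <- pmax(p0, p1) + radius
  i_lo <- pmax(floor(lo / voxel_size) + 1, 1)
  i_hi <- pmin(ceiling(hi / voxel_size), dims)
  if (any(i_lo > i_hi)) return(arr)
  zz <- i_lo[1]:i_hi[1]; yy <- i_lo[2]:i_hi[2]; xx <- i_lo[3]:i_hi[3]
  g <- expand.grid(z = (zz - 0.5) * voxel_size[1],
                   y = (yy - 0.5) * voxel_size[2],
                   x = (xx - 0.5) * voxel_size[3])
  d <- p1 - p0
  len2 <- sum(d^2)
  if (len2 == 0) {
    t <- 0
    dist2 <- (g$z - p0[1])^2 + (g$y - p0[2])^2 + (g$x - p0[3])^2
  } else {
    t <- pmin(pmax(((g$z - p0[1]) * d[1] + (g$y - p0[2]) * d[2] +
                      (g$x - p0[3]) * d[3]) / len2, 0), 1)
    dist2 <- (g$z - (p0[1] + t * d[1]))^2 + (g$y - (p0[2] + t * d[2]))^2 +
             (g$x - (p0[3] + t * d[3]))^2
  }
  sel <- which(dist2 <= radius^2)
  if (length(sel)) {
    gi <- expand.grid(z = zz, y = yy, x = xx)
    idx <- cbind(gi$z[sel], gi$y[sel], gi$x[sel])
    arr[idx] <- pmax(arr[idx], value)
  }
  arr
}

paint_sphere <- function(arr, centre, radius, voxel_size, value) {
  paint_capsule(arr, centre, centre, radius, voxel_size, value)
}

# Logical ellipsoid mask over the whole grid (voxel-centre rule).
ellipsoid_mask <- function(dims, voxel_size, centre, semiaxes) {
  az <- (((seq_len(dims[1]) - 0.5) * voxel_size[1] - centre[1]) / semiaxes[1])^2
  ay <- (((seq_len(dims[2]) - 0.5) * voxel_size[2] - centre[2]) / semiaxes[2])^2
  ax <- (((seq_len(dims[3]) - 0.5) * voxel_size[3] - centre[3]) / semiaxes[3])^2
  outer(outer(az, ay, `+`), ax, `+`) <= 1
}

apply_noise <- function(arr, sd_abs, poisson) {
  dims <- dim(arr)
  if (sd_abs > 0)
    arr <- arr + stats::rnorm(length(arr), 0, sd_abs)
  if (poisson)
    arr <- stats::rpois(length(arr), pmax(arr, 0))
  arr <- round(pmin(pmax(arr, 0), 65535))
  dim(arr) <- dims
  arr
}

# Parameters -----------------------------------------------------------------

#' Synthetic xenograft generator parameters
#'
#' Defaults emulate the imaged study conditions: a roughly 50-um-scale
#' ellipsoidal graft in the perivitelline space, imaged at 5-um optical
#' sections (static) or 8-um sections every 10 minutes (time-lapse), with
#' vessels sprouting from the common-cardinal-vein (CCV) side of the
#' graft along +x, and point-like macrophages performing a random walk
#' with stochastic dwell events at the growing vessel tip. Foreground
#' intensities (400/300/350 detector units) sit well above the default
#' detection thresholds (250/100/100); the `"clean"` preset is noise free
#' so recovery of planted quantities is exact, `"noisy"` adds Gaussian
#' noise with sd equal to 5% of the graft intensity, and `"null-dwell"`
#' switches dwell behaviour off (the association null model).
#'
#' @param kind `"static"` (single z-stack) or `"timelapse"`.
#' @param preset `"clean"`, `"noisy"` or `"null-dwell"`.
#' @param ... Named overrides of any default listed below.
#' @return A list of class `generator_params`. Key fields: `dim`
#'   (z, y, x voxels), `voxel_size` (um), `graft_centre_um`,
#'   `graft_semiaxes_um`, channel intensities, `ccv_point`/`ccv_axis`,
#'   `n_vessels`, `vessel_radius_um`, `target_vessel_fraction`,
#'   `n_macrophages`, `macrophage_radius_um`, `noise_sd_frac`,
#'   `poisson_noise`; for time-lapse additionally `n_frames`,
#'   `frame_interval`, `vessel_root_um`, `tip_start_x_um`,
#'   `elongation_um_per_frame`, `sigma_free`, `sigma_free_z`,
#'   `sigma_dwell`, `capture_radius_um`, `dwell_prob`,
#'   `dwell_duration_min`, `refractory_min`, `n_seeded_near_tip`.
#' @export
generator_params <- function(kind = c("static", "timelapse"),
                             preset = c("clean", "noisy", "null-dwell"),
                             ...) {
  kind <- match.arg(kind)
  preset <- match.arg(preset)
  p <- if (kind == "static") {
    list(kind = kind,
         dim = c(14L, 100L, 100L),
         voxel_size = c(5, 0.6, 0.6),
         graft_centre_um = c(35, 30, 30),
         graft_semiaxes_um = c(25, 24, 24),
         graft_intensity = 400,
         vessel_intensity = 300,
         macrophage_intensity = 350,
         ccv_point = c(35, 30, 0),
         ccv_axis = c(0, 0, 1),
         n_vessels = 3L,
         vessel_radius_um = 3,
         target_vessel_fraction = 0.25,
         n_macrophages = 6L,
         macrophage_radius_um = 4,
         noise_sd_frac = 0,
         poisson_noise = FALSE)
  } else {
    list(kind = kind,
         dim = c(8L, 128L, 128L),
         voxel_size = c(8, 0.6, 0.6),
         graft_centre_um = c(32, 38.4, 38),
         graft_semiaxes_um = c(16, 32, 34),
         graft_intensity = 400,
         vessel_intensity = 300,
         macrophage_intensity = 350,
         ccv_point = c(32, 38.4, 0),
         ccv_axis = c(0, 0, 1),
         vessel_radius_um = 3,
         vessel_root_um = c(28, 38.4, 6),
         tip_start_x_um = 20,
         elongation_um_per_frame = 0.8,
         n_frames = 18L,
         frame_interval = 10,
         n_macrophages = 8L,
         macrophage_radius_um = 4,
         sigma_free = 6,
         sigma_free_z = 2,
         sigma_dwell = 0.1,
         capture_radius_um = 10,
         dwell_prob = 0.8,
         dwell_duration_min = 70,
         refractory_min = 70,
         n_seeded_near_tip = 3L,
         noise_sd_frac = 0,
         poisson_noise = FALSE)
  }
  if (preset == "noisy") p$noise_sd_frac <- 0.05
  if (preset == "null-dwell") {
    if (kind != "timelapse")
      xv_stop("xv_bad_config", "the null-dwell preset is a time-lapse preset")
    p$dwell_prob <- 0
    p$n_seeded_near_tip <- 0L
  }
  over <- list(...)
  bad <- setdiff(names(over), names(p))
  if (length(bad))
    xv_stop("xv_bad_config", "unknown generator parameter(s): %s",
            paste(bad, collapse = ", "))
  p[names(over)] <- over
  if (!is.null(p$sigma_dwell) && p$sigma_dwell > p$sigma_free)
    xv_stop("xv_bad_config", "sigma_dwell must not exceed sigma_free")
  structure(p, class = "generator_params")
}

# Static generator -----------------------------------------------------------

#' Generate a synthetic static xenograft stack with known ground truth
#'
#' Builds a three-channel z-stack: an ellipsoidal graft at constant
#' intensity, vessel tubes entering from the CCV (x = 0) side and grown
#' voxel-by-voxel (lengthwise, then in thickness) until the planted
#' vascular fraction of the graft is hit exactly in voxel units, and
#' spherical macrophages at sampled in-graft positions. Noise, if any, is
#' applied last. Identical `(params, seed)` give bit-identical output;
#' the caller's random-number state is untouched.
#'
#' @param params [generator_params()] of kind `"static"`.
#' @param seed Integer seed.
#' @return List with `stack` (a [volumetric_stack()]) and `truth`, a list
#'   holding `graft_mask`, `vessel_mask`, `n_graft_voxels`,
#'   `graft_volume_um3`, `vessel_fraction` (realised, exact),
#'   `vessel_volume_um3`, `macrophage_centres_um` (data.frame),
#'   `region_fractions` (per proximal/middle/distal third along the CCV
#'   axis) and `annotations` (an [annotation_set()]).
#' @export
generate_static <- function(params = generator_params("static"), seed = 1L) {
  stopifnot(inherits(params, "generator_params"), params$kind == "static")
  with_fixed_rng(as.integer(seed), generate_static_impl(params))
}

generate_static_impl <- function(p) {
  dims <- p$dim; d <- p$voxel_size
  vv <- prod(d)
  graft <- ellipsoid_mask(dims, d, p$graft_centre_um, p$graft_semiaxes_um)
  idx <- which(graft)
  N <- length(idx)
  if (!N) xv_stop("xv_bad_config", "graft ellipsoid contains no voxels")
  f <- p$target_vessel_fraction
  if (f < 0 || f > 1)
    xv_stop("xv_fraction_unreachable",
            "target vessel fraction %.3g is not reachable within the graft", f)
  k <- round(f * N)

  zyx <- arrayInd(idx, dims)
  pos <- sweep(zyx - 0.5, 2, d, `*`)

  vessel_mask <- array(FALSE, dims)
  if (k > 0) {
    # vessel skeletons: rays entering at x = 0 on the CCV side, heading +x
    dmin <- rep(Inf, N); tmin <- rep(Inf, N)
    for (vno in seq_len(p$n_vessels)) {
      p0 <- c(p$graft_centre_um[1] +
                stats::runif(1, -0.5, 0.5) * p$graft_semiaxes_um[1],
              p$graft_centre_um[2] +
                stats::runif(1, -0.6, 0.6) * p$graft_semiaxes_um[2],
              0)
      u <- c(stats::runif(1, -0.15, 0.15), stats::runif(1, -0.15, 0.15), 1)
      u <- u / sqrt(sum(u^2))
      rel_z <- pos[, 1] - p0[1]; rel_y <- pos[, 2] - p0[2]
      rel_x <- pos[, 3] - p0[3]
      t <- pmax(rel_z * u[1] + rel_y * u[2] + rel_x * u[3], 0)
      dd <- sqrt((rel_z - t * u[1])^2 + (rel_y - t * u[2])^2 +
                 (rel_x - t * u[3])^2)
      upd <- dd < dmin
      dmin[upd] <- dd[upd]; tmin[upd] <- t[upd]
    }
    ord <- order(dmin, tmin, zyx[, 1], zyx[, 2], zyx[, 3])
    vessel_mask[idx[ord[seq_len(k)]]] <- TRUE
  }

  # macrophages: separated positions at graft voxel centres
  centres <- matrix(numeric(0), 0, 3)
  tries <- 0L
  while (nrow(centres) < p$n_macrophages && tries < 2000L) {
    tries <- tries + 1L
    cand <- pos[sample.int(N, 1L), ]
    if (nrow(centres) == 0 ||
        min(sqrt(colSums((t(centres) - cand)^2))) >
          2 * p$macrophage_radius_um + 2)
      centres <- rbind(centres, cand)
  }

  gch <- array(0, dims); gch[graft] <- p$graft_intensity
  vch <- array(0, dims); vch[vessel_mask] <- p$vessel_intensity
  mch <- array(0, dims)
  for (i in seq_len(nrow(centres)))
    mch <- paint_sphere(mch, centres[i, ], p$macrophage_radius_um, d,
                        p$macrophage_intensity)

  sd_abs <- p$noise_sd_frac * p$graft_intensity
  gch <- apply_noise(gch, sd_abs, p$poisson_noise)
  vch <- apply_noise(vch, p$noise_sd_frac * p$vessel_intensity,
                     p$poisson_noise)
  mch <- apply_noise(mch, p$noise_sd_frac * p$macrophage_intensity,
                     p$poisson_noise)
  vox <- array(0, c(dims, 3L))
  vox[, , , 1] <- gch; vox[, , , 2] <- vch; vox[, , , 3] <- mch
  stack <- volumetric_stack(vox, c(graft = 1L, vessel = 2L, macrophage = 3L),
                            d)

  # generator-side regional bookkeeping: thirds along the CCV axis by
  # voxel rank, remainder to the proximal-most regions
  s <- pos[, 3]  # axis is +x by construction
  rord <- order(s, zyx[, 1], zyx[, 2], zyx[, 3])
  base <- N %/% 3L; r <- N %% 3L
  sizes <- base + c(r >= 1L, r >= 2L, 0L)
  reg <- integer(N); reg[rord] <- rep.int(1:3, sizes)
  ves <- vessel_mask[idx]
  reg_g <- tabulate(reg, 3L)
  reg_v <- tabulate(reg[ves], 3L)
  region_fractions <- stats::setNames(reg_v / reg_g,
                                      c("proximal", "middle", "distal"))

  truth <- list(
    graft_mask = graft,
    vessel_mask = vessel_mask,
    n_graft_voxels = N,
    graft_volume_um3 = N * vv,
    vessel_fraction = k / N,
    vessel_volume_um3 = k * vv,
    macrophage_centres_um = data.frame(z_um = centres[, 1],
                                       y_um = centres[, 2],
                                       x_um = centres[, 3]),
    region_fractions = region_fractions,
    annotations = annotation_set(ccv_point = p$ccv_point,
                                 ccv_axis = p$ccv_axis))
  list(stack = stack, truth = truth)
}

# Time-lapse generator -------------------------------------------------------

#' Generate a synthetic time-lapse movie with known ground truth
#'
#' One designated vessel elongates along +x from the CCV side at a
#' constant rate; its tip trajectory is recorded per frame. Macrophages
#' perform a random walk inside the graft (proposed steps leaving the
#' graft are rejected). When a free walker comes within
#' `capture_radius_um` of the tip it enters a dwell state with
#' probability `dwell_prob`: it snaps to 1 um from the tip, then moves
#' with jitter `sigma_dwell` around that anchor for `dwell_duration_min`
#' minutes of spanned time. On release it retreats from the tip at the
#' free step size and cannot be recaptured for `refractory_min` minutes
#' (dissociated macrophages resume normal migration). All dwell events
#' are logged. `n_seeded_near_tip` walkers start near the tip so planted
#' presets reliably produce associations.
#'
#' @param params [generator_params()] of kind `"timelapse"`.
#' @param seed Integer seed.
#' @return List with `movie` (a [timelapse_stack()]) and `truth`: a list
#'   with `graft_mask`, `tracks` (data.frame `track_id`, `frame`, `z_um`,
#'   `y_um`, `x_um`, `state`), `dwell_events` (data.frame `track_id`,
#'   `tip_id`, `start_frame`, `end_frame`, `duration_min`, `truncated`),
#'   and `annotations` (tip trajectory plus analysis window covering all
#'   frames).
#' @export
generate_timelapse <- function(params = generator_params("timelapse"),
                               seed = 1L) {
  stopifnot(inherits(params, "generator_params"),
            params$kind == "timelapse")
  if (params$n_frames < 2L)
    xv_stop("xv_bad_config", "need at least 2 frames")
  with_fixed_rng(as.integer(seed), generate_timelapse_impl(params))
}

generate_timelapse_impl <- function(p) {
  dims <- p$dim; d <- p$voxel_size
  graft <- ellipsoid_mask(dims, d, p$graft_centre_um, p$graft_semiaxes_um)
  in_graft <- function(q) {
    all(q >= 0) &&
      sum(((q - p$graft_centre_um) / p$graft_semiaxes_um)^2) <= 1
  }
  nf <- p$n_frames
  tip <- cbind(z_um = rep(p$vessel_root_um[1], nf),
               y_um = rep(p$vessel_root_um[2], nf),
               x_um = p$tip_start_x_um +
                 (seq_len(nf) - 1) * p$elongation_um_per_frame)

  nm <- p$n_macrophages
  state <- rep("free", nm)        # free | dwell | refractory
  timer <- integer(nm)            # frames remaining in dwell/refractory
  anchor <- matrix(NA_real_, nm, 3)
  posn <- matrix(NA_real_, nm, 3)
  dwell_frames <- round(p$dwell_duration_min / p$frame_interval)
  refr_frames <- round(p$refractory_min / p$frame_interval)

  # initial positions: seeded walkers near the initial tip, the rest
  # uniform over graft voxel centres at the vessel's z
  gidx <- which(graft)
  gzyx <- arrayInd(gidx, dims)
  gpos <- sweep(gzyx - 0.5, 2, d, `*`)
  for (i in seq_len(nm)) {
    if (i <= p$n_seeded_near_tip) {
      # staggered starting distances so planted dwell events spread over
      # the window (~60% coverage) instead of coinciding
      r0 <- 6 + 6 * (i - 1) / max(1L, p$n_seeded_near_tip - 1L)
      repeat {
        th <- stats::runif(1, 0, 2 * pi)
        cand <- tip[1, ] + c(stats::runif(1, -2, 2),
                             r0 * sin(th), r0 * cos(th))
        if (in_graft(cand)) break
      }
    } else {
      # unseeded walkers are spread through the whole graft volume, so
      # most sit on other optical sections than the vessel
      cand <- gpos[sample.int(nrow(gpos), 1L), ]
    }
    posn[i, ] <- cand
  }

  tracks <- vector("list", nf)
  events <- list()
  open_event <- vector("list", nm)
  frames_list <- vector("list", nf)

  for (f in seq_len(nf)) {
    tipf <- tip[f, ]
    for (i in seq_len(nm)) {
      if (f > 1L) {
        if (state[i] == "dwell") {
          posn[i, ] <- anchor[i, ] +
            stats::rnorm(3, 0, p$sigma_dwell) * c(0.2, 1, 1)
          timer[i] <- timer[i] - 1L
          if (timer[i] <= 0L) {
            ev <- open_event[[i]]
            ev$end_frame <- f
            ev$truncated <- FALSE
            events[[length(events) + 1L]] <- ev
            open_event[i] <- list(NULL)
            state[i] <- "refractory"
            timer[i] <- refr_frames
          }
          next
        }
        # free or refractory motion
        if (state[i] == "refractory") {
          timer[i] <- timer[i] - 1L
          if (timer[i] <= 0L) state[i] <- "free"
          dist_tip <- sqrt(sum((posn[i, ] - tipf)^2))
          if (dist_tip <= p$capture_radius_um + p$sigma_free) {
            dirv <- posn[i, ] - tipf
            nv <- sqrt(sum(dirv^2))
            if (nv < 1e-9) dirv <- c(0, 0, 1) else dirv <- dirv / nv
            cand <- posn[i, ] + dirv * p$sigma_free
          } else {
            cand <- posn[i, ] + c(stats::rnorm(1, 0, p$sigma_free_z),
                                  stats::rnorm(1, 0, p$sigma_free),
                                  stats::rnorm(1, 0, p$sigma_free))
          }
        } else {
          cand <- posn[i, ] + c(stats::rnorm(1, 0, p$sigma_free_z),
                                stats::rnorm(1, 0, p$sigma_free),
                                stats::rnorm(1, 0, p$sigma_free))
        }
        if (in_graft(cand)) posn[i, ] <- cand
      }
      # capture check for free walkers (also on the first frame)
      if (state[i] == "free" &&
          sqrt(sum((posn[i, ] - tipf)^2)) <= p$capture_radius_um &&
          stats::runif(1) < p$dwell_prob) {
        dirv <- posn[i, ] - tipf
        nv <- sqrt(sum(dirv^2))
        if (nv < 1e-9) dirv <- c(0, 0, 1) else dirv <- dirv / nv
        anchor[i, ] <- tipf + dirv * 1.0
        posn[i, ] <- anchor[i, ] +
          stats::rnorm(3, 0, p$sigma_dwell) * c(0.2, 1, 1)
        state[i] <- "dwell"
        timer[i] <- dwell_frames
        open_event[[i]] <- data.frame(track_id = i, tip_id = 1L,
                                      start_frame = f, end_frame = NA_integer_,
                                      truncated = NA)
      }
    }
    tracks[[f]] <- data.frame(track_id = seq_len(nm), frame = f,
                              z_um = posn[, 1], y_um = posn[, 2],
                              x_um = posn[, 3], state = state)

    # render the frame
    gch <- array(0, dims); gch[graft] <- p$graft_intensity
    vch <- array(0, dims)
    vch <- paint_capsule(vch, p$vessel_root_um, tipf, p$vessel_radius_um,
                         d, p$vessel_intensity)
    mch <- array(0, dims)
    for (i in seq_len(nm))
      mch <- paint_sphere(mch, posn[i, ], p$macrophage_radius_um, d,
                          p$macrophage_intensity)
    if (p$noise_sd_frac > 0 || p$poisson_noise) {
      gch <- apply_noise(gch, p$noise_sd_frac * p$graft_intensity,
                         p$poisson_noise)
      vch <- apply_noise(vch, p$noise_sd_frac * p$vessel_intensity,
                         p$poisson_noise)
      mch <- apply_noise(mch, p$noise_sd_frac * p$macrophage_intensity,
                         p$poisson_noise)
    }
    vox <- array(0, c(dims, 3L))
    vox[, , , 1] <- gch; vox[, , , 2] <- vch; vox[, , , 3] <- mch
    frames_list[[f]] <- volumetric_stack(
      vox, c(graft = 1L, vessel = 2L, macrophage = 3L), d)
  }
  # close any dwell still open at the last frame
  for (i in seq_len(nm)) {
    if (!is.null(open_event[[i]])) {
      ev <- open_event[[i]]
      ev$end_frame <- nf
      ev$truncated <- TRUE
      events[[length(events) + 1L]] <- ev
    }
  }
  events <- if (length(events)) do.call(rbind, events) else
    data.frame(track_id = integer(0), tip_id = integer(0),
               start_frame = integer(0), end_frame = integer(0),
               truncated = logical(0))
  if (nrow(events)) {
    events$duration_min <- (events$end_frame - events$start_frame) *
      p$frame_interval
    events <- events[order(events$track_id, events$start_frame), ]
    rownames(events) <- NULL
  } else events$duration_min <- numeric(0)

  traj <- data.frame(frame = seq_len(nf), z_um = tip[, "z_um"],
                     y_um = tip[, "y_um"], x_um = tip[, "x_um"],
                     tip_id = 1L)
  truth <- list(
    graft_mask = graft,
    tracks = do.call(rbind, tracks),
    dwell_events = events,
    annotations = annotation_set(ccv_point = p$ccv_point,
                                 ccv_axis = p$ccv_axis,
                                 analysis_window = c(1L, nf),
                                 tip_trajectory = traj))
  list(movie = timelapse_stack(frames_list, p$frame_interval),
       truth = truth)
}
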