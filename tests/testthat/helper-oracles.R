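# Independent oracles and fixture builders shared across the suite.
# Everything here is deliberately brute-force and independent of the
# package's own code paths.

# build a lattice from an explicit voxel coordinate matrix (x, y, z 1-based)
lattice_from_voxels <- function(xyz, dims, voxel_edge = 1, pop = 1L) {
  st <- array(0L, dim = dims)
  st[cbind(xyz[, 1L], xyz[, 2L], xyz[, 3L])] <- pop
  new_lattice(dims, voxel_edge, st)
}

# axis-aligned solid cuboid of nx x ny x nz voxels at a given corner
cuboid_lattice <- function(nx, ny, nz, dims = c(nx + 10L, ny + 10L, nz + 5L),
                           voxel_edge = 1, corner = c(5L, 5L, 0L)) {
  g <- expand.grid(x = seq_len(nx) + corner[1L],
                   y = seq_len(ny) + corner[2L],
                   z = seq_len(nz) + corner[3L])
  lattice_from_voxels(as.matrix(g), dims, voxel_edge)
}

# voxelised hemisphere (radius in voxels) resting on the base plane
hemisphere_lattice <- function(radius, voxel_edge = 1,
                               dims = rep(2L * ceiling(radius) + 12L, 3L)) {
  cx <- dims[1L] / 2; cy <- dims[2L] / 2
  g <- expand.grid(x = seq_len(dims[1L]), y = seq_len(dims[2L]),
                   z = seq_len(dims[3L]))
  d2 <- (g$x - 0.5 - cx)^2 + (g$y - 0.5 - cy)^2 + (g$z - 0.5)^2
  lattice_from_voxels(as.matrix(g[d2 <= radius^2, ]), dims, voxel_edge)
}

# brute-force minimum-area bounding rectangle of a footprint (voxel columns
# given as a 2-column matrix of x, y indices): exhaustive directional sweep
# over all corner points at 0.5 degree steps, no convex hull shortcut
oracle_length_width <- function(fp, voxel_edge = 1, step_deg = 0.5) {
  pts <- rbind(cbind(fp[, 1L] - 1, fp[, 2L] - 1), cbind(fp[, 1L], fp[, 2L] - 1),
               cbind(fp[, 1L] - 1, fp[, 2L]),     cbind(fp[, 1L], fp[, 2L])) *
    voxel_edge
  best <- c(Inf, NA, NA)
  for (th in seq(0, 90 - step_deg, by = step_deg) * pi / 180) {
    p1 <- pts %*% c(cos(th), sin(th))
    p2 <- pts %*% c(-sin(th), cos(th))
    e1 <- max(p1) - min(p1); e2 <- max(p2) - min(p2)
    if (e1 * e2 < best[1L]) best <- c(e1 * e2, e1, e2)
  }
  c(length = max(best[2:3]), width = min(best[2:3]))
}

footprint_of <- function(lat) {
  xyz <- voxcal:::lin_to_xyz(lat$occ, lat$dims)
  unique.matrix(xyz[, c("x", "y"), drop = FALSE])
}

# random blob footprint: union of a few random rectangles/discs, guaranteed
# non-empty and connected enough for a measurement
random_footprint_lattice <- function(seed, dims = c(60L, 60L, 5L)) {
  set.seed(seed)
  mask <- matrix(FALSE, dims[1L], dims[2L])
  n_shapes <- sample(2:4, 1)
  for (s in seq_len(n_shapes)) {
    cx <- sample(15:45, 1); cy <- sample(15:45, 1)
    if (runif(1) < 0.5) {
      w <- sample(3:12, 1); h <- sample(3:12, 1)
      mask[pmax(1, cx - w):pmin(dims[1], cx + w),
           pmax(1, cy - h):pmin(dims[2], cy + h)] <- TRUE
    } else {
      r <- sample(3:9, 1)
      g <- expand.grid(x = seq_len(dims[1L]), y = seq_len(dims[2L]))
      keep <- (g$x - cx)^2 + (g$y - cy)^2 <= r^2
      mask[cbind(g$x[keep], g$y[keep])] <- TRUE
    }
  }
  fp <- which(mask, arr.ind = TRUE)
  lattice_from_voxels(cbind(fp, 1L), dims, voxel_edge = 1)
}

# two-way crossed normal data with known variance components, for ICC
# parameter recovery: y_ij = subject_i + rater_j + e_ij
twoway_icc_data <- function(n_subjects, k_raters, sd_subject, sd_rater,
                            sd_error, seed = 1) {
  set.seed(seed)
  subj <- rnorm(n_subjects, 0, sd_subject)
  rater <- rnorm(k_raters, 0, sd_rater)
  outer(subj, rater, "+") + 100 +
    matrix(rnorm(n_subjects * k_raters, 0, sd_error), n_subjects)
}

# records data frame built by hand (not via the generator) for the
# repeatability statistics
manual_records <- function(mouse_id, day, operator_id, length, width,
                           height = NA_real_, area = NA_real_,
                           weight = NA_real_, instrument = "calliper",
                           strain = "SCID", excluded = FALSE) {
  data.frame(study_id = "fixture", mouse_id = mouse_id, strain = strain,
             day = day, operator_id = operator_id, instrument = instrument,
             length = length, width = width, height = height, area = area,
             weight = weight, excluded = excluded)
}
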