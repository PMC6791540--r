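# Voxel lattice: the simulator's world. State codes are integers so the
# lattice can be stored as a dense 3D integer array and exported as-is.

#' Voxel state codes
#'
#' Integer codes used in the `state` array of a `vc_lattice`: `EMPTY` (0),
#' `POP_A` (1, the founding tumour cell population), `POP_B` (2, the
#' aggressive mutant sub-population of the birthday-cake morphology) and
#' `NECROTIC` (3, ulcerated tissue: excluded from volume and blocking
#' division targets).
#'
#' @format Named integer vector of length 4.
#' @export
VOXEL_STATES <- c(EMPTY = 0L, POP_A = 1L, POP_B = 2L, NECROTIC = 3L)

.EMPTY <- 0L
.POP_A <- 1L
.POP_B <- 2L
.NECROTIC <- 3L

#' Construct a voxel lattice
#'
#' @param dims Integer triple `(nx, ny, nz)` in voxels. The `z = 1` layer sits
#'   on the base plane (the body wall under the skin); cells never occupy
#'   space below it.
#' @param voxel_edge Edge length of one voxel in mm.
#' @param state Optional pre-filled 3D integer array of voxel states; defaults
#'   to an all-`EMPTY` lattice.
#' @return An object of class `vc_lattice`: a list with `dims`, `voxel_edge`,
#'   `state` (3D integer array) and `occ` (cached linear indices of occupied,
#'   i.e. `POP_A`/`POP_B`, voxels).
#' @export
new_lattice <- function(dims, voxel_edge = 0.2, state = NULL) {
  dims <- as.integer(dims)
  if (length(dims) != 3L || any(dims < 1L))
    stop_config("dims must be a positive integer triple (nx, ny, nz)")
  if (!is.numeric(voxel_edge) || length(voxel_edge) != 1L || voxel_edge <= 0)
    stop_config("voxel_edge must be a single positive number (mm)")
  if (is.null(state)) {
    state <- array(.EMPTY, dim = dims)
  } else {
    state <- array(as.integer(state), dim = dims)
  }
  lat <- structure(
    list(dims = dims, voxel_edge = voxel_edge, state = state, occ = NULL),
    class = "vc_lattice"
  )
  lat$occ <- which(state == .POP_A | state == .POP_B)
  lat
}

# linear index -> (x, y, z) matrix, 1-based
lin_to_xyz <- function(idx, dims) {
  nx <- dims[1L]; nplane <- dims[1L] * dims[2L]
  i0 <- idx - 1L
  z <- i0 %/% nplane
  r <- i0 - z * nplane
  y <- r %/% nx
  x <- r - y * nx
  cbind(x = x + 1L, y = y + 1L, z = z + 1L)
}

xyz_to_lin <- function(x, y, z, dims) {
  (x) + (y - 1L) * dims[1L] + (z - 1L) * dims[1L] * dims[2L]
}

# voxel indices of a solid hemisphere of given radius (voxels) resting on the
# base plane, centred at (cx, cy) in voxel units; voxel centres at (i - 0.5)
hemisphere_voxels <- function(cx, cy, radius, dims) {
  r <- ceiling(radius)
  xs <- seq.int(max(1L, floor(cx - r)), min(dims[1L], ceiling(cx + r)))
  ys <- seq.int(max(1L, floor(cy - r)), min(dims[2L], ceiling(cy + r)))
  zs <- seq.int(1L, min(dims[3L], r))
  g <- expand.grid(x = xs, y = ys, z = zs)
  d2 <- (g$x - 0.5 - cx)^2 + (g$y - 0.5 - cy)^2 + (g$z - 0.5)^2
  g <- g[d2 <= radius^2, , drop = FALSE]
  xyz_to_lin(g$x, g$y, g$z, dims)
}

MORPHOLOGIES <- c("one_peak", "two_peak", "three_peak",
                  "igloo", "birthday_cake", "volcano")

#' Initialise a tumour seed configuration
#'
#' Places the initial cell clusters for one of the six morphology presets on
#' the base plane of a fresh lattice. Seeds are radius-3 voxel hemispheres
#' (about 57 voxels each):
#' * `one_peak` / `volcano` — a single central cluster (the volcano crater is
#'   carved later, during simulation, by [apply_ulceration()]);
#' * `two_peak` / `three_peak` — 2 or 3 disjoint, non-adjacent clusters;
#' * `igloo` — one cluster plus a 20-voxel, 1-voxel-wide trail of cells at
#'   z in \{1, 2\}, the track left by the inoculating needle;
#' * `birthday_cake` — one cluster whose apex cap (radius 1) is the
#'   aggressive `POP_B` sub-population.
#'
#' @param morphology One of `"one_peak"`, `"two_peak"`, `"three_peak"`,
#'   `"igloo"`, `"birthday_cake"`, `"volcano"`.
#' @param dims Lattice dimensions in voxels; must leave >= 5 voxels of lateral
#'   margin around every seed cluster.
#' @param seed Unused placeholder for API symmetry (seed placement is
#'   deterministic); the simulation RNG is seeded in [simulate_tumour()].
#' @param voxel_edge Voxel edge in mm.
#' @return A `vc_lattice` holding the seed configuration.
#' @export
init_tumour <- function(morphology, dims = c(100L, 100L, 50L), seed = NULL,
                        voxel_edge = 0.2) {
  morphology <- match.arg(morphology, MORPHOLOGIES)
  lat <- new_lattice(dims, voxel_edge)
  dims <- lat$dims
  radius <- 3
  margin <- radius + 5
  if (any(dims[1:2] < 2 * margin + 1) || dims[3L] < radius + 2)
    stop_geometry("lattice dims too small for seed configuration: need >= ",
                  2 * margin + 1, " laterally and >= ", radius + 2, " in z")
  cx <- dims[1L] / 2; cy <- dims[2L] / 2

  centres <- switch(morphology,
    one_peak = , volcano = , igloo = , birthday_cake =
      cbind(cx, cy),
    two_peak = cbind(c(cx - 6, cx + 6), c(cy, cy)),
    three_peak = cbind(c(cx - 7, cx + 7, cx), c(cy - 5, cy - 5, cy + 7))
  )
  if (any(centres[, 1] < margin | centres[, 1] > dims[1L] - margin |
          centres[, 2] < margin | centres[, 2] > dims[2L] - margin))
    stop_geometry("seed clusters do not fit with a 5-voxel lateral margin")

  st <- lat$state
  for (i in seq_len(nrow(centres))) {
    st[hemisphere_voxels(centres[i, 1], centres[i, 2], radius, dims)] <- .POP_A
  }

  if (morphology == "igloo") {
    # needle trail: straight 20-voxel line, 1 voxel wide, at z in {1, 2},
    # extending +x from the cluster edge
    x0 <- floor(cx + radius)
    xs <- seq.int(x0 + 1L, x0 + 20L)
    if (max(xs) > dims[1L] - 5L)
      stop_geometry("lattice too small for the igloo needle trail")
    yl <- as.integer(round(cy))
    st[xyz_to_lin(xs, rep(yl, 20L), rep(1L, 20L), dims)] <- .POP_A
    st[xyz_to_lin(xs, rep(yl, 20L), rep(2L, 20L), dims)] <- .POP_A
  }

  if (morphology == "birthday_cake") {
    # aggressive sub-clone: radius-1 cap at the seed apex
    occ <- which(st == .POP_A)
    xyz <- lin_to_xyz(occ, dims)
    zmax <- max(xyz[, "z"])
    apex <- xyz[xyz[, "z"] == zmax, , drop = FALSE]
    ax <- apex[1L, "x"]; ay <- apex[1L, "y"]
    d2 <- (xyz[, "x"] - ax)^2 + (xyz[, "y"] - ay)^2 + (xyz[, "z"] - zmax)^2
    st[occ[d2 <= 1.5^2]] <- .POP_B
  }

  lat$state <- st
  lat$occ <- which(st == .POP_A | st == .POP_B)
  lat
}

#' Ground-truth tumour volume
#'
#' The exact volume of the simulated tumour: the count of occupied
#' (`POP_A` + `POP_B`) voxels times the voxel volume. Necrotic voxels are
#' lost tissue and do not count.
#'
#' @param lattice A `vc_lattice`.
#' @return Volume in mm^3 (0 for an empty lattice).
#' @export
ground_truth_volume <- function(lattice) {
  length(lattice$occ) * lattice$voxel_edge^3
}

#' Rotate a lattice 90 degrees about the z axis
#'
#' Utility used mainly to check rotation invariance of volume and calliper
#' length. The x axis maps onto y.
#'
#' @param lattice A `vc_lattice`.
#' @return The rotated `vc_lattice` (dims permuted accordingly).
#' @export
rotate_lattice_z <- function(lattice) {
  st <- lattice$state
  d <- dim(st)
  # (x, y, z) -> (y, nx + 1 - x, z)
  rot <- aperm(st, c(2L, 1L, 3L))[, rev(seq_len(d[1L])), , drop = FALSE]
  new_lattice(dim(rot), lattice$voxel_edge, rot)
}

#' @export
print.vc_lattice <- function(x, ...) {
  xyz <- if (length(x$occ)) lin_to_xyz(x$occ, x$dims) else NULL
  cat(sprintf("<vc_lattice %dx%dx%d voxels, edge %.3g mm>\n",
              x$dims[1L], x$dims[2L], x$dims[3L], x$voxel_edge))
  cat(sprintf("  occupied: %d voxels (%.3g mm^3), necrotic: %d\n",
              length(x$occ), ground_truth_volume(x),
              sum(x$state == .NECROTIC)))
  if (!is.null(xyz))
    cat(sprintf("  height: %d voxels\n", max(xyz[, "z"])))
  invisible(x)
}

# number of face-connected components among occupied voxels (used by tests
# and seed validation)
connected_components <- function(lattice) {
  occ <- lattice$occ
  if (!length(occ)) return(0L)
  dims <- lattice$dims
  nx <- dims[1L]; nplane <- nx * dims[2L]
  inside <- new.env(hash = TRUE, size = length(occ) * 2L)
  for (i in occ) assign(as.character(i), TRUE, envir = inside)
  seen <- new.env(hash = TRUE, size = length(occ) * 2L)
  offs <- c(-1L, 1L, -nx, nx, -nplane, nplane)
  ncomp <- 0L
  for (s in occ) {
    key <- as.character(s)
    if (!is.null(seen[[key]])) next
    ncomp <- ncomp + 1L
    stack <- s
    seen[[key]] <- TRUE
    while (length(stack)) {
      v <- stack[[length(stack)]]
      stack <- stack[-length(stack)]
      for (nb in v + offs) {
        k <- as.character(nb)
        if (!is.null(inside[[k]]) && is.null(seen[[k]])) {
          seen[[k]] <- TRUE
          stack <- c(stack, nb)
        }
      }
    }
  }
  ncomp
}

# condition helpers ---------------------------------------------------------

stop_config <- function(...) {
  stop(errorCondition(paste0(...), class = c("vc_config_error", "vc_error")))
}
stop_geometry <- function(...) {
  stop(errorCondition(paste0(...), class = c("vc_geometry_error", "vc_error")))
}
stop_boundary <- function(...) {
  stop(errorCondition(paste0(...), class = c("vc_boundary_error", "vc_error")))
}
stop_data <- function(...) {
  stop(errorCondition(paste0(...), class = c("vc_data_error", "vc_error")))
}
stop_measurement <- function(...) {
  stop(errorCondition(paste0(...),
                      class = c("vc_measurement_error", "vc_error")))
}
stop_metric <- function(...) {
  stop(errorCondition(paste0(...), class = c("vc_metric_error", "vc_error")))
}
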