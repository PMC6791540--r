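# Virtual calliper: measure a voxel tumour the way an operator with a
# calliper (or the scanner) would, then convert to volume.
#
# The footprint is the projection of occupied voxels onto the base plane.
# Length and width are the sides of the minimum-area bounding rectangle of
# the footprint's voxel corner points, found by a rotating-calipers style
# directional sweep: this emulates an operator aligning the first jaw with
# the tumour's apparent long axis and placing the second jaw at right
# angles. For an axis-aligned cuboid it returns the plain x/y extents.

#' Spheroid volume (calliper formula)
#'
#' The standard calliper-to-volume conversion,
#' `V = (pi/6) * length * width^2`, which treats the tumour as a regular
#' spheroid whose height equals its width.
#'
#' @param length,width Calliper length and width in mm (vectorised). If
#'   `length < width` the two are swapped with a warning.
#' @return Volume in mm^3.
#' @export
spheroid_volume <- function(length, width) {
  check_nonneg(length = length, width = width)
  swap <- !is.na(length) & !is.na(width) & length < width
  if (any(swap)) {
    warning("length < width for ", sum(swap),
            " measurement(s); swapping (length is the longer dimension)")
    tmp <- length[swap]; length[swap] <- width[swap]; width[swap] <- tmp
  }
  pi / 6 * length * width^2
}

#' Cylindrical volume (scan formula)
#'
#' `V = area * height`: the tumour footprint area extruded to the measured
#' height.
#'
#' @param area Footprint area in mm^2.
#' @param height Tumour height in mm.
#' @return Volume in mm^3.
#' @export
cylindrical_volume <- function(area, height) {
  check_nonneg(area = area, height = height)
  area * height
}

#' Ellipsoid volume
#'
#' `V = (pi/6) * length * width * height`: a half-axis ellipsoid volume using
#' all three measured dimensions. Reduces to [spheroid_volume()] when
#' `height == width`.
#'
#' @param length,width,height Dimensions in mm.
#' @return Volume in mm^3.
#' @export
ellipsoid_volume <- function(length, width, height) {
  check_nonneg(length = length, width = width, height = height)
  pi / 6 * length * width * height
}

check_nonneg <- function(...) {
  args <- list(...)
  for (nm in names(args)) {
    v <- args[[nm]]
    if (!is.numeric(v)) stop_measurement(nm, " must be numeric")
    if (any(v < 0, na.rm = TRUE))
      stop_measurement(nm, " must be >= 0 (negative measurement)")
  }
  invisible(NULL)
}

# extents of a 2D point cloud along directions theta and theta + 90 degrees,
# for a vector of angles; returns list(par, perp) of extents
directional_extents <- function(pts, theta) {
  col_range <- function(m) {
    rows <- asplit(m, 1L)   # hulls are small; pmin/pmax over rows is cheap
    do.call(pmax, rows) - do.call(pmin, rows)
  }
  u <- rbind(cos(theta), sin(theta))          # 2 x k
  v <- rbind(-sin(theta), cos(theta))
  list(par = col_range(pts %*% u), perp = col_range(pts %*% v))
}

#' Simulated calliper measurement
#'
#' Measures a voxel tumour's footprint length/width, height and footprint
#' area. The footprint is the base-plane projection of occupied voxels;
#' length and width are the sides of its minimum-area bounding rectangle
#' (sweep over orientations at `angle_step` resolution, over the footprint
#' voxels' outer corner points), with length the longer side. Height is the
#' top face of the highest occupied voxel; area the footprint voxel count
#' times the voxel face area.
#'
#' @param lattice A non-empty `vc_lattice`.
#' @param angle_step Directional sweep resolution in degrees (default 1;
#'   sub-voxel exactness would be spurious at 0.2 mm voxels).
#' @return A list of class `vc_measurement` with `length`, `width`, `height`
#'   (mm), `area` (mm^2) and `theta` (length orientation, radians).
#' @export
simulated_calliper <- function(lattice, angle_step = 1) {
  occ <- lattice$occ
  if (!length(occ))
    stop_measurement("empty lattice: no tumour to measure")
  ve <- lattice$voxel_edge
  xyz <- lin_to_xyz(occ, lattice$dims)
  fp <- unique.matrix(xyz[, c("x", "y"), drop = FALSE])
  n <- nrow(fp)
  corners <- rbind(
    cbind(fp[, 1L] - 1L, fp[, 2L] - 1L),
    cbind(fp[, 1L],      fp[, 2L] - 1L),
    cbind(fp[, 1L] - 1L, fp[, 2L]),
    cbind(fp[, 1L],      fp[, 2L])
  ) * ve
  hull <- corners[grDevices::chull(corners), , drop = FALSE]
  if (nrow(hull) < 3L) hull <- corners        # degenerate (collinear) footprint

  theta <- seq(0, pi / 2, by = angle_step * pi / 180)
  ext <- directional_extents(hull, theta)
  rect_area <- ext$par * ext$perp
  k <- which.min(rect_area)
  len <- max(ext$par[k], ext$perp[k])
  wid <- min(ext$par[k], ext$perp[k])
  th <- if (ext$par[k] >= ext$perp[k]) theta[k] else theta[k] + pi / 2

  structure(list(length = len, width = wid,
                 height = max(xyz[, "z"]) * ve,
                 area = n * ve^2, theta = th),
            class = "vc_measurement")
}

#' @export
print.vc_measurement <- function(x, ...) {
  cat(sprintf(
    "<vc_measurement length %.2f mm, width %.2f mm, height %.2f mm, area %.2f mm^2>\n",
    x$length, x$width, x$height, x$area))
  invisible(x)
}

#' Measure a snapshot sequence into a growth curve
#'
#' Applies [simulated_calliper()] to each daily lattice snapshot and converts
#' the measurements with the chosen formula. Empty days are recorded as
#' volume 0 and flagged.
#'
#' @param snapshots List of `vc_lattice` objects, one per day (day 0 first),
#'   or a `vc_sim` run with `keep_snapshots = TRUE`.
#' @param method `"SC"` (spheroid, the calliper emulation), `"CYL"` or
#'   `"ELL"`.
#' @param arm Arm label for the curve.
#' @return A `data.frame` growth curve (`day`, `volume_mm3`, `method`, `arm`,
#'   `empty`).
#' @export
measure_curve <- function(snapshots, method = c("SC", "CYL", "ELL"),
                          arm = "control") {
  method <- match.arg(method)
  if (inherits(snapshots, "vc_sim")) {
    if (is.null(snapshots$snapshots))
      stop_measurement("vc_sim was run without keep_snapshots = TRUE")
    snapshots <- snapshots$snapshots
  }
  if (!length(snapshots)) stop_measurement("empty snapshot sequence")
  vols <- numeric(length(snapshots))
  empty <- logical(length(snapshots))
  for (i in seq_along(snapshots)) {
    lat <- snapshots[[i]]
    if (!length(lat$occ)) {
      vols[i] <- 0; empty[i] <- TRUE
      next
    }
    m <- simulated_calliper(lat)
    vols[i] <- switch(method,
      SC  = spheroid_volume(m$length, m$width),
      CYL = cylindrical_volume(m$area, m$height),
      ELL = ellipsoid_volume(m$length, m$width, m$height))
  }
  data.frame(day = seq_along(snapshots) - 1L, volume_mm3 = vols,
             method = method, arm = arm, empty = empty)
}
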