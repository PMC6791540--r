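# Rule-based stochastic growth of a two-population tumour on the lattice.
#
# Update rules (one step = one day):
#   1. Every occupied voxel with at least one EMPTY face neighbour divides
#      with probability p_divi (POP_B: p_divi * mutant_p_divi_factor, capped
#      at 1). Daughters are placed into one EMPTY face neighbour, sampled
#      with weight 1 for lateral/downward targets and 1 + bias for the +z
#      target. Parents are swept in a random permutation; a parent whose
#      empty neighbours were all taken earlier in the sweep skips division
#      (first-come-wins conflict resolution).
#   2. During the treatment window (treatment_start <= day <
#      treatment_start + lam_len) every tumour cell, daughters included,
#      independently dies (becomes EMPTY) with probability lam.
#   3. volcano morphology: on ulceration_day a crater is carved once by
#      apply_ulceration().
# The base plane is reflective: no division target below z = 1.

#' Simulation parameters
#'
#' Bundles the model parameters theta = \{bias, p_divi, lambda, lambda_len\}
#' with the morphology preset, treatment schedule, lattice geometry and seed.
#'
#' @param morphology Morphology preset; see [init_tumour()].
#' @param bias Vertical growth bias, dimensionless weight >= 0. The +z
#'   division target carries weight `1 + bias`; 0 recovers an unbiased choice.
#' @param p_divi Per-cell per-day division probability in \[0, 1\].
#' @param lam Treatment magnitude: per-cell per-day death probability in
#'   \[0, 1\] while treatment is active.
#' @param lam_len Treatment duration in days.
#' @param treatment_start First treated day (default 15; with the default
#'   duration of 10 days, volumes on days 15..25 reflect treatment).
#' @param total_days Number of simulated days.
#' @param mutant_p_divi_factor Division-probability multiplier (> 1) for the
#'   aggressive `POP_B` sub-clone of the birthday-cake preset.
#' @param ulceration_day Day the volcano crater is carved.
#' @param crater_fraction Fraction of tumour voxels removed by ulceration.
#' @param dims,voxel_edge Lattice geometry; see [new_lattice()].
#' @param seed Integer RNG seed; identical `(params, seed)` give identical
#'   trajectories.
#' @return A validated list of class `vc_params`.
#' @export
sim_params <- function(morphology = "one_peak",
                       bias = 1.0,
                       p_divi = 0.1,
                       lam = 0.4,
                       lam_len = 10L,
                       treatment_start = 15L,
                       total_days = 30L,
                       mutant_p_divi_factor = 2.0,
                       ulceration_day = 20L,
                       crater_fraction = 0.15,
                       dims = c(100L, 100L, 50L),
                       voxel_edge = 0.2,
                       seed = 1L) {
  if (length(morphology) != 1L || !morphology %in% MORPHOLOGIES)
    stop_config("unknown morphology '", paste(morphology, collapse = ","),
                "'; must be one of ", paste(MORPHOLOGIES, collapse = ", "))
  p <- list(morphology = morphology, bias = bias, p_divi = p_divi,
            lam = lam, lam_len = as.integer(lam_len),
            treatment_start = as.integer(treatment_start),
            total_days = as.integer(total_days),
            mutant_p_divi_factor = mutant_p_divi_factor,
            ulceration_day = as.integer(ulceration_day),
            crater_fraction = crater_fraction,
            dims = as.integer(dims), voxel_edge = voxel_edge,
            seed = as.integer(seed))
  problems <- character()
  if (!is.numeric(bias) || bias < 0) problems <- c(problems, "bias must be >= 0")
  for (nm in c("p_divi", "lam")) {
    v <- p[[nm]]
    if (!is.numeric(v) || v < 0 || v > 1)
      problems <- c(problems, paste(nm, "must be in [0, 1]"))
  }
  if (p$lam_len < 0) problems <- c(problems, "lam_len must be >= 0")
  if (p$treatment_start < 0)
    problems <- c(problems, "treatment_start must be >= 0")
  if (p$total_days < 1) problems <- c(problems, "total_days must be >= 1")
  if (p$treatment_start + p$lam_len > p$total_days)
    problems <- c(problems, "treatment_start + lam_len must be <= total_days")
  if (p$mutant_p_divi_factor <= 0)
    problems <- c(problems, "mutant_p_divi_factor must be > 0")
  if (p$crater_fraction < 0 || p$crater_fraction >= 1)
    problems <- c(problems, "crater_fraction must be in [0, 1)")
  if (length(problems))
    stop_config("invalid simulation parameters: ",
                paste(problems, collapse = "; "))
  structure(p, class = "vc_params")
}

#' @export
print.vc_params <- function(x, ...) {
  cat(sprintf(
    "<vc_params %s: bias=%g p_divi=%g lam=%g lam_len=%d window=[%d,%d) days=%d seed=%d>\n",
    x$morphology, x$bias, x$p_divi, x$lam, x$lam_len,
    x$treatment_start, x$treatment_start + x$lam_len, x$total_days, x$seed))
  invisible(x)
}

#' Advance the lattice by one day
#'
#' Applies the division sweep, then (if `day` is inside the treatment window)
#' the treatment kill, then (volcano preset, on `ulceration_day`) ulceration.
#' Uses the current RNG stream; [simulate_tumour()] owns the seeding.
#'
#' @param lattice A `vc_lattice`.
#' @param params A `vc_params`.
#' @param day Day index of the state being produced (1-based: the first step
#'   after initialisation produces the day-1 state).
#' @return The updated `vc_lattice`, with a `counts` attribute recording
#'   `births`, `deaths` and `ulcerated` for this step.
#' @export
ca_step <- function(lattice, params, day) {
  st <- lattice$state
  dims <- lattice$dims
  nx <- dims[1L]; ny <- dims[2L]; nz <- dims[3L]
  nplane <- nx * ny
  occ <- lattice$occ
  births <- 0L; deaths <- 0L; ulcer <- 0L

  if (length(occ)) {
    xyz <- lin_to_xyz(occ, dims)
    if (any(xyz[, "x"] <= 1L | xyz[, "x"] >= nx |
            xyz[, "y"] <= 1L | xyz[, "y"] >= ny | xyz[, "z"] >= nz))
      stop_boundary("tumour reached the lattice boundary on day ", day,
                    "; enlarge dims to avoid truncated morphologies")

    # neighbour linear indices, columns: -x +x -y +y -z +z
    offs <- c(-1L, 1L, -nx, nx, -nplane, nplane)
    nbr <- outer(occ, offs, "+")
    valid <- matrix(TRUE, length(occ), 6L)
    valid[xyz[, "z"] == 1L, 5L] <- FALSE   # reflective base plane
    safe <- nbr; safe[!valid] <- 1L
    empty_nbr <- valid & (matrix(st[safe], length(occ), 6L) == .EMPTY)

    pd <- rep(params$p_divi, length(occ))
    if (params$morphology == "birthday_cake") {
      isB <- st[occ] == .POP_B
      pd[isB] <- min(1, params$p_divi * params$mutant_p_divi_factor)
    }
    dividers <- which(rowSums(empty_nbr) > 0L &
                        stats::runif(length(occ)) < pd)
    if (length(dividers)) {
      sweep_order <- if (length(dividers) > 1L)
        dividers[sample.int(length(dividers))] else dividers
      w <- c(1, 1, 1, 1, 1, 1 + params$bias)
      for (i in sweep_order) {
        targ <- safe[i, ]                         # invalid slots point at voxel 1
        open <- valid[i, ] & st[targ] == .EMPTY   # live re-check
        if (!any(open)) next
        cand <- targ[open]
        pick <- if (length(cand) == 1L) cand
                else cand[sample.int(length(cand), 1L, prob = w[open])]
        st[pick] <- st[occ[i]]
        occ <- c(occ, pick)
        births <- births + 1L
      }
    }
  }

  in_window <- day >= params$treatment_start &&
    day < params$treatment_start + params$lam_len
  if (in_window && params$lam > 0 && length(occ)) {
    kill <- stats::runif(length(occ)) < params$lam
    if (any(kill)) {
      st[occ[kill]] <- .EMPTY
      deaths <- sum(kill)
      occ <- occ[!kill]
    }
  }

  lattice$state <- st
  lattice$occ <- occ

  if (params$morphology == "volcano" && day == params$ulceration_day &&
      length(lattice$occ)) {
    before <- length(lattice$occ)
    lattice <- apply_ulceration(lattice, params$crater_fraction)
    ulcer <- before - length(lattice$occ)
  }

  attr(lattice, "counts") <- c(births = births, deaths = deaths,
                               ulcerated = as.integer(ulcer))
  lattice
}

#' Carve an ulceration crater
#'
#' Removes (marks `NECROTIC`) the `floor(crater_fraction * N)` occupied
#' voxels closest to the tumour apex — the top of the occupied column of
#' maximal height (ties broken towards the footprint centroid) — producing a
#' central depression. Necrotic voxels no longer count towards volume and
#' block division targets.
#'
#' @param lattice A non-empty `vc_lattice`.
#' @param crater_fraction Fraction in \[0, 1) of occupied voxels to remove.
#' @return The cratered `vc_lattice`.
#' @export
apply_ulceration <- function(lattice, crater_fraction) {
  if (!is.numeric(crater_fraction) || crater_fraction < 0 ||
      crater_fraction >= 1)
    stop_config("crater_fraction must be in [0, 1)")
  occ <- lattice$occ
  if (!length(occ)) stop_measurement("cannot ulcerate an empty lattice")
  n_remove <- floor(crater_fraction * length(occ))
  if (n_remove == 0L) return(lattice)

  xyz <- lin_to_xyz(occ, lattice$dims)
  zmax <- max(xyz[, "z"])
  at_top <- xyz[, "z"] == zmax
  fx <- mean(xyz[, "x"]); fy <- mean(xyz[, "y"])
  cand <- which(at_top)
  d_cent <- (xyz[cand, "x"] - fx)^2 + (xyz[cand, "y"] - fy)^2
  apex <- cand[order(d_cent, occ[cand])[1L]]
  ax <- xyz[apex, "x"]; ay <- xyz[apex, "y"]

  d2 <- (xyz[, "x"] - ax)^2 + (xyz[, "y"] - ay)^2 + (xyz[, "z"] - zmax)^2
  drop_idx <- order(d2, occ)[seq_len(n_remove)]
  lattice$state[occ[drop_idx]] <- .NECROTIC
  lattice$occ <- occ[-drop_idx]
  lattice
}

# evaluate expr under a private RNG stream seeded with `seed`, restoring the
# caller's stream afterwards
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Simulate a tumour
#'
#' Initialises the seed configuration and advances it `total_days` steps,
#' recording the ground-truth (GT) volume each day and, optionally, virtual
#' calliper measurements and lattice snapshots. The RNG is seeded from
#' `params$seed`, so identical parameters give bit-identical trajectories.
#'
#' @param params A [sim_params()] object.
#' @param measure_sc If `TRUE` (default) run [simulated_calliper()] on every
#'   daily state and record footprint length/width/height/area.
#' @param keep_snapshots If `TRUE`, keep a `vc_lattice` per day (memory: one
#'   dense array per day).
#' @param arm Label stored on the returned curves (`"control"` or
#'   `"treated"`); purely descriptive.
#' @return A list of class `vc_sim` with elements `params`, `days`
#'   (0..total_days), `gt` (GT volume per day, mm^3), `measurements` (data
#'   frame of daily calliper reads, when requested; empty days carry NA
#'   dimensions and are flagged), `snapshots` (optional list), `final`
#'   (final `vc_lattice`) and `counts` (per-day births/deaths/ulcerated).
#' @export
simulate_tumour <- function(params, measure_sc = TRUE,
                            keep_snapshots = FALSE, arm = "control") {
  stopifnot(inherits(params, "vc_params"))
  with_seed(params$seed, {
    lat <- init_tumour(params$morphology, params$dims,
                       voxel_edge = params$voxel_edge)
    ndays <- params$total_days
    gt <- numeric(ndays + 1L)
    counts <- matrix(0L, ndays, 3L,
                     dimnames = list(NULL, c("births", "deaths", "ulcerated")))
    meas <- if (measure_sc)
      vector("list", ndays + 1L) else NULL
    snaps <- if (keep_snapshots) vector("list", ndays + 1L) else NULL

    record <- function(slot) {
      gt[slot] <<- ground_truth_volume(lat)
      if (measure_sc) meas[[slot]] <<- measure_or_na(lat)
      if (keep_snapshots) snaps[[slot]] <<- lat
    }
    record(1L)
    for (day in seq_len(ndays)) {
      lat <- ca_step(lat, params, day)
      counts[day, ] <- attr(lat, "counts")
      record(day + 1L)
    }

    out <- list(params = params, days = 0:ndays, gt = gt, arm = arm,
                counts = counts, final = lat)
    if (measure_sc) {
      m <- do.call(rbind, meas)
      m <- cbind(day = 0:ndays, as.data.frame(m))
      out$measurements <- m
    }
    if (keep_snapshots) out$snapshots <- snaps
    structure(out, class = "vc_sim")
  })
}

measure_or_na <- function(lat) {
  if (!length(lat$occ))
    return(c(length = NA_real_, width = NA_real_, height = NA_real_,
             area = NA_real_))
  m <- simulated_calliper(lat)
  c(length = m$length, width = m$width, height = m$height, area = m$area)
}

#' @export
print.vc_sim <- function(x, ...) {
  cat(sprintf("<vc_sim %s, %s arm, %d days, seed %d>\n", x$params$morphology,
              x$arm, x$params$total_days, x$params$seed))
  cat(sprintf("  GT volume day 0: %.3g mm^3, day %d: %.3g mm^3\n",
              x$gt[1L], x$params$total_days, x$gt[length(x$gt)]))
  invisible(x)
}

#' Extract a growth curve from a simulation
#'
#' @param sim A `vc_sim`.
#' @param method `"GT"` (voxel-count ground truth), `"SC"` (simulated
#'   calliper + spheroid formula), `"CYL"` (footprint area x height) or
#'   `"ELL"` (ellipsoid formula).
#' @return A `data.frame` with columns `day`, `volume_mm3`, `method`, `arm`
#'   and `empty` (flag: no tumour left that day; volume recorded as 0).
#' @export
growth_curve <- function(sim, method = c("GT", "SC", "CYL", "ELL")) {
  method <- match.arg(method)
  if (method == "GT") {
    return(data.frame(day = sim$days, volume_mm3 = sim$gt, method = "GT",
                      arm = sim$arm, empty = sim$gt == 0))
  }
  if (is.null(sim$measurements))
    stop_measurement("simulation was run with measure_sc = FALSE; ",
                     "no calliper record to convert")
  m <- sim$measurements
  vol <- switch(method,
    SC  = ifelse(is.na(m$length), 0, spheroid_volume(m$length, m$width)),
    CYL = ifelse(is.na(m$area), 0, cylindrical_volume(m$area, m$height)),
    ELL = ifelse(is.na(m$length), 0,
                 ellipsoid_volume(m$length, m$width, m$height)))
  data.frame(day = m$day, volume_mm3 = vol, method = method, arm = sim$arm,
             empty = is.na(m$length))
}
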