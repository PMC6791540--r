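# Treatment-efficacy indices on control/treated growth-curve pairs, the
# GT-vs-SC ensemble experiment, and a one-at-a-time sensitivity scan.

curve_volume_at <- function(curve, day) {
  if (is.data.frame(curve)) {
    i <- match(day, curve$day)
    if (is.na(i)) stop_metric("growth curve is not defined at day ", day)
    curve$volume_mm3[i]
  } else {
    # bare numeric vector: assume days 0..(n-1)
    if (day + 1L > length(curve)) stop_metric("curve not defined at day ", day)
    curve[[day + 1L]]
  }
}

curve_days <- function(curve) {
  if (is.data.frame(curve)) curve$day else seq_along(curve) - 1L
}

#' Tumour growth inhibition (TGI)
#'
#' `TGI = (1 - [V_T(t) * V_C(0)] / [V_T(0) * V_C(t)]) * 100`: the treated
#' arm's relative growth compared to the control arm's, as a percentage.
#' 0% means identical relative growth, 100% complete regression of the
#' treated tumour, negative values faster-than-control growth.
#'
#' @param control,treated Growth curves: data frames with `day` and
#'   `volume_mm3` (e.g. from [growth_curve()]) or bare per-day volume vectors
#'   starting at day 0.
#' @param t Evaluation day (> 0).
#' @return TGI in percent.
#' @export
tgi <- function(control, treated, t) {
  if (t <= 0) stop_metric("evaluation day must be > 0")
  vc0 <- curve_volume_at(control, 0L)
  vct <- curve_volume_at(control, t)
  vt0 <- curve_volume_at(treated, 0L)
  vtt <- curve_volume_at(treated, t)
  if (!is.finite(vt0) || vt0 <= 0)
    stop_metric("TGI undefined: treated baseline volume V_T(0) must be > 0")
  if (!is.finite(vct) || vct <= 0)
    stop_metric("TGI undefined: control volume V_C(t) must be > 0")
  (1 - (vtt * vc0) / (vt0 * vct)) * 100
}

#' AUC efficacy index
#'
#' `AUC = (1 - AUC_T / AUC_C) * 100`, with the areas under the treated and
#' control growth curves computed by trapezoidal integration over days 0..t
#' on the shared daily grid.
#'
#' @inheritParams tgi
#' @param t Evaluation day; defaults to the last shared day.
#' @return AUC index in percent.
#' @export
auc_index <- function(control, treated, t = NULL) {
  dc <- curve_days(control); dt <- curve_days(treated)
  if (is.null(t)) t <- min(max(dc), max(dt))
  keep_c <- dc <= t; keep_t <- dt <= t
  if (!identical(dc[keep_c], dt[keep_t]))
    stop_metric("control and treated curves must share the same day grid")
  days <- dc[keep_c]
  if (length(days) < 2L) stop_metric("need at least two days to integrate")
  vc <- if (is.data.frame(control)) control$volume_mm3[keep_c]
        else control[keep_c]
  vt <- if (is.data.frame(treated)) treated$volume_mm3[keep_t]
        else treated[keep_t]
  auc_c <- trapz(days, vc)
  auc_t <- trapz(days, vt)
  if (auc_c <= 0) stop_metric("AUC undefined: control AUC must be > 0")
  (1 - auc_t / auc_c) * 100
}

trapz <- function(x, y) {
  n <- length(x)
  sum((y[-1L] + y[-n]) * diff(x)) / 2
}

#' Run a paired control/treated simulation ensemble
#'
#' For each replicate, simulates one control (`lam = 0`) and one treated
#' tumour with a shared per-replicate seed (`params$seed + replicate`:
#' common random numbers, so the two arms are identical until treatment
#' starts) and computes TGI and the AUC index under both GT and SC volumes
#' at each evaluation day. Replicates that hit the lattice boundary are
#' skipped and counted.
#'
#' @param params Base [sim_params()]; the treated arm uses it as-is, the
#'   control arm with `lam = 0`.
#' @param n_replicates Number of replicate pairs (>= 2).
#' @param eval_days Evaluation days, default the paper's endpoints 18/24/30
#'   (clipped to `total_days`).
#' @param pairing `"paired"` (replicate i control vs replicate i treated;
#'   the default, isolating measurement error from biological variability)
#'   or `"cross"` (every control paired with every treated curve).
#' @return A `data.frame` of class `vc_efficacy`: `morphology`, `replicate`
#'   (for `"cross"`, `control_rep`/`treated_rep`), `method` (GT/SC),
#'   `eval_day`, `tgi_pct`, `auc_pct`. Attribute `skipped` counts boundary
#'   failures; a warning is raised if they exceed 5%.
#' @export
run_ensemble <- function(params, n_replicates, eval_days = c(18L, 24L, 30L),
                         pairing = c("paired", "cross")) {
  stopifnot(inherits(params, "vc_params"))
  pairing <- match.arg(pairing)
  if (n_replicates < 2L) stop_config("n_replicates must be >= 2")
  eval_days <- as.integer(eval_days[eval_days <= params$total_days])
  if (!length(eval_days) || any(eval_days <= 0L))
    stop_config("eval_days must lie in (0, total_days]")

  curves_c <- vector("list", n_replicates)
  curves_t <- vector("list", n_replicates)
  skipped <- 0L
  for (r in seq_len(n_replicates)) {
    p_t <- params; p_t$seed <- params$seed + r
    p_c <- p_t; p_c$lam <- 0
    res <- tryCatch({
      sim_c <- simulate_tumour(p_c, arm = "control")
      sim_t <- simulate_tumour(p_t, arm = "treated")
      list(c = sim_c, t = sim_t)
    }, vc_boundary_error = function(e) NULL)
    if (is.null(res)) { skipped <- skipped + 1L; next }
    curves_c[[r]] <- list(gt = growth_curve(res$c, "GT"),
                          sc = growth_curve(res$c, "SC"))
    curves_t[[r]] <- list(gt = growth_curve(res$t, "GT"),
                          sc = growth_curve(res$t, "SC"))
  }
  ok <- which(!vapply(curves_c, is.null, logical(1L)))
  if (skipped > 0.05 * n_replicates)
    warning(skipped, " of ", n_replicates,
            " replicates hit the lattice boundary and were skipped")

  pairs <- if (pairing == "paired") cbind(ok, ok)
           else as.matrix(expand.grid(ok, ok))
  rows <- vector("list", nrow(pairs) * length(eval_days) * 2L)
  k <- 0L
  for (i in seq_len(nrow(pairs))) {
    ic <- pairs[i, 1L]; it <- pairs[i, 2L]
    for (meth in c("GT", "SC")) {
      cc <- curves_c[[ic]][[tolower(meth)]]
      tt <- curves_t[[it]][[tolower(meth)]]
      for (d in eval_days) {
        k <- k + 1L
        rows[[k]] <- data.frame(
          morphology = params$morphology,
          control_rep = ic, treated_rep = it, method = meth, eval_day = d,
          tgi_pct = tgi(cc, tt, d),
          auc_pct = auc_index(cc, tt, d))
      }
    }
  }
  out <- do.call(rbind, rows)
  if (pairing == "paired") {
    out$replicate <- out$control_rep
    out <- out[, c("morphology", "replicate", "method", "eval_day",
                   "tgi_pct", "auc_pct")]
  }
  attr(out, "skipped") <- skipped
  class(out) <- c("vc_efficacy", class(out))
  out
}

#' Compare GT and SC efficacy-index distributions
#'
#' Summarises two TGI (or AUC-index) samples by mean, standard deviation and
#' a histogram overlap coefficient: both samples are binned on 50 shared
#' equal-width bins spanning the pooled range and the overlap is the sum of
#' the bin-wise minima of the two relative frequencies (1 = identical
#' histograms, 0 = disjoint supports).
#'
#' @param samples_gt,samples_sc Numeric vectors (>= 2 values each), or
#'   `vc_efficacy` frames from which `tgi_pct` is taken by `method`.
#' @param n_bins Number of shared bins.
#' @return A list of class `vc_dist_comparison`: `mean_gt`, `mean_sc`,
#'   `sd_gt`, `sd_sc`, `overlap_coefficient`.
#' @export
compare_distributions <- function(samples_gt, samples_sc, n_bins = 50L) {
  if (inherits(samples_gt, "vc_efficacy"))
    samples_gt <- samples_gt$tgi_pct[samples_gt$method == "GT"]
  if (inherits(samples_sc, "vc_efficacy"))
    samples_sc <- samples_sc$tgi_pct[samples_sc$method == "SC"]
  if (length(samples_gt) < 2L || length(samples_sc) < 2L)
    stop_metric("need >= 2 samples per method")
  rng <- range(c(samples_gt, samples_sc))
  if (diff(rng) == 0) {
    ov <- 1  # both distributions are the same point mass
  } else {
    brk <- seq(rng[1L], rng[2L], length.out = n_bins + 1L)
    h1 <- hist(samples_gt, breaks = brk, plot = FALSE)$counts
    h2 <- hist(samples_sc, breaks = brk, plot = FALSE)$counts
    ov <- sum(pmin(h1 / sum(h1), h2 / sum(h2)))
  }
  structure(list(mean_gt = mean(samples_gt), mean_sc = mean(samples_sc),
                 sd_gt = stats::sd(samples_gt), sd_sc = stats::sd(samples_sc),
                 overlap_coefficient = ov),
            class = "vc_dist_comparison")
}

#' @export
print.vc_dist_comparison <- function(x, ...) {
  cat(sprintf(
    "<GT %.1f +/- %.1f vs SC %.1f +/- %.1f (overlap %.2f)>\n",
    x$mean_gt, x$sd_gt, x$mean_sc, x$sd_sc, x$overlap_coefficient))
  invisible(x)
}

#' One-at-a-time parameter sensitivity scan
#'
#' Varies one parameter at a time around a base configuration and, for each
#' grid point, reports the mean SC - GT volume bias at `vol_day` (control
#' arm) and the mean TGI(GT) - TGI(SC) bias at `tgi_day`, with Monte-Carlo
#' standard errors.
#'
#' @param base Base [sim_params()].
#' @param param_grid Named list: parameter name -> vector of values (e.g.
#'   `list(p_divi = c(0.05, 0.1, 0.2))`). An empty list yields an empty
#'   table.
#' @param n_replicates Replicate pairs per grid point.
#' @param vol_day,tgi_day Evaluation days for the two biases (defaults 30
#'   and 24, clipped to `total_days`).
#' @return A `data.frame` with one row per grid point: `parameter`, `value`,
#'   `mean_vol_bias`, `se_vol_bias` (mm^3), `mean_tgi_bias`, `se_tgi_bias`
#'   (percentage points), `n_ok`, `n_skipped`.
#' @export
sensitivity_scan <- function(base, param_grid, n_replicates = 50L,
                             vol_day = 30L, tgi_day = 24L) {
  stopifnot(inherits(base, "vc_params"))
  if (!length(param_grid))
    return(data.frame(parameter = character(), value = numeric(),
                      mean_vol_bias = numeric(), se_vol_bias = numeric(),
                      mean_tgi_bias = numeric(), se_tgi_bias = numeric(),
                      n_ok = integer(), n_skipped = integer()))
  if (is.null(names(param_grid)) || any(!nzchar(names(param_grid))))
    stop_config("param_grid must be a named list of value vectors")
  vol_day <- min(vol_day, base$total_days)
  tgi_day <- min(tgi_day, base$total_days)

  rows <- list()
  for (pname in names(param_grid)) {
    if (!pname %in% names(base))
      stop_config("unknown parameter in grid: ", pname)
    for (v in param_grid[[pname]]) {
      p <- base
      p[[pname]] <- v
      p <- do.call(sim_params, p[setdiff(names(p), NULL)])
      eff <- run_ensemble(p, n_replicates,
                          eval_days = unique(c(tgi_day, vol_day)))
      # volume bias needs the raw curves: re-simulate the control arm is
      # wasteful, so recover it from a dedicated light pass
      vb <- vapply(seq_len(n_replicates), function(r) {
        pc <- p; pc$seed <- p$seed + r; pc$lam <- 0
        pc <- do.call(sim_params, pc[setdiff(names(pc), NULL)])
        sim <- tryCatch(simulate_tumour(pc), vc_boundary_error = function(e) NULL)
        if (is.null(sim)) return(NA_real_)
        gc_ <- growth_curve(sim, "GT"); sc_ <- growth_curve(sim, "SC")
        curve_volume_at(sc_, vol_day) - curve_volume_at(gc_, vol_day)
      }, numeric(1L))
      vb <- vb[!is.na(vb)]
      tg <- eff[eff$eval_day == tgi_day, ]
      tb <- tg$tgi_pct[tg$method == "GT"] - tg$tgi_pct[tg$method == "SC"]
      rows[[length(rows) + 1L]] <- data.frame(
        parameter = pname, value = v,
        mean_vol_bias = mean(vb),
        se_vol_bias = stats::sd(vb) / sqrt(length(vb)),
        mean_tgi_bias = mean(tb),
        se_tgi_bias = stats::sd(tb) / sqrt(length(tb)),
        n_ok = length(vb), n_skipped = attr(eff, "skipped"))
    }
  }
  do.call(rbind, rows)
}
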