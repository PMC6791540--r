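# Measurement-agreement statistics: inter-operator CV and ICC, precision
# banding, Bland-Altman volume-vs-weight analysis, relative-error banding,
# scan-vs-calliper consistency counts and Welch one-sided tests.

#' Coefficient of variation
#'
#' `CV = sigma / mu` with the sample (n - 1) standard deviation. Returns
#' `NA` (the "null" of the precision analysis) for fewer than two values or
#' a non-positive mean.
#'
#' @param values Numeric vector of positive measurements.
#' @return Dimensionless CV, or `NA_real_`.
#' @export
coefficient_of_variation <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) < 2L) return(NA_real_)
  m <- mean(values)
  if (m <= 0) return(NA_real_)
  stats::sd(values) / m
}

record_volumes <- function(records, volume_formula = c("eq1", "eq2", "ell")) {
  volume_formula <- match.arg(volume_formula)
  switch(volume_formula,
    eq1 = spheroid_volume(records$length, records$width),
    eq2 = {
      if (is.null(records$area) || is.null(records$height))
        stop_data("cylindrical volume needs area and height columns")
      cylindrical_volume(records$area, records$height)
    },
    ell = {
      if (is.null(records$height))
        stop_data("ellipsoid volume needs a height column")
      ellipsoid_volume(records$length, records$width, records$height)
    })
}

drop_excluded <- function(records) {
  if (!is.null(records$excluded)) {
    records <- records[!records$excluded %in% TRUE, , drop = FALSE]
  }
  records
}

#' Per-tumour per-day inter-operator precision points
#'
#' Groups measurement records by `(mouse_id, day)`, averages duplicate
#' same-operator readings, converts to volume with the chosen formula and
#' returns the inter-operator CV per group. Groups with a single operator
#' yield no point; groups whose CV cannot be computed yield a null
#' (`NA`) point.
#'
#' @param records A measurement-record data frame (see [read_records()] /
#'   [generate_records()]); rows flagged `excluded` are dropped first.
#' @param volume_formula `"eq1"` (spheroid), `"eq2"` (cylindrical) or
#'   `"ell"` (ellipsoid).
#' @return A `data.frame`: `mouse_id`, `day`, `n_operators`, `cv`.
#' @export
precision_points <- function(records, volume_formula = "eq1") {
  records <- drop_excluded(records)
  if (!nrow(records))
    return(data.frame(mouse_id = character(), day = integer(),
                      n_operators = integer(), cv = numeric()))
  records$..vol <- record_volumes(records, volume_formula)
  # average duplicate readings by the same operator in the same group
  agg <- stats::aggregate(..vol ~ mouse_id + day + operator_id,
                          data = records, FUN = mean)
  out <- do.call(rbind, lapply(
    split(agg, list(agg$mouse_id, agg$day), drop = TRUE),
    function(g) {
      data.frame(mouse_id = g$mouse_id[1L], day = g$day[1L],
                 n_operators = nrow(g),
                 cv = coefficient_of_variation(g$..vol))
    }))
  out <- out[out$n_operators >= 2L, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Banded summary of precision points
#'
#' Fractions of precision points below / at-or-above the acceptability
#' threshold, and the fraction of nulls (groups without a computable CV).
#' The three fractions sum to one.
#'
#' @param points Output of [precision_points()].
#' @param threshold CV acceptability bound (default 0.2).
#' @return Named numeric vector `(fraction_below, fraction_above,
#'   fraction_null)`.
#' @export
precision_band_summary <- function(points, threshold = 0.2) {
  if (!nrow(points)) stop_data("no precision points to summarise")
  n <- nrow(points)
  nulls <- sum(is.na(points$cv))
  below <- sum(points$cv < threshold, na.rm = TRUE)
  c(fraction_below = below / n,
    fraction_above = (n - nulls - below) / n,
    fraction_null = nulls / n)
}

#' ICC stratified by number of operators
#'
#' Stratifies `(mouse_id, day)` groups by the number of distinct operators
#' `k` and, within each stratum, estimates a two-way random-effects,
#' absolute-agreement, single-measurement ICC — ICC(2,1) in
#' Shrout-Fleiss / ICC(A,1) in McGraw-Wong terms — across the n-groups x
#' k-operators volume table, with an F-based 95% confidence interval.
#' Within each group the k operators fill the rater columns in operator-id
#' order (operators differ between groups; the column is an operator slot).
#'
#' @inheritParams precision_points
#' @param min_groups Minimum groups per stratum (default 2); smaller strata
#'   are skipped with a note in the `note` column.
#' @param conf_level Confidence level for the interval.
#' @return A `data.frame`: `n_operators`, `n_groups`, `icc`, `lower`,
#'   `upper`, `note`.
#' @export
icc_by_operator_count <- function(records, volume_formula = "eq1",
                                  min_groups = 2L, conf_level = 0.95) {
  records <- drop_excluded(records)
  records$..vol <- record_volumes(records, volume_formula)
  agg <- stats::aggregate(..vol ~ mouse_id + day + operator_id,
                          data = records, FUN = mean)
  groups <- split(agg, list(agg$mouse_id, agg$day), drop = TRUE)
  ks <- vapply(groups, nrow, integer(1L))
  out <- list()
  for (k in sort(unique(ks[ks >= 2L]))) {
    gs <- groups[ks == k]
    if (length(gs) < min_groups) {
      out[[length(out) + 1L]] <- data.frame(
        n_operators = k, n_groups = length(gs), icc = NA_real_,
        lower = NA_real_, upper = NA_real_,
        note = "stratum skipped: fewer than min_groups groups")
      next
    }
    mat <- t(vapply(gs, function(g) g$..vol[order(g$operator_id)],
                    numeric(k)))
    fit <- icc_a1(mat, conf_level = conf_level)
    out[[length(out) + 1L]] <- data.frame(
      n_operators = k, n_groups = nrow(mat), icc = fit$icc,
      lower = fit$lower, upper = fit$upper, note = "")
  }
  if (!length(out))
    return(data.frame(n_operators = integer(), n_groups = integer(),
                      icc = numeric(), lower = numeric(), upper = numeric(),
                      note = character()))
  do.call(rbind, out)
}

#' Two-way random-effects absolute-agreement single-measurement ICC
#'
#' ICC(A,1) of McGraw & Wong (1996) on an n x k table (rows: subjects,
#' columns: raters/slots), with the F-distribution confidence interval.
#' `MSE = 0` (all raters identical within every subject) returns ICC 1 by
#' convention.
#'
#' @param mat Numeric matrix, subjects in rows, raters in columns, no
#'   missing values.
#' @param conf_level Confidence level.
#' @return List with `icc`, `lower`, `upper` and the mean squares `msr`,
#'   `msc`, `mse`.
#' @export
icc_a1 <- function(mat, conf_level = 0.95) {
  mat <- as.matrix(mat)
  if (any(is.na(mat))) stop_data("ICC table must be complete")
  n <- nrow(mat); k <- ncol(mat)
  if (n < 2L || k < 2L) stop_data("ICC needs >= 2 subjects and >= 2 raters")
  grand <- mean(mat)
  rowm <- rowMeans(mat); colm <- colMeans(mat)
  msr <- k * sum((rowm - grand)^2) / (n - 1)
  msc <- n * sum((colm - grand)^2) / (k - 1)
  sse <- sum((mat - outer(rowm, colm, "+") + grand)^2)
  mse <- sse / ((n - 1) * (k - 1))

  if (mse == 0 && msc == 0) {
    icc <- if (msr == 0) NA_real_ else 1
    return(list(icc = icc, lower = NA_real_, upper = NA_real_,
                msr = msr, msc = msc, mse = mse))
  }
  icc <- (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))

  alpha <- 1 - conf_level
  a <- (k * icc) / (n * (1 - icc))
  b <- 1 + (k * icc * (n - 1)) / (n * (1 - icc))
  v <- (a * msc + b * mse)^2 /
    ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
  f_l <- stats::qf(1 - alpha / 2, n - 1, v)
  f_u <- stats::qf(1 - alpha / 2, v, n - 1)
  lower <- n * (msr - f_l * mse) /
    (f_l * (k * msc + (k * n - k - n) * mse) + n * msr)
  upper <- n * (f_u * msr - mse) /
    (k * msc + (k * n - k - n) * mse + n * f_u * msr)
  list(icc = icc, lower = lower, upper = upper,
       msr = msr, msc = msc, mse = mse)
}

#' Bland-Altman agreement between volume estimates and excised weight
#'
#' Converts weights to equivalent volumes with `V_eq = weight / density`
#' (g over g/cm^3, scaled to mm^3) and summarises the paired differences
#' `volume - V_eq` against the pair means, plus an ordinary least-squares
#' fit of difference on mean whose slope measures proportional bias.
#'
#' @param volumes Estimated volumes, mm^3.
#' @param weights Excised tumour weights, g (same length, paired).
#' @param density Assumed tissue density, g/cm^3 (default 1; soft tissue
#'   spans about 0.90-1.09).
#' @param conf_level Confidence level for the slope interval.
#' @return A list of class `vc_bland_altman`: `summary` (a one-row data
#'   frame with `mean_discrepancy`, `median_discrepancy`, `slope_m`,
#'   `slope_lower`, `slope_upper`, `intercept`, `r_squared`, `loa_lower`,
#'   `loa_upper`) and `points` (`mean`, `difference` per pair).
#' @export
bland_altman <- function(volumes, weights, density = 1, conf_level = 0.95) {
  if (length(volumes) != length(weights))
    stop_data("volumes and weights must be paired (equal length)")
  keep <- !is.na(volumes) & !is.na(weights)
  volumes <- volumes[keep]; weights <- weights[keep]
  if (any(volumes < 0) || any(weights <= 0))
    stop_data("volumes must be >= 0 and weights > 0")
  v_eq <- weights / density * 1000   # g / (g/cm^3) -> cm^3 -> mm^3
  diffs <- volumes - v_eq
  means <- (volumes + v_eq) / 2
  fit <- stats::lm(diffs ~ means)
  ci <- stats::confint(fit, level = conf_level)
  sdd <- stats::sd(diffs)
  smry <- data.frame(
    mean_discrepancy = mean(diffs),
    median_discrepancy = stats::median(diffs),
    slope_m = unname(stats::coef(fit)[2L]),
    slope_lower = ci[2L, 1L], slope_upper = ci[2L, 2L],
    intercept = unname(stats::coef(fit)[1L]),
    r_squared = summary(fit)$r.squared,
    loa_lower = mean(diffs) - 1.96 * sdd,
    loa_upper = mean(diffs) + 1.96 * sdd)
  structure(list(summary = smry,
                 points = data.frame(mean = means, difference = diffs)),
            class = "vc_bland_altman")
}

#' @export
print.vc_bland_altman <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    "<Bland-Altman: mean diff %.1f mm^3, median %.1f mm^3, slope m = %.3f, R^2 = %.2f>\n",
    s$mean_discrepancy, s$median_discrepancy, s$slope_m, s$r_squared))
  invisible(x)
}

#' Relative-error banding of volume against weight
#'
#' Computes the relative error `(V_eq - weight) / weight` per pair, where
#' `V_eq = volume * density / 1000` expresses the estimated volume as an
#' equivalent weight in grams, and reports the proportions in the canonical
#' bands: volume exceeding weight, absolute error below each requested band,
#' and weight at least half the volume equivalent.
#'
#' @inheritParams bland_altman
#' @param bands Absolute relative-error thresholds to band on (default 0.2
#'   and 0.5).
#' @return A list: `proportions` (named: `volume_exceeds_weight`,
#'   `abs_err_lt_<band>` per band, `weight_ge_half_volume`),
#'   `relative_errors` (per pair), `n_used`, `n_dropped` (zero/missing
#'   weights).
#' @export
relative_error_banding <- function(volumes, weights, density = 1,
                                   bands = c(0.2, 0.5)) {
  if (length(volumes) != length(weights))
    stop_data("volumes and weights must be paired (equal length)")
  bad <- is.na(volumes) | is.na(weights) | weights <= 0
  n_dropped <- sum(bad)
  volumes <- volumes[!bad]; weights <- weights[!bad]
  if (!length(volumes)) stop_data("no usable volume/weight pairs")
  v_eq <- volumes * density / 1000   # mm^3 -> cm^3 -> g
  rel <- (v_eq - weights) / weights
  props <- c(volume_exceeds_weight = mean(rel > 0))
  for (b in bands)
    props[paste0("abs_err_lt_", format(b))] <- mean(abs(rel) < b)
  props["weight_ge_half_volume"] <- mean(weights >= v_eq / 2)
  list(proportions = props, relative_errors = rel,
       n_used = length(rel), n_dropped = n_dropped)
}

#' Scan-vs-calliper same-day consistency
#'
#' Pairs every scan with the same-mouse, same-day calliper measurement
#' (multiple calliper readings are averaged) and counts, per linear
#' dimension, the fraction of scan measurements within `tolerance` mm of
#' the calliper value, the fraction beyond `extreme` mm, and 1-mm-binned
#' difference counts (split by `strain` when the column is present).
#'
#' @param scan_records,calliper_records Measurement-record data frames;
#'   `excluded` rows are dropped.
#' @param tolerance Agreement tolerance in mm (default 3).
#' @param extreme Secondary threshold in mm (default 8).
#' @param dimensions Columns to compare (default `length` and `width`).
#' @return A list of class `vc_consistency`: per-dimension list with
#'   `fraction_within`, `fraction_beyond_extreme`, `n_pairs`, `differences`,
#'   `histogram` (data frame `bin`, `strain`, `count`); plus `n_unmatched`
#'   scans.
#' @export
consistency_within <- function(scan_records, calliper_records, tolerance = 3,
                               extreme = 8, dimensions = c("length", "width")) {
  scan_records <- drop_excluded(scan_records)
  calliper_records <- drop_excluded(calliper_records)
  key <- function(d) paste(d$mouse_id, d$day, sep = "\r")
  cal_key <- key(calliper_records)
  scn_key <- key(scan_records)
  matched <- scn_key %in% cal_key
  n_unmatched <- sum(!matched)
  scans <- scan_records[matched, , drop = FALSE]
  scn_key <- scn_key[matched]
  if (!nrow(scans)) stop_data("no scan records match a same-day calliper record")

  out <- list(n_unmatched = n_unmatched, tolerance = tolerance,
              extreme = extreme)
  for (dm in dimensions) {
    cal_mean <- tapply(calliper_records[[dm]], cal_key, mean, na.rm = TRUE)
    d <- scans[[dm]] - as.numeric(cal_mean[scn_key])
    ok <- !is.na(d)
    d <- d[ok]
    strain <- if (!is.null(scans$strain)) as.character(scans$strain[ok])
              else rep("all", length(d))
    bins <- floor(d)  # 1 mm bins [b, b+1)
    hist_df <- as.data.frame(table(bin = bins, strain = strain),
                             responseName = "count",
                             stringsAsFactors = FALSE)
    hist_df$bin <- as.numeric(as.character(hist_df$bin))
    out[[dm]] <- list(
      fraction_within = mean(abs(d) <= tolerance),
      fraction_beyond_extreme = mean(abs(d) > extreme),
      n_pairs = length(d),
      differences = d,
      histogram = hist_df[hist_df$count > 0, , drop = FALSE])
  }
  structure(out, class = "vc_consistency")
}

#' @export
print.vc_consistency <- function(x, ...) {
  for (dm in setdiff(names(x), c("n_unmatched", "tolerance", "extreme"))) {
    cat(sprintf(
      "%s: %.2f%% within +/-%g mm, %.2f%% beyond %g mm (n = %d)\n",
      dm, 100 * x[[dm]]$fraction_within, x$tolerance,
      100 * x[[dm]]$fraction_beyond_extreme, x$extreme, x[[dm]]$n_pairs))
  }
  cat(sprintf("unmatched scans: %d\n", x$n_unmatched))
  invisible(x)
}

#' Welch one-sided t-tests with Holm adjustment
#'
#' One two-sample, unequal-variance (Welch) t-test per comparison, one-sided
#' with a configurable direction, Holm-adjusted across the family. A
#' degenerate comparison (zero variance in both groups and equal means) is
#' assigned p = 1 and flagged.
#'
#' @param groups_a,groups_b Lists of numeric vectors (>= 2 values each),
#'   compared element-wise.
#' @param labels Optional comparison labels.
#' @param alternative Direction of the alternative for `a` vs `b`
#'   (default `"less"`: a < b).
#' @return A `data.frame`: `comparison`, `statistic`, `df`, `p_value`,
#'   `p_adjusted`, `degenerate`.
#' @export
welch_one_sided_tests <- function(groups_a, groups_b, labels = NULL,
                                  alternative = c("less", "greater")) {
  alternative <- match.arg(alternative)
  if (!is.list(groups_a)) groups_a <- list(groups_a)
  if (!is.list(groups_b)) groups_b <- list(groups_b)
  if (length(groups_a) != length(groups_b))
    stop_data("groups_a and groups_b must have the same number of comparisons")
  if (is.null(labels)) labels <- paste0("comparison_", seq_along(groups_a))
  rows <- lapply(seq_along(groups_a), function(i) {
    a <- groups_a[[i]]; b <- groups_b[[i]]
    if (length(a) < 2L || length(b) < 2L)
      stop_data("each group needs >= 2 values (", labels[i], ")")
    if (stats::sd(a) == 0 && stats::sd(b) == 0) {
      return(data.frame(comparison = labels[i], statistic = NA_real_,
                        df = NA_real_, p_value = 1, degenerate = TRUE))
    }
    tt <- stats::t.test(a, b, alternative = alternative, var.equal = FALSE)
    data.frame(comparison = labels[i], statistic = unname(tt$statistic),
               df = unname(tt$parameter), p_value = tt$p.value,
               degenerate = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adjusted <- stats::p.adjust(out$p_value, method = "holm")
  out[, c("comparison", "statistic", "df", "p_value", "p_adjusted",
          "degenerate")]
}
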