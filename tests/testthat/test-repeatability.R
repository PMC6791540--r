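test_that("coefficient of variation: exact values, nulls, scale invariance", {
  expect_equal(coefficient_of_variation(c(5, 5, 5)), 0)
  expect_equal(coefficient_of_variation(c(2, 4)), sqrt(2) / 3,
               tolerance = 1e-12)          # 0.4714: sd = sqrt(2), mean = 3
  expect_identical(coefficient_of_variation(7), NA_real_)
  expect_identical(coefficient_of_variation(c(-3, 1)), NA_real_)  # mean <= 0
  set.seed(8)
  for (i in 1:5) {
    x <- rlnorm(10, 3, 0.4)
    expect_equal(coefficient_of_variation(17.3 * x),
                 coefficient_of_variation(x))
  }
})

test_that("precision points group by tumour-day and average duplicates", {
  rec <- manual_records(
    mouse_id = c("m1", "m1", "m2", "m2", "m2", "m3", "m1", "m1"),
    day = c(1, 1, 1, 1, 1, 1, 2, 2),
    operator_id = c("a", "b", "a", "b", "c", "a", "a", "a"),
    length = c(10, 10, 12, 14, 13, 9, 11, 13),
    width = c(8, 8, 9, 10, 9.5, 7, 8, 9))
  pts <- precision_points(rec, "eq1")
  # m3 day1 (1 operator) and m1 day2 (same operator twice) yield no points
  expect_identical(nrow(pts), 2L)
  p_m1 <- pts[pts$mouse_id == "m1", ]
  expect_identical(p_m1$n_operators, 2L)
  expect_equal(p_m1$cv, 0)               # identical measurements
  p_m2 <- pts[pts$mouse_id == "m2", ]
  vols <- spheroid_volume(c(12, 14, 13), c(9, 10, 9.5))
  expect_equal(p_m2$cv, sd(vols) / mean(vols))
})

test_that("three operators at volumes 500/600/700 give cv = 0.1667", {
  expect_equal(coefficient_of_variation(c(500, 600, 700)), 1 / 6,
               tolerance = 1e-12)
})

test_that("precision band summary partitions exactly into three fractions", {
  pts <- data.frame(mouse_id = "m", day = 1:4, n_operators = 2L,
                    cv = c(0.1, 0.3, 0, NA))
  bands <- precision_band_summary(pts, 0.2)
  expect_equal(unname(bands), c(0.5, 0.25, 0.25))
  expect_equal(sum(bands), 1)
  all0 <- precision_band_summary(data.frame(cv = c(0, 0), n_operators = 2L))
  expect_equal(unname(all0), c(1, 0, 0))
  expect_equal(unname(precision_band_summary(data.frame(cv = c(0.1, 0.3)))),
               c(0.5, 0.5, 0))
  expect_error(precision_band_summary(data.frame(cv = numeric())),
               class = "vc_data_error")
})

test_that("ICC(A,1) matches the reference implementation on frozen tables", {
  # expected values computed with pingouin.intraclass_corr (ICC2 row);
  # point estimates to 1e-9, CI bounds to pingouin's printed 2 dp
  mat <- matrix(c(10.2, 11.0, 10.8,  8.1,  8.4,  7.9,
                  12.5, 13.1, 12.2,  9.0,  9.6,  9.3,
                  15.2, 14.8, 15.9,  7.4,  7.0,  7.7,
                  11.1, 11.9, 11.4, 13.3, 12.9, 13.8),
                ncol = 3, byrow = TRUE)
  fit <- icc_a1(mat)
  expect_equal(fit$icc, 0.9774699211005784, tolerance = 1e-9)
  expect_equal(round(fit$lower, 2), 0.93)
  expect_equal(round(fit$upper, 2), 0.99)

  biased <- matrix(c(10.2, 13.0, 10.8,  8.1, 11.4,  7.9,
                     12.5, 16.1,  9.2,  9.0, 12.6,  8.3,
                     15.2, 17.8, 12.9,  7.4, 10.0,  8.7),
                   ncol = 3, byrow = TRUE)
  fit2 <- icc_a1(biased)
  expect_equal(fit2$icc, 0.5274593373953548, tolerance = 1e-9)
  expect_equal(round(fit2$lower, 2), 0.02)
  expect_equal(round(fit2$upper, 2), 0.90)
})

test_that("ICC limiting behaviour: perfect agreement and pure noise", {
  ident <- matrix(rep(c(3, 7, 11, 20, 4, 9), 3), ncol = 3)
  expect_equal(icc_a1(ident)$icc, 1)

  set.seed(21)
  noise <- matrix(rnorm(600), ncol = 3)   # no subject effect at all
  fit <- icc_a1(noise)
  expect_lt(abs(fit$icc), 0.1)
  expect_true(fit$lower < 0 || fit$lower < fit$icc)
})

test_that("ICC recovers known variance components on two-way data", {
  cases <- list(
    c(sb = 10, so = 0.5, se = 1),   # between >> within -> icc near 1
    c(sb = 2,  so = 1,   se = 1),
    c(sb = 1,  so = 0,   se = 2)
  )
  for (cs in cases) {
    truth <- cs[["sb"]]^2 / (cs[["sb"]]^2 + cs[["so"]]^2 + cs[["se"]]^2)
    mat <- twoway_icc_data(500, 3, cs[["sb"]], cs[["so"]], cs[["se"]],
                           seed = round(sum(cs) * 10))
    fit <- icc_a1(mat)
    expect_gt(fit$icc, fit$lower)
    expect_lt(fit$icc, fit$upper)
    # analytic component value within the estimate's CI (the rater variance
    # is estimated from only k = 3 raters, so a point tolerance would be
    # anti-conservative for the biased-rater cases)
    expect_gt(truth, fit$lower)
    expect_lt(truth, fit$upper)
    expect_lt(abs(fit$icc - truth), 0.1)
    if (truth > 0.97) expect_gt(fit$icc, 0.97)
  }
})

test_that("icc_by_operator_count stratifies groups by distinct operators", {
  set.seed(12)
  recs <- list()
  for (m in 1:12) {
    k <- if (m <= 6) 2L else 3L
    base <- rlnorm(1, log(12), 0.3)
    for (o in seq_len(k)) {
      recs[[length(recs) + 1L]] <- manual_records(
        mouse_id = paste0("m", m), day = 1, operator_id = paste0("op", o),
        length = base * 1.3 * exp(rnorm(1, 0, 0.05)),
        width = base * exp(rnorm(1, 0, 0.05)))
    }
  }
  rec <- do.call(rbind, recs)
  out <- icc_by_operator_count(rec, "eq1")
  expect_identical(out$n_operators, c(2L, 3L))
  expect_identical(out$n_groups, c(6L, 6L))
  expect_true(all(out$icc > 0 & out$icc <= 1))
  # a stratum with a single group is skipped with a note
  one <- icc_by_operator_count(rec[rec$mouse_id %in%
                                     c("m1", "m2", "m7"), , drop = FALSE])
  expect_match(one$note[one$n_operators == 3L], "skipped")
})

test_that("Bland-Altman: exact trivial cases and proportional bias recovery", {
  w <- c(0.2, 0.5, 1.0, 1.5, 2.2)          # g
  # exact fixtures are intentionally degenerate: silence lm's perfect-fit note
  exact <- suppressWarnings(bland_altman(w * 1000, w))
  expect_equal(exact$summary$mean_discrepancy, 0)
  expect_equal(exact$summary$slope_m, 0)

  off <- suppressWarnings(bland_altman(w * 1000 + 100, w))
  expect_equal(off$summary$mean_discrepancy, 100)
  expect_equal(off$summary$median_discrepancy, 100)
  expect_equal(off$summary$slope_m, 0)

  # mean difference identity
  set.seed(4)
  v <- rlnorm(40, log(800), 0.5); wt <- rlnorm(40, log(0.7), 0.4)
  ba <- bland_altman(v, wt)
  expect_equal(ba$summary$mean_discrepancy, mean(v) - mean(wt * 1000))

  # proportional bias: V = 1.5 * W_eq -> diff = 0.4 * mean, slope CI covers it
  set.seed(9)
  wt2 <- rlnorm(60, log(1), 0.3)
  ba2 <- suppressWarnings(bland_altman(1.5 * wt2 * 1000, wt2))
  expect_lt(ba2$summary$slope_lower, 0.4)
  expect_gt(ba2$summary$slope_upper, 0.4)
  expect_equal(ba2$summary$slope_m, 0.4, tolerance = 1e-6)
  expect_gt(ba2$summary$r_squared, 0.99)

  expect_error(bland_altman(1:3, 1:4), class = "vc_data_error")
})

test_that("relative-error banding: identity, exact formula, zero weights", {
  w <- c(0.5, 1, 2)
  ident <- relative_error_banding(w * 1000, w)
  expect_equal(unname(ident$proportions["volume_exceeds_weight"]), 0)
  expect_equal(unname(ident$proportions["abs_err_lt_0.2"]), 1)

  one <- relative_error_banding(1300, 1.0)
  expect_equal(unname(one$relative_errors), 0.3)

  dropped <- relative_error_banding(c(1000, 1200), c(1, 0))
  expect_identical(dropped$n_dropped, 1L)
  expect_identical(dropped$n_used, 1L)

  # weight >= half volume <=> relative error <= 1
  v <- c(1000, 1500, 2500); wt <- c(1, 1, 1)
  res <- relative_error_banding(v, wt)
  expect_equal(unname(res$proportions["weight_ge_half_volume"]), 2 / 3)
})

test_that("scan-calliper consistency counts pairs within tolerance", {
  cal <- manual_records(mouse_id = c("m1", "m2", "m3"), day = 1,
                        operator_id = "a", length = c(10, 12, 20),
                        width = c(8, 9, 15))
  scn <- manual_records(mouse_id = c("m1", "m2", "m3"), day = 1,
                        operator_id = "b", instrument = "scan",
                        length = c(8, 12, 24), width = c(8, 10, 16),
                        height = 5)
  scn <- rbind(scn, scn[3, ])
  scn$mouse_id[4] <- "m4"                 # unmatched scan
  res <- consistency_within(scn, cal, tolerance = 3)
  # length differences: -2, 0, +4 -> 2/3 within +/-3
  expect_equal(res$length$fraction_within, 2 / 3)
  expect_equal(res$width$fraction_within, 1)
  expect_identical(res$n_unmatched, 1L)
  expect_equal(res$length$fraction_beyond_extreme, 0)
  expect_identical(sum(res$length$histogram$count), 3L)

  # identical paired values -> 100% within any positive tolerance
  same <- consistency_within(cal, cal, tolerance = 0.5)
  expect_equal(same$length$fraction_within, 1)
  # tolerance -> infinity returns 1 by construction
  expect_equal(consistency_within(scn, cal, tolerance = Inf)$length$fraction_within, 1)
})

test_that("multiple same-day calliper readings are averaged before pairing", {
  cal <- manual_records(mouse_id = c("m1", "m1"), day = 1,
                        operator_id = c("a", "b"), length = c(10, 14),
                        width = c(8, 8))
  scn <- manual_records(mouse_id = "m1", day = 1, operator_id = "s",
                        instrument = "scan", length = 12.5, width = 8)
  res <- consistency_within(scn, cal, tolerance = 3)
  expect_equal(res$length$differences, 0.5)   # 12.5 - mean(10, 14)
})

test_that("Welch one-sided tests: direction, Holm, degenerate groups", {
  set.seed(3)
  a <- rnorm(50, 0, 1); b <- rnorm(50, 5, 1)
  res <- welch_one_sided_tests(list(a), list(b), labels = "shifted")
  expect_lt(res$p_adjusted, 1e-6)             # 5 sigma separation
  expect_equal(res$p_adjusted, res$p_value)   # Holm with m = 1

  multi <- welch_one_sided_tests(list(a, a), list(b, a + 0.01))
  # Holm: the smallest of two p-values is doubled
  expect_equal(multi$p_adjusted[1], min(1, 2 * multi$p_value[1]))

  deg <- welch_one_sided_tests(list(rep(2, 5)), list(rep(2, 4)))
  expect_true(deg$degenerate)
  expect_equal(deg$p_value, 1)

  wrong_dir <- welch_one_sided_tests(list(b), list(a))
  expect_gt(wrong_dir$p_adjusted, 0.99)       # alternative is "less"
})
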