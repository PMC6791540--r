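test_that("read_records parses, validates and reports rejections", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "mouse,day,op,device,len_mm,wid_mm,wt_g",
    "m1,1,a,calliper,10.2,8.1,",
    "m1,1,b,calliper,11.0,8.4,",
    "m2,3,a,calliper,NA,7.0,0.9",
    "m2,3,b,calliper,9.0,oops,0.9",
    "m3,5,a,calliper,12.0,9.0,1.2"), path)
  schema <- schema_map(columns = c(
    mouse_id = "mouse", day = "day", operator_id = "op",
    instrument = "device", length = "len_mm", width = "wid_mm",
    weight = "wt_g"))
  rr <- read_records(path, schema)
  expect_identical(rr$n_kept, 3L)
  expect_identical(rr$n_rejected, 2L)
  expect_match(rr$rejects$reason[1], "length missing")
  expect_match(rr$rejects$reason[2], "unparseable numeric in width")
  expect_equal(rr$records$weight[3], 1.2)
  expect_true(is.numeric(rr$records$day))
})

test_that("well-formed fixtures load completely", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("mouse_id,day,operator_id,instrument,length,width",
               "m1,1,a,calliper,10,8",
               "m2,1,a,calliper,12,9",
               "m3,1,b,scan,11,7"), path)
  rr <- read_records(path, schema_map())
  expect_identical(rr$n_kept, 3L)
  expect_identical(rr$n_rejected, 0L)
})

test_that("unit factors convert file units into mm", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("mouse_id,day,operator_id,length,width",
               "m1,1,a,1.0,0.8"), path)       # cm in file
  schema <- schema_map(
    columns = c(mouse_id = "mouse_id", day = "day",
                operator_id = "operator_id", length = "length",
                width = "width"),
    unit_factors = c(length = 10, width = 10))
  rr <- read_records(path, schema)
  expect_equal(rr$records$length, 10)
  expect_equal(rr$records$width, 8)
})

test_that("missing mapped columns raise a schema error naming the column", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("mouse_id,day,operator_id,length", "m1,1,a,10"), path)
  err <- tryCatch(read_records(path, schema_map()),
                  vc_config_error = function(e) conditionMessage(e))
  expect_match(err, "width")
})

test_that("write/read round trip reproduces records exactly", {
  g <- generate_records(generator_config(n_mice = 6L, n_days = 2L, seed = 5))
  path <- withr::local_tempfile(fileext = ".csv")
  write_records(g$records, path)
  fields <- c("study_id", "mouse_id", "day", "operator_id", "instrument",
              "length", "width", "height", "area", "weight", "excluded",
              "strain")
  schema <- schema_map(columns = setNames(fields, fields))
  rr <- read_records(path, schema)
  expect_identical(rr$n_rejected, 0L)
  expect_equal(rr$records$length, g$records$length, tolerance = 1e-12)
  expect_equal(rr$records$weight, g$records$weight, tolerance = 1e-12)
  expect_identical(rr$records$mouse_id, g$records$mouse_id)
})

test_that("schema files round-trip through read_schema", {
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("# layout of a cm-unit export",
               "mouse_id: Animal", "day: Day", "operator_id: Operator",
               "length: L", "width: W", "unit.length: 10", "unit.width: 10"),
             path)
  sc <- read_schema(path)
  expect_identical(unname(sc$columns[["length"]]), "L")
  expect_equal(unname(sc$unit_factors[["width"]]), 10)
})

test_that("generator is deterministic and honours its config", {
  cfg <- generator_config(n_mice = 10L, n_operators = 2L, n_days = 2L,
                          seed = 42)
  a <- generate_records(cfg)
  b <- generate_records(cfg)
  expect_identical(a$records, b$records)
  expect_identical(a$truth, b$truth)
  expect_error(generator_config(noise_cv = -1), class = "vc_config_error")
  expect_error(generator_config(missing_rate = 2), class = "vc_config_error")
})

test_that("noiseless generator reproduces true volumes through the formula", {
  g <- generate_records(generator_config(
    n_mice = 8L, n_operators = 2L, n_days = 2L, noise_cv = 0,
    operator_bias_sdlog = 0, missing_rate = 0, seed = 3))
  vols <- spheroid_volume(g$records$length, g$records$width)
  truth_vol <- g$truth$true_volume[match(
    paste(g$records$mouse_id, g$records$day),
    paste(g$truth$mouse_id, g$truth$day))]
  expect_equal(vols, truth_vol, tolerance = 1e-10)
  # every precision point has cv exactly 0
  pts <- precision_points(g$records, "eq1")
  expect_true(all(pts$cv == 0))
  # weights are exact at density 1: zero relative-error exceedance
  w <- g$records[!is.na(g$records$weight), ]
  reb <- relative_error_banding(spheroid_volume(w$length, w$width), w$weight)
  expect_equal(unname(reb$proportions["volume_exceeds_weight"]), 0)
})

test_that("generated inter-operator volume CV matches the delta method", {
  # V ~ l * w^2 with independent multiplicative noise of CV 0.1 per
  # dimension -> volume CV ~= sqrt(1 + 4) * 0.1. With many operators the
  # per-group sample CV is nearly unbiased, so compare the mean CV directly.
  g <- generate_records(generator_config(
    n_mice = 300L, n_operators = 6L, n_days = 1L, noise_cv = 0.1,
    operator_bias_sdlog = 0, missing_rate = 0, seed = 14))
  pts <- precision_points(g$records, "eq1")
  predicted <- sqrt(5) * 0.1
  expect_lt(abs(mean(pts$cv) / predicted - 1), 0.1)
})

test_that("lattice snapshots round-trip through NPY + sidecar", {
  lat <- init_tumour("two_peak", c(40L, 40L, 20L), voxel_edge = 0.25)
  dir <- withr::local_tempdir()
  path <- file.path(dir, "snap.npy")
  write_lattice_npy(lat, path)
  back <- read_lattice_npy(path)
  expect_identical(back$state, lat$state)
  expect_identical(back$dims, lat$dims)
  expect_equal(back$voxel_edge, lat$voxel_edge)
  # header is a valid NPY v1.0 preamble
  con <- file(path, "rb"); on.exit(close(con))
  expect_identical(readBin(con, "raw", 6L),
                   as.raw(c(0x93, 0x4e, 0x55, 0x4d, 0x50, 0x59)))
})
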