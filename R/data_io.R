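# Readers/writers for tabular measurement records and a synthetic-record
# generator with controlled statistical structure, so every statistic in the
# package is testable without access to proprietary study data.

RECORD_FIELDS <- c("study_id", "mouse_id", "day", "operator_id", "instrument",
                   "length", "width", "height", "area", "weight", "excluded",
                   "strain")
REQUIRED_FIELDS <- c("mouse_id", "day", "operator_id", "instrument",
                     "length", "width")
NUMERIC_FIELDS <- c("length", "width", "height", "area", "weight")

#' Schema map for a measurement CSV dialect
#'
#' Declares how the columns of a particular CSV layout map onto the
#' canonical measurement-record fields, and the unit factors that bring the
#' file's numbers to package units (mm, mm^2, g). Supplementary datasets
#' from different sources only need a schema edit, not code.
#'
#' @param columns Named character vector: canonical field -> column name in
#'   the file. Fields absent from the file are simply not mapped; the
#'   required fields are `mouse_id`, `day`, `operator_id`, `instrument`,
#'   `length`, `width`.
#' @param unit_factors Named numeric vector of multiplicative factors
#'   applied after parsing (e.g. `c(length = 10, width = 10)` for a file in
#'   cm). Unmentioned fields keep factor 1.
#' @param na_strings Strings treated as missing.
#' @param default_instrument Instrument assumed when the file has no
#'   instrument column.
#' @return A list of class `vc_schema`.
#' @export
schema_map <- function(columns = stats::setNames(REQUIRED_FIELDS,
                                                 REQUIRED_FIELDS),
                       unit_factors = numeric(),
                       na_strings = c("", "NA", "NULL"),
                       default_instrument = "calliper") {
  columns <- unlist(columns)
  unknown <- setdiff(names(columns), RECORD_FIELDS)
  if (length(unknown))
    stop_config("schema maps unknown record fields: ",
                paste(unknown, collapse = ", "))
  missing_req <- setdiff(setdiff(REQUIRED_FIELDS, "instrument"),
                         names(columns))
  if (length(missing_req))
    stop_config("schema must map required fields: ",
                paste(missing_req, collapse = ", "))
  if (any(unit_factors <= 0)) stop_config("unit factors must be positive")
  structure(list(columns = columns, unit_factors = unit_factors,
                 na_strings = na_strings,
                 default_instrument = default_instrument),
            class = "vc_schema")
}

#' Read a schema map from a flat key:value file
#'
#' Lines of the form `field: column`, plus optional `unit.<field>: factor`
#' lines; `#` starts a comment.
#'
#' @param path Path to the schema file.
#' @return A `vc_schema`.
#' @export
read_schema <- function(path) {
  kv <- parse_kv_file(path)
  unit_keys <- grep("^unit\\.", names(kv), value = TRUE)
  factors <- vapply(kv[unit_keys], as.numeric, numeric(1L))
  names(factors) <- sub("^unit\\.", "", unit_keys)
  cols <- unlist(kv[setdiff(names(kv), c(unit_keys, "default_instrument"))])
  schema_map(columns = cols, unit_factors = factors,
             default_instrument = kv$default_instrument %||% "calliper")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read measurement records from a CSV file
#'
#' Parses a delimited file under a [schema_map()], applies unit conversions
#' and validates every row against the record invariants (positive lengths
#' and weights, known instrument). Failing rows are rejected with row-level
#' diagnostics rather than aborting the read.
#'
#' @param path CSV file with a header row.
#' @param schema A `vc_schema` describing the file's layout.
#' @return A list of class `vc_records`: `records` (validated data frame),
#'   `n_kept`, `n_rejected`, `rejects` (data frame `row`, `reason`).
#' @export
read_records <- function(path, schema = schema_map()) {
  if (!file.exists(path)) stop_data("no such file: ", path)
  raw <- utils::read.csv(path, colClasses = "character",
                         check.names = FALSE, strip.white = TRUE)
  missing_cols <- setdiff(unname(schema$columns), names(raw))
  if (length(missing_cols))
    stop_config("mapped column(s) absent from ", path, ": ",
                paste(missing_cols, collapse = ", "))

  n <- nrow(raw)
  rec <- data.frame(row.names = seq_len(n))
  for (f in names(schema$columns)) {
    v <- raw[[schema$columns[[f]]]]
    v[v %in% schema$na_strings] <- NA
    rec[[f]] <- v
  }
  if (is.null(rec$instrument))
    rec$instrument <- schema$default_instrument
  if (is.null(rec$excluded)) rec$excluded <- "FALSE"

  reasons <- character(n)
  for (f in intersect(NUMERIC_FIELDS, names(rec))) {
    parsed <- suppressWarnings(as.numeric(rec[[f]]))
    bad <- !is.na(rec[[f]]) & is.na(parsed)
    reasons[bad & !nzchar(reasons)] <- paste0("unparseable numeric in ", f)
    fac <- if (f %in% names(schema$unit_factors))
      schema$unit_factors[[f]] else 1
    rec[[f]] <- parsed * fac
  }
  rec$excluded <- tolower(trimws(rec$excluded)) %in%
    c("true", "t", "1", "yes", "y")
  suppressWarnings(day_num <- as.numeric(rec$day))
  if (!all(is.na(day_num))) rec$day <- day_num

  for (f in c("length", "width")) {
    bad <- is.na(rec[[f]]) | rec[[f]] <= 0
    reasons[bad & !nzchar(reasons)] <-
      paste0(f, " missing or non-positive")
  }
  if (!is.null(rec$weight)) {
    bad <- !is.na(rec$weight) & rec$weight <= 0
    reasons[bad & !nzchar(reasons)] <- "non-positive weight"
  }
  bad <- !rec$instrument %in% c("calliper", "scan")
  reasons[bad & !nzchar(reasons)] <- "unknown instrument"
  bad <- is.na(rec$mouse_id) | is.na(rec$operator_id) | is.na(rec$day)
  reasons[bad & !nzchar(reasons)] <- "missing identifier (mouse/operator/day)"

  keep <- !nzchar(reasons)
  rejects <- data.frame(row = which(!keep), reason = reasons[!keep])
  records <- rec[keep, , drop = FALSE]
  rownames(records) <- NULL
  structure(list(records = records, n_kept = nrow(records),
                 n_rejected = nrow(rejects), rejects = rejects),
            class = "vc_records")
}

#' @export
print.vc_records <- function(x, ...) {
  cat(sprintf("<vc_records: %d kept, %d rejected>\n", x$n_kept, x$n_rejected))
  invisible(x)
}

#' Write measurement records to CSV
#'
#' Canonical comma-delimited, header-row, UTF-8 output; a round trip through
#' [read_records()] with the default schema reproduces the records.
#'
#' @param records Measurement-record data frame.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_records <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Generator configuration for synthetic measurement records
#'
#' The generator's statistical structure mirrors a multi-operator calliper
#' study: per-mouse true volumes are log-normal; linear dimensions are
#' derived spheroid-consistently (`V = (pi/6) l w^2` with a drawn
#' length/width aspect ratio); each operator observes every dimension with a
#' multiplicative per-operator bias factor and multiplicative log-normal
#' noise. Weight is exact (`true volume x density`), so every
#' volume-vs-weight discrepancy downstream comes from the measurement model.
#'
#' @param n_mice Number of mice.
#' @param n_operators Operators measuring every mouse/day.
#' @param n_days Measurement days per mouse (spaced `day_spacing` apart).
#' @param day_spacing Days between measurements.
#' @param volume_meanlog,volume_sdlog Log-normal parameters of the true
#'   baseline volume (mm^3); defaults centre on ~500 mm^3, a typical
#'   mid-study xenograft.
#' @param growth_rate Exponential volume growth per day.
#' @param aspect_meanlog,aspect_sdlog Log-normal parameters of the
#'   length/width aspect ratio (draws < 1 are inverted so length >= width).
#' @param height_ratio Height/width ratio (subcutaneous tumours are flatter
#'   than wide; default 0.7).
#' @param operator_bias_sdlog Log-scale SD of per-operator multiplicative
#'   dimension bias (0 = unbiased operators).
#' @param noise_cv Multiplicative measurement noise CV per dimension.
#' @param density Tissue density g/cm^3 for weight generation.
#' @param missing_rate Probability a record is dropped (lost measurement).
#' @param excluded_rate Probability a record is flagged `excluded`.
#' @param instruments Instruments to emit records for; scans carry height
#'   and footprint area, callipers only length/width.
#' @param seed RNG seed.
#' @return A list of class `vc_gen_config`.
#' @export
generator_config <- function(n_mice = 50L, n_operators = 3L, n_days = 3L,
                             day_spacing = 3L,
                             volume_meanlog = log(500), volume_sdlog = 0.5,
                             growth_rate = 0.1,
                             aspect_meanlog = log(1.25), aspect_sdlog = 0.15,
                             height_ratio = 0.7,
                             operator_bias_sdlog = 0.05,
                             noise_cv = 0.1,
                             density = 1.0,
                             missing_rate = 0.02,
                             excluded_rate = 0,
                             instruments = "calliper",
                             seed = 1L) {
  cfg <- as.list(environment())
  problems <- character()
  for (nm in c("missing_rate", "excluded_rate")) {
    if (cfg[[nm]] < 0 || cfg[[nm]] > 1)
      problems <- c(problems, paste(nm, "must be in [0, 1]"))
  }
  if (noise_cv < 0) problems <- c(problems, "noise_cv must be >= 0")
  if (operator_bias_sdlog < 0)
    problems <- c(problems, "operator_bias_sdlog must be >= 0")
  if (height_ratio <= 0) problems <- c(problems, "height_ratio must be > 0")
  if (n_mice < 1 || n_operators < 1 || n_days < 1)
    problems <- c(problems, "n_mice, n_operators, n_days must be >= 1")
  if (!all(instruments %in% c("calliper", "scan")))
    problems <- c(problems, "instruments must be calliper and/or scan")
  if (length(problems))
    stop_config("invalid generator config: ", paste(problems, collapse = "; "))
  structure(cfg, class = "vc_gen_config")
}

#' Generate synthetic measurement records with known ground truth
#'
#' Draws the latent truth (per-mouse volumes and dimensions, per-operator
#' bias factors) and emits observed records per operator/day/instrument,
#' together with the latent truth tables needed for parameter-recovery
#' tests. Identical seed and config give identical output. Excised weight
#' is attached to the last-day records of each mouse.
#'
#' @param config A [generator_config()].
#' @return A list of class `vc_synth`: `records` (measurement-record data
#'   frame), `truth` (per mouse/day: true volume mm^3, true dimensions mm,
#'   true weight g), `operator_factors` (per operator).
#' @export
generate_records <- function(config = generator_config()) {
  stopifnot(inherits(config, "vc_gen_config"))
  cfg <- config
  with_seed(cfg$seed, {
    mice <- sprintf("m%03d", seq_len(cfg$n_mice))
    ops <- sprintf("op%02d", seq_len(cfg$n_operators))
    days <- seq(0L, by = cfg$day_spacing, length.out = cfg$n_days)
    sdlog_noise <- sqrt(log(1 + cfg$noise_cv^2))

    op_factor <- stats::setNames(
      exp(stats::rnorm(cfg$n_operators, 0, cfg$operator_bias_sdlog)), ops)

    v0 <- stats::rlnorm(cfg$n_mice, cfg$volume_meanlog, cfg$volume_sdlog)
    aspect <- stats::rlnorm(cfg$n_mice, cfg$aspect_meanlog, cfg$aspect_sdlog)
    aspect <- pmax(aspect, 1 / aspect)   # length >= width
    strain <- sample(c("SCID", "BALB/c", "C57BL/6", "NSG", "Nude"),
                     cfg$n_mice, replace = TRUE)

    truth <- do.call(rbind, lapply(seq_len(cfg$n_mice), function(i) {
      v <- v0[i] * exp(cfg$growth_rate * days)
      w <- (6 * v / (pi * aspect[i]))^(1 / 3)   # V = (pi/6) * (a*w) * w^2
      data.frame(mouse_id = mice[i], strain = strain[i], day = days,
                 true_volume = v, true_length = aspect[i] * w,
                 true_width = w, true_height = cfg$height_ratio * w,
                 true_weight = v * cfg$density / 1000)
    }))

    recs <- list()
    for (i in seq_len(nrow(truth))) {
      tr <- truth[i, ]
      last_day <- tr$day == max(days)
      for (op in ops) {
        for (inst in cfg$instruments) {
          if (stats::runif(1) < cfg$missing_rate) next
          f <- op_factor[[op]]
          noise <- exp(stats::rnorm(3L, 0, sdlog_noise))
          l <- tr$true_length * f * noise[1L]
          w <- tr$true_width * f * noise[2L]
          h <- tr$true_height * f * noise[3L]
          recs[[length(recs) + 1L]] <- data.frame(
            study_id = "synthetic", mouse_id = tr$mouse_id,
            strain = tr$strain, day = tr$day, operator_id = op,
            instrument = inst,
            length = max(l, w), width = min(l, w),
            height = if (inst == "scan") h else NA_real_,
            area = if (inst == "scan") pi / 4 * l * w else NA_real_,
            weight = if (last_day) tr$true_weight else NA_real_,
            excluded = stats::runif(1) < cfg$excluded_rate)
        }
      }
    }
    records <- do.call(rbind, recs)
    rownames(records) <- NULL
    structure(list(records = records, truth = truth,
                   operator_factors = data.frame(
                     operator_id = ops, factor = unname(op_factor))),
              class = "vc_synth")
  })
}

#' @export
print.vc_synth <- function(x, ...) {
  cat(sprintf("<vc_synth: %d records, %d mice, %d operators>\n",
              nrow(x$records), length(unique(x$records$mouse_id)),
              nrow(x$operator_factors)))
  invisible(x)
}

# parse a flat "key: value" config file; '#' comments; returns named list of
# strings
parse_kv_file <- function(path) {
  if (!file.exists(path)) stop_config("no such config file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    m <- regmatches(ln, regexec("^([^:]+):(.*)$", ln))[[1L]]
    if (length(m) != 3L)
      stop_config("malformed config line (expected 'key: value'): ", ln)
    out[[trimws(m[2L])]] <- trimws(m[3L])
  }
  out
}
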