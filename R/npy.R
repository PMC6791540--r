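# Minimal NPY (v1.0) writer/reader for integer lattice snapshots, plus a
# JSON sidecar with the lattice geometry. Fortran (column-major) order
# matches R's array layout, so the voxel data round-trips byte-for-byte
# and loads directly in numpy.

npy_header <- function(dims) {
  dict <- sprintf("{'descr': '<i4', 'fortran_order': True, 'shape': (%s), }",
                  paste(dims, collapse = ", "))
  # total header (magic 6 + version 2 + len 2 + dict) padded to 64 bytes
  pad <- 64L - ((10L + nchar(dict) + 1L) %% 64L)
  if (pad == 64L) pad <- 0L
  paste0(dict, strrep(" ", pad), "\n")
}

#' Write a lattice snapshot as NPY + JSON sidecar
#'
#' Stores the voxel state array as a little-endian int32 NPY file readable
#' by numpy, and a `<path>.json` sidecar holding `dims` and `voxel_edge`.
#'
#' @param lattice A `vc_lattice`.
#' @param path Output `.npy` path.
#' @return `path`, invisibly.
#' @export
write_lattice_npy <- function(lattice, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x93, 0x4e, 0x55, 0x4d, 0x50, 0x59, 0x01, 0x00)), con)
  hdr <- npy_header(lattice$dims)
  writeBin(as.integer(nchar(hdr)), con, size = 2L, endian = "little")
  writeChar(hdr, con, eos = NULL)
  writeBin(as.integer(lattice$state), con, size = 4L, endian = "little")
  jsonlite::write_json(
    list(dims = lattice$dims, voxel_edge = lattice$voxel_edge),
    paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' Read a lattice snapshot written by [write_lattice_npy()]
#'
#' @param path The `.npy` path (the `<path>.json` sidecar must sit next to
#'   it).
#' @return A `vc_lattice`.
#' @export
read_lattice_npy <- function(path) {
  side <- paste0(path, ".json")
  if (!file.exists(side)) stop_data("missing JSON sidecar: ", side)
  meta <- jsonlite::read_json(side, simplifyVector = TRUE)
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", 8L)
  if (!identical(magic[1:6],
                 as.raw(c(0x93, 0x4e, 0x55, 0x4d, 0x50, 0x59))))
    stop_data("not an NPY file: ", path)
  hlen <- readBin(con, "integer", 1L, size = 2L, endian = "little",
                  signed = FALSE)
  hdr <- readChar(con, hlen)
  m <- regmatches(hdr, regexec("'shape':\\s*\\(([0-9, ]+)\\)", hdr))[[1L]]
  dims <- as.integer(strsplit(m[2L], ",")[[1L]])
  if (!identical(dims, as.integer(meta$dims)))
    stop_data("NPY shape disagrees with sidecar dims")
  vals <- readBin(con, "integer", prod(dims), size = 4L, endian = "little")
  new_lattice(dims, meta$voxel_edge, array(vals, dim = dims))
}
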