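# Minimal single-file NIfTI-1 I/O.
#
# No NIfTI package is available in this R stack, so the package carries a
# small reader/writer for the subset of NIfTI-1 it needs: single-file
# (.nii / .nii.gz), 3D, little-endian, datatypes uint8 / int16 / int32 /
# float32 / float64, with scl_slope/scl_inter honoured on read. The writer
# emits an sform with a diagonal voxel-size affine so files open cleanly in
# standard viewers and in nibabel.

NIFTI_DTYPES <- list(
  uint8   = list(code = 2L,  bitpix = 8L),
  int16   = list(code = 4L,  bitpix = 16L),
  int32   = list(code = 8L,  bitpix = 32L),
  float32 = list(code = 16L, bitpix = 32L),
  float64 = list(code = 64L, bitpix = 64L)
)

#' Write a voxel grid to a NIfTI-1 file
#'
#' @param grid a [voxel_grid()].
#' @param path output path; a `.gz` suffix triggers gzip compression.
#' @param datatype `"auto"` stores binary/uint8-ranged integer data as
#'   `uint8` and everything else as `float32`; or force one of `"uint8"`,
#'   `"int16"`, `"int32"`, `"float32"`, `"float64"`.
#' @return `path`, invisibly.
#' @export
write_nifti <- function(grid, path, datatype = "auto") {
  stopifnot(inherits(grid, "voxel_grid"))
  v <- grid$values
  if (identical(datatype, "auto")) {
    datatype <- if (all(v == round(v)) && min(v) >= 0 && max(v) <= 255)
      "uint8" else "float32"
  }
  dt <- NIFTI_DTYPES[[datatype]]
  if (is.null(dt)) stop("unsupported datatype: ", datatype)

  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))

  wb <- function(x, size) writeBin(x, con, size = size, endian = "little")
  wchar <- function(s, len) {
    raw <- charToRaw(s)
    writeBin(c(raw[seq_len(min(length(raw), len))],
               raw(len - min(length(raw), len))), con)
  }
  d <- dim(v)
  vs <- grid$voxel_size_mm

  wb(348L, 4L)                               # sizeof_hdr
  writeBin(raw(36L), con)                    # data_type..dim_info
  wb(as.integer(c(3L, d, 1L, 1L, 1L, 1L)), 2L)   # dim[8]
  wb(numeric(3), 4L)                         # intent_p1..p3
  wb(0L, 2L)                                 # intent_code
  wb(dt$code, 2L)                            # datatype
  wb(dt$bitpix, 2L)                          # bitpix
  wb(0L, 2L)                                 # slice_start
  wb(c(1, vs, 1, 1, 1, 1), 4L)               # pixdim[8]
  wb(352, 4L)                                # vox_offset
  wb(1, 4L)                                  # scl_slope
  wb(0, 4L)                                  # scl_inter
  wb(0L, 2L)                                 # slice_end
  writeBin(raw(1L), con)                     # slice_code
  writeBin(as.raw(10L), con)                 # xyzt_units: mm
  wb(numeric(4), 4L)                         # cal_max..toffset
  wb(integer(2), 4L)                         # glmax, glmin
  wchar("cisconvert", 80L)                   # descrip
  wchar("", 24L)                             # aux_file
  wb(0L, 2L)                                 # qform_code
  wb(1L, 2L)                                 # sform_code
  wb(numeric(6), 4L)                         # quatern_b..qoffset_z
  wb(c(vs[1], 0, 0, 0), 4L)                  # srow_x
  wb(c(0, vs[2], 0, 0), 4L)                  # srow_y
  wb(c(0, 0, vs[3], 0), 4L)                  # srow_z
  wchar("", 16L)                             # intent_name
  writeBin(c(charToRaw("n+1"), raw(1L)), con) # magic
  writeBin(raw(4L), con)                     # extension flag

  vals <- as.vector(v)
  if (datatype %in% c("uint8", "int16", "int32")) {
    size <- dt$bitpix / 8L
    if (datatype == "uint8") writeBin(as.raw(vals), con)
    else wb(as.integer(vals), size)
  } else {
    wb(as.double(vals), dt$bitpix / 8L)
  }
  invisible(path)
}

#' Read a NIfTI-1 file into a voxel grid
#'
#' Reads single-file little-endian NIfTI-1 (optionally gzipped) with 3D
#' data (trailing singleton dimensions are dropped). Values are rescaled by
#' `scl_slope`/`scl_inter` when set.
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @return A [voxel_grid()].
#' @export
read_nifti <- function(path) {
  con <- gzfile(path, "rb")   # gzfile transparently reads plain files too
  on.exit(close(con))
  rb <- function(what, n, size) readBin(con, what, n = n, size = size,
                                        endian = "little", signed = TRUE)
  hdr <- rb(integer(), 1L, 4L)
  if (!identical(hdr, 348L))
    stop("not a little-endian NIfTI-1 file (sizeof_hdr != 348)")
  readBin(con, raw(), 36L)
  dims <- rb(integer(), 8L, 2L)
  ndim <- dims[1]
  if (ndim < 3L) stop("expected >= 3 dimensions")
  d <- dims[2:4]
  if (ndim > 3L && any(dims[5:(1 + ndim)] > 1L))
    stop("only 3D volumes are supported")
  rb(numeric(), 3L, 4L)
  rb(integer(), 1L, 2L)                      # intent_code
  datatype <- rb(integer(), 1L, 2L)
  rb(integer(), 1L, 2L)                      # bitpix
  rb(integer(), 1L, 2L)                      # slice_start
  pixdim <- rb(numeric(), 8L, 4L)
  vox_offset <- rb(numeric(), 1L, 4L)
  scl_slope <- rb(numeric(), 1L, 4L)
  scl_inter <- rb(numeric(), 1L, 4L)
  # skip the rest of the header + extensions up to vox_offset
  readBin(con, raw(), as.integer(vox_offset) - 120L)

  n <- prod(d)
  vals <- switch(as.character(datatype),
    "2"  = as.integer(readBin(con, raw(), n)),
    "4"  = rb(integer(), n, 2L),
    "8"  = rb(integer(), n, 4L),
    "16" = rb(numeric(), n, 4L),
    "64" = rb(numeric(), n, 8L),
    stop("unsupported NIfTI datatype code: ", datatype)
  )
  if (length(vals) != n) stop("truncated NIfTI data section")
  if (is.finite(scl_slope) && scl_slope != 0 &&
      !(scl_slope == 1 && scl_inter == 0))
    vals <- vals * scl_slope + scl_inter
  voxel_grid(array(vals, d), pixdim[2:4])
}
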