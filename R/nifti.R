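# Minimal single-file NIfTI-1 (.nii, uncompressed, little-endian) I/O.
# No NIfTI package is available in the target library set, so the fixed
# 348-byte header is read and written directly. Supported datatypes:
# uint8 (2), int16 (4), int32 (8), float32 (16), float64 (64). Spacing is
# carried in pixdim and the origin in an axis-aligned sform.

#' Write a volume to a NIfTI-1 file
#'
#' Accepts an [hu_volume()], [skull_mask()], [pressure_field()] or a plain
#' array. Masks are stored as uint8, everything else as float32 (or
#' float64 with `datatype = 64`).
#'
#' @param x the volume object.
#' @param path output path ending in `.nii`.
#' @param datatype NIfTI datatype code (2, 16 or 64); default chosen from
#'   the object.
#' @param spacing_mm,origin_mm overrides for plain arrays.
#' @return `path`, invisibly.
#' @export
write_nifti <- function(x, path, datatype = NULL, spacing_mm = NULL,
                        origin_mm = NULL) {
  if (inherits(x, "hu_volume")) {
    vals <- x$values; sp <- x$spacing_mm; or <- x$origin_mm
  } else if (inherits(x, "skull_mask")) {
    vals <- x$mask * 1L; sp <- x$spacing_mm; or <- x$origin_mm
    if (is.null(datatype)) datatype <- 2L
  } else if (inherits(x, "pressure_field")) {
    vals <- x$max_pressure; sp <- x$spacing_mm; or <- x$origin_mm
  } else if (inherits(x, "bmode_stack")) {
    vals <- x$slices
    sp <- c(x$in_plane_spacing_mm, x$slice_spacing_mm); or <- x$origin_mm
  } else {
    vals <- as.array(x)
    sp <- spacing_mm %||% rep(1, length(dim(vals)))
    or <- origin_mm %||% rep(0, length(dim(vals)))
  }
  if (!is.null(spacing_mm)) sp <- spacing_mm
  if (!is.null(origin_mm)) or <- origin_mm
  if (is.null(datatype)) datatype <- 16L
  dims <- dim(vals)
  nd <- length(dims)
  stopifnot(nd >= 1L, nd <= 7L)
  dim8 <- c(nd, dims, rep(1L, 7L - nd))
  pixdim8 <- c(1, sp, rep(1, 7 - nd))
  sp3 <- c(sp, rep(1, 3))[1:3]
  or3 <- c(or, rep(0, 3))[1:3]
  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(v, size) writeBin(as.integer(v), con, size = size,
                                   endian = "little")
  wf <- function(v) writeBin(as.numeric(v), con, size = 4, endian = "little")
  wi(348L, 4)                                   # sizeof_hdr
  writeBin(raw(36), con)                        # data_type..dim_info
  wi(dim8, 2)                                   # dim[8]
  wf(c(0, 0, 0)); wi(0L, 2)                     # intent_p1..3, intent_code
  bitpix <- c(`2` = 8L, `4` = 16L, `8` = 32L, `16` = 32L, `64` = 64L)[
    as.character(datatype)]
  wi(datatype, 2); wi(bitpix, 2)
  wi(0L, 2)                                     # slice_start
  wf(pixdim8)                                   # pixdim[8]
  wf(352)                                       # vox_offset
  wf(c(1, 0))                                   # scl_slope, scl_inter
  wi(0L, 2)                                     # slice_end
  writeBin(as.raw(c(0L, 2L)), con)              # slice_code, xyzt_units = mm
  wf(c(0, 0, 0))                                # cal_max, cal_min, slice_dur
  wf(0)                                         # toffset
  wi(c(0L, 0L), 4)                              # glmax, glmin
  writeBin(raw(80 + 24), con)                   # descrip, aux_file
  wi(c(0L, 1L), 2)                              # qform_code = 0, sform = 1
  wf(rep(0, 6))                                 # quaternion b,c,d + offsets
  wf(c(sp3[1], 0, 0, or3[1]))                   # srow_x
  wf(c(0, sp3[2], 0, or3[2]))                   # srow_y
  wf(c(0, 0, sp3[3], or3[3]))                   # srow_z
  writeBin(raw(16), con)                        # intent_name
  writeBin(c(charToRaw("n+1"), as.raw(0)), con) # magic
  writeBin(raw(4), con)                         # extension flag
  v <- as.vector(vals)
  if (datatype %in% c(2L, 4L, 8L)) {
    writeBin(as.integer(round(v)), con,
             size = bitpix / 8, endian = "little")
  } else {
    writeBin(as.numeric(v), con, size = bitpix / 8, endian = "little")
  }
  invisible(path)
}

#' Read a NIfTI-1 volume written by [write_nifti()]
#'
#' Supports uncompressed single-file little-endian NIfTI-1 with datatypes
#' uint8, int16, int32, float32 and float64 and an axis-aligned sform.
#'
#' @param path `.nii` file path.
#' @return list with `values` (array), `spacing_mm`, `origin_mm`,
#'   `datatype`.
#' @export
read_nifti <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  ri <- function(n, size) readBin(con, "integer", n = n, size = size,
                                  endian = "little")
  rf <- function(n) readBin(con, "numeric", n = n, size = 4,
                            endian = "little")
  hdr_size <- ri(1, 4)
  if (hdr_size != 348L) stop("not a little-endian NIfTI-1 file")
  readBin(con, "raw", 36)
  dim8 <- ri(8, 2)
  nd <- dim8[1]
  dims <- dim8[2:(1 + nd)]
  rf(3); ri(1, 2)                              # intent params + intent_code
  datatype <- ri(1, 2); bitpix <- ri(1, 2)
  ri(1, 2)                                     # slice_start
  pixdim8 <- rf(8)
  vox_offset <- rf(1)
  rf(2); readBin(con, "raw", 4)
  rf(4); ri(2, 4)
  readBin(con, "raw", 104)
  ri(2, 2)                                     # qform/sform codes
  rf(6)
  srx <- rf(4); sry <- rf(4); srz <- rf(4)
  origin <- c(srx[4], sry[4], srz[4])[seq_len(min(nd, 3))]
  seek(con, where = vox_offset)
  n <- prod(dims)
  vals <- switch(as.character(datatype),
    `2` = readBin(con, "integer", n = n, size = 1, signed = FALSE),
    `4` = readBin(con, "integer", n = n, size = 2, endian = "little"),
    `8` = readBin(con, "integer", n = n, size = 4, endian = "little"),
    `16` = readBin(con, "numeric", n = n, size = 4, endian = "little"),
    `64` = readBin(con, "numeric", n = n, size = 8, endian = "little"),
    stop("unsupported NIfTI datatype: ", datatype))
  list(values = array(vals, dims),
       spacing_mm = pixdim8[2:(1 + nd)],
       origin_mm = origin, datatype = datatype)
}
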