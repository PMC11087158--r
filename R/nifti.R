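# Minimal single-file NIfTI-1 (.nii, uncompressed) I/O.
# Scope: axis-aligned grids only (diagonal sform), little-endian on disk.
# No NIfTI package is available in the target environment, so this is a
# deliberately small, round-trip-tested subset of the format: enough to
# exchange dose grids (float32, cGy) and binary masks (uint8) with standard
# neuroimaging tools. Internal array order is (z, y, x); on disk x is fastest,
# as the format requires.

.nifti_datatypes <- c(`2` = "uint8", `4` = "int16", `8` = "int32",
                      `16` = "float32", `64` = "float64")

#' Write a dose grid or structure mask as NIfTI-1
#'
#' Dose grids are stored as float32 (cGy), masks as uint8 0/1. Spacing goes to
#' `pixdim`, the origin to a diagonal sform. Files are uncompressed `.nii`,
#' little-endian.
#'
#' @param g a `dose_grid` or `structure_mask`.
#' @param path output path (conventionally ending in `.nii`).
#' @return `path`, invisibly.
#' @export
write_nifti <- function(g, path) {
  stopifnot(inherits(g, c("dose_grid", "structure_mask")))
  is_mask <- inherits(g, "structure_mask")
  v <- aperm(g$values, c(3, 2, 1))        # (x, y, z), x fastest when flattened
  sp_xyz <- rev(g$spacing)
  or_xyz <- rev(g$origin)
  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(x, size) writeBin(as.integer(x), con, size = size,
                                   endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")
  wc <- function(s, len) {
    raw <- charToRaw(s)
    writeBin(c(raw, raw(len - length(raw))), con)
  }
  wi(348, 4)                               # sizeof_hdr
  wc("", 10); wc("", 18)                   # data_type, db_name (unused)
  wi(0, 4); wi(0, 2); wc("r", 1); wc("", 1)  # extents, session_error, regular, dim_info
  wi(c(3, dim(v), 1, 1, 1, 1), 2)          # dim[8]
  wf(c(0, 0, 0)); wi(0, 2)                 # intent_p1-3, intent_code
  wi(if (is_mask) 2 else 16, 2)            # datatype
  wi(if (is_mask) 8 else 32, 2)            # bitpix
  wi(0, 2)                                 # slice_start
  wf(c(1, sp_xyz, 1, 1, 1, 1))             # pixdim[8] (qfac = 1)
  wf(352)                                  # vox_offset
  wf(1); wf(0)                             # scl_slope, scl_inter
  wi(0, 2); wc("", 1)                      # slice_end, slice_code
  wc(rawToChar(as.raw(2)), 1)              # xyzt_units: mm
  wf(c(0, 0, 0, 0))                        # cal_max, cal_min, slice_duration, toffset
  wi(c(0, 0), 4)                           # glmax, glmin
  wc("oardose", 80); wc("", 24)            # descrip, aux_file
  wi(0, 2); wi(1, 2)                       # qform_code = 0, sform_code = 1
  wf(c(0, 0, 0))                           # quatern_b, c, d
  wf(or_xyz)                               # qoffset_x, y, z
  wf(c(sp_xyz[1], 0, 0, or_xyz[1]))        # srow_x
  wf(c(0, sp_xyz[2], 0, or_xyz[2]))        # srow_y
  wf(c(0, 0, sp_xyz[3], or_xyz[3]))        # srow_z
  wc("", 16)                               # intent_name
  wc("n+1", 4)                             # magic
  writeBin(raw(4), con)                    # no extensions
  if (is_mask) {
    writeBin(as.integer(v), con, size = 1, endian = "little")
  } else {
    writeBin(as.numeric(v), con, size = 4, endian = "little")
  }
  invisible(path)
}

#' Read a NIfTI-1 file as a dose grid or structure mask
#'
#' Accepts 3D single-file uncompressed NIfTI-1 with a diagonal (axis-aligned)
#' sform or, failing that, pixdim spacing and zero origin. `scl_slope` /
#' `scl_inter` are applied when set.
#'
#' @param path file path.
#' @param as `"dose"` or `"mask"`.
#' @param present,status forwarded to [structure_mask()] when `as = "mask"`.
#' @return A `dose_grid` or `structure_mask`.
#' @export
read_nifti <- function(path, as = c("dose", "mask"), present = TRUE,
                       status = if (present) "ok" else "failed") {
  as <- match.arg(as)
  con <- file(path, "rb")
  on.exit(close(con))
  ri <- function(n, size) readBin(con, "integer", n = n, size = size,
                                  endian = "little")
  rf <- function(n) readBin(con, "numeric", n = n, size = 4, endian = "little")
  hdr_size <- ri(1, 4)
  if (!identical(hdr_size, 348L))
    stop("not a little-endian NIfTI-1 file: ", path)
  invisible(readBin(con, "raw", n = 36))
  dims <- ri(8, 2)
  if (dims[1] < 3 || any(dims[5:8][seq_len(max(0, dims[1] - 3))] > 1))
    stop("only 3D NIfTI volumes are supported: ", path)
  nx <- dims[2]; ny <- dims[3]; nz <- dims[4]
  rf(3); ri(1, 2)                          # intent_p, intent_code
  datatype <- ri(1, 2)
  ri(1, 2); ri(1, 2)                       # bitpix, slice_start
  pixdim <- rf(8)
  vox_offset <- rf(1)
  scl_slope <- rf(1); scl_inter <- rf(1)
  invisible(readBin(con, "raw", n = 123 - 120 + 1 + 16 + 104))  # through aux_file
  seek(con, 252)
  ri(1, 2)                                 # qform_code
  sform_code <- ri(1, 2)
  rf(3); rf(3)                             # quatern, qoffset
  srow <- matrix(rf(12), nrow = 3, byrow = TRUE)
  seek(con, 344)
  magic <- rawToChar(readBin(con, "raw", n = 3))
  if (!magic %in% c("n+1", "ni1"))
    stop("bad NIfTI magic in ", path)
  dt <- .nifti_datatypes[as.character(datatype)]
  if (is.na(dt)) stop("unsupported NIfTI datatype code ", datatype)
  seek(con, vox_offset)
  n <- nx * ny * nz
  data <- switch(dt,
    uint8   = readBin(con, "integer", n = n, size = 1, signed = FALSE,
                      endian = "little"),
    int16   = readBin(con, "integer", n = n, size = 2, endian = "little"),
    int32   = readBin(con, "integer", n = n, size = 4, endian = "little"),
    float32 = readBin(con, "numeric", n = n, size = 4, endian = "little"),
    float64 = readBin(con, "numeric", n = n, size = 8, endian = "little"))
  if (length(data) != n) stop("truncated NIfTI data in ", path)
  if (scl_slope != 0 && !(scl_slope == 1 && scl_inter == 0))
    data <- data * scl_slope + scl_inter
  v <- aperm(array(data, dim = c(nx, ny, nz)), c(3, 2, 1))
  if (sform_code > 0) {
    offdiag <- srow[1:3, 1:3]; diag(offdiag) <- 0
    if (any(abs(offdiag) > 1e-6))
      stop("only axis-aligned (diagonal sform) NIfTI grids are supported")
    sp_xyz <- abs(diag(srow[1:3, 1:3]))
    or_xyz <- srow[, 4]
  } else {
    sp_xyz <- abs(pixdim[2:4])
    or_xyz <- c(0, 0, 0)
  }
  spacing <- rev(sp_xyz); origin <- rev(or_xyz)
  if (as == "dose") {
    dose_grid(pmax(v, 0), spacing, origin)
  } else {
    structure_mask(v != 0, spacing, origin, present = present, status = status)
  }
}
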