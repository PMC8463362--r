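# Minimal NIfTI-1 IO.
#
# The R stack in this environment carries no NIfTI package, so the package
# reads and writes the format directly. Restrictions (checked, not silent):
# single-file .nii / .nii.gz, little-endian, 3-D, axis-aligned affine with
# positive diagonal. Data are written as float32 with an sform carrying
# spacing and origin; readers accept the common scalar datatypes and apply
# scl_slope/scl_inter rescaling.

nifti_pad <- function(s, n) {
  r <- raw(n)
  b <- charToRaw(s)
  r[seq_along(b)] <- b
  r
}

#' Write a CT volume as NIfTI-1
#'
#' @param vol a `ct_volume`.
#' @param path output path ending in `.nii` or `.nii.gz`.
#' @return `path`, invisibly.
#' @export
write_nifti <- function(vol, path) {
  d <- dim(vol$values)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  wi <- function(x, size) writeBin(as.integer(x), con, size = size,
                                   endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")
  wi(348L, 4)                              # sizeof_hdr
  writeBin(raw(35), con)                   # data_type..dim_info (unused)
  writeBin(raw(1), con)
  wi(c(3L, d, 1L, 1L, 1L, 1L), 2)         # dim[8]
  wf(c(0, 0, 0))                           # intent_p1..p3
  wi(0L, 2)                                # intent_code
  wi(16L, 2)                               # datatype: float32
  wi(32L, 2)                               # bitpix
  wi(0L, 2)                                # slice_start
  wf(c(1, vol$spacing, 0, 0, 0, 0))        # pixdim[8]
  wf(352)                                  # vox_offset
  wf(1); wf(0)                             # scl_slope, scl_inter
  wi(0L, 2); writeBin(raw(1), con)         # slice_end, slice_code
  writeBin(as.raw(2L), con)                # xyzt_units: mm
  wf(c(0, 0, 0, 0))                        # cal_max..toffset
  wi(c(0L, 0L), 4)                         # glmax, glmin
  writeBin(nifti_pad("thromboperv phantom/volume", 80), con)  # descrip
  writeBin(raw(24), con)                   # aux_file
  wi(0L, 2)                                # qform_code
  wi(1L, 2)                                # sform_code
  wf(c(0, 0, 0))                           # quatern b,c,d
  wf(c(0, 0, 0))                           # qoffset x,y,z
  wf(c(vol$spacing[1], 0, 0, vol$origin[1]))   # srow_x
  wf(c(0, vol$spacing[2], 0, vol$origin[2]))   # srow_y
  wf(c(0, 0, vol$spacing[3], vol$origin[3]))   # srow_z
  writeBin(raw(16), con)                   # intent_name
  writeBin(c(charToRaw("n+1"), raw(1)), con)   # magic
  writeBin(raw(4), con)                    # extension flag
  writeBin(as.numeric(vol$values), con, size = 4, endian = "little")
  invisible(path)
}

#' Read a NIfTI-1 volume
#'
#' @param path a `.nii` or `.nii.gz` file.
#' @return a `ct_volume`. Non-axis-aligned affines are rejected.
#' @export
read_nifti <- function(path) {
  if (!file.exists(path)) {
    perv_error(sprintf("file not found: %s", path), "perv_input_error")
  }
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rb") else file(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", 348)
  if (length(hdr) < 348) {
    perv_error(sprintf("truncated NIfTI header: %s", path), "perv_input_error")
  }
  ri <- function(off, n, size) {
    readBin(hdr[(off + 1):(off + n * size)], "integer", n = n, size = size,
            endian = "little")
  }
  rf <- function(off, n) {
    readBin(hdr[(off + 1):(off + n * 4)], "double", n = n, size = 4,
            endian = "little")
  }
  if (ri(0, 1, 4) != 348L) {
    perv_error("unsupported NIfTI (not little-endian NIfTI-1)",
               "perv_input_error")
  }
  magic <- rawToChar(hdr[345:347])
  if (!magic %in% c("n+1", "ni1")) {
    perv_error("bad NIfTI magic", "perv_input_error")
  }
  dims <- ri(40, 8, 2)
  ndim <- dims[1]
  if (ndim < 3 || any(dims[5:8] > 1)) {
    perv_error("only 3-D NIfTI volumes are supported", "perv_input_error")
  }
  d <- dims[2:4]
  datatype <- ri(70, 1, 2)
  pixdim <- rf(76, 8)
  vox_offset <- rf(108, 1)
  scl_slope <- rf(112, 1)
  scl_inter <- rf(116, 1)
  sform_code <- ri(254, 1, 2)
  srow <- rbind(rf(280, 4), rf(296, 4), rf(312, 4))
  if (sform_code > 0) {
    rot <- srow[, 1:3]
    offdiag <- rot; diag(offdiag) <- 0
    if (max(abs(offdiag)) > 1e-4 * max(abs(diag(rot))) || any(diag(rot) <= 0)) {
      perv_error("only axis-aligned NIfTI affines with positive spacing are supported",
                 "perv_input_error")
    }
    spacing <- diag(rot)
    origin <- srow[, 4]
  } else {
    spacing <- pixdim[2:4]
    origin <- c(0, 0, 0)
  }
  n <- prod(d)
  skip <- vox_offset - 348
  if (skip > 0) readBin(con, "raw", skip)
  vals <- switch(as.character(datatype),
    "2"   = as.numeric(readBin(con, "integer", n, size = 1, signed = FALSE)),
    "4"   = as.numeric(readBin(con, "integer", n, size = 2, endian = "little")),
    "8"   = as.numeric(readBin(con, "integer", n, size = 4, endian = "little")),
    "16"  = readBin(con, "double", n, size = 4, endian = "little"),
    "64"  = readBin(con, "double", n, size = 8, endian = "little"),
    "256" = as.numeric(readBin(con, "integer", n, size = 1, signed = TRUE)),
    "512" = as.numeric(readBin(con, "integer", n, size = 2, signed = FALSE,
                               endian = "little")),
    perv_error(sprintf("unsupported NIfTI datatype %d", datatype),
               "perv_input_error")
  )
  if (length(vals) != n) {
    perv_error("truncated NIfTI data section", "perv_input_error")
  }
  if (is.finite(scl_slope) && scl_slope != 0 && !(scl_slope == 1 && scl_inter == 0)) {
    vals <- vals * scl_slope + scl_inter
  }
  ct_volume(array(vals, d), spacing, origin)
}
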