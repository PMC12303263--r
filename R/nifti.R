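# Minimal NIfTI-1 single-file (.nii) I/O, float32, little-endian.
# No NIfTI package is available in the target library set, so the 348-byte
# header is written directly. Geometry is stored in the sform (affine with
# isotropic voxel size on the diagonal and the origin in the translation
# column); qform is left unset (qform_code 0, sform_code 2).

#' Write a 3D or 4D array as a NIfTI-1 file
#'
#' @param x numeric array (3D, or 4D with volumes stacked on dim 4).
#' @param path output path ending in `.nii`.
#' @param voxel_size_mm isotropic voxel edge, mm.
#' @param origin mm coordinate of voxel (0,0,0); length-3.
#' @return `path`, invisibly.
#' @export
write_nifti <- function(x, path, voxel_size_mm = 2, origin = NULL) {
  nd <- length(dim(x))
  if (!nd %in% c(3, 4)) vm_stop("array must be 3D or 4D", class = "voicemod_validation_error")
  shape <- dim(x)
  if (is.null(origin)) origin <- -(shape[1:3] - 1) / 2 * voxel_size_mm
  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(v, size = 4) writeBin(as.integer(v), con, size = size, endian = "little")
  wf <- function(v) writeBin(as.numeric(v), con, size = 4, endian = "little")
  wc <- function(s, len) {
    raw <- charToRaw(s)
    writeBin(c(raw, raw(len - length(raw))), con)
  }
  wi(348)                                  # sizeof_hdr
  wc("", 34)                               # data_type[10] db_name[18] extents(4) session_error(2)
  writeBin(raw(1), con)                    # regular
  writeBin(as.raw(0), con)                 # dim_info
  dims <- c(nd, shape, rep(1, 7 - nd))
  wi(dims, size = 2)                       # dim[8]
  wf(c(0, 0, 0))                           # intent_p1..p3
  wi(0, size = 2)                          # intent_code
  wi(16, size = 2)                         # datatype: float32
  wi(32, size = 2)                         # bitpix
  wi(0, size = 2)                          # slice_start
  wf(c(1, rep(voxel_size_mm, 3), rep(1, 4)))  # pixdim[8]
  wf(352)                                  # vox_offset
  wf(c(1, 0))                              # scl_slope, scl_inter
  wi(0, size = 2)                          # slice_end
  writeBin(as.raw(c(0, 0)), con)           # slice_code, xyzt_units
  wf(c(0, 0, 0))                           # cal_max, cal_min, slice_duration
  wf(0)                                    # toffset
  wi(c(0, 0))                              # glmax, glmin
  wc("voicemod synthetic volume", 80)      # descrip
  wc("", 24)                               # aux_file
  wi(0, size = 2)                          # qform_code
  wi(2, size = 2)                          # sform_code (aligned)
  wf(rep(0, 6))                            # quatern b,c,d + qoffset x,y,z
  wf(c(voxel_size_mm, 0, 0, origin[1]))    # srow_x
  wf(c(0, voxel_size_mm, 0, origin[2]))    # srow_y
  wf(c(0, 0, voxel_size_mm, origin[3]))    # srow_z
  wc("", 16)                               # intent_name
  wc("n+1", 4)                             # magic
  writeBin(raw(4), con)                    # extension flag
  writeBin(as.numeric(x), con, size = 4, endian = "little")
  invisible(path)
}

#' Read a NIfTI-1 file written by [write_nifti()]
#'
#' Supports single-file little-endian float32/float64/int16 images with
#' diagonal sform, which covers everything this package emits.
#'
#' @param path path to a `.nii` file.
#' @return List with `data` (array), `voxel_size_mm`, `origin`.
#' @export
read_nifti <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", 348)
  ri <- function(off, size, n = 1) {
    readBin(hdr[(off + 1):(off + size * n)], "integer", n = n, size = size,
            endian = "little")
  }
  rf <- function(off, n = 1) {
    readBin(hdr[(off + 1):(off + 4 * n)], "numeric", n = n, size = 4,
            endian = "little")
  }
  if (ri(0, 4) != 348) vm_stop("not a NIfTI-1 file (bad sizeof_hdr): %s", path,
                               class = "voicemod_validation_error")
  dims <- ri(40, 2, 8)
  nd <- dims[1]
  shape <- dims[2:(1 + nd)]
  datatype <- ri(70, 2)
  pix <- rf(76, 8)
  vox_offset <- rf(108)
  srow <- matrix(rf(280, 12), 3, 4, byrow = TRUE)
  origin <- srow[, 4]
  seek(con, vox_offset)
  nvox <- prod(shape)
  data <- switch(as.character(datatype),
    "16" = readBin(con, "numeric", n = nvox, size = 4, endian = "little"),
    "64" = readBin(con, "numeric", n = nvox, size = 8, endian = "little"),
    "4"  = readBin(con, "integer", n = nvox, size = 2, endian = "little"),
    vm_stop("unsupported NIfTI datatype %d", datatype,
            class = "voicemod_validation_error"))
  list(data = array(data, dim = shape), voxel_size_mm = pix[2],
       origin = origin)
}
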