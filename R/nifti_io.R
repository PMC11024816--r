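# Minimal NIfTI-1 reader/writer. No NIfTI package ships with the target R
# environment, so the 348-byte header is handled directly. Supported:
# single-file .nii / .nii.gz, datatypes uint8 / int16 / int32 / float32 /
# float64, scl_slope/scl_inter rescaling, sform > qform > pixdim affines.
# The implementation is cross-checked against nibabel in the test suite.

NIFTI_DT <- list(`2` = list(what = "integer", size = 1, signed = FALSE),
                 `4` = list(what = "integer", size = 2, signed = TRUE),
                 `8` = list(what = "integer", size = 4, signed = TRUE),
                 `16` = list(what = "double", size = 4, signed = TRUE),
                 `64` = list(what = "double", size = 8, signed = TRUE))

nifti_con <- function(path, mode) {
  if (grepl("\\.gz$", path)) gzfile(path, mode) else file(path, mode)
}

#' Read a NIfTI-1 volume
#'
#' @param path .nii or .nii.gz file
#' @return list with `data` (3D array, scl applied) and `affine` (4 x 4
#'   voxel-index to world-mm transform, 0-based voxel-centre convention)
#' @export
read_nifti <- function(path) {
  if (!file.exists(path)) stop(sprintf("NIfTI file '%s' does not exist", path))
  con <- nifti_con(path, "rb")
  on.exit(close(con))
  magic_sz <- readBin(con, "integer", 1, size = 4, endian = "little")
  endian <- "little"
  if (magic_sz != 348L) {
    sw <- readBin(writeBin(magic_sz, raw(), size = 4, endian = "big"),
                  "integer", 1, size = 4, endian = "little")
    if (sw == 348L) endian <- "big"
    else stop(sprintf("'%s' is not a NIfTI-1 file (sizeof_hdr = %d)", path, magic_sz))
  }
  readBin(con, "raw", 36)                       # data_type..dim_info
  dim <- readBin(con, "integer", 8, size = 2, endian = endian)
  readBin(con, "raw", 14)                       # intent_p1..intent_code
  datatype <- readBin(con, "integer", 1, size = 2, endian = endian)
  readBin(con, "integer", 1, size = 2, endian = endian)  # bitpix
  readBin(con, "raw", 2)                        # slice_start
  pixdim <- readBin(con, "double", 8, size = 4, endian = endian)
  vox_offset <- readBin(con, "double", 1, size = 4, endian = endian)
  scl_slope <- readBin(con, "double", 1, size = 4, endian = endian)
  scl_inter <- readBin(con, "double", 1, size = 4, endian = endian)
  readBin(con, "raw", 132)                      # slice_end..aux_file
  qform_code <- readBin(con, "integer", 1, size = 2, endian = endian)
  sform_code <- readBin(con, "integer", 1, size = 2, endian = endian)
  quat <- readBin(con, "double", 6, size = 4, endian = endian)
  srow <- matrix(readBin(con, "double", 12, size = 4, endian = endian),
                 nrow = 3, byrow = TRUE)
  readBin(con, "raw", 16)                       # intent_name
  magic <- rawToChar(readBin(con, "raw", 4)[1:3])
  if (!magic %in% c("n+1", "ni1"))
    stop(sprintf("'%s' has bad NIfTI magic '%s'", path, magic))
  ndim <- dim[1]
  if (ndim < 3) stop(sprintf("'%s' is %d-dimensional; need a 3D volume", path, ndim))
  shape <- dim[2:4]
  if (ndim > 3 && any(dim[5:(ndim + 1)] > 1))
    stop(sprintf("'%s' has a non-singleton dimension beyond the third", path))
  dt <- NIFTI_DT[[as.character(datatype)]]
  if (is.null(dt)) stop(sprintf("'%s': unsupported NIfTI datatype %d", path, datatype))
  # skip to vox_offset (sequential read: gz streams cannot seek)
  skip <- round(vox_offset) - 348
  if (skip > 0) readBin(con, "raw", skip)
  n <- prod(shape)
  vals <- readBin(con, dt$what, n, size = dt$size, signed = dt$signed,
                  endian = endian)
  if (length(vals) < n) stop(sprintf("'%s': truncated data section", path))
  vals <- as.double(vals)
  if (is.finite(scl_slope) && scl_slope != 0 && !(scl_slope == 1 && scl_inter == 0))
    vals <- vals * scl_slope + scl_inter
  affine <- nifti_affine(sform_code, srow, qform_code, quat, pixdim)
  list(data = array(vals, dim = shape), affine = affine)
}

nifti_affine <- function(sform_code, srow, qform_code, quat, pixdim) {
  if (sform_code > 0) {
    aff <- rbind(srow, c(0, 0, 0, 1))
  } else if (qform_code > 0) {
    b <- quat[1]; c <- quat[2]; d <- quat[3]
    a <- sqrt(max(0, 1 - b^2 - c^2 - d^2))
    R <- rbind(c(a^2 + b^2 - c^2 - d^2, 2 * (b * c - a * d), 2 * (b * d + a * c)),
               c(2 * (b * c + a * d), a^2 + c^2 - b^2 - d^2, 2 * (c * d - a * b)),
               c(2 * (b * d - a * c), 2 * (c * d + a * b), a^2 + d^2 - b^2 - c^2))
    qfac <- if (pixdim[1] < 0) -1 else 1
    S <- diag(c(pixdim[2], pixdim[3], qfac * pixdim[4]))
    aff <- rbind(cbind(R %*% S, quat[4:6]), c(0, 0, 0, 1))
  } else {
    aff <- diag(c(pixdim[2:4], 1))
  }
  if (abs(det(aff[1:3, 1:3])) < 1e-12)
    stop("NIfTI affine is not invertible")
  aff
}

#' Write a 3D array as NIfTI-1
#'
#' Data are stored as float64 with an sform affine.
#'
#' @param data 3D numeric array
#' @param affine 4 x 4 voxel-to-world transform
#' @param path output .nii or .nii.gz
#' @return `path`, invisibly
#' @export
write_nifti <- function(data, affine, path) {
  stopifnot(length(dim(data)) == 3, all(dim(affine) == c(4, 4)))
  con <- nifti_con(path, "wb")
  on.exit(close(con))
  wi <- function(x, size) writeBin(as.integer(x), con, size = size, endian = "little")
  wf <- function(x) writeBin(as.double(x), con, size = 4, endian = "little")
  wraw <- function(n) writeBin(raw(n), con)
  pix <- sqrt(colSums(affine[1:3, 1:3]^2))
  wi(348, 4); wraw(36)
  wi(c(3, dim(data), 1, 1, 1, 1), 2)            # dim
  wraw(14)                                      # intent
  wi(64, 2); wi(64, 2)                          # datatype float64, bitpix
  wraw(2)                                       # slice_start
  wf(c(1, pix, 0, 0, 0, 0))                     # pixdim (qfac 1)
  wf(352); wf(1); wf(0)                         # vox_offset, scl_slope, scl_inter
  wraw(132)                                     # slice_end..aux_file
  wi(0, 2); wi(1, 2)                            # qform_code 0, sform_code 1
  wf(rep(0, 6))                                 # quaternion + offsets
  wf(t(affine[1:3, ]))                          # srow_x, srow_y, srow_z
  wraw(16)                                      # intent_name
  writeBin(c(charToRaw("n+1"), raw(1)), con)    # magic
  wraw(4)                                       # extension flag
  writeBin(as.double(data), con, size = 8, endian = "little")
  invisible(path)
}
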