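# Minimal self-contained NIfTI-1 I/O.
#
# The package only needs single-file .nii / .nii.gz volumes with an sform
# affine, which this reader/writer covers: datatypes uint8, int16, int32,
# float32, float64; scl_slope/scl_inter honoured on read; RAS+ world
# convention with 0-based voxel indices. Complex volumes are stored as paired
# `_real` / `_imag` files with the dialect recorded in the header description.

NIFTI_DT <- list(uint8 = 2L, int16 = 4L, int32 = 8L, float32 = 16L,
                 float64 = 64L)
NIFTI_BITPIX <- c(`2` = 8L, `4` = 16L, `8` = 32L, `16` = 32L, `64` = 64L)

nii_con <- function(path, open) {
  if (grepl("\\.gz$", path)) gzfile(path, open) else file(path, open)
}

#' Write a volume as NIfTI-1
#'
#' @param data numeric, integer, or logical 3-D array.
#' @param path output path ending in `.nii` or `.nii.gz`.
#' @param spacing isotropic voxel size in mm.
#' @param affine optional 4x4 voxel-to-world matrix (sform, 0-based indices);
#'   defaults to diagonal scaling by `spacing`.
#' @param datatype one of "uint8", "int16", "int32", "float32", "float64".
#' @param descrip free-text header description (<= 79 chars).
#' @return `path`, invisibly.
#' @export
write_nifti <- function(data, path, spacing = 1, affine = NULL,
                        datatype = "float32", descrip = "") {
  stopifnot(length(dim(data)) == 3L, datatype %in% names(NIFTI_DT))
  if (is.null(affine)) affine <- spacing_affine(spacing)
  dims <- dim(data)
  dt <- NIFTI_DT[[datatype]]
  bitpix <- NIFTI_BITPIX[[as.character(dt)]]
  con <- nii_con(path, "wb")
  on.exit(close(con))
  writeBin(348L, con, size = 4)                        # sizeof_hdr
  writeBin(raw(36), con)                               # unused
  writeBin(as.integer(c(3L, dims, 1L, 1L, 1L, 1L)), con, size = 2)  # dim
  writeBin(numeric(3), con, size = 4)                  # intent_p1..p3
  writeBin(integer(1), con, size = 2)                  # intent_code
  writeBin(as.integer(dt), con, size = 2)              # datatype
  writeBin(as.integer(bitpix), con, size = 2)          # bitpix
  writeBin(integer(1), con, size = 2)                  # slice_start
  writeBin(c(1, rep(spacing, 3), 0, 0, 0, 0), con, size = 4)  # pixdim
  writeBin(352, con, size = 4)                         # vox_offset
  writeBin(c(1, 0), con, size = 4)                     # scl_slope, scl_inter
  writeBin(integer(1), con, size = 2)                  # slice_end
  writeBin(raw(2), con)                                # slice_code, xyzt_units
  writeBin(numeric(2), con, size = 4)                  # cal_max, cal_min
  writeBin(numeric(2), con, size = 4)                  # slice_duration, toffset
  writeBin(integer(2), con, size = 4)                  # glmax, glmin
  desc <- substr(descrip, 1, 79)
  dr <- c(charToRaw(desc), raw(80 - nchar(desc, type = "bytes")))
  writeBin(dr, con)                                    # descrip
  writeBin(raw(24), con)                               # aux_file
  writeBin(c(0L, 1L), con, size = 2)                   # qform_code=0, sform_code=1
  writeBin(numeric(6), con, size = 4)                  # quatern b,c,d + offsets
  writeBin(as.numeric(t(affine[1:3, ])), con, size = 4)  # srow_x,y,z
  writeBin(raw(16), con)                               # intent_name
  writeBin(c(charToRaw("n+1"), as.raw(0)), con)        # magic
  writeBin(raw(4), con)                                # extension flag
  storage <- if (dt %in% c(2L, 4L, 8L)) "integer" else "double"
  vals <- if (storage == "integer") as.integer(data) else as.numeric(data)
  writeBin(vals, con, size = bitpix / 8)
  invisible(path)
}

#' Read a NIfTI-1 volume
#'
#' @param path `.nii` or `.nii.gz` file.
#' @return A list with elements `data` (3-D array), `spacing` (mm),
#'   `affine` (4x4 sform), and `descrip`.
#' @export
read_nifti <- function(path) {
  con <- nii_con(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", 348)
  endian <- "little"
  sz <- readBin(hdr[1:4], "integer", 1, 4, endian = endian)
  if (sz != 348L) {
    endian <- "big"
    sz <- readBin(hdr[1:4], "integer", 1, 4, endian = endian)
    if (sz != 348L) stop("not a NIfTI-1 file: ", path)
  }
  rd <- function(off, what, n, size)
    readBin(hdr[(off + 1):348], what, n, size, signed = TRUE, endian = endian)
  dims <- rd(40, "integer", 8, 2)
  ndim <- dims[1]
  shape <- dims[2:(1 + max(ndim, 3))]
  if (any(shape[seq_len(ndim)[-(1:3)]] > 1))
    stop("only 3-D volumes are supported")
  shape <- shape[1:3]
  datatype <- rd(70, "integer", 1, 2)
  pixdim <- rd(76, "numeric", 8, 4)
  vox_offset <- rd(108, "numeric", 1, 4)
  scl_slope <- rd(112, "numeric", 1, 4)
  scl_inter <- rd(116, "numeric", 1, 4)
  descrip <- rawToChar(hdr[149:228][hdr[149:228] != as.raw(0)])
  sform_code <- rd(254, "integer", 1, 2)
  srow <- matrix(rd(280, "numeric", 12, 4), 3, 4, byrow = TRUE)
  affine <- rbind(srow, c(0, 0, 0, 1))
  if (sform_code == 0L) affine <- diag(c(pixdim[2:4], 1))
  n <- prod(shape)
  seek(con, vox_offset)
  data <- switch(as.character(datatype),
    `2`  = readBin(con, "integer", n, 1, signed = FALSE, endian = endian),
    `4`  = readBin(con, "integer", n, 2, endian = endian),
    `8`  = readBin(con, "integer", n, 4, endian = endian),
    `16` = readBin(con, "numeric", n, 4, endian = endian),
    `64` = readBin(con, "numeric", n, 8, endian = endian),
    stop("unsupported NIfTI datatype: ", datatype))
  data <- array(as.numeric(data), shape)
  if (is.finite(scl_slope) && scl_slope != 0 && !(scl_slope == 1 && scl_inter == 0))
    data <- data * scl_slope + scl_inter
  list(data = data, spacing = pixdim[2], affine = affine, descrip = descrip)
}

#' Write a complex volume as a paired real/imaginary NIfTI set
#'
#' The dialect (`complex-pair`) is recorded in both headers' description
#' fields so downstream tools can reassemble the field.
#'
#' @param data complex 3-D array.
#' @param prefix output prefix; `<prefix>_real.nii.gz` and
#'   `<prefix>_imag.nii.gz` are written.
#' @inheritParams write_nifti
#' @return Character vector of the two paths, invisibly.
#' @export
write_nifti_complex <- function(data, prefix, spacing = 1, affine = NULL,
                                descrip = "") {
  d <- paste0("complex-pair ", descrip)
  paths <- c(paste0(prefix, "_real.nii.gz"), paste0(prefix, "_imag.nii.gz"))
  write_nifti(Re(data), paths[1], spacing, affine, "float32", d)
  write_nifti(Im(data), paths[2], spacing, affine, "float32", d)
  invisible(paths)
}

#' Read a complex volume from a paired real/imaginary NIfTI set
#'
#' @param prefix prefix used by [write_nifti_complex()].
#' @return A list like [read_nifti()] but with complex `data`.
#' @export
read_nifti_complex <- function(prefix) {
  re <- read_nifti(paste0(prefix, "_real.nii.gz"))
  im <- read_nifti(paste0(prefix, "_imag.nii.gz"))
  re$data <- re$data + 1i * im$data
  re
}
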