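# Minimal self-contained NIfTI-1 I/O (single-file .nii / .nii.gz).  No
# NIfTI package is assumed; only the fields this package needs are handled:
# dims, pixdim, datatype, scl slope/intercept, and the sform affine.
# Written files are float32, little-endian, vox_offset 352, magic "n+1".

nifti_open <- function(path, mode) {
  if (grepl("\\.gz$", path)) gzfile(path, mode) else file(path, mode)
}

#' Read a NIfTI-1 volume
#'
#' Supports single-file `.nii` / `.nii.gz`, datatypes uint8, int16, int32,
#' float32, float64, any dimensionality up to 4D, and honours
#' `scl_slope`/`scl_inter`.
#'
#' @param path file path.
#' @return Numeric array with attributes `pixdim` (voxel spacing, mm) and
#'   `affine` (4 x 4 sform matrix; identity-scaled if absent).
#' @export
read_nifti <- function(path) {
  con <- nifti_open(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", 348)
  sizeof_hdr <- readBin(hdr[1:4], "integer", 1, 4, endian = "little")
  endian <- "little"
  if (sizeof_hdr != 348L) {
    sizeof_hdr <- readBin(hdr[1:4], "integer", 1, 4, endian = "big")
    if (sizeof_hdr != 348L) stop("not a NIfTI-1 file: ", path)
    endian <- "big"
  }
  rd <- function(off, what, n, size)
    readBin(hdr[(off + 1):(off + n * size)], what, n, size, endian = endian)
  dim_raw <- rd(40, "integer", 8, 2)
  ndim <- dim_raw[1]
  if (ndim < 1L || ndim > 7L) stop("bad dim[0] in NIfTI header")
  dims <- dim_raw[2:(1 + ndim)]
  datatype <- rd(70, "integer", 1, 2)
  pixdim <- rd(76, "numeric", 8, 4)[2:(1 + min(ndim, 3L))]
  vox_offset <- rd(108, "numeric", 1, 4)
  scl_slope <- rd(112, "numeric", 1, 4)
  scl_inter <- rd(116, "numeric", 1, 4)
  sform_code <- rd(254, "integer", 1, 2)
  srow <- matrix(rd(280, "numeric", 12, 4), nrow = 3, byrow = TRUE)
  magic <- rawToChar(hdr[345:347])
  if (!magic %in% c("n+1", "ni1")) stop("unsupported NIfTI magic: ", magic)
  skip <- vox_offset - 348
  if (skip > 0) readBin(con, "raw", skip)
  n <- prod(dims)
  data <- switch(as.character(datatype),
    "2" = as.numeric(readBin(con, "integer", n, 1, signed = FALSE)),
    "4" = as.numeric(readBin(con, "integer", n, 2, endian = endian)),
    "8" = as.numeric(readBin(con, "integer", n, 4, endian = endian)),
    "16" = readBin(con, "numeric", n, 4, endian = endian),
    "64" = readBin(con, "numeric", n, 8, endian = endian),
    stop("unsupported NIfTI datatype: ", datatype))
  if (is.finite(scl_slope) && scl_slope != 0 &&
      !(scl_slope == 1 && scl_inter == 0))
    data <- data * scl_slope + scl_inter
  arr <- array(data, dims)
  attr(arr, "pixdim") <- abs(pixdim)
  affine <- if (sform_code > 0) rbind(srow, c(0, 0, 0, 1))
            else diag(c(abs(pixdim), 1))[1:4, 1:4]
  attr(arr, "affine") <- affine
  arr
}

#' Write a NIfTI-1 volume
#'
#' Writes a float32 single-file NIfTI-1 image with the given voxel spacing
#' and sform affine.
#'
#' @param arr numeric array (3D or 4D).
#' @param path output path (`.nii` or `.nii.gz`).
#' @param pixdim voxel spacing, mm (length 3).
#' @param affine optional 4 x 4 sform; defaults to `diag(c(pixdim, 1))`.
#' @return `path`, invisibly.
#' @export
write_nifti <- function(arr, path, pixdim = c(1, 1, 1), affine = NULL) {
  dims <- dim(arr)
  ndim <- length(dims)
  stopifnot(ndim %in% c(3L, 4L), length(pixdim) == 3L)
  if (is.null(affine)) affine <- diag(c(pixdim, 1))
  stopifnot(identical(dim(affine), c(4L, 4L)) || all(dim(affine) == c(4, 4)))
  con <- nifti_open(path, "wb")
  on.exit(close(con))
  wi <- function(x, size) writeBin(as.integer(x), con, size, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, 4L, endian = "little")
  wc <- function(s, len) {
    r <- charToRaw(s)
    writeBin(c(r, raw(len - length(r))), con)
  }
  wi(348, 4)                       # sizeof_hdr
  wc("", 10); wc("", 18)           # data_type, db_name
  wi(0, 4); wi(0, 2); wc("r", 1); wc("", 1)  # extents..dim_info
  wi(c(ndim, dims, rep(1L, 7L - ndim)), 2)   # dim[8]
  wf(c(0, 0, 0)); wi(0, 2)         # intent_p1-3, intent_code
  wi(16, 2); wi(32, 2); wi(0, 2)   # datatype float32, bitpix, slice_start
  wf(c(0, pixdim, rep(1, 7 - 3)))  # pixdim[8] (qfac 0)
  wf(352); wf(1); wf(0)            # vox_offset, scl_slope, scl_inter
  wi(0, 2); wc("", 1); wc("", 1)   # slice_end, slice_code, xyzt_units
  wf(c(0, 0, 0, 0))                # cal_max, cal_min, slice_dur, toffset
  wi(c(0, 0), 4)                   # glmax, glmin
  wc("decidemri", 80); wc("", 24)  # descrip, aux_file
  wi(0, 2); wi(1, 2)               # qform_code 0, sform_code 1
  wf(c(0, 0, 0)); wf(c(0, 0, 0))   # quatern b,c,d ; qoffset x,y,z
  wf(affine[1, ]); wf(affine[2, ]); wf(affine[3, ])
  wc("", 16)                       # intent_name
  writeBin(c(charToRaw("n+1"), as.raw(0)), con)
  writeBin(raw(4), con)            # extension flag
  writeBin(as.numeric(arr), con, 4L, endian = "little")
  invisible(path)
}
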