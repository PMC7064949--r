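#' Read a 4D series with its protocol
#'
#' Loads a 4D NIfTI series and the paired protocol CSV, validating that the
#' number of volumes matches the number of protocol rows.
#'
#' @param path path to a 4D NIfTI file.
#' @param protocol_path path to a protocol CSV
#'   (`index,b_s_per_mm2,te_ms`).
#' @return List with `series` (a [decide_series]) and `protocol`
#'   (a [decide_protocol]).
#' @export
read_series <- function(path, protocol_path) {
  arr <- read_nifti(path)
  if (length(dim(arr)) != 4L)
    stop("expected 4D series, got ", length(dim(arr)), "D: ", path)
  protocol <- read_protocol(protocol_path)
  if (dim(arr)[4] != nrow(protocol))
    stop(sprintf("series has %d volumes but protocol has %d entries",
                 dim(arr)[4], nrow(protocol)))
  series <- decide_series(unclass(array(arr, dim(arr))),
                          spacing = attr(arr, "pixdim"))
  attr(series, "affine") <- attr(arr, "affine")
  message(sprintf("read %s: %s voxels, %d volumes", path,
                  paste(dim(arr)[1:3], collapse = "x"), dim(arr)[4]))
  list(series = series, protocol = protocol)
}

#' Read a 3D mask
#'
#' @param path NIfTI path; nonzero voxels are in-mask.
#' @return Logical 3D array.
#' @export
read_mask <- function(path) {
  arr <- read_nifti(path)
  if (length(dim(arr)) == 4L && dim(arr)[4] == 1L)
    arr <- array(arr, dim(arr)[1:3])
  if (length(dim(arr)) != 3L) stop("expected 3D mask: ", path)
  m <- arr != 0
  attributes(m) <- list(dim = dim(arr))
  m
}

#' Write parameter maps
#'
#' One float32 NIfTI per map plus a JSON sidecar with units and provenance
#' (seed, config hash input, package version).  An `fo2` map is added only
#' when an explicit calibration is supplied.
#'
#' @param maps named list of 3D arrays sharing a grid (typically the output
#'   of a volume fit; non-array elements are ignored).
#' @param out_dir output directory (created if needed).
#' @param spacing voxel spacing (mm).
#' @param affine optional 4 x 4 sform affine, preserved on every map.
#' @param fo2_calibration optional list (A, K) — see [fo2_from_t2fb()].
#' @param provenance optional named list merged into the sidecar.
#' @return Character vector of files written, invisibly.
#' @export
write_maps <- function(maps, out_dir, spacing = c(1, 1, 1), affine = NULL,
                       fo2_calibration = NULL, provenance = list()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  arrays <- Filter(function(x) is.array(x) && length(dim(x)) == 3L, maps)
  if (length(arrays) == 0L) stop("no 3D maps to write")
  d3 <- dim(arrays[[1]])
  for (m in arrays) stopifnot(identical(dim(m), d3))
  if (!is.null(fo2_calibration) && !is.null(arrays$t2fb)) {
    fo2 <- array(0, d3)
    pos <- arrays$t2fb > 0
    fo2[pos] <- fo2_from_t2fb(arrays$t2fb[pos], fo2_calibration)
    arrays$fo2 <- fo2
  }
  units <- c(s0 = "a.u.", f = "fraction", d = "mm^2/s", d_star = "mm^2/s",
             t2fb = "ms", v = "fraction", fo2 = "fraction",
             residual = "a.u.")
  files <- character(0)
  for (nm in names(arrays)) {
    fp <- file.path(out_dir, paste0(nm, ".nii.gz"))
    write_nifti(arrays[[nm]], fp, pixdim = spacing, affine = affine)
    files <- c(files, fp)
  }
  sidecar <- c(list(
    maps = names(arrays),
    units = as.list(units[intersect(names(units), names(arrays))]),
    model_parameters = c("f", "d", "d_star", "t2fb", "v"),
    spacing_mm = spacing,
    package = "decidemri",
    version = as.character(utils::packageVersion("decidemri")),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
    provenance)
  sc_path <- file.path(out_dir, "maps.json")
  writeLines(jsonlite::toJSON(sidecar, auto_unbox = TRUE, pretty = TRUE,
                              digits = NA), sc_path)
  invisible(c(files, sc_path))
}
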