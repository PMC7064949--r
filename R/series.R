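#' 4D signal series
#'
#' Container for a diffusion-relaxation series: a 4D array (x, y, z, volume)
#' whose 4th dimension is indexed by the acquisition protocol, plus voxel
#' spacing in millimetres.
#'
#' @param data 4D numeric array.
#' @param spacing numeric length-3 voxel spacing (mm), all > 0.
#' @return Object of class `decide_series`.
#' @export
decide_series <- function(data, spacing = c(1, 1, 1)) {
  if (length(dim(data)) != 4L)
    stop("expected 4D data (x, y, z, volume); got ",
         length(dim(data)), "D")
  stopifnot(length(spacing) == 3L, all(spacing > 0))
  structure(list(data = data, spacing = as.numeric(spacing)),
            class = "decide_series")
}

#' @export
print.decide_series <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<decide_series> %d x %d x %d voxels, %d volumes, spacing %s mm\n",
              d[1], d[2], d[3], d[4],
              paste(signif(x$spacing, 3), collapse = " x ")))
  invisible(x)
}

n_volumes <- function(series) dim(series$data)[4]

check_series_protocol <- function(series, protocol) {
  nv <- n_volumes(series)
  np <- nrow(protocol)
  if (nv != np)
    stop(sprintf("series has %d volumes but protocol has %d entries", nv, np))
  invisible(TRUE)
}

check_mask <- function(mask, series) {
  if (!identical(dim(mask), dim(series$data)[1:3]))
    stop("mask grid does not match series grid")
  if (!any(mask != 0)) stop("mask is empty")
  invisible(TRUE)
}
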