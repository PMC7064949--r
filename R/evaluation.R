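#' Voxelwise relative error of a parameter map
#'
#' `E(p) = (p_est - p_true) / p_true` per voxel over the mask; voxels where
#' the truth is zero are excluded and counted.  The summary statistic is the
#' mask-mean of |E|.
#'
#' @param p_est,p_true 3D maps on the same grid.
#' @param mask 3D mask.
#' @return List with `error` (3D map, NA where excluded), `mean_abs`
#'   (mean |E| over valid mask voxels), and `n_excluded`.
#' @export
relative_error <- function(p_est, p_true, mask) {
  stopifnot(identical(dim(p_est), dim(p_true)),
            identical(dim(p_est), dim(mask)))
  vox <- which(mask != 0)
  if (length(vox) == 0L) stop("mask is empty")
  err <- array(NA_real_, dim(p_est))
  valid <- vox[p_true[vox] != 0]
  err[valid] <- (p_est[valid] - p_true[valid]) / p_true[valid]
  list(error = err, mean_abs = mean(abs(err[valid])),
       n_excluded = length(vox) - length(valid))
}

#' ROI summary statistics
#'
#' Median, 25th/75th percentiles (linear interpolation between order
#' statistics, `quantile` type 7), mean and SD over mask voxels.
#'
#' @param map 3D map.
#' @param mask 3D mask, nonempty.
#' @return List `median, p25, p75, mean, sd, n`.
#' @export
roi_summary <- function(map, mask) {
  stopifnot(identical(dim(map), dim(mask)))
  x <- map[mask != 0]
  if (length(x) == 0L) stop("mask is empty")
  q <- stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  list(median = q[2], p25 = q[1], p75 = q[3], mean = mean(x),
       sd = stats::sd(x), n = length(x))
}

#' Gestational-age trend
#'
#' Ordinary least-squares regression `y = b GA + a` of per-subject ROI
#' summaries on gestational age (decimal weeks), with Pearson correlation
#' and its two-sided t-test p-value; significance flagged at 5%.
#'
#' @param values numeric per-subject summaries.
#' @param ga gestational ages in decimal weeks (weeks + days/7).
#' @return List of class `ga_trend`: `slope, intercept, r, p_value, n,
#'   significant`.  Constant `values` give slope 0 with `r` and `p_value`
#'   NA (flagged degenerate).
#' @export
ga_trend <- function(values, ga) {
  stopifnot(length(values) == length(ga), length(values) >= 3L,
            all(is.finite(values)), all(is.finite(ga)))
  if (stats::var(ga) == 0) stop("zero variance in gestational age")
  fit <- stats::lm(values ~ ga)
  co <- stats::coef(fit)
  if (stats::var(values) == 0) {
    out <- list(slope = 0, intercept = unname(co[1]), r = NA_real_,
                p_value = NA_real_, n = length(values), significant = FALSE,
                degenerate = TRUE)
  } else {
    ct <- stats::cor.test(ga, values)
    out <- list(slope = unname(co[2]), intercept = unname(co[1]),
                r = unname(ct$estimate), p_value = ct$p.value,
                n = length(values), significant = ct$p.value < 0.05,
                degenerate = FALSE)
  }
  structure(out, class = "ga_trend")
}

#' @export
print.ga_trend <- function(x, ...) {
  cat(sprintf("<ga_trend> slope=%.4g intercept=%.4g r=%.3f p=%.3g n=%d%s\n",
              x$slope, x$intercept,
              ifelse(is.na(x$r), NaN, x$r),
              ifelse(is.na(x$p_value), NaN, x$p_value), x$n,
              if (isTRUE(x$significant)) " *" else ""))
  invisible(x)
}
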