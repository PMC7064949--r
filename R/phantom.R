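# Synthetic placenta-like phantoms: smooth random parameter fields inside an
# ellipsoidal mask, forward-model series with Gaussian or Rician noise, and
# smooth per-volume B-spline motion with exactly calibrated mask-average
# deformation.

#' Phantom specification
#'
#' Default parameter ranges are the cohort ROI means +/- one SD of the
#' unregistered-data estimates, clipped to the fit bounds: f 0.225 (0.21),
#' d 0.0015 (0.0003) mm^2/s, d* 0.0385 (0.018) mm^2/s, T2fb 181.1 (25.7) ms,
#' v 0.306 (0.051).
#'
#' @param shape grid shape (3 integers).
#' @param spacing voxel spacing in mm (default 2.5 mm isotropic, a typical
#'   in-plane placental DW-MRI resolution).
#' @param semi_frac ellipsoid semi-axes as fractions of the half-extent.
#' @param ranges named list of `c(low, high)` ranges for
#'   `s0, f, d, d_star, t2fb, v`.
#' @param smoothness Gaussian smoothing length of the parameter fields
#'   (voxels); `Inf` gives spatially constant maps at the range midpoints.
#' @param snr signal-to-noise ratio (mask-mean S0 over noise SD).
#' @param noise `"gaussian"` or `"rician"`.
#' @param seed RNG seed.
#' @return List of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(32, 32, 16), spacing = c(2.5, 2.5, 2.5),
                         semi_frac = c(0.8, 0.8, 0.8),
                         ranges = list(s0 = c(90, 110),
                                       f = c(0.015, 0.435),
                                       d = c(0.0012, 0.0018),
                                       d_star = c(0.0205, 0.0565),
                                       t2fb = c(155.4, 206.8),
                                       v = c(0.255, 0.357)),
                         smoothness = 3, snr = 20,
                         noise = c("gaussian", "rician"), seed = 1L) {
  noise <- match.arg(noise)
  bounds <- fit_bounds()
  for (nm in setdiff(names(ranges), "s0")) {
    lh <- ranges[[nm]]
    if (lh[1] < bounds[[nm]][1] || lh[2] > bounds[[nm]][2])
      stop("range for ", nm, " outside fit bounds")
  }
  stopifnot(snr > 0, all(shape >= 1), all(spacing > 0))
  structure(list(shape = as.integer(shape), spacing = spacing,
                 semi_frac = semi_frac, ranges = ranges,
                 smoothness = smoothness, snr = snr, noise = noise,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Generate a phantom
#'
#' Smooth seeded random fields per parameter inside an ellipsoidal mask
#' (smoothed white noise, normalized, scaled so +/-2 SD spans the declared
#' range, clipped to it); zero outside the mask.
#'
#' @param spec a [phantom_spec].
#' @return List with `maps` (3D arrays `s0, f, d, d_star, t2fb, v`), `mask`
#'   (logical 3D array), and `spec`.
#' @export
make_phantom <- function(spec) {
  set.seed(spec$seed)
  shape <- spec$shape
  mask <- ellipsoid_mask(shape, spec$semi_frac)
  maps <- list()
  for (nm in names(spec$ranges)) {
    lh <- spec$ranges[[nm]]
    mid <- mean(lh)
    if (is.infinite(spec$smoothness)) {
      field <- array(mid, shape)
    } else {
      z <- gaussian_smooth3(array(stats::rnorm(prod(shape)), shape),
                            spec$smoothness)
      z <- (z - mean(z)) / stats::sd(z)
      field <- mid + (diff(lh) / 4) * z   # +/-2 SD spans the range
      field <- pmin(pmax(field, lh[1]), lh[2])
    }
    field[!mask] <- 0
    maps[[nm]] <- field
  }
  list(maps = maps, mask = mask, spec = spec)
}

#' Simulate a noisy model series from parameter maps
#'
#' Evaluates the forward model voxelwise at every protocol entry and adds
#' noise with `SD = mean(S0 over mask) / snr`.  Gaussian noise (the model's
#' likelihood assumption) is added everywhere; Rician noise replaces each
#' value by the magnitude of the complex signal plus two independent
#' Gaussian channels, so background magnitudes follow a Rayleigh
#' distribution with the same sigma.
#'
#' @param maps named list of 3D parameter maps (from [make_phantom()]).
#' @param mask 3D mask.
#' @param protocol a [decide_protocol].
#' @param constants a [decide_constants].
#' @param snr signal-to-noise ratio; `Inf` for a noiseless series.
#' @param noise `"gaussian"` or `"rician"`.
#' @param seed RNG seed.
#' @param spacing voxel spacing (mm).
#' @return A [decide_series].
#' @export
simulate_series <- function(maps, mask, protocol,
                            constants = decide_constants(), snr = 20,
                            noise = c("gaussian", "rician"), seed = 1L,
                            spacing = c(2.5, 2.5, 2.5)) {
  noise <- match.arg(noise)
  stopifnot(snr > 0)
  clean <- synthesize_targets(maps, mask, protocol, constants, spacing)
  if (is.infinite(snr)) return(clean)
  sigma <- mean(maps$s0[mask != 0]) / snr
  add_noise(clean, sigma, noise, seed)
}

#' @rdname simulate_series
#' @param series a [decide_series] of noiseless signals.
#' @param sigma noise standard deviation (signal units).
#' @export
add_noise <- function(series, sigma, noise = c("gaussian", "rician"),
                      seed = 1L) {
  noise <- match.arg(noise)
  stopifnot(sigma >= 0)
  set.seed(seed)
  dat <- series$data
  if (sigma > 0) {
    n1 <- array(stats::rnorm(length(dat), sd = sigma), dim(dat))
    if (noise == "gaussian") dat <- dat + n1
    else {
      n2 <- array(stats::rnorm(length(dat), sd = sigma), dim(dat))
      dat <- sqrt((dat + n1)^2 + n2^2)
    }
  }
  decide_series(dat, series$spacing)
}

#' Simulate smooth per-volume motion
#'
#' For every volume an independent smooth random displacement field is drawn
#' on a coarse B-spline control grid (optionally AR(1)-correlated across
#' volumes to mimic breathing) and scaled per axis so that the mask-average
#' absolute displacement equals `mean_disp` exactly (defaults 2.11, 2.54,
#' 1.56 mm).  Each volume is then resampled through its field; the
#' ground-truth fields are returned for evaluation.
#'
#' @param series a [decide_series] (apply motion before adding noise:
#'   scanner noise arises after motion).
#' @param mask 3D mask used for the deformation scaling.
#' @param mean_disp per-axis target mask-average |displacement| in mm.
#' @param smoothness control-point spacing of the motion fields (voxels).
#' @param temporal_ar AR(1) coefficient in [0, 1) linking consecutive
#'   volumes' fields (0 = independent).
#' @param seed RNG seed.
#' @return List with `series` (deformed), `fields` (list of
#'   [decide_field]), and `achieved` (per-volume 3 x nv matrix of
#'   mask-average |u| in mm).
#' @export
simulate_motion <- function(series, mask, mean_disp = c(2.11, 2.54, 1.56),
                            smoothness = 8, temporal_ar = 0, seed = 1L) {
  stopifnot(all(mean_disp >= 0), temporal_ar >= 0, temporal_ar < 1)
  set.seed(seed)
  d3 <- dim(series$data)[1:3]
  nv <- n_volumes(series)
  sp <- series$spacing
  vox <- which(mask != 0)
  Bs <- lapply(1:3, function(ax) bspline_basis(d3[ax], smoothness))
  Ks <- vapply(Bs, ncol, 1L)
  out <- series
  fields <- vector("list", nv)
  achieved <- matrix(0, 3, nv)
  coef_prev <- NULL
  for (i in seq_len(nv)) {
    coef <- array(stats::rnorm(prod(Ks) * 3), c(Ks, 3))
    if (!is.null(coef_prev) && temporal_ar > 0)
      coef <- temporal_ar * coef_prev + sqrt(1 - temporal_ar^2) * coef
    coef_prev <- coef
    u <- array(0, c(d3, 3))
    for (k in 1:3) {
      uk <- ffd_component(coef[, , , k, drop = TRUE], Bs[[1]], Bs[[2]],
                          Bs[[3]]) * sp[k]   # raw field in mm
      m <- mean(abs(uk[vox]))
      uk <- if (m > 0 && mean_disp[k] > 0) uk * (mean_disp[k] / m)
            else array(0, d3)
      u[, , , k] <- uk
      achieved[k, i] <- mean(abs(uk[vox]))
    }
    fields[[i]] <- decide_field(u, sp)
    out$data[, , , i] <- warp_volume(series$data[, , , i], fields[[i]])
  }
  list(series = out, fields = fields, achieved = achieved)
}
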