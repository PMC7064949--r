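#' Normalized root mean square error between data and fit
#'
#' `sqrt(mean((data - fit)^2))` over mask voxels and all volumes, divided by
#' the mask-mean of the data (default) or by its range.
#'
#' @param data,fit [decide_series] on the same grid.
#' @param mask 3D mask.
#' @param normalizer `"mean"` (default) or `"range"`.
#' @return Scalar NRMSE.
#' @export
nrmse <- function(data, fit, mask, normalizer = c("mean", "range")) {
  normalizer <- match.arg(normalizer)
  stopifnot(identical(dim(data$data), dim(fit$data)))
  check_mask(mask, data)
  vox <- which(mask != 0)
  d3 <- dim(data$data)[1:3]
  D <- matrix(data$data, nrow = prod(d3))[vox, , drop = FALSE]
  Fv <- matrix(fit$data, nrow = prod(d3))[vox, , drop = FALSE]
  norm <- if (normalizer == "mean") mean(D) else diff(range(D))
  if (norm == 0) stop("zero normalizer: mask-mean of the data is 0")
  sqrt(mean((D - Fv)^2)) / norm
}

#' Model-driven registration
#'
#' Alternates linearized model fitting, target synthesis, and pairwise
#' free-form-deformation registration: in iteration k, the model is fitted
#' voxelwise to the current registered series, a noise-free target volume is
#' synthesized for every protocol entry, and each ORIGINAL volume is
#' registered to its target with control spacing `control_spacings[k]`
#' (fields composed across iterations; originals warped exactly once, so
#' interpolation error does not accumulate).  The returned quantitative maps
#' come from a final constrained nonlinear fit of the registered series.
#'
#' @param series a [decide_series] (the unregistered data).
#' @param mask 3D mask.
#' @param protocol a [decide_protocol].
#' @param constants a [decide_constants].
#' @param reg_config a [registration_config]; entry k of
#'   `control_spacings` is used in iteration k (last entry reused with a
#'   warning if iterations exceed it).
#' @param n_iterations number of fit/synthesize/register sweeps (default 3).
#' @param d_grid diffusivity grid for the linearized fit.
#' @param final_nls logical; run the final nonlinear fit (default `TRUE`).
#' @param nls_starts multi-starts for the final fit.
#' @param nls_smooth_sigma Gaussian pre-smoothing (voxels) for the final
#'   nonlinear fit only (the registration loop always uses raw volumes).
#' @return List with `registered` ([decide_series]), `fields` (list of
#'   [decide_field], one per volume), `maps` (final nonlinear fit, or the
#'   last linearized maps when `final_nls = FALSE`), and `nrmse_trace`
#'   (baseline plus one value per iteration).
#' @export
mdr_run <- function(series, mask, protocol, constants = decide_constants(),
                    reg_config = registration_config(),
                    n_iterations = 3L,
                    d_grid = exp(seq(log(5e-4), log(4e-3), length.out = 15L)),
                    final_nls = TRUE, nls_starts = 1L,
                    nls_smooth_sigma = 0) {
  check_series_protocol(series, protocol)
  check_mask(mask, series)
  stopifnot(n_iterations >= 1L)
  spacings <- reg_config$control_spacings
  if (n_iterations > length(spacings))
    warning("more iterations than control spacings; last spacing reused")
  d3 <- dim(series$data)[1:3]
  nv <- n_volumes(series)
  sp <- series$spacing
  fields <- replicate(nv, zero_field(d3, sp), simplify = FALSE)
  registered <- series
  fit_and_targets <- function(reg) {
    maps <- lls_fit_volume(reg, mask, protocol, constants, d_grid)
    targets <- synthesize_targets(maps, mask, protocol, constants, sp)
    list(maps = maps, targets = targets)
  }
  ft <- fit_and_targets(registered)
  trace <- nrmse(registered, ft$targets, mask)
  for (k in seq_len(n_iterations)) {
    s_k <- spacings[min(k, length(spacings))]
    cfg_k <- registration_config(control_spacings = s_k,
                                 metric = reg_config$metric,
                                 lambda_bend = reg_config$lambda_bend,
                                 max_iter = reg_config$max_iter,
                                 step0 = reg_config$step0)
    for (i in seq_len(nv)) {
      reg <- register_pair(registered$data[, , , i],
                           ft$targets$data[, , , i], cfg_k, sp)
      fields[[i]] <- compose_fields(fields[[i]], reg$field)
      registered$data[, , , i] <- warp_volume(series$data[, , , i],
                                              fields[[i]])
    }
    ft <- fit_and_targets(registered)
    trace <- c(trace, nrmse(registered, ft$targets, mask))
  }
  maps <- if (final_nls)
    nls_fit_volume(registered, mask, protocol, constants,
                   smooth_sigma = nls_smooth_sigma, n_starts = nls_starts)
  else ft$maps
  list(registered = registered, fields = fields, maps = maps,
       nrmse_trace = trace)
}
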