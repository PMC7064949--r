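#' Box constraints for the nonlinear fit
#'
#' Defaults follow the constrained voxelwise fit: 0 < f < 1, 0 < d < 1
#' (mm^2 s^-1), 0 < d* < 1 (mm^2 s^-1), 0 < T2fb < 500 (ms), 0 < v < 1.
#' The optimizer works in logit-transformed coordinates so the constraints
#' hold by construction.
#'
#' @param f,d,d_star,t2fb,v numeric `c(low, high)` pairs.
#' @return List of class `fit_bounds`.
#' @export
fit_bounds <- function(f = c(0, 1), d = c(0, 1), d_star = c(0, 1),
                       t2fb = c(0, 500), v = c(0, 1)) {
  b <- list(f = f, d = d, d_star = d_star, t2fb = t2fb, v = v)
  for (nm in names(b))
    if (length(b[[nm]]) != 2L || b[[nm]][1] >= b[[nm]][2])
      stop("invalid bounds for ", nm)
  structure(b, class = "fit_bounds")
}

# Transformed coordinates: th = (F, D, D*, T, V, logS0) with
# F = logit((f-lo)/(hi-lo)) etc.; S0 is log-transformed (positive, unbounded).
nls_theta_from_params <- function(p, bounds) {
  tr <- function(x, lh) stats::qlogis(pmin(pmax((x - lh[1]) / (lh[2] - lh[1]),
                                                1e-12), 1 - 1e-12))
  c(tr(p$f, bounds$f), tr(p$d, bounds$d), tr(p$d_star, bounds$d_star),
    tr(p$t2fb, bounds$t2fb), tr(p$v, bounds$v), log(p$s0))
}

nls_params_from_theta <- function(th, bounds) {
  inv <- function(u, lh) lh[1] + (lh[2] - lh[1]) * stats::plogis(u)
  list(f = inv(th[1], bounds$f), d = inv(th[2], bounds$d),
       d_star = inv(th[3], bounds$d_star), t2fb = inv(th[4], bounds$t2fb),
       v = inv(th[5], bounds$v), s0 = exp(th[6]))
}

# Model prediction and analytic Jacobian w.r.t. transformed coordinates.
nls_model_jac <- function(th, b, te, constants, bounds, want_jac = TRUE) {
  p <- nls_params_from_theta(th, bounds)
  r2fb <- 1 / p$t2fb
  e1 <- exp(-b * p$d_star - te * r2fb)
  e2 <- exp(-b * p$d - te * constants$r2mb)
  e3 <- exp(-b * p$d - te * constants$r2t)
  mix <- p$v * e2 + (1 - p$v) * e3
  S <- p$s0 * (p$f * e1 + (1 - p$f) * mix)
  if (!want_jac) return(list(S = S, p = p))
  # chain factors d(param)/d(theta) for the scaled-logit transform
  dchain <- function(x, lh) (x - lh[1]) * (lh[2] - x) / (lh[2] - lh[1])
  dS_df <- p$s0 * (e1 - mix)
  dS_dd <- p$s0 * (1 - p$f) * (-b) * mix
  dS_dds <- p$s0 * p$f * (-b) * e1
  dS_dt2 <- p$s0 * p$f * (te / p$t2fb^2) * e1   # via r2fb = 1/t2fb
  dS_dv <- p$s0 * (1 - p$f) * (e2 - e3)
  J <- cbind(dS_df * dchain(p$f, bounds$f),
             dS_dd * dchain(p$d, bounds$d),
             dS_dds * dchain(p$d_star, bounds$d_star),
             dS_dt2 * dchain(p$t2fb, bounds$t2fb),
             dS_dv * dchain(p$v, bounds$v),
             S)                                  # dS/dlogS0 = S
  list(S = S, J = J, p = p)
}

# Levenberg-Marquardt in transformed coordinates.  Returns theta, SSE and a
# convergence flag; only steps that decrease the SSE are accepted, so the
# reported residual never exceeds the residual at the initializer.
lm_minimize <- function(th0, signal, b, te, constants, bounds,
                        maxit = 300L, tol = 1e-14) {
  th <- th0
  mj <- nls_model_jac(th, b, te, constants, bounds)
  r <- mj$S - signal
  sse <- sum(r^2)
  lambda <- 1e-3
  converged <- FALSE
  for (it in seq_len(maxit)) {
    J <- mj$J
    g <- crossprod(J, r)
    H <- crossprod(J)
    dH <- diag(H)
    improved <- FALSE
    for (tries in 1:30) {
      step <- tryCatch(
        solve(H + lambda * diag(dH + 1e-12, length(th)), -g),
        error = function(e) NULL)
      if (!is.null(step)) {
        th_new <- th + as.numeric(step)
        mj_new <- nls_model_jac(th_new, b, te, constants, bounds)
        sse_new <- sum((mj_new$S - signal)^2)
        if (is.finite(sse_new) && sse_new < sse) {
          improved <- TRUE
          rel <- (sse - sse_new) / max(sse, .Machine$double.xmin)
          th <- th_new; mj <- mj_new; r <- mj$S - signal; sse <- sse_new
          lambda <- max(lambda / 3, 1e-12)
          if (rel < tol) converged <- TRUE
          break
        }
      }
      lambda <- lambda * 4
      if (lambda > 1e12) break
    }
    if (!improved || converged) { converged <- TRUE; break }
  }
  list(theta = th, sse = sse, converged = converged)
}

#' Nonlinear fit of a single voxel signal
#'
#' Constrained Levenberg-Marquardt minimization of the sum of squared
#' differences between the measured signal and the forward model, with S0
#' fitted jointly (six free parameters).  Constraints are enforced by
#' logit/log transforms.  A small multi-start (default 5: the initializer
#' plus 4 jittered copies, +-25% perturbation in transformed space) guards
#' against the pseudo-diffusivity local minima known from perfusion MRI.
#'
#' @param signal numeric signal vector paired with `protocol`.
#' @param protocol a [decide_protocol].
#' @param constants a [decide_constants].
#' @param init a [decide_params] (or plain list) initializer within bounds.
#' @param bounds a [fit_bounds].
#' @param n_starts number of starts (>= 1).
#' @param jitter_sd multiplicative jitter SD in transformed space.
#' @return List with `params` (list s0, f, d, d_star, t2fb, v), `residual`
#'   (norm), `converged`, and `at_bounds` (named logical for the five model
#'   parameters).
#' @export
nls_fit_voxel <- function(signal, protocol, constants = decide_constants(),
                          init, bounds = fit_bounds(), n_starts = 5L,
                          jitter_sd = 0.25) {
  if (any(!is.finite(signal)))
    return(list(params = NULL, residual = NA_real_, converged = FALSE,
                at_bounds = NULL, flag = "nonfinite_signal"))
  b <- protocol$b; te <- protocol$te
  th0 <- nls_theta_from_params(init, bounds)
  best <- NULL
  for (k in seq_len(max(1L, n_starts))) {
    th_start <- if (k == 1L) th0
                else th0 * (1 + jitter_sd * stats::rnorm(length(th0)))
    fit <- lm_minimize(th_start, signal, b, te, constants, bounds)
    if (is.null(best) || fit$sse < best$sse) best <- fit
  }
  p <- nls_params_from_theta(best$theta, bounds)
  frac <- stats::plogis(best$theta[1:5])
  at_b <- frac < 1e-4 | frac > 1 - 1e-4
  names(at_b) <- c("f", "d", "d_star", "t2fb", "v")
  list(params = p, residual = sqrt(best$sse), converged = best$converged,
       at_bounds = at_b, flag = "ok")
}

#' Fit the ROI-mean signal curve
#'
#' Fits the model to the across-mask mean signal; used as the voxelwise
#' initializer.  Starts from literature-scale values with S0 scaled to the
#' data.
#'
#' @inheritParams nls_fit_voxel
#' @param series a [decide_series].
#' @param mask 3D mask on the series grid.
#' @return As [nls_fit_voxel()], for the mean curve.
#' @export
nls_fit_roi_mean <- function(series, mask, protocol,
                             constants = decide_constants(),
                             bounds = fit_bounds(), n_starts = 5L) {
  check_series_protocol(series, protocol)
  check_mask(mask, series)
  vox <- which(mask != 0)
  flat <- matrix(series$data, nrow = prod(dim(series$data)[1:3]))
  mean_sig <- colMeans(flat[vox, , drop = FALSE])
  s0_init <- max(mean_sig) * 1.5
  init <- list(f = 0.2, d = 0.0015, d_star = constants$d_star_fixed,
               t2fb = constants$t2fb_fixed, v = 0.3, s0 = max(s0_init, 1e-6))
  fit <- nls_fit_voxel(mean_sig, protocol, constants, init, bounds, n_starts)
  if (!isTRUE(fit$converged) || is.null(fit$params)) {
    warning("ROI-mean fit did not converge; returning literature defaults")
    fit$params <- init
  }
  fit
}

#' Voxelwise nonlinear fit of a volume
#'
#' Optional per-volume spatial Gaussian pre-smoothing (sigma in voxels),
#' then a constrained voxelwise fit initialized from the ROI-mean fit.
#'
#' @inheritParams nls_fit_roi_mean
#' @param smooth_sigma Gaussian SD in voxels (0 = no smoothing).
#' @param n_starts starts per voxel (default 1: the ROI-mean initializer;
#'   increase to guard local minima at a linear cost).
#' @return List of 3D maps (`s0`, `f`, `d`, `d_star`, `t2fb`, `v`,
#'   `residual`, `converged`, `n_at_bound`) plus `roi_init` (the ROI-mean
#'   parameter list).
#' @export
nls_fit_volume <- function(series, mask, protocol,
                           constants = decide_constants(),
                           bounds = fit_bounds(), smooth_sigma = 0,
                           n_starts = 1L) {
  check_series_protocol(series, protocol)
  check_mask(mask, series)
  dat <- series$data
  if (smooth_sigma > 0) {
    for (i in seq_len(dim(dat)[4]))
      dat[, , , i] <- gaussian_smooth3(dat[, , , i], smooth_sigma)
    series <- decide_series(dat, series$spacing)
  }
  roi <- nls_fit_roi_mean(series, mask, protocol, constants, bounds)
  init <- roi$params
  d3 <- dim(dat)[1:3]
  vox <- which(mask != 0)
  flat <- matrix(dat, nrow = prod(d3))
  zero <- array(0, d3)
  maps <- list(s0 = zero, f = zero, d = zero, d_star = zero, t2fb = zero,
               v = zero, residual = zero, converged = zero,
               n_at_bound = zero)
  for (i in seq_along(vox)) {
    fit <- nls_fit_voxel(flat[vox[i], ], protocol, constants, init, bounds,
                         n_starts = n_starts)
    if (is.null(fit$params)) next
    p <- fit$params
    maps$s0[vox[i]] <- p$s0; maps$f[vox[i]] <- p$f; maps$d[vox[i]] <- p$d
    maps$d_star[vox[i]] <- p$d_star; maps$t2fb[vox[i]] <- p$t2fb
    maps$v[vox[i]] <- p$v
    maps$residual[vox[i]] <- fit$residual
    maps$converged[vox[i]] <- as.numeric(fit$converged)
    maps$n_at_bound[vox[i]] <- sum(fit$at_bounds)
  }
  maps$roi_init <- init
  maps
}
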