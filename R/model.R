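#' Fixed model constants
#'
#' Literature-based relaxation rates for the maternal-blood and tissue
#' compartments, and the fixed pseudo-diffusivity / fetal-blood T2 used by the
#' linearized fit.  All overridable.
#'
#' @param r2mb maternal blood relaxation rate (ms^-1); default 1/240.
#' @param r2t tissue relaxation rate (ms^-1); default 1/46.
#' @param d_star_fixed pseudo-diffusivity fixed in the linearization
#'   (mm^2 s^-1); default 0.073.
#' @param t2fb_fixed fetal-blood T2 fixed in the linearization (ms);
#'   default 144.89.
#' @return A list of class `decide_constants`.
#' @export
decide_constants <- function(r2mb = 1 / 240, r2t = 1 / 46,
                             d_star_fixed = 0.073, t2fb_fixed = 144.89) {
  stopifnot(r2mb > 0, r2t > 0, d_star_fixed > 0, t2fb_fixed > 0)
  structure(list(r2mb = r2mb, r2t = r2t,
                 d_star_fixed = d_star_fixed, t2fb_fixed = t2fb_fixed),
            class = "decide_constants")
}

#' Single-voxel model parameter set
#'
#' The five independent parameters of the three-compartment placental
#' diffusion-relaxation model plus the unweighted signal S0: rapid-perfusing
#' (fetal blood) volume fraction f, tissue diffusivity d, pseudo-diffusivity
#' d*, fetal-blood T2 (ms; the model uses its reciprocal r2fb), and
#' slow-perfusing (maternal blood) volume fraction v of the non-f space.
#'
#' @param s0 unweighted signal, > 0.
#' @param f rapid-perfusing volume fraction in (0, 1).
#' @param d diffusivity (mm^2 s^-1), > 0.
#' @param d_star pseudo-diffusivity (mm^2 s^-1), > 0.
#' @param t2fb fetal blood T2 (ms), > 0.
#' @param v slow-perfusing volume fraction in (0, 1).
#' @return A list of class `decide_params`.
#' @export
decide_params <- function(s0, f, d, d_star, t2fb, v) {
  stopifnot(is.finite(s0), s0 > 0,
            is.finite(f), f > 0, f < 1,
            is.finite(d), d > 0,
            is.finite(d_star), d_star > 0,
            is.finite(t2fb), t2fb > 0,
            is.finite(v), v > 0, v < 1)
  structure(list(s0 = s0, f = f, d = d, d_star = d_star, t2fb = t2fb, v = v),
            class = "decide_params")
}

#' @export
print.decide_params <- function(x, ...) {
  cat(sprintf(
    "<decide_params> s0=%.4g f=%.4g d=%.4g d*=%.4g T2fb=%.4g v=%.4g\n",
    x$s0, x$f, x$d, x$d_star, x$t2fb, x$v))
  invisible(x)
}

#' Forward signal model
#'
#' Evaluates the three-compartment signal
#' \deqn{S(b, TE) = S_0\left(f e^{-b d^* - TE\, r_{2fb}} +
#'   (1-f)\left[v e^{-b d - TE\, r_{2mb}} +
#'   (1-v) e^{-b d - TE\, r_{2t}}\right]\right)}
#' at every (b, TE) of the protocol.  Both the maternal-blood and the tissue
#' compartments are attenuated by \eqn{e^{-bd}} (the linearized-model form,
#' which keeps the amplitude reparameterization exact).
#'
#' @param params a [decide_params].
#' @param protocol a [decide_protocol].
#' @param constants a [decide_constants].
#' @return Numeric vector of signals, one per protocol entry, all > 0.
#' @export
decide_signal <- function(params, protocol, constants = decide_constants()) {
  stopifnot(inherits(protocol, "decide_protocol"), nrow(protocol) >= 1L)
  b <- protocol$b; te <- protocol$te
  r2fb <- 1 / params$t2fb
  e1 <- exp(-b * params$d_star - te * r2fb)
  e2 <- exp(-b * params$d - te * constants$r2mb)
  e3 <- exp(-b * params$d - te * constants$r2t)
  params$s0 * (params$f * e1 +
               (1 - params$f) * (params$v * e2 + (1 - params$v) * e3))
}

#' Amplitude reparameterization of the model
#'
#' Maps physiology (S0, f, v) to the three nonnegative linear amplitudes
#' lambda1 = S0 f, lambda2 = S0 (1-f) v, lambda3 = S0 (1-f)(1-v), and back.
#' The two maps are exact inverses; lambda1+lambda2+lambda3 = S0.
#'
#' @param s0,f,v physiology: s0 > 0, f and v in (0, 1).
#' @return `lambda_from_physio`: numeric `c(lam1, lam2, lam3)`.
#' @export
lambda_from_physio <- function(s0, f, v) {
  stopifnot(s0 > 0, f > 0, f < 1, v > 0, v < 1)
  c(lam1 = s0 * f, lam2 = s0 * (1 - f) * v, lam3 = s0 * (1 - f) * (1 - v))
}

#' @rdname lambda_from_physio
#' @param lam numeric vector `c(lam1, lam2, lam3)`, all >= 0, with
#'   `lam2 + lam3 > 0` and a positive sum.
#' @return `physio_from_lambda`: list with `s0`, `f`, `v`.
#' @export
physio_from_lambda <- function(lam) {
  stopifnot(length(lam) == 3L, all(is.finite(lam)), all(lam >= 0))
  lam <- unname(lam)
  s <- sum(lam)
  if (s <= 0) stop("degenerate amplitudes: lambda1+lambda2+lambda3 must be > 0")
  if (lam[2] + lam[3] <= 0)
    stop("degenerate amplitudes: lambda2+lambda3 must be > 0")
  list(s0 = s, f = lam[1] / s, v = lam[2] / (lam[2] + lam[3]))
}

#' Fetal-blood oxygen saturation from T2
#'
#' Converts fetal-blood T2 (ms) to fractional oxygen saturation using a
#' quadratic blood-relaxometry calibration
#' \deqn{1/T_2 = A + K (1 - FO_2)^2.}
#' No calibration is assumed by default: the constants must be supplied
#' explicitly (the package never fabricates oxygenation silently).  The
#' result is clipped to [0, 1] and is monotone increasing in T2.
#'
#' @param t2fb fetal-blood T2 (ms), > 0; vectorized.
#' @param calibration list with elements `A` (plasma-limit relaxation rate,
#'   ms^-1) and `K` (deoxygenation coefficient, ms^-1), both > 0.
#' @return Fractional oxygen saturation in [0, 1].
#' @seealso [fo2_calibration_default()] for a documented synthetic default.
#' @export
fo2_from_t2fb <- function(t2fb, calibration) {
  stopifnot(all(t2fb > 0))
  if (missing(calibration) || is.null(calibration))
    stop("an explicit FO2 calibration (A, K) is required")
  A <- calibration$A; K <- calibration$K
  stopifnot(is.numeric(A), is.numeric(K), A > 0, K > 0)
  q <- (1 / t2fb - A) / K
  if (any(q < 0))
    warning("some T2 values exceed the calibration's oxygenated limit; ",
            "FO2 clipped to 1")
  fo2 <- 1 - sqrt(pmax(q, 0))
  pmin(pmax(fo2, 0), 1)
}

#' @rdname fo2_from_t2fb
#' @details `t2fb_from_fo2` is the analytic inverse on the calibration's
#'   valid range (FO2 in [0, 1]).
#' @param fo2 fractional oxygen saturation in [0, 1]; vectorized.
#' @export
t2fb_from_fo2 <- function(fo2, calibration) {
  stopifnot(all(fo2 >= 0), all(fo2 <= 1))
  A <- calibration$A; K <- calibration$K
  1 / (A + K * (1 - fo2)^2)
}

#' @rdname fo2_from_t2fb
#' @details `fo2_calibration_default()` returns a synthetic 1.5T fetal-blood
#'   calibration (A = 0.004 ms^-1, K = 0.035 ms^-1: fully oxygenated blood
#'   T2 = 250 ms, fully deoxygenated about 26 ms).  It is a placeholder shape,
#'   not a measured curve; substitute site-specific constants for physiology.
#' @export
fo2_calibration_default <- function() list(A = 0.004, K = 0.035)
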