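#' Design matrix of the linearized model
#'
#' With the pseudo-diffusivity and fetal-blood relaxation fixed at literature
#' values, the signal model is linear in the three compartment amplitudes:
#' S = A lambda, where row i of A is
#' `[exp(-b_i d* - te_i r2fb), exp(-b_i d - te_i r2mb), exp(-b_i d - te_i r2t)]`.
#' The tissue diffusivity `d` remains free and is handled by grid search in
#' [lls_fit_volume()].
#'
#' @param protocol a [decide_protocol].
#' @param d tissue diffusivity (mm^2 s^-1) used for columns 2-3.
#' @param constants a [decide_constants]; supplies d*, T2fb (fixed), r2mb, r2t.
#' @return List with `a` (n x 3 matrix) and `fixed` (the rates used).
#' @export
build_design_matrix <- function(protocol, d, constants = decide_constants()) {
  stopifnot(d > 0)
  b <- protocol$b; te <- protocol$te
  r2fb <- 1 / constants$t2fb_fixed
  a <- cbind(exp(-b * constants$d_star_fixed - te * r2fb),
             exp(-b * d - te * constants$r2mb),
             exp(-b * d - te * constants$r2t))
  list(a = a,
       fixed = list(d = d, d_star = constants$d_star_fixed,
                    r2fb = r2fb, r2mb = constants$r2mb, r2t = constants$r2t))
}

# Exact nonnegative least squares for p = 3 by active-set enumeration: the
# optimum of this convex problem has some subset of coefficients at zero, so
# trying all 8 subsets and keeping the feasible minimum is globally exact.
nnls3 <- function(A, y) {
  best <- list(x = c(0, 0, 0), sse = sum(y^2))
  for (mask_bits in 1:7) {
    P <- which(bitwAnd(mask_bits, c(1L, 2L, 4L)) > 0)
    Ap <- A[, P, drop = FALSE]
    x_p <- tryCatch(qr.solve(Ap, y), error = function(e) NULL)
    if (is.null(x_p) || any(!is.finite(x_p)) || any(x_p < 0)) next
    r <- y - Ap %*% x_p
    sse <- sum(r^2)
    if (sse < best$sse - 1e-15 * max(1, best$sse)) {
      x <- c(0, 0, 0); x[P] <- x_p
      best <- list(x = x, sse = sse)
    }
  }
  best
}

#' Linearized fit of a single voxel
#'
#' Solves `min ||S - A lambda||^2` subject to `lambda >= 0` (nonnegative
#' least squares; exact for three amplitudes).  Set `nonneg = FALSE` for the
#' faster unconstrained solve with clipping to zero.
#'
#' @param signal numeric signal vector, length = rows of the design.
#' @param design a design matrix object from [build_design_matrix()].
#' @param nonneg logical; enforce nonnegativity exactly (default `TRUE`).
#' @return List with `lambda` (length 3), `residual` (norm), and `flag`
#'   (`"ok"`, `"rank_deficient"`, or `"degenerate"`).
#' @export
lls_fit_voxel <- function(signal, design, nonneg = TRUE) {
  A <- design$a
  stopifnot(length(signal) == nrow(A))
  if (qr(A)$rank < 3L)
    return(list(lambda = c(0, 0, 0), residual = sqrt(sum(signal^2)),
                flag = "rank_deficient"))
  if (nonneg) {
    fit <- nnls3(A, signal)
    lam <- fit$x
    res <- sqrt(fit$sse)
  } else {
    lam <- pmax(as.numeric(qr.solve(A, signal)), 0)
    res <- sqrt(sum((signal - A %*% lam)^2))
  }
  flag <- if (lam[2] + lam[3] <= 0 && sum(lam) > 0) "degenerate" else "ok"
  list(lambda = lam, residual = res, flag = flag)
}

#' Linearized fit of a volume
#'
#' Voxelwise variable-projection fit: for each candidate diffusivity on
#' `d_grid` the amplitudes are solved linearly, and the candidate with the
#' smallest residual is kept.  Fast path: all voxels are solved
#' unconstrained in one matrix solve per grid point; voxels with negative
#' amplitudes are re-solved with exact nonnegative least squares.
#'
#' @param series a [decide_series].
#' @param mask 3D logical/0-1 array on the series grid.
#' @param protocol a [decide_protocol].
#' @param constants a [decide_constants].
#' @param d_grid candidate diffusivities (mm^2 s^-1); default 15 log-spaced
#'   points on 5e-4 to 4e-3.
#' @return List of 3D maps `s0`, `f`, `v`, `d`, `residual`, and `qc`
#'   (0 = ok, 1 = degenerate amplitudes, v imputed at 0.5).
#' @export
lls_fit_volume <- function(series, mask, protocol,
                           constants = decide_constants(),
                           d_grid = exp(seq(log(5e-4), log(4e-3),
                                            length.out = 15L))) {
  check_series_protocol(series, protocol)
  check_mask(mask, series)
  stopifnot(length(d_grid) >= 1L)
  d3 <- dim(series$data)[1:3]
  vox <- which(mask != 0)
  S <- matrix(series$data, nrow = prod(d3))[vox, , drop = FALSE]  # M x N
  M <- nrow(S)
  best_sse <- rep(Inf, M)
  best_lam <- matrix(0, M, 3)
  best_d <- rep(d_grid[1], M)
  for (d in d_grid) {
    des <- build_design_matrix(protocol, d, constants)
    A <- des$a
    lam <- t(qr.solve(A, t(S)))                       # M x 3 unconstrained
    neg <- which(rowSums(lam < -1e-12 * pmax(rowSums(abs(lam)), 1)) > 0)
    for (i in neg) {
      fit <- nnls3(A, S[i, ])
      lam[i, ] <- fit$x
    }
    lam[lam < 0] <- 0
    sse <- rowSums((S - lam %*% t(A))^2)
    upd <- sse < best_sse
    best_sse[upd] <- sse[upd]
    best_lam[upd, ] <- lam[upd, , drop = FALSE]
    best_d[upd] <- d
  }
  lam_sum <- rowSums(best_lam)
  v23 <- best_lam[, 2] + best_lam[, 3]
  degen <- v23 <= 0
  f <- ifelse(lam_sum > 0, best_lam[, 1] / lam_sum, 0)
  v <- ifelse(degen, 0.5, best_lam[, 2] / pmax(v23, .Machine$double.xmin))
  zero_map <- array(0, d3)
  mk <- function(vals) { m <- zero_map; m[vox] <- vals; m }
  list(s0 = mk(lam_sum), f = mk(f), v = mk(v), d = mk(best_d),
       residual = mk(sqrt(best_sse)), qc = mk(as.numeric(degen)))
}

# Evaluate the forward model voxelwise from parameter maps restricted to
# `vox` (linear indices); returns an M x N signal matrix.
signal_matrix_from_maps <- function(maps, vox, protocol, constants) {
  s0 <- maps$s0[vox]; f <- maps$f[vox]; v <- maps$v[vox]; d <- maps$d[vox]
  d_star <- if (!is.null(maps$d_star)) maps$d_star[vox]
            else rep(constants$d_star_fixed, length(vox))
  t2fb <- if (!is.null(maps$t2fb)) maps$t2fb[vox]
          else rep(constants$t2fb_fixed, length(vox))
  r2fb <- 1 / t2fb
  n <- nrow(protocol)
  out <- matrix(0, length(vox), n)
  for (i in seq_len(n)) {
    b <- protocol$b[i]; te <- protocol$te[i]
    e1 <- exp(-b * d_star - te * r2fb)
    e2 <- exp(-b * d - te * constants$r2mb)
    e3 <- exp(-b * d - te * constants$r2t)
    out[, i] <- s0 * (f * e1 + (1 - f) * (v * e2 + (1 - v) * e3))
  }
  out
}

#' Synthesize model target volumes
#'
#' Evaluates the forward model voxelwise from fitted parameter maps at every
#' protocol entry, producing the noise-free series used as registration
#' targets.  If `maps` lacks `d_star` / `t2fb` maps the linearization's fixed
#' constants are used (the output of [lls_fit_volume()]).
#'
#' @param maps list of 3D maps with at least `s0`, `f`, `v`, `d`.
#' @param mask 3D mask; voxels outside are taken from `background` (a
#'   [decide_series] on the same grid) or left zero.
#' @param protocol a [decide_protocol].
#' @param constants a [decide_constants].
#' @param spacing voxel spacing (mm) for the output series.
#' @param background optional [decide_series] supplying outside-mask voxels.
#' @return A [decide_series] of model-predicted volumes.
#' @export
synthesize_targets <- function(maps, mask, protocol,
                               constants = decide_constants(),
                               spacing = c(1, 1, 1), background = NULL) {
  d3 <- dim(maps$s0)
  n <- nrow(protocol)
  vox <- which(mask != 0)
  sig <- signal_matrix_from_maps(maps, vox, protocol, constants)
  out <- if (is.null(background)) array(0, c(d3, n)) else background$data
  flat <- matrix(out, nrow = prod(d3))
  flat[vox, ] <- sig
  decide_series(array(flat, c(d3, n)),
                spacing = if (is.null(background)) spacing
                          else background$spacing)
}
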