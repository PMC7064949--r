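#' Dense displacement field
#'
#' Per-voxel 3-vector displacement in millimetres on the image grid, mapping
#' moving to target space: the warped image is `moving(x + u(x))`.
#'
#' @param u 4D array `dim = c(nx, ny, nz, 3)` of displacements (mm).
#' @param spacing voxel spacing (mm).
#' @return Object of class `decide_field`.
#' @export
decide_field <- function(u, spacing = c(1, 1, 1)) {
  stopifnot(length(dim(u)) == 4L, dim(u)[4] == 3L, all(is.finite(u)))
  structure(list(u = u, spacing = as.numeric(spacing)),
            class = "decide_field")
}

zero_field <- function(shape, spacing) decide_field(array(0, c(shape, 3)), spacing)

#' Registration configuration
#'
#' @param control_spacings B-spline control-point spacings in voxels, coarse
#'   to fine; default `c(10, 5, 2.5)` (the model-driven registration
#'   schedule).
#' @param metric similarity metric; only `"ssd"` (sum of squared
#'   differences) is implemented — moving and target share the model's
#'   intensity scale by construction.
#' @param lambda_bend bending-energy weight relative to the mean squared
#'   target intensity.
#' @param max_iter gradient-descent iterations per level.
#' @param step0 initial step length (voxels of maximal control-point motion).
#' @return List of class `registration_config`.
#' @export
registration_config <- function(control_spacings = c(10, 5, 2.5),
                                metric = "ssd", lambda_bend = 1e-3,
                                max_iter = 60L, step0 = 1) {
  stopifnot(all(control_spacings > 0), max_iter >= 1L, step0 > 0,
            lambda_bend >= 0)
  metric <- match.arg(metric, "ssd")
  structure(list(control_spacings = control_spacings, metric = metric,
                 lambda_bend = lambda_bend, max_iter = as.integer(max_iter),
                 step0 = step0),
            class = "registration_config")
}

#' Warp a volume by a displacement field
#'
#' Resamples `volume` at `x + u(x)` with trilinear interpolation;
#' out-of-grid samples take nearest-edge values.
#'
#' @param volume 3D array.
#' @param field a [decide_field] on the same grid.
#' @return Warped 3D array.
#' @export
warp_volume <- function(volume, field) {
  d <- dim(volume)
  stopifnot(identical(d, dim(field$u)[1:3]))
  g <- coord_grids(d)
  sp <- field$spacing
  out <- sample_trilinear(volume,
                          g$x + field$u[, , , 1] / sp[1],
                          g$y + field$u[, , , 2] / sp[2],
                          g$z + field$u[, , , 3] / sp[3])
  array(out, d)
}

#' Compose two displacement fields
#'
#' Returns the field of the composed warp "apply `total` after `step`":
#' `u_new(x) = u_step(x) + u_total(x + u_step(x))`, so that warping once by
#' the composition equals warping by `total` and then registering that
#' result by `step`.
#'
#' @param total,step [decide_field]s on the same grid.
#' @return A [decide_field].
#' @export
compose_fields <- function(total, step) {
  d <- dim(total$u)[1:3]
  g <- coord_grids(d)
  sp <- total$spacing
  xi <- g$x + step$u[, , , 1] / sp[1]
  yi <- g$y + step$u[, , , 2] / sp[2]
  zi <- g$z + step$u[, , , 3] / sp[3]
  u <- array(0, dim(total$u))
  for (k in 1:3)
    u[, , , k] <- step$u[, , , k] +
      array(sample_trilinear(total$u[, , , k], xi, yi, zi), d)
  decide_field(u, sp)
}

# One FFD level: gradient descent on SSD + bending energy over the control
# coefficients.  Only cost-decreasing steps are accepted.
ffd_register_level <- function(moving, target, spacing_vox, cfg, sp_mm) {
  d <- dim(moving)
  Bs <- lapply(1:3, function(ax) bspline_basis(d[ax], spacing_vox))
  Ks <- vapply(Bs, ncol, 1L)
  D2s <- lapply(Ks, diff2_matrix)
  coef <- array(0, c(Ks, 3))            # displacements in voxel units
  g <- coord_grids(d)
  bend_w <- cfg$lambda_bend * mean(target^2)
  field_from_coef <- function(coef) {
    lapply(1:3, function(k)
      ffd_component(coef[, , , k, drop = TRUE], Bs[[1]], Bs[[2]], Bs[[3]]))
  }
  cost_of <- function(coef) {
    u <- field_from_coef(coef)
    w <- array(sample_trilinear(moving, g$x + u[[1]], g$y + u[[2]],
                                g$z + u[[3]]), d)
    r <- w - target
    bp <- 0
    if (bend_w > 0)
      for (k in 1:3)
        bp <- bp + bend_penalty(coef[, , , k, drop = TRUE], D2s)$value
    list(cost = sum(r^2) + bend_w * bp, warped = w, r = r, u = u)
  }
  cur <- cost_of(coef)
  step <- cfg$step0
  for (it in seq_len(cfg$max_iter)) {
    # image gradient of the warped moving image (central differences)
    gr <- image_gradient(cur$warped)
    grad <- array(0, c(Ks, 3))
    for (k in 1:3) {
      gvox <- 2 * cur$r * gr[[k]]
      gc <- ffd_component_t(gvox, Bs[[1]], Bs[[2]], Bs[[3]])
      if (bend_w > 0)
        gc <- gc + bend_w * bend_penalty(coef[, , , k, drop = TRUE], D2s)$grad
      grad[, , , k] <- gc
    }
    gmax <- max(abs(grad))
    if (gmax == 0) break
    improved <- FALSE
    for (tries in 1:12) {
      coef_new <- coef - (step / gmax) * grad
      new <- cost_of(coef_new)
      if (new$cost < cur$cost) {
        coef <- coef_new; cur <- new
        step <- min(step * 1.5, 4 * cfg$step0)
        improved <- TRUE
        break
      }
      step <- step / 2
      if (step < 1e-3) break
    }
    if (!improved) break
  }
  u_mm <- array(0, c(d, 3))
  for (k in 1:3) u_mm[, , , k] <- cur$u[[k]] * sp_mm[k]
  list(field = decide_field(u_mm, sp_mm), warped = cur$warped,
       cost = cur$cost)
}

# Central-difference spatial gradient (in voxel units) of a 3D array.
image_gradient <- function(A) {
  d <- dim(A)
  shift <- function(ax, by) {
    idx <- pmin(pmax(seq_len(d[ax]) + by, 1L), d[ax])
    if (ax == 1) A[idx, , , drop = FALSE]
    else if (ax == 2) A[, idx, , drop = FALSE]
    else A[, , idx, drop = FALSE]
  }
  lapply(1:3, function(ax) {
    g <- (shift(ax, 1L) - shift(ax, -1L)) / 2
    array(g, d)
  })
}

#' Pairwise deformable registration
#'
#' Registers `moving` to `target` with the default internal backend: a
#' multi-level cubic B-spline free-form deformation, sum-of-squared-
#' differences similarity, bending-energy regularization and backtracking
#' gradient descent.  The similarity of the warped result never exceeds the
#' unwarped similarity (only cost-decreasing steps are taken).  Alternative
#' backends can be plugged in as a function with the same signature via
#' `backend`.
#'
#' @param moving,target 3D arrays on the same grid.
#' @param config a [registration_config]; each entry of
#'   `control_spacings` is one level, coarse to fine, with fields composed
#'   across levels.
#' @param spacing voxel spacing (mm).
#' @param backend `"ffd"` or a function
#'   `(moving, target, config, spacing) -> list(field, warped)`.
#' @return List with `field` (a [decide_field], mm), `warped` (3D array),
#'   and `ssd` (final sum of squared differences).
#' @export
register_pair <- function(moving, target, config = registration_config(),
                          spacing = c(1, 1, 1), backend = "ffd") {
  if (!identical(dim(moving), dim(target)))
    stop("moving and target grids differ")
  if (is.function(backend)) {
    out <- tryCatch(backend(moving, target, config, spacing),
                    error = function(e) {
                      warning("registration backend failed (",
                              conditionMessage(e), "); returning identity")
                      list(field = zero_field(dim(moving), spacing),
                           warped = moving)
                    })
    out$ssd <- sum((out$warped - target)^2)
    return(out)
  }
  total <- zero_field(dim(moving), spacing)
  cur <- moving
  for (s in config$control_spacings) {
    lev <- ffd_register_level(cur, target, s, config, spacing)
    total <- compose_fields(total, lev$field)
    cur <- warp_volume(moving, total)
  }
  list(field = total, warped = cur, ssd = sum((cur - target)^2))
}
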