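# Cubic B-spline free-form deformation machinery.  A displacement component
# is a tensor-product cubic B-spline over a control grid with spacing s
# voxels; dense fields are obtained by applying the 1-D basis matrix along
# each axis, and cost gradients are pulled back to the control grid with the
# transposed matrices.

# Number of control points needed to cover n voxels at spacing s.
n_control <- function(n, s) floor((n - 1) / s) + 4L

# n x K cubic B-spline basis matrix; control point k sits at voxel
# 1 + (k - 2) * s.
bspline_basis <- function(n, s) {
  K <- n_control(n, s)
  x <- seq_len(n)
  u <- (x - 1) / s
  i <- floor(u)
  t <- u - i
  w <- cbind((1 - t)^3 / 6,
             (3 * t^3 - 6 * t^2 + 4) / 6,
             (-3 * t^3 + 3 * t^2 + 3 * t + 1) / 6,
             t^3 / 6)
  B <- matrix(0, n, K)
  for (m in 0:3) B[cbind(x, i + m + 1L)] <- B[cbind(x, i + m + 1L)] + w[, m + 1L]
  B
}

# Dense displacement component (3D array) from a control coefficient array.
ffd_component <- function(coef, Bx, By, Bz) {
  A <- apply_along(coef, Bx, 1L)
  A <- apply_along(A, By, 2L)
  apply_along(A, Bz, 3L)
}

# Transpose contraction: voxel-space gradient -> control-space gradient.
ffd_component_t <- function(grad, Bx, By, Bz) {
  A <- apply_along(grad, t(Bx), 1L)
  A <- apply_along(A, t(By), 2L)
  apply_along(A, t(Bz), 3L)
}

# Second-difference matrix for the bending penalty.
diff2_matrix <- function(n) {
  if (n < 3L) return(matrix(0, 0, n))
  D <- matrix(0, n - 2L, n)
  for (i in seq_len(n - 2L)) D[i, i + 0:2] <- c(1, -2, 1)
  D
}

# Bending penalty and its gradient for one coefficient array.
bend_penalty <- function(coef, D2s) {
  val <- 0
  grad <- array(0, dim(coef))
  for (ax in 1:3) {
    if (nrow(D2s[[ax]]) == 0L) next
    d <- apply_along(coef, D2s[[ax]], ax)
    val <- val + sum(d^2)
    grad <- grad + 2 * apply_along(d, t(D2s[[ax]]), ax)
  }
  list(value = val, grad = grad)
}
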