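# Internal dense-array helpers: separable Gaussian smoothing, trilinear
# sampling, and tensor-product contractions used by the B-spline machinery.

# Apply a matrix M (m x n) along dimension `dim` of array A (size n there).
apply_along <- function(A, M, dim) {
  d <- dim(A)
  perm <- c(dim, setdiff(seq_along(d), dim))
  Ap <- aperm(A, perm)
  dp <- dim(Ap)
  out <- M %*% matrix(Ap, nrow = dp[1])
  dim(out) <- c(nrow(M), dp[-1])
  aperm(out, order(perm))
}

# 1-D Gaussian convolution matrix with replicate-edge handling.
gauss_matrix <- function(n, sigma) {
  if (sigma <= 0) return(diag(n))
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-0.5 * ((-r:r) / sigma)^2)
  k <- k / sum(k)
  M <- matrix(0, n, n)
  for (i in seq_len(n)) {
    idx <- pmin(pmax(i + (-r:r), 1L), n)  # replicate padding
    for (j in seq_along(idx)) M[i, idx[j]] <- M[i, idx[j]] + k[j]
  }
  M
}

# Separable Gaussian smoothing of a 3D array; sigma in voxels (scalar or
# per-axis).
gaussian_smooth3 <- function(A, sigma) {
  sigma <- rep(sigma, length.out = 3L)
  d <- dim(A)
  for (ax in 1:3)
    if (sigma[ax] > 0) A <- apply_along(A, gauss_matrix(d[ax], sigma[ax]), ax)
  A
}

# Trilinear sampling of 3D volume at continuous voxel coordinates (1-based).
# Coordinates outside the grid are clamped to the nearest edge.
sample_trilinear <- function(vol, xi, yi, zi) {
  d <- dim(vol)
  xi <- pmin(pmax(xi, 1), d[1]); yi <- pmin(pmax(yi, 1), d[2])
  zi <- pmin(pmax(zi, 1), d[3])
  x0 <- pmin(floor(xi), d[1] - 1L); y0 <- pmin(floor(yi), d[2] - 1L)
  z0 <- pmin(floor(zi), d[3] - 1L)
  if (d[1] == 1L) x0 <- rep(1, length(xi))
  if (d[2] == 1L) y0 <- rep(1, length(yi))
  if (d[3] == 1L) z0 <- rep(1, length(zi))
  fx <- xi - x0; fy <- yi - y0; fz <- zi - z0
  idx <- function(i, j, k) vol[cbind(i, j, k)]
  x1 <- pmin(x0 + 1, d[1]); y1 <- pmin(y0 + 1, d[2]); z1 <- pmin(z0 + 1, d[3])
  c000 <- idx(x0, y0, z0); c100 <- idx(x1, y0, z0)
  c010 <- idx(x0, y1, z0); c110 <- idx(x1, y1, z0)
  c001 <- idx(x0, y0, z1); c101 <- idx(x1, y0, z1)
  c011 <- idx(x0, y1, z1); c111 <- idx(x1, y1, z1)
  c00 <- c000 * (1 - fx) + c100 * fx
  c10 <- c010 * (1 - fx) + c110 * fx
  c01 <- c001 * (1 - fx) + c101 * fx
  c11 <- c011 * (1 - fx) + c111 * fx
  c0 <- c00 * (1 - fy) + c10 * fy
  c1 <- c01 * (1 - fy) + c11 * fy
  c0 * (1 - fz) + c1 * fz
}

# Voxel-centre coordinate grids for a 3D shape (1-based voxel units).
coord_grids <- function(d) {
  list(x = array(rep(seq_len(d[1]), times = d[2] * d[3]), d),
       y = array(rep(rep(seq_len(d[2]), each = d[1]), times = d[3]), d),
       z = array(rep(seq_len(d[3]), each = d[1] * d[2]), d))
}

# Ellipsoidal mask centred in the grid; semi-axes as fractions of half-extent.
ellipsoid_mask <- function(shape, semi_frac = c(0.8, 0.8, 0.8)) {
  g <- coord_grids(shape)
  cx <- (shape + 1) / 2
  ax <- pmax((shape - 1) / 2, 0.5) * semi_frac
  r2 <- ((g$x - cx[1]) / ax[1])^2 + ((g$y - cx[2]) / ax[2])^2 +
    ((g$z - cx[3]) / ax[3])^2
  array(r2 <= 1, shape)
}
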