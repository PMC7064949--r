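# Independent oracles and shared fixtures.  Every oracle here is written as
# a plain scalar/loop implementation, separate from the vectorized package
# paths it checks.

# Cohort-mean parameter set (unregistered-data column), S0 = 1.
table1_params <- function() {
  list(s0 = 1, f = 0.225, d = 0.0015, d_star = 0.0385, t2fb = 181.1,
       v = 0.306)
}

# Scalar per-entry signal oracle: one (b, te) at a time, no vectorization.
scalar_signal_oracle <- function(p, b, te, r2mb = 1 / 240, r2t = 1 / 46) {
  stopifnot(length(b) == 1L, length(te) == 1L)
  comp1 <- p$f * exp(-b * p$d_star) * exp(-te / p$t2fb)
  comp2 <- (1 - p$f) * p$v * exp(-b * p$d) * exp(-te * r2mb)
  comp3 <- (1 - p$f) * (1 - p$v) * exp(-b * p$d) * exp(-te * r2t)
  p$s0 * (comp1 + comp2 + comp3)
}

# Dense multivariate-normal log-density oracle (explicit inverse and
# determinant, no Cholesky).
mvn_logpdf_oracle <- function(x, mu, sigma) {
  k <- length(mu)
  d <- x - mu
  -0.5 * (k * log(2 * pi) + log(det(sigma)) +
            as.numeric(t(d) %*% solve(sigma) %*% d))
}

# Quadrature oracle for the amplitude/noise-marginalized log-likelihood:
# integrates the Gaussian likelihood over S0 and the noise SD with the
# priors implied by the -(N/2) log(.) closed form: p(sigma) ~ sigma^-2 and
# a flat prior on the amplitude in g-normalized units, i.e.
# p(S0) ~ sqrt(g'g) (the raw flat-S0 integral carries a (g'g)^(-1/2)
# Jacobian that the closed form does not).  Returns the log integral up to
# one g-independent additive constant.
marginal_loglik_oracle <- function(S, g) {
  0.5 * log(sum(g^2)) + marginal_loglik_quadrature(S, g)
}

marginal_loglik_quadrature <- function(S, g) {
  n <- length(S)
  f_of <- function(s0, sig)
    -n * log(sig) - sum((S - s0 * g)^2) / (2 * sig^2) - 2 * log(sig)
  s0_hat <- sum(S * g) / sum(g * g)
  sig_hat <- sqrt(max(sum((S - s0_hat * g)^2), 1e-12) / n)
  s0_grid <- seq(s0_hat - 8 * sig_hat / sqrt(sum(g^2)) * 3,
                 s0_hat + 8 * sig_hat / sqrt(sum(g^2)) * 3,
                 length.out = 401)
  sig_grid <- exp(seq(log(sig_hat) - 3, log(sig_hat) + 3, length.out = 401))
  lv <- outer(s0_grid, sig_grid, Vectorize(function(a, b) f_of(a, b)))
  # integrate in (s0, sigma); trapezoid weights via cell sizes
  m <- max(lv)
  ds0 <- diff(s0_grid)[1]
  dsig <- diff(sig_grid)          # irregular in sigma
  w <- c(dsig, dsig[length(dsig)])
  val <- sum(exp(lv - m) * rep(w, each = length(s0_grid))) * ds0
  m + log(val)
}

# Closed-form simple-regression oracle via normal equations.
regression_oracle <- function(y, x) {
  n <- length(y)
  sx <- sum(x); sy <- sum(y)
  sxx <- sum(x^2); sxy <- sum(x * y); syy <- sum(y^2)
  b <- (n * sxy - sx * sy) / (n * sxx - sx^2)
  a <- (sy - b * sx) / n
  r <- (n * sxy - sx * sy) /
    sqrt((n * sxx - sx^2) * (n * syy - sy^2))
  tstat <- r * sqrt((n - 2) / (1 - r^2))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  list(slope = b, intercept = a, r = r, p_value = p)
}

# Small phantom with the linearization's fixed d* and T2fb held constant,
# so the linear model is exactly correct for it.
linear_consistent_phantom <- function(shape = c(10, 10, 5), seed = 3,
                                      smoothness = 2) {
  cst <- decide_constants()
  spec <- phantom_spec(
    shape = shape, seed = seed, smoothness = smoothness,
    ranges = list(s0 = c(90, 110), f = c(0.1, 0.4),
                  d = c(0.0012, 0.0018),
                  d_star = c(cst$d_star_fixed, cst$d_star_fixed),
                  t2fb = c(cst$t2fb_fixed, cst$t2fb_fixed),
                  v = c(0.25, 0.36)))
  make_phantom(spec)
}

default_protocol28 <- function() build_protocol("decide_default", dedup = TRUE)
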