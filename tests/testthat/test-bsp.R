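test_that("marginal log-likelihood handles the projection limit cases", {
  prot <- default_protocol28()
  p <- table1_params()
  theta <- bsp_theta_from_params(p)
  g <- decide_signal(p, prot)              # S0 = 1 model signal
  n <- nrow(prot)

  # S proportional to g: Cauchy-Schwarz equality, guarded large value
  ll_par <- bsp_log_likelihood(42 * g, theta, prot)
  expect_true(is.finite(ll_par))
  ll_typ <- bsp_log_likelihood(42 * g + rnorm(n, sd = 1), theta, prot)
  expect_gt(ll_par, ll_typ)

  # S orthogonal to g: projection vanishes, closed form -(N/2) log(S'S)
  withr::with_seed(3, e <- rnorm(n))
  s_orth <- e - sum(e * g) / sum(g * g) * g
  expect_equal(bsp_log_likelihood(s_orth, theta, prot),
               -(n / 2) * log(sum(s_orth^2)), tolerance = 1e-10)
})

test_that("marginal log-likelihood differences match the quadrature oracle", {
  prot <- default_protocol28()
  p1 <- table1_params()
  p2 <- list(s0 = 1, f = 0.35, d = 0.0019, d_star = 0.06, t2fb = 140,
             v = 0.25)
  p3 <- list(s0 = 1, f = 0.12, d = 0.0011, d_star = 0.02, t2fb = 250,
             v = 0.45)
  withr::with_seed(41, {
    S <- 100 * decide_signal(p1, prot) + rnorm(nrow(prot), sd = 4)
  })
  lls <- vapply(list(p1, p2, p3), function(p)
    bsp_log_likelihood(S, bsp_theta_from_params(p), prot), numeric(1))
  oracle <- vapply(list(p1, p2, p3), function(p)
    marginal_loglik_oracle(S, decide_signal(p, prot)), numeric(1))
  # both are defined up to one additive constant: compare differences
  expect_equal(lls - lls[1], oracle - oracle[1], tolerance = 1e-2)
})

test_that("log-prior matches the dense multivariate-normal oracle", {
  withr::with_seed(12, {
    A <- matrix(rnorm(25), 5)
    sigma <- crossprod(A) + diag(0.5, 5)
    mu <- rnorm(5)
    expect_equal(bsp_log_prior(mu, mu, sigma),
                 -0.5 * log((2 * pi)^5 * det(sigma)), tolerance = 1e-10)
    for (i in 1:10) {
      th <- mu + rnorm(5)
      expect_equal(bsp_log_prior(th, mu, sigma),
                   mvn_logpdf_oracle(th, mu, sigma), tolerance = 1e-10)
    }
    # one isotropic SD away drops the density by exp(-1/2)
    iso <- diag(0.7, 5)
    th1 <- mu; th1[3] <- mu[3] + sqrt(0.7)
    expect_equal(bsp_log_prior(th1, mu, iso) - bsp_log_prior(mu, mu, iso),
                 -0.5, tolerance = 1e-12)
    expect_error(bsp_log_prior(mu, mu, matrix(0, 5, 5)), "singular")
  })
})

test_that("Gibbs mean update draws from N(theta_bar, sigma / M)", {
  withr::with_seed(22, {
    M <- 40L
    thetas <- matrix(rnorm(M * 5, sd = 2), M, 5)
    tbar <- colMeans(thetas)
    # degenerate limit: vanishing sigma returns the mean
    mu0 <- bsp_gibbs_mu(thetas, diag(1e-20, 5))
    expect_equal(mu0, tbar, tolerance = 1e-8)
    # determinism under a fixed seed
    s <- diag(c(1, 2, 3, 4, 5))
    set.seed(99); a <- bsp_gibbs_mu(thetas, s)
    set.seed(99); b <- bsp_gibbs_mu(thetas, s)
    expect_identical(a, b)
    # Monte-Carlo mean within 3 standard errors
    draws <- t(replicate(10000, bsp_gibbs_mu(thetas, s)))
    se <- sqrt(diag(s) / M / 10000)
    expect_true(all(abs(colMeans(draws) - tbar) < 3.5 * se))
    expect_error(bsp_gibbs_mu(thetas[1, , drop = FALSE], s), "at least 2")
  })
})

test_that("Gibbs covariance update has the inverse-Wishart mean", {
  withr::with_seed(23, {
    M <- 100L
    thetas <- matrix(rnorm(M * 5), M, 5)
    mu <- colMeans(thetas)
    scale <- crossprod(sweep(thetas, 2, mu))
    draws <- replicate(2000, bsp_gibbs_sigma(thetas, mu))
    mean_draw <- apply(draws, c(1, 2), mean)
    expected <- scale / (M - 5 - 1)
    expect_lt(norm(mean_draw - expected, "F") / norm(expected, "F"), 0.05)
    # every draw is symmetric positive-definite
    for (k in seq(1, 2000, by = 97)) {
      s <- draws[, , k]
      expect_equal(s, t(s), tolerance = 1e-12)
      expect_true(all(eigen(s, only.values = TRUE)$values > 0))
    }
    # all-equal thetas trigger the ridge path
    same <- matrix(rep(mu, each = 10), 10, 5)
    expect_true(attr(bsp_gibbs_sigma(same, mu), "ridged"))
    expect_error(bsp_gibbs_sigma(thetas[1:5, ], mu), "at least")
  })
})

test_that("single-voxel MH update accepts null proposals and is seeded", {
  prot <- default_protocol28()
  p <- table1_params()
  theta <- bsp_theta_from_params(p)
  sig <- 100 * decide_signal(p, prot)
  mu <- theta; sigma <- diag(0.5, 5)
  set.seed(5)
  upd <- bsp_mh_update(theta, sig, mu, sigma, step = 1e-15, prot)
  expect_true(upd$accepted)
  expect_equal(upd$theta, theta, tolerance = 1e-10)
  set.seed(6); a <- bsp_mh_update(theta, sig, mu, sigma, 0.2, prot)
  set.seed(6); b <- bsp_mh_update(theta, sig, mu, sigma, 0.2, prot)
  expect_identical(a, b)
})

test_that("with the likelihood disabled the chain samples the prior", {
  # independent chains per voxel with frozen hyperparameters: the last kept
  # draw across voxels is an i.i.d. sample from N(mu, sigma)
  spec <- phantom_spec(shape = c(8, 8, 3), smoothness = 2, seed = 31)
  ph <- make_phantom(spec)
  prot <- default_protocol28()
  series <- simulate_series(ph$maps, ph$mask, prot, snr = 50, seed = 32,
                            spacing = spec$spacing)
  cfg <- mcmc_config(n_burn = 800L, n_keep = 200L, seed = 33)
  fit <- bsp_fit_roi(series, ph$mask, prot, config = cfg,
                     use_likelihood = FALSE)
  mu0 <- fit$mu_trace[1, ]          # frozen at the initialization moments
  expect_true(all(apply(fit$mu_trace, 2, function(x) length(unique(x))) == 1))
  last <- fit$theta_samples[dim(fit$theta_samples)[1], , ]
  # standardize with the frozen covariance from the trace
  sigma0 <- fit$sigma_trace[1, , ]
  z <- sweep(last, 2, mu0) %*% solve(chol(sigma0))
  pvals <- apply(z, 2, function(x) stats::ks.test(x, "pnorm")$p.value)
  expect_true(all(pvals > 0.01))
})

test_that("shrinkage: BSP tightens noisy maps without losing accuracy", {
  # The shrinkage inequality is asserted on the sampling (transformed)
  # scale, where the Gaussian hierarchy lives.  The LSQ arm is clipped to
  # the fit bounds before transforming (which REDUCES its spread, making
  # the check conservative); the BSP arm is not clipped.  Natural-unit SDs
  # are additionally compared at SNR 20: at lower SNR the LSQ T2fb spread
  # is truncated by its 500 ms box constraint while the Bayesian
  # log-parameterization is unbounded above, so that comparison measures
  # the truncation, not the estimator.
  spec <- phantom_spec(shape = c(12, 12, 6), snr = 20, seed = 7)
  ph <- make_phantom(spec)
  prot <- default_protocol28()
  m <- ph$mask != 0
  clip_tf <- list(
    f = function(x) stats::qlogis(pmin(pmax(x, 1e-3), 1 - 1e-3)),
    d = function(x) log(pmax(x, 1e-6)),
    d_star = function(x) log(pmax(x, 1e-6)),
    t2fb = function(x) -log(pmin(pmax(x, 1), 499)),
    v = function(x) stats::qlogis(pmin(pmax(x, 1e-3), 1 - 1e-3)))
  free_tf <- list(f = stats::qlogis, d = log, d_star = log,
                  t2fb = function(x) -log(x), v = stats::qlogis)
  for (snr in c(10, 20, 40)) {
    noisy <- simulate_series(ph$maps, ph$mask, prot, snr = snr, seed = 7,
                             spacing = spec$spacing)
    withr::with_seed(70 + snr,
      lsq <- nls_fit_volume(noisy, ph$mask, prot, n_starts = 1L))
    cfg <- mcmc_config(n_burn = 3000L, n_keep = 1500L, seed = 70 + snr)
    fit <- bsp_fit_roi(noisy, ph$mask, prot, config = cfg, lsq_maps = lsq)
    for (nm in c("f", "d", "d_star", "t2fb", "v")) {
      expect_lte(stats::sd(free_tf[[nm]](fit$maps[[nm]]$median[m])),
                 stats::sd(clip_tf[[nm]](lsq[[nm]][m])),
                 label = sprintf("transformed-scale SD of BSP %s at SNR %d",
                                 nm, snr))
      if (snr == 20)
        expect_lte(stats::sd(fit$maps[[nm]]$mean[m]), stats::sd(lsq[[nm]][m]),
                   label = sprintf("natural-unit SD of BSP %s at SNR 20", nm))
    }
    if (snr == 20) {
      # the noise-prone parameters also improve in voxelwise RMSE
      for (nm in c("d_star", "t2fb", "v")) {
        rmse_lsq <- sqrt(mean((lsq[[nm]][m] - ph$maps[[nm]][m])^2))
        rmse_bsp <- sqrt(mean((fit$maps[[nm]]$mean[m] - ph$maps[[nm]][m])^2))
        expect_lte(rmse_bsp, rmse_lsq,
                   label = sprintf("BSP RMSE of %s at SNR 20", nm))
      }
    }
  }
})

test_that("BSP summaries are bit-reproducible under a fixed seed", {
  spec <- phantom_spec(shape = c(6, 6, 3), smoothness = 2, seed = 51)
  ph <- make_phantom(spec)
  prot <- default_protocol28()
  noisy <- simulate_series(ph$maps, ph$mask, prot, snr = 30, seed = 52,
                           spacing = spec$spacing)
  cfg <- mcmc_config(n_burn = 150L, n_keep = 100L, seed = 53)
  withr::with_seed(1, lsq <- nls_fit_volume(noisy, ph$mask, prot, n_starts = 1L))
  a <- bsp_fit_roi(noisy, ph$mask, prot, config = cfg, lsq_maps = lsq)
  b <- bsp_fit_roi(noisy, ph$mask, prot, config = cfg, lsq_maps = lsq)
  expect_identical(a$maps, b$maps)
  expect_identical(a$mu_trace, b$mu_trace)
})
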