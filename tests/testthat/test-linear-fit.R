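test_that("design matrix rows match a scalar recomputation", {
  prot <- default_protocol28()
  cst <- decide_constants()
  des <- build_design_matrix(prot, d = 0.0015, cst)
  expect_equal(dim(des$a), c(28L, 3L))
  expect_true(all(des$a > 0 & des$a <= 1))
  # every row with b > 0 or te > 0 is strictly below 1 (positive rates)
  expect_true(all(des$a < 1))
  for (i in c(1L, 10L, 28L)) {
    row <- c(exp(-prot$b[i] * cst$d_star_fixed - prot$te[i] / cst$t2fb_fixed),
             exp(-prot$b[i] * 0.0015 - prot$te[i] / 240),
             exp(-prot$b[i] * 0.0015 - prot$te[i] / 46))
    expect_equal(des$a[i, ], row, tolerance = 1e-14)
  }
})

test_that("voxel LLS recovers amplitudes exactly on noiseless data", {
  prot <- default_protocol28()
  des <- build_design_matrix(prot, d = 0.0015)
  lam_true <- c(1/3, 1/3, 1/3)
  fit <- lls_fit_voxel(as.numeric(des$a %*% lam_true), des)
  expect_equal(fit$lambda, lam_true, tolerance = 1e-8)
  expect_equal(fit$flag, "ok")

  z <- lls_fit_voxel(rep(0, 28), des)
  expect_equal(z$lambda, c(0, 0, 0))
  expect_equal(z$residual, 0)
})

test_that("LLS + inversion reproduces the cohort-mean f and v", {
  p <- table1_params()
  # fix the linearization constants at the generating values
  cst <- decide_constants(d_star_fixed = p$d_star, t2fb_fixed = p$t2fb)
  prot <- default_protocol28()
  sig <- decide_signal(p, prot, cst)
  des <- build_design_matrix(prot, d = p$d, cst)
  fit <- lls_fit_voxel(sig, des)
  ph <- physio_from_lambda(fit$lambda)
  expect_equal(ph$f, 0.225, tolerance = 1e-6)
  expect_equal(ph$v, 0.306, tolerance = 1e-6)
  expect_equal(ph$s0, 1, tolerance = 1e-6)
})

test_that("nonnegative solution satisfies the KKT conditions", {
  prot <- default_protocol28()
  withr::with_seed(21, {
    for (rep in 1:20) {
      des <- build_design_matrix(prot, d = runif(1, 5e-4, 4e-3))
      # signals that drive unconstrained solutions negative
      y <- as.numeric(des$a %*% runif(3, -0.5, 1)) + rnorm(28, sd = 0.05)
      fit <- lls_fit_voxel(y, des)
      lam <- fit$lambda
      expect_true(all(lam >= 0))
      g <- as.numeric(crossprod(des$a, des$a %*% lam - y))
      active <- lam <= 1e-12
      expect_true(all(g[active] >= -1e-6))          # ascent blocked at 0
      expect_true(all(abs(g[!active]) < 1e-6))      # stationarity inside
    }
  })
})

test_that("volume fit selects the residual-minimizing diffusivity", {
  ph <- linear_consistent_phantom()
  prot <- default_protocol28()
  d_grid <- exp(seq(log(5e-4), log(4e-3), length.out = 15L))
  # put the true d on the grid so recovery can be exact
  dm <- ph$maps$d
  dm[ph$mask] <- d_grid[7]
  ph$maps$d <- dm
  series <- simulate_series(ph$maps, ph$mask, prot, snr = Inf,
                            spacing = ph$spec$spacing)
  maps <- lls_fit_volume(series, ph$mask, prot, d_grid = d_grid)
  m <- ph$mask != 0
  expect_gte(mean(maps$d[m] == d_grid[7]), 0.99)
  expect_lt(max(abs(maps$f[m] - ph$maps$f[m])), 1e-6)
  expect_lt(max(abs(maps$v[m] - ph$maps$v[m])), 1e-6)
  expect_lt(max(abs(maps$s0[m] - ph$maps$s0[m]) / ph$maps$s0[m]), 1e-6)
  expect_true(all(maps$s0[!m] == 0))

  # argmin property on one voxel: chosen d beats every other grid point
  vox <- which(m)[1]
  sig <- series$data[arrayInd(vox, dim(ph$mask))[1],
                     arrayInd(vox, dim(ph$mask))[2],
                     arrayInd(vox, dim(ph$mask))[3], ]
  res_at <- vapply(d_grid, function(d)
    lls_fit_voxel(sig, build_design_matrix(prot, d))$residual, numeric(1))
  expect_equal(maps$residual[vox], min(res_at), tolerance = 1e-9)
})

test_that("synthesized targets are exactly model-consistent", {
  ph <- linear_consistent_phantom(seed = 9)
  prot <- default_protocol28()
  d_grid <- exp(seq(log(5e-4), log(4e-3), length.out = 15L))
  ph$maps$d[ph$mask] <- d_grid[8]   # keep the truth on the search grid
  series <- simulate_series(ph$maps, ph$mask, prot, snr = Inf,
                            spacing = ph$spec$spacing)
  maps <- lls_fit_volume(series, ph$mask, prot)
  targets <- synthesize_targets(maps, ph$mask, prot,
                                spacing = ph$spec$spacing)
  m <- rep(ph$mask != 0, nrow(prot))
  expect_lt(max(abs(targets$data[m] - series$data[m])), 1e-6 * max(series$data))
  # re-fitting the synthesis gives zero residual (noise-free targets)
  refit <- lls_fit_volume(targets, ph$mask, prot)
  expect_lt(max(refit$residual), 1e-8 * max(series$data))
  # scalar oracle spot check on one voxel and volume
  vox_ind <- which(ph$mask != 0)[5]
  ijk <- arrayInd(vox_ind, dim(ph$mask))
  p_vox <- list(s0 = maps$s0[vox_ind], f = maps$f[vox_ind],
                d = maps$d[vox_ind],
                d_star = decide_constants()$d_star_fixed,
                t2fb = decide_constants()$t2fb_fixed, v = maps$v[vox_ind])
  expect_equal(targets$data[ijk[1], ijk[2], ijk[3], 17],
               scalar_signal_oracle(p_vox, prot$b[17], prot$te[17]),
               tolerance = 1e-10)
})
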