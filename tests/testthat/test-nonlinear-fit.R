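test_that("noiseless cohort-mean signal is recovered to 0.1%", {
  p <- table1_params()
  prot <- default_protocol28()
  sig <- decide_signal(p, prot)
  init <- list(f = 0.2, d = 0.0015, d_star = 0.073, t2fb = 144.89,
               v = 0.3, s0 = 1.2)
  withr::with_seed(1, {
    fit <- nls_fit_voxel(sig, prot, init = init, n_starts = 5L)
  })
  expect_true(fit$converged)
  for (nm in c("f", "d", "t2fb", "v", "s0"))
    expect_equal(fit$params[[nm]], p[[nm]], tolerance = 1e-3)
  expect_equal(fit$params$d_star, p$d_star, tolerance = 5e-3)
  expect_lt(fit$residual, 1e-8)
})

test_that("random interior truths are recovered from noiseless data", {
  prot <- default_protocol28()
  n_cases <- 60L
  ok <- logical(n_cases)
  withr::with_seed(77, {
    for (i in seq_len(n_cases)) {
      truth <- list(f = runif(1, 0.05, 0.6), d = runif(1, 8e-4, 3e-3),
                    d_star = runif(1, 0.02, 0.15), t2fb = runif(1, 80, 350),
                    v = runif(1, 0.1, 0.6), s0 = runif(1, 50, 150))
      sig <- decide_signal(truth, prot)
      init <- list(f = 0.2, d = 0.0015, d_star = 0.073, t2fb = 144.89,
                   v = 0.3, s0 = max(sig) * 1.5)
      fit <- nls_fit_voxel(sig, prot, init = init, n_starts = 5L)
      rel <- vapply(c("f", "d", "d_star", "t2fb", "v"), function(nm)
        abs(fit$params[[nm]] / truth[[nm]] - 1), numeric(1))
      ok[i] <- all(rel < 5e-3)
    }
  })
  expect_gte(mean(ok), 0.95)
})

test_that("reported residual never exceeds the initializer's residual", {
  prot <- default_protocol28()
  withr::with_seed(31, {
    for (rep in 1:8) {
      truth <- list(f = runif(1, 0.1, 0.5), d = runif(1, 1e-3, 2e-3),
                    d_star = runif(1, 0.02, 0.1), t2fb = runif(1, 100, 300),
                    v = runif(1, 0.2, 0.5), s0 = 100)
      sig <- decide_signal(truth, prot) + rnorm(28, sd = 2)
      init <- list(f = 0.2, d = 0.0015, d_star = 0.073, t2fb = 144.89,
                   v = 0.3, s0 = 120)
      res_init <- sqrt(sum((sig - decide_signal(init, prot))^2))
      fit <- nls_fit_voxel(sig, prot, init = init, n_starts = 1L)
      expect_lte(fit$residual, res_init + 1e-12)
    }
  })
})

test_that("degenerate and invalid signals are handled by contract", {
  prot <- default_protocol28()
  init <- list(f = 0.2, d = 0.0015, d_star = 0.073, t2fb = 144.89,
               v = 0.3, s0 = 100)
  # constant signal: no decay information; must return finite flagged output
  withr::with_seed(8, {
    fit <- nls_fit_voxel(rep(100, 28), prot, init = init, n_starts = 1L)
  })
  expect_true(is.finite(fit$residual))
  expect_true(all(vapply(fit$params, is.finite, logical(1))))
  bad <- nls_fit_voxel(c(rep(1, 27), NA), prot, init = init)
  expect_equal(bad$flag, "nonfinite_signal")
  expect_false(bad$converged)
})

test_that("median f recovery at SNR 50 is within 10% of truth", {
  prot <- default_protocol28()
  truth <- table1_params()
  clean <- decide_signal(truth, prot)
  sigma <- truth$s0 / 50
  init <- list(f = 0.2, d = 0.0015, d_star = 0.073, t2fb = 144.89,
               v = 0.3, s0 = 1.2)
  f_hat <- numeric(100)
  withr::with_seed(19, {
    for (i in 1:100) {
      fit <- nls_fit_voxel(clean + rnorm(28, sd = sigma), prot,
                           init = init, n_starts = 1L)
      f_hat[i] <- fit$params$f
    }
  })
  expect_lt(abs(stats::median(f_hat) / truth$f - 1), 0.10)
})

test_that("ROI-mean fit recovers a homogeneous phantom and matches 1-voxel fits", {
  cst <- decide_constants()
  spec <- phantom_spec(shape = c(8, 8, 4), smoothness = Inf, seed = 2)
  ph <- make_phantom(spec)
  prot <- default_protocol28()
  series <- simulate_series(ph$maps, ph$mask, prot, snr = Inf,
                            spacing = spec$spacing)
  withr::with_seed(4, {
    roi <- nls_fit_roi_mean(series, ph$mask, prot)
  })
  mids <- lapply(spec$ranges, mean)
  for (nm in c("f", "d", "d_star", "t2fb", "v", "s0"))
    expect_equal(roi$params[[nm]], mids[[nm]], tolerance = 1e-4)

  # single-voxel mask: ROI-mean curve IS that voxel's curve
  one <- array(FALSE, dim(ph$mask))
  one[which(ph$mask)[1]] <- TRUE
  withr::with_seed(4, {
    roi1 <- nls_fit_roi_mean(series, one, prot)
  })
  vox <- which(one)
  ijk <- arrayInd(vox, dim(one))
  sig <- series$data[ijk[1], ijk[2], ijk[3], ]
  init <- list(f = 0.2, d = 0.0015, d_star = cst$d_star_fixed,
               t2fb = cst$t2fb_fixed, v = 0.3, s0 = max(sig) * 1.5)
  withr::with_seed(4, {
    direct <- nls_fit_voxel(sig, prot, init = init, n_starts = 5L)
  })
  expect_equal(unlist(roi1$params), unlist(direct$params), tolerance = 1e-6)
})

test_that("pre-smoothing obeys its contracts and reduces noisy-map error", {
  spec <- phantom_spec(shape = c(10, 10, 5), smoothness = 2, seed = 13)
  ph <- make_phantom(spec)
  prot <- default_protocol28()
  noisy <- simulate_series(ph$maps, ph$mask, prot, snr = 50, seed = 14,
                           spacing = spec$spacing)
  withr::with_seed(6, m0 <- nls_fit_volume(noisy, ph$mask, prot, n_starts = 1L))
  withr::with_seed(6, m0b <- nls_fit_volume(noisy, ph$mask, prot,
                                            smooth_sigma = 0, n_starts = 1L))
  expect_identical(m0$d, m0b$d)   # sigma = 0 is bitwise the unsmoothed path

  withr::with_seed(6, m1 <- nls_fit_volume(noisy, ph$mask, prot,
                                           smooth_sigma = 1, n_starts = 1L))
  m <- ph$mask != 0
  rmse <- function(est) sqrt(mean((est[m] - ph$maps$d[m])^2))
  expect_lt(rmse(m1$d), rmse(m0$d))

  # smoothing a spatially constant series changes nothing inside the volume
  flat <- decide_series(array(7, c(6, 6, 3, 2)), c(1, 1, 1))
  sm <- flat
  for (i in 1:2) sm$data[, , , i] <- decidemri:::gaussian_smooth3(flat$data[, , , i], 1)
  expect_equal(sm$data, flat$data, tolerance = 1e-12)
})
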