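# Hierarchical Bayesian shrinkage-prior estimation.  Each ROI voxel's
# transformed parameter vector theta_i = (F, D, D*, log r2fb, V) is drawn
# from a shared multivariate Gaussian N(mu, Sigma); inference is
# Metropolis-within-Gibbs: componentwise random-walk MH on each theta_i,
# conjugate draws for mu (flat hyperprior) and Sigma (Jeffreys-type
# hyperprior giving an Inverse-Wishart conditional with df = M).

#' Transform model parameters to the sampling coordinates
#'
#' F = logit(f), D = log(d), D* = log(d*), log(r2fb) = -log(T2fb),
#' V = logit(v).  The inverse maps land in valid parameter ranges by
#' construction.
#'
#' @param p list with f, d, d_star, t2fb, v.
#' @return Numeric 5-vector (F, D, Dstar, logR2fb, V).
#' @export
bsp_theta_from_params <- function(p) {
  c(stats::qlogis(p$f), log(p$d), log(p$d_star), -log(p$t2fb),
    stats::qlogis(p$v))
}

#' @rdname bsp_theta_from_params
#' @param theta numeric 5-vector in transformed space.
#' @export
bsp_params_from_theta <- function(theta) {
  list(f = stats::plogis(theta[1]), d = exp(theta[2]),
       d_star = exp(theta[3]), t2fb = exp(-theta[4]),
       v = stats::plogis(theta[5]))
}

# Vectorized natural-parameter matrices from an M x 5 transformed matrix.
bsp_natural <- function(Theta) {
  list(f = stats::plogis(Theta[, 1]), d = exp(Theta[, 2]),
       d_star = exp(Theta[, 3]), t2fb = exp(-Theta[, 4]),
       v = stats::plogis(Theta[, 5]))
}

# Normalized model signal (S0 = 1) for all voxels: M x N matrix.
bsp_model_g <- function(Theta, b, te, constants) {
  nat <- bsp_natural(Theta)
  r2fb <- 1 / nat$t2fb
  e1 <- exp(-outer(nat$d_star, b) - outer(r2fb, te))
  ebd <- exp(-outer(nat$d, b))
  e2 <- ebd * exp(-outer(rep(constants$r2mb, nrow(Theta)), te))
  e3 <- ebd * exp(-outer(rep(constants$r2t, nrow(Theta)), te))
  nat$f * e1 + (1 - nat$f) * (nat$v * e2 + (1 - nat$v) * e3)
}

# Vectorized marginal log-likelihood for M voxels (rows of S and Theta).
bsp_loglik_mat <- function(Theta, S, StS, b, te, constants) {
  g <- bsp_model_g(Theta, b, te, constants)
  Stg <- rowSums(S * g)
  gtg <- rowSums(g * g)
  R <- StS - Stg^2 / gtg
  n <- length(b)
  guard <- R <= StS * 1e-15
  R[guard] <- StS[guard] * 1e-15  # S parallel to g: perfect-fit guard
  -(n / 2) * log(R)
}

#' Marginal log-likelihood of a voxel signal
#'
#' The Gaussian likelihood with the signal amplitude S0 (improper flat prior)
#' and the noise scale analytically marginalized:
#' \deqn{\log p(S\mid\theta) = -\tfrac{N}{2}\log\left(S^TS -
#'   (S^Tg)^2/(g^Tg)\right) + const,}
#' where g is the model signal with S0 = 1.  When S is exactly proportional
#' to g the residual term vanishes and a large finite guard value is
#' returned.
#'
#' @param signal numeric signal vector.
#' @param theta transformed 5-vector (see [bsp_theta_from_params()]).
#' @param protocol a [decide_protocol].
#' @param constants a [decide_constants].
#' @return Scalar log-likelihood (up to an additive constant).
#' @export
bsp_log_likelihood <- function(signal, theta, protocol,
                               constants = decide_constants()) {
  stopifnot(sum(signal^2) > 0)
  as.numeric(bsp_loglik_mat(matrix(theta, nrow = 1),
                            matrix(signal, nrow = 1), sum(signal^2),
                            protocol$b, protocol$te, constants))
}

#' Multivariate Gaussian log-prior
#'
#' Log-density of a transformed parameter vector under the ROI-level prior
#' N(mu, sigma).
#'
#' @param theta numeric 5-vector (or M x 5 matrix for many voxels).
#' @param mu numeric 5-vector.
#' @param sigma 5 x 5 symmetric positive-definite covariance.
#' @return Scalar (or length-M vector) log-density.
#' @export
bsp_log_prior <- function(theta, mu, sigma) {
  ch <- tryCatch(chol(sigma), error = function(e) stop("sigma is singular"))
  Theta <- if (is.matrix(theta)) theta else matrix(theta, nrow = 1)
  delta <- sweep(Theta, 2, mu)
  z <- backsolve(ch, t(delta), transpose = TRUE)   # solves t(ch) %*% z = delta
  maha <- colSums(z^2)
  val <- -0.5 * (ncol(Theta) * log(2 * pi) + 2 * sum(log(diag(ch))) + maha)
  if (is.matrix(theta)) val else as.numeric(val)
}

#' Gibbs draw of the ROI mean
#'
#' Under a flat hyperprior, mu | theta, Sigma ~ N(theta_bar, Sigma / M).
#'
#' @param thetas M x 5 matrix of transformed voxel parameters, M >= 2.
#' @param sigma current 5 x 5 covariance.
#' @return A 5-vector draw.
#' @export
bsp_gibbs_mu <- function(thetas, sigma) {
  M <- nrow(thetas)
  if (M < 2L) stop("need at least 2 voxels to update the ROI mean")
  theta_bar <- colMeans(thetas)
  ch <- chol(sigma / M)
  as.numeric(theta_bar + t(ch) %*% stats::rnorm(ncol(thetas)))
}

#' Gibbs draw of the ROI covariance
#'
#' Under a Jeffreys-type hyperprior the conditional is Inverse-Wishart with
#' df = M and scale sum_i (theta_i - mu)(theta_i - mu)^T.  Sampled as the
#' inverse of a Wishart draw.  A singular scale matrix triggers a small
#' ridge (flagged via attribute `ridged`).
#'
#' @param thetas M x 5 matrix, M >= 7 (proper Inverse-Wishart in 5 dims).
#' @param mu 5-vector.
#' @return A 5 x 5 symmetric positive-definite draw.
#' @export
bsp_gibbs_sigma <- function(thetas, mu) {
  M <- nrow(thetas)
  p <- ncol(thetas)
  if (M < p + 2L) stop("need at least ", p + 2L, " voxels for the covariance update")
  delta <- sweep(thetas, 2, mu)
  scale <- crossprod(delta)
  ridged <- FALSE
  if (!all(is.finite(scale)) || rcond(scale) < 1e-12) {
    scale <- scale + diag(1e-8, p)
    ridged <- TRUE
  }
  W <- stats::rWishart(1, df = M, Sigma = solve(scale))[, , 1]
  sig <- solve(W)
  sig <- (sig + t(sig)) / 2
  attr(sig, "ridged") <- ridged
  sig
}

#' Single Metropolis-Hastings update of one voxel
#'
#' Gaussian random-walk proposal in transformed space, accepted with
#' probability min(1, exp(delta log-posterior)).  Set
#' `use_likelihood = FALSE` to sample from the prior alone (used by the
#' prior-recovery diagnostics).
#'
#' @param theta current transformed 5-vector.
#' @param signal voxel signal vector.
#' @param mu,sigma prior hyperparameters.
#' @param step proposal SD (scalar or length 5).
#' @param protocol a [decide_protocol].
#' @param constants a [decide_constants].
#' @param use_likelihood logical.
#' @return List with `theta` and `accepted`.
#' @export
bsp_mh_update <- function(theta, signal, mu, sigma, step, protocol,
                          constants = decide_constants(),
                          use_likelihood = TRUE) {
  stopifnot(all(step > 0))
  prop <- theta + step * stats::rnorm(length(theta))
  lp_cur <- bsp_log_prior(theta, mu, sigma)
  lp_new <- bsp_log_prior(prop, mu, sigma)
  if (use_likelihood) {
    lp_cur <- lp_cur + bsp_log_likelihood(signal, theta, protocol, constants)
    lp_new <- lp_new + bsp_log_likelihood(signal, prop, protocol, constants)
  }
  if (log(stats::runif(1)) < lp_new - lp_cur)
    list(theta = prop, accepted = TRUE)
  else list(theta = theta, accepted = FALSE)
}

#' MCMC configuration
#'
#' @param n_burn burn-in iterations discarded.
#' @param n_keep retained (post burn-in) iterations.
#' @param thin keep every `thin`-th retained iteration.
#' @param proposal_scale initial per-parameter proposal SDs (length 5 or 1).
#' @param adapt_window iterations between step adaptations (burn-in only).
#' @param seed RNG seed.
#' @return List of class `mcmc_config`.
#' @export
mcmc_config <- function(n_burn = 4000L, n_keep = 3000L, thin = 1L,
                        proposal_scale = c(0.25, 0.1, 0.25, 0.1, 0.1),
                        adapt_window = 50L, seed = 1L) {
  stopifnot(n_burn >= 1L, n_keep >= 1L, thin >= 1L, adapt_window >= 1L,
            all(proposal_scale > 0))
  structure(list(n_burn = as.integer(n_burn), n_keep = as.integer(n_keep),
                 thin = as.integer(thin),
                 proposal_scale = rep(proposal_scale, length.out = 5L),
                 adapt_window = as.integer(adapt_window),
                 seed = as.integer(seed)),
            class = "mcmc_config")
}

split_rhat <- function(x) {
  n <- length(x) %/% 2L
  if (n < 4L) return(NA_real_)
  halves <- cbind(x[seq_len(n)], x[n + seq_len(n)])
  m <- 2L
  means <- colMeans(halves)
  vars <- apply(halves, 2, stats::var)
  B <- n * stats::var(means)
  W <- mean(vars)
  if (W <= 0) return(1)
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' Bayesian shrinkage-prior fit of an ROI
#'
#' Full Metropolis-within-Gibbs sweep over the voxels of an ROI.  Per
#' iteration: componentwise random-walk MH update of every voxel's
#' transformed parameters (vectorized across voxels), then conjugate draws
#' of the ROI mean and covariance.  Chains are initialized from voxelwise
#' constrained least-squares estimates (at-bound values nudged inside), with
#' mu and Sigma initialized at their sample moments.  Proposal scales are
#' adapted toward 30% acceptance during burn-in only.
#'
#' @param series a [decide_series].
#' @param mask 3D mask with at least 7 voxels.
#' @param protocol a [decide_protocol].
#' @param constants a [decide_constants].
#' @param config an [mcmc_config].
#' @param lsq_maps optional precomputed output of [nls_fit_volume()]; fitted
#'   internally when `NULL`.
#' @param use_likelihood logical; `FALSE` samples the prior hierarchy alone
#'   (diagnostic mode).
#' @return List with `maps` (per-parameter lists of 3D `mean`, `median`,
#'   `sd` maps in natural units), `acceptance` (per-voxel mean acceptance
#'   map), `mu_trace`, `sigma_trace`, `rhat` (split R-hat of mu components),
#'   `theta_samples` (kept draws, n x M x 5) and `config`.
#' @export
bsp_fit_roi <- function(series, mask, protocol,
                        constants = decide_constants(),
                        config = mcmc_config(), lsq_maps = NULL,
                        use_likelihood = TRUE) {
  check_series_protocol(series, protocol)
  check_mask(mask, series)
  vox <- which(mask != 0)
  M <- length(vox)
  if (M < 7L)
    stop("BSP requires an ROI of at least 7 voxels (proper covariance update)")
  set.seed(config$seed)
  if (is.null(lsq_maps))
    lsq_maps <- nls_fit_volume(series, mask, protocol, constants,
                               n_starts = 1L)
  d3 <- dim(series$data)[1:3]
  S <- matrix(series$data, nrow = prod(d3))[vox, , drop = FALSE]
  StS <- rowSums(S^2)
  b <- protocol$b; te <- protocol$te
  eps <- 1e-3
  Theta <- cbind(
    stats::qlogis(pmin(pmax(lsq_maps$f[vox], eps), 1 - eps)),
    log(pmax(lsq_maps$d[vox], 1e-6)),
    log(pmax(lsq_maps$d_star[vox], 1e-6)),
    -log(pmin(pmax(lsq_maps$t2fb[vox], 1), 499)),
    stats::qlogis(pmin(pmax(lsq_maps$v[vox], eps), 1 - eps)))
  mu <- colMeans(Theta)
  sigma <- stats::cov(Theta) + diag(1e-6, 5)
  # per-voxel, per-parameter proposal scales: the marginal likelihood's
  # sharpness varies strongly across voxels, so a single global scale cannot
  # hold a usable acceptance rate for all of them
  step <- matrix(config$proposal_scale, M, 5, byrow = TRUE)
  ll <- if (use_likelihood) bsp_loglik_mat(Theta, S, StS, b, te, constants)
        else rep(0, M)
  n_iter <- config$n_burn + config$n_keep
  keep_idx <- seq(config$n_burn + 1L, n_iter, by = config$thin)
  n_kept <- length(keep_idx)
  # likelihood tempering schedule (burn-in only): voxelwise LSQ starting
  # points can sit in deep degenerate modes (e.g. f near 1 with tiny T2fb)
  # that a random walk cannot leave; ramping the likelihood weight from ~0
  # to 1 over the first half of burn-in lets the shrinkage prior pull such
  # voxels into the ROI distribution before full data weight applies.
  # After burn-in beta = 1 exactly, preserving detailed balance.
  anneal_len <- max(1L, config$n_burn %/% 4L)
  beta_of <- function(it) if (it >= anneal_len) 1 else (it / anneal_len)^2
  samples <- array(NA_real_, c(n_kept, M, 5))
  mu_trace <- matrix(NA_real_, n_kept, 5)
  sigma_trace <- array(NA_real_, c(n_kept, 5, 5))
  acc_count <- rep(0, M)
  acc_window <- matrix(0, M, 5)
  n_window <- 0L
  kept <- 0L
  for (it in seq_len(n_iter)) {
    beta <- if (use_likelihood) beta_of(it) else 0
    ch <- chol(sigma)
    z <- backsolve(ch, t(sweep(Theta, 2, mu)), transpose = TRUE)
    lprior <- -colSums(z^2) / 2
    for (j in 1:5) {
      prop <- Theta
      prop[, j] <- Theta[, j] + step[, j] * stats::rnorm(M)
      zp <- backsolve(ch, t(sweep(prop, 2, mu)), transpose = TRUE)
      lprior_p <- -colSums(zp^2) / 2
      ll_p <- if (use_likelihood)
        bsp_loglik_mat(prop, S, StS, b, te, constants) else rep(0, M)
      accept <- log(stats::runif(M)) < beta * (ll_p - ll) + (lprior_p - lprior)
      Theta[accept, j] <- prop[accept, j]
      ll[accept] <- ll_p[accept]
      lprior[accept] <- lprior_p[accept]
      acc_window[, j] <- acc_window[, j] + accept
      if (it > config$n_burn) acc_count <- acc_count + accept / 5
    }
    n_window <- n_window + 1L
    if (it <= config$n_burn && n_window >= config$adapt_window) {
      rate <- acc_window / n_window
      step <- step * exp(2 * (rate - 0.3))
      acc_window[] <- 0; n_window <- 0L
    }
    if (use_likelihood && beta >= 1) {
      # hyperparameters are frozen while the likelihood is tempered (and in
      # the no-likelihood diagnostic mode): with a down-weighted likelihood
      # the hyperparameter posterior is weakly anchored and the whole ROI
      # distribution would diffuse
      mu <- bsp_gibbs_mu(Theta, sigma)
      sigma <- bsp_gibbs_sigma(Theta, mu)
    }
    if (it > config$n_burn && (it - config$n_burn - 1L) %% config$thin == 0L) {
      kept <- kept + 1L
      samples[kept, , ] <- Theta
      mu_trace[kept, ] <- mu
      sigma_trace[kept, , ] <- sigma
      # prior changed under the kept draw of (mu, sigma); recompute lazily
    }
    ch <- NULL
  }
  rhat <- apply(mu_trace, 2, split_rhat)
  if (any(rhat > 1.1, na.rm = TRUE))
    warning("possible non-convergence: split R-hat of mu components = ",
            paste(signif(rhat, 3), collapse = ", "))
  par_names <- c("f", "d", "d_star", "t2fb", "v")
  nat_fun <- list(
    f = function(x) stats::plogis(x), d = exp, d_star = exp,
    t2fb = function(x) exp(-x), v = function(x) stats::plogis(x))
  zero <- array(0, d3)
  maps <- list()
  for (j in seq_along(par_names)) {
    nat <- nat_fun[[j]](samples[, , j, drop = FALSE])
    dim(nat) <- c(n_kept, M)
    mmean <- zero; mmed <- zero; msd <- zero
    mmean[vox] <- colMeans(nat)
    mmed[vox] <- apply(nat, 2, stats::median)
    msd[vox] <- apply(nat, 2, stats::sd)
    maps[[par_names[j]]] <- list(mean = mmean, median = mmed, sd = msd)
  }
  acc_map <- zero
  acc_map[vox] <- acc_count / config$n_keep
  list(maps = maps, acceptance = acc_map, mu_trace = mu_trace,
       sigma_trace = sigma_trace, rhat = rhat, theta_samples = samples,
       config = config)
}
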