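#' Spatial-temporal smoothing configuration
#'
#' Controls the stage-2 locally-weighted residual smoother.  Residuals nearby
#' in space and time get more weight: spatial neighbors are districts within
#' the same province (weight `zeta`), temporal proximity is weighted by a
#' tricube kernel with bandwidth `lambda` years.
#'
#' @param lambda temporal bandwidth in years (> 0); observations more than
#'   `lambda` years away get zero weight.
#' @param zeta same-province spatial weight in [0, 1]; other provinces get 0.
#' @param kernel temporal kernel shape; only "tricube" is implemented.
#' @return list of class `st_config`.
#' @export
st_config <- function(lambda = 10, zeta = 0.5, kernel = "tricube") {
  if (lambda <= 0) stop("`lambda` must be > 0", call. = FALSE)
  if (zeta < 0 || zeta > 1) stop("`zeta` must be in [0, 1]", call. = FALSE)
  kernel <- match.arg(kernel, "tricube")
  structure(list(lambda = lambda, zeta = zeta, kernel = kernel),
            class = "st_config")
}

#' Gaussian process regression configuration
#'
#' Matérn-kernel settings for the stage-3 (and covariate) Gaussian process.
#' `sigma = NULL` means the amplitude is estimated per indicator as the
#' standard deviation of the residuals left after stage-2 smoothing, with a
#' floor of `sigma_floor`.
#'
#' @param sigma Matérn amplitude in logit units (> 0), or NULL to estimate.
#' @param rho length-scale in years (> 0); default 3, matching the few-year
#'   persistence of district-level deviations from the smoothed mean.
#' @param nu smoothness; one of 1/2, 3/2, 5/2.
#' @param n_draws posterior draws (>= 2; default 1000).
#' @param jitter initial diagonal jitter; multiplied by 10 up to
#'   `max_jitter` when a Cholesky factorization fails.
#' @param max_jitter largest jitter tried before erroring.
#' @param sigma_floor lower bound for the estimated amplitude.
#' @return list of class `gpr_config`.
#' @export
gpr_config <- function(sigma = NULL, rho = 3, nu = 3/2, n_draws = 1000,
                       jitter = 1e-8, max_jitter = 1e-2, sigma_floor = 0.1) {
  if (!is.null(sigma) && sigma <= 0) stop("`sigma` must be > 0", call. = FALSE)
  if (rho <= 0) stop("`rho` must be > 0", call. = FALSE)
  if (!nu %in% c(1/2, 3/2, 5/2)) {
    stop("`nu` must be one of 1/2, 3/2, 5/2", call. = FALSE)
  }
  if (n_draws < 2) stop("`n_draws` must be >= 2", call. = FALSE)
  structure(list(sigma = sigma, rho = rho, nu = nu, n_draws = n_draws,
                 jitter = jitter, max_jitter = max_jitter,
                 sigma_floor = sigma_floor),
            class = "gpr_config")
}

#' Matérn covariance function
#'
#' Stationary kernel used by the Gaussian process stages.  For the default
#' smoothness nu = 3/2: `sigma^2 (1 + sqrt(3) d / rho) exp(-sqrt(3) d / rho)`.
#'
#' @param d non-negative distances (years).
#' @param config a [gpr_config()]; its `sigma` must be set.
#' @return covariance values, same shape as `d`.
#' @examples
#' matern_cov(0, gpr_config(sigma = 2))        # 4
#' matern_cov(1, gpr_config(sigma = 1, rho = 1, nu = 1/2))  # exp(-1)
#' @export
matern_cov <- function(d, config) {
  if (is.null(config$sigma)) stop("`config$sigma` must be set", call. = FALSE)
  if (any(d < 0)) stop("distances must be non-negative", call. = FALSE)
  s2 <- config$sigma^2
  r <- d / config$rho
  if (config$nu == 1/2) {
    s2 * exp(-r)
  } else if (config$nu == 3/2) {
    s2 * (1 + sqrt(3) * r) * exp(-sqrt(3) * r)
  } else if (config$nu == 5/2) {
    s2 * (1 + sqrt(5) * r + 5 * r^2 / 3) * exp(-sqrt(5) * r)
  } else {
    stop("unsupported nu; supported: 1/2, 3/2, 5/2", call. = FALSE)
  }
}

# Cholesky with escalating diagonal jitter: first attempt is exact (no
# jitter); on failure the jitter starts at config$jitter and multiplies by 10
# up to config$max_jitter before erroring with `label`.
chol_jitter <- function(S, config, label = "matrix") {
  R <- tryCatch(chol(S), error = function(e) NULL)
  if (!is.null(R)) return(R)
  j <- config$jitter
  repeat {
    R <- tryCatch(chol(S + diag(j, nrow(S))), error = function(e) NULL)
    if (!is.null(R)) return(R)
    j <- j * 10
    if (j > config$max_jitter) {
      stop(sprintf("Cholesky factorization failed for %s even with jitter %g",
                   label, config$max_jitter), call. = FALSE)
    }
  }
}

# One-dimensional GP regression over a year grid.
#   grid: years at which the posterior is wanted; prior_mean: same length.
#   obs_years/y/noise_var: observations (possibly several per year).
# Returns list(mean, cov).
gp_solve <- function(grid, prior_mean, obs_years, y, noise_var, config,
                     label = "district") {
  prior_mean <- unname(prior_mean)
  K <- matern_cov(abs(outer(grid, grid, "-")), config)
  if (length(obs_years) == 0) {
    return(list(mean = prior_mean, cov = K))
  }
  m_obs <- prior_mean[match(obs_years, grid)]
  K_oo <- matern_cov(abs(outer(obs_years, obs_years, "-")), config) +
    diag(noise_var, length(obs_years))
  K_go <- matern_cov(abs(outer(grid, obs_years, "-")), config)
  R <- chol_jitter(K_oo, config, label)
  alpha <- backsolve(R, forwardsolve(t(R), y - m_obs))
  V <- forwardsolve(t(R), t(K_go))
  list(mean = prior_mean + drop(K_go %*% alpha), cov = K - crossprod(V))
}
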