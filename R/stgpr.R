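#' Stage 1: logit-space ordinary least squares on covariates
#'
#' Regresses the logit-transformed coverage observations of one indicator on
#' the centred year, six socio-demographic covariate surfaces and the
#' province-level indicator series:
#' intercept, year, electricity, female headship, household size, women's
#' education, improved walls, health facilities per capita, and the
#' province indicator (proportion scale).  The regression is unweighted
#' ordinary least squares; a precision-weighted variant is available behind
#' `weighted = TRUE`.
#'
#' @param obs logit observations for one indicator: data.frame with columns
#'   `district`, `year`, `logit`, `logit_var`.
#' @param covs named list of district x year matrices: `elec`, `fhead`,
#'   `hhsize`, `edu`, `wall`, `hfpc`.
#' @param prov_series province x year matrix of the indicator's
#'   province-level coverage (proportion scale).
#' @param geo geography map.
#' @param years study years (columns of the covariate matrices).
#' @param weighted use 1/logit_var weights instead of OLS.
#' @return object of class `stage1_fit`: list with `beta` (named length-9
#'   vector; collinear terms dropped to 0 with a warning), `fitted`
#'   (district x year matrix of linear predictions), `residuals`
#'   (data.frame district, year, resid, weight rows of the fitting sample),
#'   `sigma` (residual standard deviation), `dropped` (names of dropped
#'   columns).
#' @export
fit_stage1 <- function(obs, covs, prov_series, geo, years, weighted = FALSE) {
  if (nrow(obs) < 10) stop("need >= 10 observations for stage 1", call. = FALSE)
  districts <- geo$districts$district
  prov_of_d <- province_of(geo)

  di <- match(obs$district, districts)
  yi <- match(obs$year, years)
  if (anyNA(di) || anyNA(yi)) {
    stop("observations outside the district/year frame", call. = FALSE)
  }
  ki <- match(prov_of_d[obs$district], rownames(prov_series))

  X <- cbind(
    intercept = 1,
    year_c = obs$year - 2000,
    elec = covs$elec[cbind(di, yi)],
    fhead = covs$fhead[cbind(di, yi)],
    hhsize = covs$hhsize[cbind(di, yi)],
    edu = covs$edu[cbind(di, yi)],
    wall = covs$wall[cbind(di, yi)],
    hfpc = covs$hfpc[cbind(di, yi)],
    prov_ind = prov_series[cbind(ki, yi)]
  )
  y <- obs$logit
  w <- if (weighted) 1 / pmax(obs$logit_var, 1e-6) else NULL

  fit <- stats::lm.fit(if (is.null(w)) X else X * sqrt(w),
                       if (is.null(w)) y else y * sqrt(w))
  beta <- fit$coefficients
  dropped <- names(beta)[is.na(beta)]
  if (length(dropped)) {
    warning("dropping collinear stage-1 columns: ",
            paste(dropped, collapse = ", "))
    beta[is.na(beta)] <- 0
  }

  # linear prediction over the full district-year frame
  nd <- length(districts); ny <- length(years)
  tc <- years - 2000
  fitted <- matrix(beta["intercept"], nd, ny, dimnames = list(districts, years))
  fitted <- fitted + matrix(tc, nd, ny, byrow = TRUE) * beta["year_c"]
  for (nm in c("elec", "fhead", "hhsize", "edu", "wall", "hfpc")) {
    fitted <- fitted + beta[nm] * covs[[nm]][districts, as.character(years), drop = FALSE]
  }
  kd <- match(prov_of_d[districts], rownames(prov_series))
  fitted <- fitted + beta["prov_ind"] * prov_series[kd, , drop = FALSE]

  res <- data.frame(district = obs$district, year = obs$year,
                    resid = y - drop(X %*% beta),
                    stringsAsFactors = FALSE)

  structure(
    list(beta = beta, fitted = fitted, residuals = res,
         sigma = stats::sd(res$resid), dropped = dropped,
         weighted = weighted),
    class = "stage1_fit"
  )
}

#' @export
print.stage1_fit <- function(x, ...) {
  cat("<stage1_fit> logit-space OLS\n")
  print(round(x$beta, 4))
  cat(sprintf("residual SD %.3f on %d observations\n", x$sigma, nrow(x$residuals)))
  invisible(x)
}

# tricube temporal kernel on |dt| with bandwidth lambda
tricube <- function(dt, lambda) {
  a <- abs(dt)
  ifelse(a <= lambda, (1 - (a / (lambda + 1))^3)^3, 0)
}

#' Spatial-temporal weight between two district-year cells
#'
#' The stage-2 smoother weights an observed residual at `datum` when
#' predicting at `target` by the product of a spatial factor (1 for the same
#' district, `zeta` for a different district within the same province, 0
#' otherwise) and a tricube temporal factor
#' `(1 - (|dt| / (lambda + 1))^3)^3` for `|dt| <= lambda`, else 0.
#'
#' @param target,datum length-2 vectors or lists: (district id, year).
#' @param geo geography map.
#' @param config an [st_config()].
#' @return a single non-negative weight.
#' @export
st_weights <- function(target, datum, geo, config = st_config()) {
  prov <- province_of(geo)
  d1 <- as.character(target[[1]]); d2 <- as.character(datum[[1]])
  spatial <- if (d1 == d2) 1 else if (prov[d1] == prov[d2]) config$zeta else 0
  spatial * tricube(as.numeric(target[[2]]) - as.numeric(datum[[2]]), config$lambda)
}

#' Stage 2: locally-weighted smoothing of stage-1 residuals
#'
#' For every district-year cell, the smoothed residual is the weighted mean
#' of the observed stage-1 residuals, with weights from [st_weights()]
#' (same-district and same-province neighbors, tricube in time).  Cells with
#' no in-support residuals fall back to the stage-1 prediction (smoothed
#' residual 0).  The output mean surface — stage-1 prediction plus smoothed
#' residual — is the prior mean of the stage-3 Gaussian process.
#'
#' @param fit a [fit_stage1()] result.
#' @param geo geography map.
#' @param years study years.
#' @param config an [st_config()].
#' @return list of class `mean_surface`: `mean` (district x year matrix),
#'   `st_resid` (district x year matrix of smoothed residuals), `stage1`
#'   (the stage-1 fitted matrix).
#' @export
smooth_residuals <- function(fit, geo, years, config = st_config()) {
  districts <- rownames(fit$fitted)
  prov_of_d <- province_of(geo)[districts]
  nd <- length(districts); ny <- length(years)

  # aggregate residuals to cell means with multiplicities
  key <- paste(fit$residuals$district, fit$residuals$year)
  rbar <- tapply(fit$residuals$resid, key, mean)
  cnt <- tapply(rep(1, length(key)), key, sum)
  cells <- strsplit(names(rbar), " ")
  d_o <- vapply(cells, `[`, "", 1L)
  t_o <- as.numeric(vapply(cells, `[`, "", 2L))
  rbar <- as.numeric(rbar); cnt <- as.numeric(cnt)

  Tmat <- tricube(outer(years, t_o, "-"), config$lambda)  # ny x n_o

  sm <- matrix(0, nd, ny, dimnames = dimnames(fit$fitted))
  p_o <- prov_of_d[d_o]
  for (i in seq_len(nd)) {
    srow <- ifelse(d_o == districts[i], 1,
                   ifelse(p_o == prov_of_d[i], config$zeta, 0))
    wnum <- Tmat %*% (srow * cnt * rbar)
    wden <- Tmat %*% (srow * cnt)
    sm[i, ] <- ifelse(wden > 0, wnum / wden, 0)
  }

  structure(list(mean = fit$fitted + sm, st_resid = sm, stage1 = fit$fitted),
            class = "mean_surface")
}

#' Stage 3: per-district Gaussian process posterior
#'
#' Each district is an independent Gaussian process over years with the
#' stage-2 mean surface as prior mean, Matérn covariance in time, and the
#' logit-space sampling variances as observation noise (multiple sources in
#' the same district-year enter as separate observations).  The posterior is
#' the standard GP regression update; escalating diagonal jitter guards the
#' Cholesky factorization.
#'
#' @param surface a [smooth_residuals()] mean surface (or any district x
#'   year matrix passed as `surface$mean`).
#' @param obs logit observations for the indicator (`district`, `year`,
#'   `logit`, `logit_var`).
#' @param years study years.
#' @param config a [gpr_config()]; when `sigma` is NULL it is set to the
#'   standard deviation of `logit - mean surface` at the observed cells,
#'   floored at `sigma_floor`.
#' @return list of class `gp_posterior`: `posteriors` (named per-district
#'   list of `mean`, `cov`), `config` (with the resolved sigma), `years`.
#' @export
gpr_posterior <- function(surface, obs, years, config = gpr_config()) {
  M <- surface$mean
  districts <- rownames(M)
  if (is.null(config$sigma)) {
    mu_at_obs <- M[cbind(match(obs$district, districts),
                         match(obs$year, years))]
    s <- stats::sd(obs$logit - mu_at_obs)
    config$sigma <- max(if (is.na(s)) 0 else s, config$sigma_floor)
  }
  obs_by_d <- split(seq_len(nrow(obs)), factor(obs$district, levels = districts))
  posteriors <- lapply(districts, function(d) {
    idx <- obs_by_d[[d]]
    gp_solve(years, M[d, ], obs$year[idx], obs$logit[idx],
             pmax(obs$logit_var[idx], 1e-10), config, label = d)
  })
  names(posteriors) <- districts
  structure(list(posteriors = posteriors, config = config, years = years),
            class = "gp_posterior")
}

#' Posterior draws on the coverage scale
#'
#' Draws seeded multivariate-normal samples from each district's GP
#' posterior in logit space and inverse-logit transforms them, giving a
#' district x year x draw array strictly inside (0, 1).
#'
#' @param posterior a [gpr_posterior()] result.
#' @param config a [gpr_config()] (for `n_draws` and jitter); defaults to
#'   the posterior's own config.
#' @param seed integer seed.
#' @return 3-d array district x year x draw (class `draw_cube` is assembled
#'   by [run_stgpr()] across indicators).
#' @export
draw_estimates <- function(posterior, config = posterior$config, seed = 1L) {
  years <- posterior$years
  districts <- names(posterior$posteriors)
  nd <- length(districts); ny <- length(years); ns <- config$n_draws
  cube <- array(NA_real_, c(nd, ny, ns),
                dimnames = list(districts, years, NULL))
  with_seed(seed, {
    for (d in districts) {
      post <- posterior$posteriors[[d]]
      sd_diag <- sqrt(pmax(diag(post$cov), 0))
      if (all(sd_diag < 1e-12)) {
        z <- matrix(post$mean, ny, ns)
      } else {
        R <- chol_jitter(post$cov, config, label = d)
        z <- post$mean + crossprod(R, matrix(stats::rnorm(ny * ns), ny, ns))
      }
      cube[d, , ] <- clamp(inv_logit(z), 1e-15, 1 - 1e-15)
    }
  })
  cube
}

#' Summarize draws into means and 95% uncertainty intervals
#'
#' Mean and 2.5th/97.5th percentiles (linear-interpolation percentile rule)
#' of the draws, on the coverage scale.
#'
#' @param cube a draw array whose last dimension indexes draws: district x
#'   year x draw, or indicator x district x year x draw.
#' @return data.frame with key columns matching the leading dimensions plus
#'   `mean`, `lower`, `upper`.
#' @export
summarize_draws <- function(cube) {
  dims <- dim(cube)
  nd <- length(dims)
  if (nd == 3) {
    keys <- expand.grid(district = dimnames(cube)[[1]],
                        year = as.integer(dimnames(cube)[[2]]),
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    flat <- matrix(cube, prod(dims[1:2]), dims[3])
  } else if (nd == 4) {
    keys <- expand.grid(indicator = dimnames(cube)[[1]],
                        district = dimnames(cube)[[2]],
                        year = as.integer(dimnames(cube)[[3]]),
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    flat <- matrix(cube, prod(dims[1:3]), dims[4])
  } else {
    stop("cube must be a 3-d or 4-d draw array", call. = FALSE)
  }
  if (ncol(flat) < 2) stop("need >= 2 draws", call. = FALSE)
  q <- apply(flat, 1, stats::quantile, probs = c(0.025, 0.975), type = 7,
             names = FALSE)
  out <- data.frame(keys, mean = rowMeans(flat),
                    lower = q[1, ], upper = q[2, ],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

# normalize province series input: 3-d array [indicator, province, year],
# long df (indicator, province, year, value), or matrix for one indicator
prov_series_matrix <- function(province_series, indicator, provinces, years) {
  if (is.array(province_series) && length(dim(province_series)) == 3) {
    return(province_series[indicator, , , drop = TRUE])
  }
  if (is.data.frame(province_series)) {
    sub <- province_series[province_series$indicator == indicator, ]
    m <- matrix(NA_real_, length(provinces), length(years),
                dimnames = list(provinces, years))
    m[cbind(match(sub$province, provinces), match(sub$year, years))] <- sub$value
    if (anyNA(m)) stop("province series incomplete for ", indicator, call. = FALSE)
    return(m)
  }
  province_series
}

#' Run the full three-stage estimator
#'
#' Orchestrates, for every indicator present in the observations: stage-1
#' logit-space OLS on the covariate surfaces, stage-2 spatial-temporal
#' residual smoothing, stage-3 per-district Gaussian process regression, and
#' posterior draws.  Fully reproducible given the seed.
#'
#' @param obs a preprocessed `observation_set` (proportion scale; the logit
#'   transform is applied internally with `eps`/`var_floor` defaults) or a
#'   data.frame already carrying `logit` and `logit_var` columns.
#' @param covs named list of district x year covariate matrices (see
#'   [fit_stage1()]).
#' @param province_series 3-d array indicator x province x year, long
#'   data.frame from [province_indicator_series()], or a single matrix.
#' @param geo geography map.
#' @param years study years.
#' @param st an [st_config()].
#' @param gpr a [gpr_config()].
#' @param seed integer seed for the posterior draws.
#' @return list of class `stgpr_result`:
#'   `cube` (indicator x district x year x draw array, class `draw_cube`),
#'   `summary` (data.frame indicator, district, year, mean, lower, upper),
#'   `stage1` (named list of stage-1 fits), `surfaces` (named list of mean
#'   surfaces), `sigmas` (resolved Matérn amplitudes), `seed`, `configs`.
#' @export
run_stgpr <- function(obs, covs, province_series, geo, years,
                      st = st_config(), gpr = gpr_config(), seed = 1L) {
  if (is.null(obs$logit)) obs <- to_logit(obs)
  indicators <- unique(obs$indicator)
  districts <- geo$districts$district
  nd <- length(districts); ny <- length(years)

  cube <- array(NA_real_, c(length(indicators), nd, ny, gpr$n_draws),
                dimnames = list(indicators, districts, years, NULL))
  stage1 <- list(); surfaces <- list(); sigmas <- numeric(0)

  for (j in seq_along(indicators)) {
    indic <- indicators[j]
    sub <- obs[obs$indicator == indic, ]
    ps <- prov_series_matrix(province_series, indic, geo$provinces, years)
    f1 <- tryCatch(
      fit_stage1(sub, covs, ps, geo, years),
      error = function(e) stop(sprintf("[%s] stage 1: %s", indic, conditionMessage(e)),
                               call. = FALSE))
    surf <- smooth_residuals(f1, geo, years, st)
    post <- tryCatch(
      gpr_posterior(surf, sub, years, gpr),
      error = function(e) stop(sprintf("[%s] stage 3: %s", indic, conditionMessage(e)),
                               call. = FALSE))
    cube[j, , , ] <- draw_estimates(post, post$config, seed = derive_seed(seed, j))
    stage1[[indic]] <- f1
    surfaces[[indic]] <- surf
    sigmas[indic] <- post$config$sigma
  }

  class(cube) <- c("draw_cube", class(cube))
  attr(cube, "seed") <- seed

  structure(
    list(cube = cube, summary = summarize_draws(cube), stage1 = stage1,
         surfaces = surfaces, sigmas = sigmas, seed = seed,
         configs = list(st = st, gpr = gpr)),
    class = "stgpr_result"
  )
}

#' @export
print.stgpr_result <- function(x, ...) {
  d <- dim(x$cube)
  cat(sprintf("<stgpr_result> %d indicators x %d districts x %d years, %d draws (seed %d)\n",
              d[1], d[2], d[3], d[4], x$seed))
  invisible(x)
}
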