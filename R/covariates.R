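#' Natural cubic spline basis for a time trend
#'
#' Thin wrapper around [splines::ns()] that fixes the conventions used by the
#' covariate completion model: the default trend basis has one interior knot
#' at 2000 and linear extrapolation beyond the boundary knots, giving
#' `1 + length(interior_knots)` columns (excluding the intercept).
#'
#' @param years numeric vector of evaluation years.
#' @param interior_knots interior knot years (default 2000, dropped
#'   automatically when outside the data range is an error).
#' @param boundary_knots length-2 boundary; defaults to `range(years)`.
#' @return basis matrix with one row per year.
#' @export
natural_spline_basis <- function(years, interior_knots = 2000,
                                 boundary_knots = range(years)) {
  interior_knots <- interior_knots[!is.na(interior_knots)]
  if (length(interior_knots) &&
      (any(interior_knots <= boundary_knots[1]) ||
       any(interior_knots >= boundary_knots[2]))) {
    stop("interior knots must lie strictly inside the boundary knots",
         call. = FALSE)
  }
  b <- splines::ns(years, knots = if (length(interior_knots)) interior_knots,
                   Boundary.knots = boundary_knots)
  colnames(b) <- paste0("ns", seq_len(ncol(b)))
  b
}

# scale transforms used for covariate modeling
cov_transform <- function(x, type, eps = 1e-4) {
  switch(type,
         proportion = logit(clamp(x, eps, 1 - eps)),
         log = log(pmax(x, 1e-8)),
         identity = x)
}
cov_backtransform <- function(z, type) {
  switch(type,
         proportion = inv_logit(z),
         log = exp(z),
         identity = pmax(z, 0))
}

#' Stage 1 of covariate completion: mixed-effects spline regression
#'
#' Fits `value ~ natural spline in year` with a district-level random
#' intercept and random slope, by REML with fallback to ML and, when the
#' random effects are inestimable (one district, singular fit), to a
#' fixed-effects-only least-squares fit with a warning.  Districts without
#' data receive the fixed-effects prediction.
#'
#' @param obs data.frame with columns `district`, `year`, `value` (already on
#'   the modeling scale).
#' @param districts all district ids the prediction frame must cover.
#' @param years all years the prediction frame must cover.
#' @param interior_knots spline interior knots (default 2000).
#' @return list of class `spline_mixed_fit`: `fitted` (data.frame district,
#'   year, mean), `resid_sd`, `ranef` (data.frame or NULL), `engine`
#'   ("lmer-REML", "lmer-ML" or "lm").
#' @export
fit_covariate_stage1 <- function(obs, districts, years,
                                 interior_knots = 2000) {
  if (nrow(obs) < 2) stop("need at least two observations", call. = FALSE)
  boundary <- range(obs$year)
  ik <- interior_knots[interior_knots > boundary[1] & interior_knots < boundary[2]]
  basis_obs <- natural_spline_basis(obs$year, ik, boundary)
  dat <- data.frame(value = obs$value,
                    district = factor(obs$district, levels = districts),
                    yearc = obs$year - 2000)
  dat <- cbind(dat, as.data.frame(basis_obs))
  bcols <- colnames(basis_obs)
  fixed <- paste("value ~", paste(bcols, collapse = " + "))

  engine <- NULL
  fit <- NULL
  if (length(unique(obs$district)) >= 3) {
    form <- stats::as.formula(paste(fixed, "+ (1 + yearc | district)"))
    fit <- tryCatch(
      suppressWarnings(suppressMessages(
        lme4::lmer(form, data = dat, REML = TRUE,
                   control = lme4::lmerControl(calc.derivs = FALSE,
                                               check.nobs.vs.nRE = "ignore"))
      )),
      error = function(e) NULL)
    if (!is.null(fit)) engine <- "lmer-REML"
    if (is.null(fit)) {
      fit <- tryCatch(
        suppressWarnings(suppressMessages(
          lme4::lmer(form, data = dat, REML = FALSE,
                     control = lme4::lmerControl(calc.derivs = FALSE,
                                                 check.nobs.vs.nRE = "ignore"))
        )),
        error = function(e) NULL)
      if (!is.null(fit)) engine <- "lmer-ML"
    }
  }
  if (is.null(fit)) {
    warning("mixed model inestimable; falling back to fixed effects only")
    fit <- stats::lm(stats::as.formula(fixed), data = dat)
    engine <- "lm"
  }

  # prediction frame
  grid <- expand.grid(district = districts, year = years,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  basis_grid <- natural_spline_basis(grid$year, ik, boundary)
  fe <- if (engine == "lm") stats::coef(fit) else lme4::fixef(fit)
  fe[is.na(fe)] <- 0
  mu <- fe[1] + drop(basis_grid %*% fe[bcols])

  re_df <- NULL
  if (engine != "lm") {
    re <- lme4::ranef(fit)$district
    re_df <- data.frame(district = rownames(re),
                        intercept = re[, "(Intercept)"],
                        slope = re[, "yearc"],
                        stringsAsFactors = FALSE)
    m <- match(grid$district, re_df$district)
    add <- ifelse(is.na(m), 0, re_df$intercept[m]) +
      ifelse(is.na(m), 0, re_df$slope[m]) * (grid$year - 2000)
    mu <- mu + add
  }

  structure(
    list(fitted = data.frame(grid, mean = mu, stringsAsFactors = FALSE),
         resid_sd = stats::sigma(fit),
         ranef = re_df, engine = engine),
    class = "spline_mixed_fit"
  )
}

#' Stage 2 of covariate completion: per-district Gaussian process
#'
#' Runs a GP over years in each district with the stage-1 fitted curve as
#' prior mean and a Matérn covariance.  Observation noise comes from the
#' per-record `variance` column when present, otherwise from the stage-1
#' residual variance.
#'
#' @param fit a [fit_covariate_stage1()] result.
#' @param obs data.frame district, year, value (modeling scale), optional
#'   `variance` (modeling scale).
#' @param years the completion year grid.
#' @param config a [gpr_config()]; `sigma = NULL` estimates the amplitude
#'   from the stage-1 residuals (floored).
#' @return data.frame district, year, mean, sd (posterior, modeling scale).
#' @export
covariate_gpr <- function(fit, obs, years, config = gpr_config()) {
  districts <- unique(fit$fitted$district)
  if (is.null(config$sigma)) {
    m <- match(paste(obs$district, obs$year),
               paste(fit$fitted$district, fit$fitted$year))
    config$sigma <- max(stats::sd(obs$value - fit$fitted$mean[m]),
                        config$sigma_floor)
    if (is.na(config$sigma)) config$sigma <- config$sigma_floor
  }
  noise_default <- max(fit$resid_sd^2, 1e-6)

  out <- lapply(districts, function(d) {
    prior <- fit$fitted$mean[fit$fitted$district == d][order(fit$fitted$year[fit$fitted$district == d])]
    o <- obs[obs$district == d & obs$year %in% years, ]
    nv <- if (!is.null(o$variance)) pmax(o$variance, 1e-6) else rep(noise_default, nrow(o))
    post <- gp_solve(years, prior, o$year, o$value, nv, config, label = d)
    data.frame(district = d, year = years, mean = post$mean,
               sd = sqrt(pmax(diag(post$cov), 0)), stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Complete a sparse covariate series into a full district-year surface
#'
#' The two-step completion model: a mixed-effects natural-spline regression
#' gives a smooth mean curve per district; a Gaussian process regression
#' around that mean absorbs the data, yielding a posterior mean and 95%
#' interval for every district-year.  Proportions are modeled on the logit
#' scale, household size on the log scale, years of education on the
#' identity scale (bounded below at 0).  The time-constant health-facility
#' density covariate should bypass this model entirely.
#'
#' @param obs data.frame district, year, value (natural scale), optional
#'   variance (natural scale; transformed by the delta method).
#' @param districts,years the completion frame.
#' @param type "proportion", "log" or "identity".
#' @param interior_knots spline knots (default 2000).
#' @param config a [gpr_config()].
#' @return data.frame district, year, mean, lower, upper (natural scale).
#' @export
complete_covariate <- function(obs, districts, years,
                               type = c("proportion", "log", "identity"),
                               interior_knots = 2000,
                               config = gpr_config()) {
  type <- match.arg(type)
  tr <- obs
  tr$value <- cov_transform(obs$value, type)
  if (!is.null(obs$variance)) {
    # delta method onto the modeling scale
    tr$variance <- switch(type,
      proportion = {
        pc <- clamp(obs$value, 1e-4, 1 - 1e-4)
        obs$variance / (pc * (1 - pc))^2
      },
      log = obs$variance / pmax(obs$value, 1e-8)^2,
      identity = obs$variance)
  }
  s1 <- fit_covariate_stage1(tr, districts, years, interior_knots)
  post <- covariate_gpr(s1, tr, years, config)
  out <- data.frame(
    district = post$district, year = post$year,
    mean = cov_backtransform(post$mean, type),
    lower = cov_backtransform(post$mean - 1.96 * post$sd, type),
    upper = cov_backtransform(post$mean + 1.96 * post$sd, type),
    stringsAsFactors = FALSE
  )
  if (type == "proportion") {
    out$mean <- clamp(out$mean, 0, 1)
    out$lower <- clamp(out$lower, 0, 1)
    out$upper <- clamp(out$upper, 0, 1)
  }
  out
}

#' Province-level indicator series as stage-1 covariates
#'
#' Aggregates district observations to provinces by precision weighting
#' (weights 1/variance, with a variance floor; population-share weights when
#' no variances are usable) and completes each indicator's province-year
#' series with the same two-step model used for covariates.  The resulting
#' series feeds the stage-1 regression as the province indicator term.
#'
#' @param obs an `observation_set` (proportion scale).
#' @param geo geography map.
#' @param years completion years.
#' @param config a [gpr_config()].
#' @return data.frame indicator, province, year, value (proportion scale).
#' @export
province_indicator_series <- function(obs, geo, years, config = gpr_config()) {
  prov <- geo$provinces
  res <- lapply(unique(obs$indicator), function(indic) {
    sub <- obs[obs$indicator == indic, ]
    grp <- interaction(sub$province, sub$year, sub$source, drop = TRUE)
    agg <- do.call(rbind, lapply(split(sub, grp), function(g) {
      w <- 1 / pmax(g$variance, 1e-6)
      data.frame(district = g$province[1], year = g$year[1],
                 value = sum(w * g$estimate) / sum(w),
                 variance = 1 / sum(w), stringsAsFactors = FALSE)
    }))
    comp <- complete_covariate(agg, prov, years, type = "proportion",
                               config = config)
    data.frame(indicator = indic, province = comp$district, year = comp$year,
               value = comp$mean, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
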