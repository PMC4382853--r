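# Small fixtures shared across test files; everything is generated in code.

tiny_geo <- function(seed = 1) generate_geography(3, 12, 2, seed = seed)

# restrict a scenario to a subset of indicators
scenario_subset <- function(sc, ids) {
  sc$indicators <- sc$indicators[sc$indicators$indicator %in% ids, ]
  rownames(sc$indicators) <- NULL
  sc
}

# a noise-free scenario: truth is exactly the stage-1 linear predictor
noiseless_scenario <- function(ids = NULL) {
  sc <- default_scenario(district_shock_sd = 0, province_shock_sd = 0,
                         covariate_shock_sd = 0)
  if (!is.null(ids)) sc <- scenario_subset(sc, ids)
  sc
}

quick_gpr <- function(n_draws = 100, ...) gpr_config(n_draws = n_draws, ...)

# independent dense-solve GP oracle (explicit matrix inversion)
gp_oracle <- function(grid, prior_mean, obs_years, y, noise_var, config) {
  prior_mean <- unname(prior_mean)
  K <- matern_cov(abs(outer(grid, grid, "-")), config)
  if (length(obs_years) == 0) return(list(mean = prior_mean, cov = K))
  m_obs <- prior_mean[match(obs_years, grid)]
  K_oo <- matern_cov(abs(outer(obs_years, obs_years, "-")), config) +
    diag(noise_var, length(obs_years))
  K_go <- matern_cov(abs(outer(grid, obs_years, "-")), config)
  A <- solve(K_oo)
  list(mean = prior_mean + drop(K_go %*% A %*% (y - m_obs)),
       cov = K - K_go %*% A %*% t(K_go))
}

# truth joined to a summary data.frame
join_truth <- function(summary, truth) {
  tl <- truth_long(truth)
  m <- match(paste(summary$indicator, summary$district, summary$year),
             paste(tl$indicator, tl$district, tl$year))
  summary$truth <- tl$p[m]
  summary
}
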