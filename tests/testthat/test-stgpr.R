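test_that("stage-1 OLS recovers generating coefficients from noiseless data", {
  sc <- noiseless_scenario()
  geo <- tiny_geo()
  truth <- generate_truth(geo, sc, seed = 4)
  lo <- to_logit(saturated_observations(truth, "anc4"))
  fit <- fit_stage1(lo, truth$covariates, truth$province_series["anc4", , ],
                    geo, sc$years)
  expect_equal(unname(fit$beta), unname(truth$beta["anc4", ]), tolerance = 1e-6)
  # residuals of the fitting sample sum to zero (intercept included)
  expect_lt(abs(sum(fit$residuals$resid)), 1e-8)
})

test_that("constant covariates are dropped as collinear and the intercept is the mean logit", {
  geo <- tiny_geo()
  years <- 1990:2010
  districts <- geo$districts$district
  const <- matrix(0.5, 12, 21, dimnames = list(districts, years))
  covs <- list(elec = const, fhead = const, hhsize = const, edu = const,
               wall = const, hfpc = const)
  ps <- matrix(0.5, 3, 21, dimnames = list(geo$provinces, years))
  set.seed(2)
  obs <- data.frame(indicator = "x", district = sample(districts, 60, TRUE),
                    year = sample(years, 60, TRUE), source = "s",
                    logit = rnorm(60, 0.3, 0.2), logit_var = 0.01,
                    stringsAsFactors = FALSE)
  expect_warning(fit <- fit_stage1(obs, covs, ps, geo, years), "collinear")
  expect_equal(unname(fit$beta["intercept"] + fit$beta["year_c"] * mean(obs$year - 2000)),
               mean(obs$logit), tolerance = 1e-6)
  expect_lt(abs(fit$beta["year_c"]), 0.05)
})

test_that("stage-1 coefficients are invariant to duplicating every observation", {
  geo <- tiny_geo()
  truth <- generate_truth(geo, default_scenario(), seed = 5)
  lo <- to_logit(saturated_observations(truth, "polio"))
  f1 <- fit_stage1(lo, truth$covariates, truth$province_series["polio", , ],
                   geo, 1990:2010)
  f2 <- fit_stage1(rbind(lo, lo), truth$covariates,
                   truth$province_series["polio", , ], geo, 1990:2010)
  expect_equal(f1$beta, f2$beta, tolerance = 1e-10)
})

test_that("spatial-temporal weights follow the tricube-within-province rule", {
  geo <- tiny_geo()
  cfg <- st_config(lambda = 10, zeta = 0.5)
  d <- geo$districts$district
  same_prov <- d[geo$districts$province == geo$districts$province[1]][1:2]
  other <- d[geo$districts$province != geo$districts$province[1]][1]
  # self weight is 1
  expect_equal(st_weights(list(d[1], 2000), list(d[1], 2000), geo, cfg), 1)
  # different province: zero regardless of time
  expect_equal(st_weights(list(d[1], 2000), list(other, 2000), geo, cfg), 0)
  # support boundary: |dt| = lambda + 1 gives zero
  expect_equal(st_weights(list(d[1], 2000), list(d[1], 2011), geo, cfg), 0)
  # same province, same year: zeta
  expect_equal(st_weights(list(same_prov[1], 2000), list(same_prov[2], 2000),
                          geo, cfg), 0.5)
  # hand-computed tricube at dt = 3
  expect_equal(st_weights(list(d[1], 2000), list(d[1], 2003), geo, cfg),
               (1 - (3 / 11)^3)^3, tolerance = 1e-12)
})

test_that("residual smoothing reproduces constant fields and isolated residuals", {
  geo <- tiny_geo()
  years <- 1990:2010
  districts <- geo$districts$district
  fitted <- matrix(0, 12, 21, dimnames = list(districts, years))

  # constant residual field: smoothed residual c wherever there is support
  res_const <- expand.grid(district = districts, year = c(1995, 2005),
                           KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  res_const$resid <- 0.7
  fit <- structure(list(fitted = fitted, residuals = res_const), class = "stage1_fit")
  out <- smooth_residuals(fit, geo, years, st_config())
  expect_equal(out$st_resid[, "2000"], setNames(rep(0.7, 12), districts))

  # single residual: the smoothed residual at its own cell equals it
  res1 <- data.frame(district = districts[1], year = 2000, resid = -0.4)
  fit1 <- structure(list(fitted = fitted, residuals = res1), class = "stage1_fit")
  out1 <- smooth_residuals(fit1, geo, years, st_config())
  expect_equal(out1$st_resid[districts[1], "2000"], -0.4)
  # cells with no in-support residuals fall back to the stage-1 prediction
  far <- districts[geo$districts$province != geo$districts$province[1]][1]
  expect_equal(out1$mean[far, "1990"], 0)
})

test_that("two-point smoothing matches hand-computed tricube weights", {
  geo <- tiny_geo()
  years <- 1990:2010
  districts <- geo$districts$district
  fitted <- matrix(0, 12, 21, dimnames = list(districts, years))
  d <- districts[1]
  res <- data.frame(district = d, year = c(1998, 2006), resid = c(1, -1))
  fit <- structure(list(fitted = fitted, residuals = res), class = "stage1_fit")
  cfg <- st_config(lambda = 10, zeta = 0.5)
  out <- smooth_residuals(fit, geo, years, cfg)
  w1 <- (1 - (2 / 11)^3)^3   # |2000 - 1998|
  w2 <- (1 - (6 / 11)^3)^3   # |2000 - 2006|
  expect_equal(out$st_resid[d, "2000"], (w1 - w2) / (w1 + w2), tolerance = 1e-12)
})

test_that("the Matern kernel matches its closed forms and decreases with distance", {
  expect_equal(matern_cov(0, gpr_config(sigma = 2)), 4)
  expect_equal(matern_cov(1, gpr_config(sigma = 1, rho = 1, nu = 1/2)), exp(-1))
  d <- 1.7
  expect_equal(matern_cov(d, gpr_config(sigma = 1.3, rho = 2.5)),
               1.3^2 * (1 + sqrt(3) * d / 2.5) * exp(-sqrt(3) * d / 2.5),
               tolerance = 1e-12)
  grid <- seq(0, 30, by = 0.5)
  for (nu in c(1/2, 3/2, 5/2)) {
    v <- matern_cov(grid, gpr_config(sigma = 1, rho = 4, nu = nu))
    expect_true(all(diff(v) < 0))
  }
  expect_error(gpr_config(nu = 2), "nu")
  expect_error(matern_cov(-1, gpr_config(sigma = 1)), "non-negative")
})

test_that("the GP posterior matches a dense-solve oracle and its limits", {
  geo <- tiny_geo()
  years <- 1990:2010
  districts <- geo$districts$district
  M <- matrix(0, 12, 21, dimnames = list(districts, years))
  surface <- list(mean = M)
  cfg <- gpr_config(sigma = 0.7, rho = 4, n_draws = 10)

  # no observations anywhere: prior fallback
  empty <- data.frame(district = character(), year = integer(),
                      logit = numeric(), logit_var = numeric())
  post0 <- gpr_posterior(surface, empty, years, cfg)
  expect_equal(post0$posteriors[[districts[1]]]$mean, unname(M[1, ]))

  # one near-exact observation is interpolated
  one <- data.frame(district = districts[1], year = 2003, logit = 1.2,
                    logit_var = 1e-10)
  post1 <- gpr_posterior(surface, one, years, cfg)
  expect_equal(post1$posteriors[[districts[1]]]$mean[years == 2003], 1.2,
               tolerance = 1e-6)

  # three observations: dense-solve oracle agreement in mean and covariance
  three <- data.frame(district = districts[2], year = c(1994, 2001, 2008),
                      logit = c(0.5, -0.2, 0.9), logit_var = c(0.1, 0.05, 0.2))
  post3 <- gpr_posterior(surface, three, years, cfg)
  oracle <- gp_oracle(years, M[2, ], three$year, three$logit, three$logit_var, cfg)
  expect_equal(post3$posteriors[[districts[2]]]$mean, oracle$mean,
               tolerance = 1e-8)
  expect_equal(post3$posteriors[[districts[2]]]$cov, oracle$cov,
               tolerance = 1e-8)
})

test_that("shrinking observation variances never inflates the posterior variance", {
  years <- 1990:2010
  cfg <- gpr_config(sigma = 0.7, rho = 4)
  M <- matrix(0, 1, 21, dimnames = list("A", years))
  obs <- data.frame(district = "A", year = c(1995, 2002, 2009),
                    logit = c(0.3, -0.1, 0.4), logit_var = c(0.2, 0.3, 0.1))
  p1 <- gpr_posterior(list(mean = M), obs, years, cfg)
  obs2 <- transform(obs, logit_var = logit_var / 10)
  p2 <- gpr_posterior(list(mean = M), obs2, years, cfg)
  v1 <- diag(p1$posteriors$A$cov)[years %in% obs$year]
  v2 <- diag(p2$posteriors$A$cov)[years %in% obs$year]
  expect_true(all(v2 <= v1 + 1e-12))
})

test_that("posterior draws have the configured count and match the posterior mean", {
  years <- 1990:2010
  cfg <- gpr_config(sigma = 0.7, rho = 4, n_draws = 1000)
  M <- matrix(0.4, 1, 21, dimnames = list("A", years))
  obs <- data.frame(district = "A", year = c(1996, 2005), logit = c(0.2, 0.8),
                    logit_var = 0.1)
  post <- gpr_posterior(list(mean = M), obs, years, cfg)
  cube <- draw_estimates(post, cfg, seed = 3)
  expect_equal(dim(cube), c(1, 21, 1000))
  expect_true(all(cube > 0 & cube < 1))
  # empirical draw mean within 4 SD / sqrt(n) of the analytic mean, in logit space
  lmean <- apply(logit(cube["A", , ]), 1, mean)
  lsd <- sqrt(diag(post$posteriors$A$cov))
  expect_true(all(abs(lmean - post$posteriors$A$mean) <=
                    4 * pmax(lsd, 1e-12) / sqrt(1000)))

  # a degenerate posterior yields constant draws
  post0 <- post
  post0$posteriors$A$cov <- matrix(0, 21, 21)
  cube0 <- draw_estimates(post0, cfg, seed = 3)
  expect_true(all(apply(cube0["A", , ], 1, sd) == 0))
})

test_that("draw summaries use linear-interpolation percentiles and are permutation invariant", {
  draws <- (1:1000) / 1001
  cube <- array(rep(draws, each = 2), c(1, 2, 1000),
                dimnames = list("A", c(2000, 2001), NULL))
  s <- summarize_draws(cube)
  sorted <- sort(draws)
  expect_equal(s$mean, rep(mean(draws), 2))
  expect_equal(s$lower, rep(unname(quantile(sorted, 0.025, type = 7)), 2))
  expect_equal(s$upper, rep(unname(quantile(sorted, 0.975, type = 7)), 2))
  # constant draws collapse to (c, c, c)
  cc <- array(0.37, c(1, 1, 50), dimnames = list("A", 2000, NULL))
  sc <- summarize_draws(cc)
  expect_equal(unlist(sc[, c("mean", "lower", "upper")], use.names = FALSE),
               rep(0.37, 3))
  # permutation invariance
  set.seed(1)
  perm <- cube[, , sample(1000), drop = FALSE]
  dimnames(perm) <- dimnames(cube)
  expect_equal(summarize_draws(perm)[, c("mean", "lower", "upper")],
               s[, c("mean", "lower", "upper")], tolerance = 1e-12)
  expect_true(all(s$lower <= s$mean & s$mean <= s$upper))
})

test_that("the full estimator is byte-identical under a repeated seed", {
  geo <- tiny_geo()
  sc <- scenario_subset(default_scenario(), c("itn", "anc4"))
  truth <- generate_truth(geo, sc, seed = 6)
  plan <- default_survey_plan(geo, sc)
  obs <- sample_observations(truth, plan, seed = 7)
  obs <- apply_prelaunch_floor(obs, launch_floor_years(sc), geo, sc$years)
  r1 <- run_stgpr(obs, truth$covariates, truth$province_series, geo, sc$years,
                  gpr = quick_gpr(), seed = 42)
  r2 <- run_stgpr(obs, truth$covariates, truth$province_series, geo, sc$years,
                  gpr = quick_gpr(), seed = 42)
  expect_identical(r1$cube, r2$cube)
  expect_identical(r1$summary, r2$summary)
  r3 <- run_stgpr(obs, truth$covariates, truth$province_series, geo, sc$years,
                  gpr = quick_gpr(), seed = 43)
  expect_false(identical(r1$cube, r3$cube))
})

test_that("a district with no data reverts to its smoothed mean function", {
  geo <- tiny_geo()
  sc <- scenario_subset(default_scenario(), "anc4")
  truth <- generate_truth(geo, sc, seed = 8)
  plan <- default_survey_plan(geo, sc)
  gone <- geo$districts$district[1]
  plan <- plan[plan$district != gone, ]
  obs <- sample_observations(truth, plan, seed = 9)
  res <- run_stgpr(obs, truth$covariates, truth$province_series, geo, sc$years,
                   gpr = quick_gpr(n_draws = 2000), seed = 10)
  surf <- res$surfaces$anc4$mean[gone, ]
  est <- res$summary[res$summary$district == gone, ]
  # posterior mean equals the mean function; the draw mean matches it up to
  # Monte-Carlo and inverse-logit convexity error
  expect_equal(logit(est$mean), unname(surf), tolerance = 0.1)
})
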