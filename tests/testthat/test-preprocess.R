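test_that("household interpolation follows the closed-form geometric rule", {
  # zero growth
  flat <- interpolate_households(data.frame(year = c(1990, 2000),
                                            count = c(1000, 1000)))
  expect_equal(flat$count[flat$year == 1995], 1000)
  # doubling decade: 1995 = 1000 * 2^0.5
  dbl <- interpolate_households(data.frame(year = c(1990, 2000),
                                           count = c(1000, 2000)))
  expect_equal(dbl$count[dbl$year == 1995], 1000 * sqrt(2), tolerance = 1e-9)
  # piecewise: continuity at interior anchors and closed form mid-segment
  pw <- interpolate_households(data.frame(year = c(1990, 2000, 2010),
                                          count = c(1000, 2000, 4000)))
  expect_equal(pw$count[pw$year == 2005], 2000 * sqrt(2), tolerance = 1e-9)
  expect_equal(pw$count[pw$year == 2000], 2000, tolerance = 1e-12)
})

test_that("interpolation extrapolates with the nearest segment's growth rate", {
  out <- interpolate_households(data.frame(year = c(2000, 2010),
                                           count = c(1000, 2000)),
                                years = 1995:2015)
  r <- 2^(1 / 10)
  expect_equal(out$count[out$year == 1995], 1000 * r^-5, tolerance = 1e-9)
  expect_equal(out$count[out$year == 2015], 2000 * r^5, tolerance = 1e-9)
})

test_that("interpolation is multiplicative and validates its inputs", {
  a <- data.frame(year = c(1991, 1999, 2007), count = c(1300, 2200, 2600))
  base <- interpolate_households(a)
  scaled <- interpolate_households(transform(a, count = count * 3.7))
  expect_equal(scaled$count, base$count * 3.7, tolerance = 1e-12)
  expect_error(interpolate_households(a[1, ]), "two anchors")
  expect_error(interpolate_households(data.frame(year = c(2000, 1990),
                                                 count = c(1, 2))), "increasing")
  expect_error(interpolate_households(data.frame(year = c(1990, 2000),
                                                 count = c(0, 2))), "positive")
})

test_that("administrative IRS coverage is sprayed/households with a cap", {
  hh <- data.frame(district = "D1", year = c(2005, 2006, 2007),
                   households = 1000)
  admin <- data.frame(district = "D1", year = c(2005, 2006, 2007),
                      sprayed = c(0, 500, 1200))
  expect_warning(out <- compute_irs_coverage(admin, hh), "capped")
  expect_equal(out$estimate, c(0, 0.5, 0.99))
  # fixed logit-space variance round-trips through the delta method
  lo <- to_logit(out)
  expect_equal(lo$logit_var[2], 0.1, tolerance = 1e-12)
  expect_error(compute_irs_coverage(data.frame(district = "D1", year = 2005,
                                               sprayed = -1), hh), "negative")
  expect_error(
    compute_irs_coverage(data.frame(district = "D2", year = 2005, sprayed = 1),
                         hh),
    "missing household")
})

make_split_obs <- function(geo, parent, ref_est, parent_est, ref_years = 2000:2004) {
  inh <- geo$splits$district[geo$splits$parent == parent]
  prov <- covbench:::province_of(geo)
  ref <- expand.grid(district = inh, year = ref_years,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  ref$estimate <- ref_est[match(ref$district, inh)]
  pre <- data.frame(district = parent, year = 1995L, estimate = parent_est,
                    stringsAsFactors = FALSE)
  obs <- rbind(ref, pre)
  obs$indicator <- "anc4"
  obs$province <- unname(prov[obs$district])
  obs$source <- "s"
  obs$variance <- 0.01
  obs$sample_size <- 50
  obs <- obs[, c("indicator", "district", "province", "year", "source",
                 "estimate", "variance", "sample_size")]
  class(obs) <- c("observation_set", "data.frame")
  obs
}

test_that("split harmonization applies reference-window ratios to pre-split records", {
  geo <- tiny_geo()
  parent <- geo$splits$parent[1]
  inh <- geo$splits$district[geo$splits$parent == parent]
  shares <- geo$splits$share[geo$splits$parent == parent]
  # choose inheritor levels so the share-weighted parent mean is 0.4
  e2 <- (0.4 - shares[1] * 0.5) / shares[2]
  obs <- make_split_obs(geo, parent, c(0.5, e2), parent_est = 0.4)
  out <- harmonize_districts(obs, geo)
  adj <- out[out$year == 1995, ]
  expect_setequal(adj$district, inh)
  expect_equal(adj$estimate[match(inh, adj$district)],
               0.4 * c(0.5, e2) / 0.4, tolerance = 1e-9)
  expect_true(all(adj$flag_split_adjusted))
  expect_equal(adj$variance, rep(0.01 * 1.5, 2))   # inflation factor
})

test_that("homogeneous splits pass pre-split estimates through unchanged", {
  geo <- tiny_geo()
  parent <- geo$splits$parent[1]
  obs <- make_split_obs(geo, parent, c(0.4, 0.4), parent_est = 0.4)
  out <- harmonize_districts(obs, geo)
  adj <- out[out$year == 1995, ]
  expect_equal(adj$estimate, c(0.4, 0.4), tolerance = 1e-12)
})

test_that("harmonization conserves the parent-level estimate when nothing is clipped", {
  geo <- tiny_geo()
  parent <- geo$splits$parent[2]
  shares <- geo$splits$share[geo$splits$parent == parent]
  obs <- make_split_obs(geo, parent, c(0.7, 0.2), parent_est = 0.35)
  out <- harmonize_districts(obs, geo)
  adj <- out[out$year == 1995, ]
  inh <- geo$splits$district[geo$splits$parent == parent]
  expect_equal(sum(shares * adj$estimate[match(inh, adj$district)]), 0.35,
               tolerance = 1e-9)
})

test_that("ratios that push an estimate above 1 are clipped to 0.99 with a warning", {
  geo <- tiny_geo()
  parent <- geo$splits$parent[1]
  obs <- make_split_obs(geo, parent, c(0.9, 0.1), parent_est = 0.8)
  expect_warning(out <- harmonize_districts(obs, geo), "clipped")
  expect_true(any(out$estimate[out$year == 1995] == 0.99))
})

test_that("unknown district ids are rejected by harmonization", {
  geo <- tiny_geo()
  obs <- make_split_obs(geo, geo$splits$parent[1], c(0.4, 0.4), 0.4)
  obs$district[1] <- "Dxx"
  expect_error(harmonize_districts(obs, geo), "unknown district")
})

test_that("pre-launch floors insert 0.0001 coverage and are idempotent", {
  geo <- tiny_geo()
  years <- 1990:2010
  obs <- data.frame(indicator = "itn", district = geo$districts$district[1],
                    province = geo$districts$province[1], year = 1995L,
                    source = "s", estimate = 0.3, variance = 0.01,
                    sample_size = 50, stringsAsFactors = FALSE)
  class(obs) <- c("observation_set", "data.frame")
  out <- apply_prelaunch_floor(obs, c(itn = 1997), geo, years)
  pre <- out[out$year < 1997, ]
  expect_equal(nrow(pre), 12 * 7)            # every district-year before 1997
  expect_true(all(pre$estimate == 1e-4))
  expect_true(all(pre$flag_floor))
  # the observed 1995 record was overridden, not duplicated
  expect_equal(sum(out$district == geo$districts$district[1] & out$year == 1995), 1)
  # idempotent
  expect_identical(apply_prelaunch_floor(out, c(itn = 1997), geo, years), out)
})

test_that("floors respect the strict inequality and unconfigured indicators", {
  geo <- tiny_geo()
  years <- 1990:2010
  obs <- data.frame(indicator = "anc4", district = geo$districts$district[1],
                    province = geo$districts$province[1], year = 1997L,
                    source = "s", estimate = 0.5, variance = 0.01,
                    sample_size = 50, flag_floor = FALSE,
                    flag_split_adjusted = FALSE, stringsAsFactors = FALSE)
  class(obs) <- c("observation_set", "data.frame")
  # no floor configured for anc4: identity
  noop <- apply_prelaunch_floor(obs, c(itn = 1997), geo, years)
  expect_equal(nrow(noop), 1)
  expect_equal(noop$estimate, 0.5)
  # year exactly at the floor year is untouched
  out <- apply_prelaunch_floor(obs, c(anc4 = 1997), geo, years)
  expect_true(all(out$estimate[out$year == 1997] == 0.5))
})

test_that("optionally floors fill only missing pre-launch cells", {
  geo <- tiny_geo()
  obs <- data.frame(indicator = "itn", district = geo$districts$district[1],
                    province = geo$districts$province[1], year = 1995L,
                    source = "s", estimate = 0.3, variance = 0.01,
                    sample_size = 50, stringsAsFactors = FALSE)
  class(obs) <- c("observation_set", "data.frame")
  out <- apply_prelaunch_floor(obs, c(itn = 1997), geo, 1990:2010,
                               override = FALSE)
  kept <- out[out$district == geo$districts$district[1] & out$year == 1995, ]
  expect_equal(kept$estimate, 0.3)
})

test_that("the logit transform applies the delta method and boundary rules", {
  base <- data.frame(indicator = "x", district = "D", province = "P",
                     year = 2000L, source = "s", estimate = 0.5,
                     variance = 0.0025, sample_size = 100)
  lo <- to_logit(base)
  expect_equal(lo$logit, 0)
  expect_equal(lo$logit_var, 0.04, tolerance = 1e-12)

  zero <- transform(base, estimate = 0, variance = 0, sample_size = NA)
  expect_equal(to_logit(zero)$logit, log(1e-4 / (1 - 1e-4)), tolerance = 1e-4)
  expect_equal(round(to_logit(zero)$logit, 4), -9.2102)
  expect_equal(to_logit(zero)$logit_var, 1e-3)   # variance floor

  # degenerate sampled proportion: weakly informative binomial variance
  degen <- transform(base, estimate = 1, variance = 0, sample_size = 20)
  pstar <- 20.5 / 21
  expect_equal(to_logit(degen)$logit_var, 1 / (20 * pstar * (1 - pstar)),
               tolerance = 1e-12)

  expect_error(to_logit(base, eps = 0.5), "eps")
})

test_that("logit and inverse logit round-trip inside the clamped range", {
  p <- c(1e-4, 0.01, 0.37, 0.5, 0.73, 0.99, 1 - 1e-4)
  expect_equal(inv_logit(logit(p)), p, tolerance = 1e-12)
})
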