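# Smooth AR(1) shock series of length n, marginal sd `sd`, lag-1 corr `ar`.
ar1_series <- function(n, sd, ar) {
  if (sd == 0) return(numeric(n))
  e <- stats::rnorm(n)
  x <- numeric(n)
  x[1] <- e[1]
  if (n > 1) {
    w <- sqrt(1 - ar^2)
    for (t in 2:n) x[t] <- ar * x[t - 1] + w * e[t]
  }
  x * sd
}

# Generate true covariate surfaces: list of district x year matrices on the
# natural scale, plus the three extra socio-demographic series used by the
# SES composite (adult education, improved sanitation, improved cooking
# fuel).  hfpc (health facilities per 1,000 people) is time-constant.
generate_covariate_truth <- function(geo, years, shock_sd) {
  d <- geo$districts$district
  nd <- length(d)
  ny <- length(years)
  tc <- years - 2000

  mk <- function(fun) {
    m <- matrix(NA_real_, nd, ny, dimnames = list(d, years))
    for (i in seq_len(nd)) m[i, ] <- fun(i)
    m
  }

  a_elec <- stats::rnorm(nd, logit(0.15), 0.7)
  a_fhead <- stats::rnorm(nd, logit(0.25), 0.3)
  a_hh <- stats::rnorm(nd, log(5.2), 0.08)
  a_edu <- stats::rnorm(nd, 4.5, 0.8)
  a_wall <- stats::rnorm(nd, logit(0.3), 0.5)
  hfpc_d <- stats::rgamma(nd, shape = 2, scale = 0.15)
  a_san <- stats::rnorm(nd, logit(0.35), 0.6)
  a_fuel <- stats::rnorm(nd, logit(0.2), 0.6)

  list(
    elec = mk(function(i) inv_logit(a_elec[i] + 0.04 * tc + ar1_series(ny, shock_sd, 0.8))),
    fhead = mk(function(i) inv_logit(a_fhead[i] + ar1_series(ny, shock_sd, 0.8))),
    hhsize = mk(function(i) exp(a_hh[i] - 0.002 * tc + ar1_series(ny, shock_sd / 2, 0.8))),
    edu = mk(function(i) pmax(0, a_edu[i] + 0.06 * (tc + 10) + ar1_series(ny, shock_sd * 2, 0.8))),
    wall = mk(function(i) inv_logit(a_wall[i] + 0.03 * tc + ar1_series(ny, shock_sd, 0.8))),
    hfpc = mk(function(i) rep(hfpc_d[i], ny)),
    sanitation = mk(function(i) inv_logit(a_san[i] + 0.03 * tc + ar1_series(ny, shock_sd, 0.8))),
    fuel = mk(function(i) inv_logit(a_fuel[i] + 0.025 * tc + ar1_series(ny, shock_sd, 0.8))),
    edu_adult = mk(function(i) pmax(0, a_edu[i] + 0.5 + 0.05 * (tc + 10) + ar1_series(ny, shock_sd * 2, 0.8)))
  )
}

#' Generate true coverage surfaces with known generating parameters
#'
#' Constructs the synthetic ground truth: true district-year coverage for
#' every indicator in the scenario, built *from* the stage-1 regression
#' equation — a known coefficient vector applied to known covariate surfaces
#' and a province-level indicator series — plus smooth AR(1) shocks at
#' province and district level, inverse-logit transformed.  Vertical
#' indicators are overridden to 0.0001 coverage strictly before their launch
#' year, mirroring the assumption that nationally coordinated programs had
#' essentially no reach before launch.
#'
#' @param geo a [generate_geography()] map.
#' @param scenario a [default_scenario()] list (its `years` define the frame).
#' @param seed integer seed.
#' @return object of class `synthetic_truth`: list with
#'   \describe{
#'     \item{p}{3-d array indicator x district x year of true coverage in (0,1).}
#'     \item{eta}{the logit-scale linear predictor (before any pre-launch override).}
#'     \item{province_series}{array indicator x province x year of true
#'       province-level coverage (the `Ind` covariate), proportion scale.}
#'     \item{covariates}{list of district x year matrices (natural scale).}
#'     \item{beta}{indicator x 9 matrix of generating coefficients
#'       (intercept, centred year, elec, fhead, hhsize, edu, wall, hfpc,
#'       province indicator).}
#'     \item{launch}{named vector of launch years (NA for routine).}
#'   }
#' @export
generate_truth <- function(geo, scenario = default_scenario(), seed = 1L) {
  validate_geography(geo)
  years <- scenario$years
  ind <- scenario$indicators
  if (any(!is.na(ind$launch) & (ind$launch < min(years) | ind$launch > max(years)))) {
    stop("launch years must fall inside the scenario year range", call. = FALSE)
  }

  with_seed(seed, {
    d <- geo$districts$district
    prov <- geo$provinces
    nd <- length(d)
    np <- length(prov)
    ny <- length(years)
    ni <- nrow(ind)
    tc <- years - 2000
    prov_of_d <- geo$districts$province

    covs <- generate_covariate_truth(geo, years, scenario$covariate_shock_sd)

    bc <- scenario$beta_common
    beta <- matrix(NA_real_, ni, 9, dimnames = list(
      ind$indicator,
      c("intercept", "year_c", "elec", "fhead", "hhsize", "edu", "wall",
        "hfpc", "prov_ind")
    ))

    p <- array(NA_real_, c(ni, nd, ny), dimnames = list(ind$indicator, d, years))
    eta <- p
    ps <- array(NA_real_, c(ni, np, ny), dimnames = list(ind$indicator, prov, years))

    sh <- scenario$shocks
    cov_ref <- scenario$cov_ref
    for (j in seq_len(ni)) {
      # anchor the intercept so a district with reference covariates and the
      # baseline province curve sits at `level_logit` (at 2000 for routine
      # indicators, at launch for vertical ones)
      tc_ref <- if (ind$type[j] == "vertical") ind$launch[j] - 2000 else 0
      prov_ref <- if (ind$type[j] == "vertical") {
        inv_logit(ind$prov_lo[j])
      } else {
        inv_logit(ind$prov_base[j])
      }
      intercept <- ind$level_logit[j] - ind$beta1[j] * tc_ref -
        sum(bc[names(cov_ref)] * cov_ref) - bc["prov_ind"] * prov_ref
      beta[j, ] <- c(intercept, ind$beta1[j], bc)

      # province-level indicator curve (logit scale), then proportion
      off <- stats::rnorm(np, 0, 0.2)
      for (k in seq_len(np)) {
        g <- if (ind$type[j] == "vertical") {
          mid <- ind$launch[j] + ind$prov_mid_lag[j]
          ind$prov_lo[j] + (ind$prov_hi[j] - ind$prov_lo[j]) *
            stats::plogis(ind$prov_rate[j] * (years - mid))
        } else {
          ind$prov_base[j] + ind$prov_trend[j] * tc + ind$prov_curv[j] * tc^2
        }
        g <- g + off[k] + ar1_series(ny, sh$province_sd, sh$ar)
        ps[j, k, ] <- inv_logit(g)
      }

      for (i in seq_len(nd)) {
        k <- match(prov_of_d[i], prov)
        lin <- beta[j, "intercept"] +
          beta[j, "year_c"] * tc +
          bc["elec"] * covs$elec[i, ] +
          bc["fhead"] * covs$fhead[i, ] +
          bc["hhsize"] * covs$hhsize[i, ] +
          bc["edu"] * covs$edu[i, ] +
          bc["wall"] * covs$wall[i, ] +
          bc["hfpc"] * covs$hfpc[i, ] +
          bc["prov_ind"] * ps[j, k, ]
        lin <- lin + ar1_series(ny, sh$district_sd, sh$ar)
        eta[j, i, ] <- lin
        pij <- inv_logit(lin)
        if (ind$type[j] == "vertical") {
          pij[years < ind$launch[j]] <- 1e-4
        }
        p[j, i, ] <- clamp(pij, 1e-6, 1 - 1e-6)
      }
    }

    structure(
      list(
        p = p, eta = eta, province_series = ps, covariates = covs,
        beta = beta,
        launch = stats::setNames(ind$launch, ind$indicator),
        years = years, geo = geo, scenario = scenario, seed = seed
      ),
      class = "synthetic_truth"
    )
  })
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat(sprintf("<synthetic_truth> %d indicators x %d districts x %d years (seed %d)\n",
              dim(x$p)[1], dim(x$p)[2], dim(x$p)[3], x$seed))
  invisible(x)
}

#' True coverage as a long data.frame
#'
#' @param truth a [generate_truth()] object.
#' @return data.frame with columns indicator, district, province, year, p.
#' @export
truth_long <- function(truth) {
  dn <- dimnames(truth$p)
  out <- expand.grid(indicator = dn[[1]], district = dn[[2]],
                     year = as.integer(dn[[3]]),
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out$province <- province_of(truth$geo)[out$district]
  out$p <- as.vector(truth$p)
  out
}
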