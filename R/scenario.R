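#' Default synthetic study scenario
#'
#' Describes the indicator roster, generating coefficients and shock scales
#' used by [generate_truth()].  The default emulates a national maternal and
#' child health study: 12 indicators over 1990--2010 in three groups —
#' four malaria-control interventions (vertical programs launched in 1997,
#' with near-zero coverage before launch), four immunizations (three routine,
#' plus a pentavalent vaccine launched in 2004), and four routine
#' mother-and-child services with stagnating or declining trends (antenatal
#' care with four visits, skilled birth attendance) or steady improvement
#' (exclusive breastfeeding, children not underweight).
#'
#' Vertical indicators scale up through a logistic province-level curve;
#' routine indicators follow a quadratic logit-space trend.  District truth
#' is generated from the stage-1 regression equation itself (known
#' coefficients on known covariate surfaces plus the province indicator
#' series) plus smooth AR(1) shocks at province and district level, so that
#' coefficient recovery is well-posed.
#'
#' @param years integer vector of study years.
#' @param district_shock_sd,province_shock_sd standard deviations (logit
#'   units) of the smooth AR(1) shocks added to the linear predictor.
#' @param ar lag-1 autocorrelation of the shock series.
#' @param covariate_shock_sd standard deviation of the smooth shocks in the
#'   covariate surfaces (on each covariate's transformed scale).
#' @return a list of class `coverage_scenario` with elements `years`,
#'   `indicators` (per-indicator data.frame), `beta_common` (shared slopes on
#'   the six socio-demographic covariates and the province indicator term),
#'   `shocks`, and `covariate_shock_sd`.
#' @export
default_scenario <- function(years = 1990:2010,
                             district_shock_sd = 0.3,
                             province_shock_sd = 0.15,
                             ar = 0.8,
                             covariate_shock_sd = 0.05) {
  ind <- data.frame(
    indicator = c("itn", "irs", "iptp2", "itn_or_irs",
                  "bcg", "measles", "polio", "penta",
                  "anc4", "sba", "ebf", "not_underweight"),
    group = c(rep("malaria", 4), rep("vaccine", 4), rep("mch", 4)),
    type = c(rep("vertical", 4), "routine", "routine", "routine", "vertical",
             rep("routine", 4)),
    launch = c(1997, 1997, 1997, 1997, NA, NA, NA, 2004, NA, NA, NA, NA),
    # typical district logit level: at 2000 for routine indicators, at the
    # launch year for vertical ones (the intercept is derived from it)
    level_logit = logit(c(0.05, 0.04, 0.05, 0.06,
                          0.87, 0.82, 0.80, 0.06,
                          0.55, 0.45, 0.35, 0.75)),
    beta1 = c(0, 0, 0, 0,
              0.01, 0.005, -0.02, 0,
              -0.025, -0.01, 0.05, 0.02),
    # province indicator curve (logit scale): vertical = logistic rise from
    # `prov_lo` to `prov_hi` at `prov_rate` centred `prov_mid_lag` years after
    # launch; routine = prov_base + prov_trend * (t - 2000) + prov_curv * (...)^2
    prov_lo = logit(c(0.02, 0.02, 0.02, 0.02, rep(NA, 3), 0.02, rep(NA, 4))),
    prov_hi = logit(c(0.85, 0.6, 0.75, 0.9, rep(NA, 3), 0.7, rep(NA, 4))),
    prov_rate = c(0.55, 0.5, 0.5, 0.55, rep(NA, 3), 0.9, rep(NA, 4)),
    prov_mid_lag = c(6, 7, 7, 6, rep(NA, 3), 3, rep(NA, 4)),
    prov_base = c(rep(NA, 4), logit(0.85), logit(0.8), logit(0.7), NA,
                  logit(0.55), logit(0.45), logit(0.35), logit(0.75)),
    prov_trend = c(rep(NA, 4), 0.01, 0.005, -0.03, NA, -0.035, -0.015, 0.09, 0.02),
    prov_curv = c(rep(NA, 4), 0, 0, -0.001, NA, -0.0012, -0.0008, 0.001, 0),
    stringsAsFactors = FALSE
  )
  structure(
    list(
      years = as.integer(years),
      indicators = ind,
      beta_common = c(elec = 0.8, fhead = -0.3, hhsize = -0.05, edu = 0.06,
                      wall = 0.4, hfpc = 0.5, prov_ind = 5),
      # reference covariate values at which `level_logit` is anchored; the
      # generating intercept is level_logit minus the reference contributions
      cov_ref = c(elec = 0.2, fhead = 0.25, hhsize = 5.2, edu = 5,
                  wall = 0.3, hfpc = 0.3),
      shocks = list(district_sd = district_shock_sd,
                    province_sd = province_shock_sd, ar = ar),
      covariate_shock_sd = covariate_shock_sd
    ),
    class = "coverage_scenario"
  )
}

#' @export
print.coverage_scenario <- function(x, ...) {
  cat(sprintf("<coverage_scenario> %d indicators, years %d-%d\n",
              nrow(x$indicators), min(x$years), max(x$years)))
  print(x$indicators[, c("indicator", "group", "type", "launch")])
  invisible(x)
}

#' Default composite-coverage component set
#'
#' The ten priority interventions whose simple average defines composite
#' coverage: combined vector control (ITN ownership or IRS), two-dose
#' intermittent preventive therapy in pregnancy, exclusive breastfeeding,
#' pentavalent, BCG, measles and polio immunization, four or more antenatal
#' visits, skilled birth attendance, and children not underweight.
#'
#' @return character vector of 10 indicator ids.
#' @export
composite_components <- function() {
  c("itn_or_irs", "iptp2", "ebf", "penta", "bcg", "measles", "polio",
    "anc4", "sba", "not_underweight")
}
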