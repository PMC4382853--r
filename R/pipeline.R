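#' Floor years implied by a scenario
#'
#' Vertical indicators are assumed to have 0.01% coverage strictly before
#' their launch year.
#'
#' @param scenario a [default_scenario()].
#' @return named vector indicator -> floor year (vertical indicators only).
#' @export
launch_floor_years <- function(scenario) {
  ind <- scenario$indicators
  stats::setNames(ind$launch, ind$indicator)[ind$type == "vertical"]
}

#' Simulate a complete synthetic study
#'
#' Generates the geography, ground truth, populations, survey plan and noisy
#' observations; re-expresses pre-2000 survey records on the old (pre-split)
#' geography; adds administrative spray records; then applies the analysis
#' preprocessing (split harmonization, pre-launch floors).  The result is
#' ready for [run_stgpr()].
#'
#' @param seed integer seed driving every stochastic step.
#' @param scenario a [default_scenario()].
#' @param n_provinces,n_districts,n_split_parents geography shape (defaults
#'   9 provinces, 72 districts, 15 split parents — the old geography has 57).
#' @param n_eff,depth,deff survey plan parameters (see
#'   [default_survey_plan()]).
#' @param admin_irs include administrative spray-count records for the IRS
#'   indicator.
#' @param harmonize apply split harmonization + floors (set FALSE to get the
#'   raw recoded observations).
#' @return list: `geo`, `truth`, `pop`, `plan`, `obs_raw` (as sampled, new
#'   geography), `obs` (preprocessed, analysis-ready), `scenario`.
#' @export
simulate_study <- function(seed = 1L, scenario = default_scenario(),
                           n_provinces = 9, n_districts = 72,
                           n_split_parents = 15,
                           n_eff = 100, depth = 4, deff = 1.5,
                           admin_irs = TRUE, harmonize = TRUE) {
  geo <- generate_geography(n_provinces, n_districts, n_split_parents,
                            seed = derive_seed(seed, 1))
  truth <- generate_truth(geo, scenario, seed = derive_seed(seed, 2))
  pop <- generate_population(geo, seed = derive_seed(seed, 3))
  plan <- default_survey_plan(geo, scenario, n_eff = n_eff, depth = depth,
                              deff = deff)
  obs_raw <- sample_observations(truth, plan, seed = derive_seed(seed, 4))

  obs <- recode_to_old_geography(obs_raw, geo, cutoff_year = 2000)

  if (admin_irs && "irs" %in% scenario$indicators$indicator) {
    admin <- generate_admin_irs(truth, pop, noise = 0.2,
                                seed = derive_seed(seed, 5))
    irs_obs <- suppressWarnings(compute_irs_coverage(admin))
    irs_obs$province <- province_of(geo)[irs_obs$district]
    launch <- truth$launch[["irs"]]
    if (!is.na(launch)) irs_obs <- irs_obs[irs_obs$year >= launch, ]
    obs <- rbind(as.data.frame(obs), as.data.frame(irs_obs)[, names(obs)])
    class(obs) <- c("observation_set", "data.frame")
  }

  if (harmonize) {
    obs <- suppressWarnings(
      harmonize_districts(obs, geo, reference_window = 2000:2010)
    )
    obs <- apply_prelaunch_floor(obs, launch_floor_years(scenario), geo,
                                 scenario$years)
  }

  list(geo = geo, truth = truth, pop = pop, plan = plan,
       obs_raw = obs_raw, obs = obs, scenario = scenario)
}

#' One simulation-calibration replicate
#'
#' Simulates a study, runs the three-stage estimator, and scores the result
#' against the known truth: empirical coverage of the 95% uncertainty
#' interval over all indicator-district-year cells, and mean absolute error
#' of each modeling stage (stage-1 linear prediction, stage-1 + spatial-
#' temporal smoothing, final Gaussian process estimate), on the coverage
#' scale.
#'
#' @param seed replicate seed.
#' @param n_draws posterior draws per replicate.
#' @param scenario study scenario.
#' @param ... passed to [simulate_study()].
#' @return list with `coverage` (fraction of cells whose truth falls inside
#'   the 95% UI), `mae_stage1`, `mae_stage2`, `mae_stage3`, `n_cells`.
#' @export
calibration_replicate <- function(seed, n_draws = 200,
                                  scenario = default_scenario(), ...) {
  study <- simulate_study(seed = seed, scenario = scenario, ...)
  res <- estimate_study(study, gpr = gpr_config(n_draws = n_draws),
                        seed = derive_seed(seed, 99))
  tp <- study$truth$p
  s <- res$summary
  tl <- truth_long(study$truth)
  m <- match(paste(s$indicator, s$district, s$year),
             paste(tl$indicator, tl$district, tl$year))
  truth_v <- tl$p[m]
  stage_mae <- function(mats) {
    mean(vapply(names(mats), function(i) {
      mean(abs(inv_logit(mats[[i]]) - tp[i, , ]))
    }, 0))
  }
  list(
    coverage = mean(truth_v >= s$lower & truth_v <= s$upper),
    mae_stage1 = stage_mae(lapply(res$stage1, `[[`, "fitted")),
    mae_stage2 = stage_mae(lapply(res$surfaces, `[[`, "mean")),
    mae_stage3 = mean(abs(s$mean - truth_v)),
    n_cells = length(truth_v)
  )
}

#' Estimate coverage for a simulated study
#'
#' Runs the three-stage estimator on a [simulate_study()] result,
#' conditioning on the true covariate surfaces and true province indicator
#' series (covariates enter stage 1 as point values; the covariate
#' completion model is exercised separately).
#'
#' @param study a [simulate_study()] list.
#' @param st an [st_config()].
#' @param gpr a [gpr_config()].
#' @param seed draw seed (defaults to the study's structure).
#' @return an `stgpr_result` (see [run_stgpr()]).
#' @export
estimate_study <- function(study, st = st_config(), gpr = gpr_config(),
                           seed = 1L) {
  run_stgpr(study$obs, study$truth$covariates, study$truth$province_series,
            study$geo, study$scenario$years, st = st, gpr = gpr, seed = seed)
}
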