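#' Default multi-source survey plan
#'
#' Emulates the cadence of national household surveys: periodic surveys, each
#' measuring a subset of indicators in every district with modest effective
#' sample sizes, a design-effect inflation, and retrospective birth-history
#' depth (a survey in year T contributes observations for years T-depth .. T,
#' with its per-district sample split across birth-years).
#'
#' @param geo geography map.
#' @param scenario study scenario (for the indicator roster and year range).
#' @param n_eff per-district effective sample size per survey.
#' @param depth retrospective depth in years (0--5).
#' @param deff design-effect multiplier (>= 1).
#' @return data.frame of class `survey_plan`: one row per
#'   (source, indicator, district) with columns `source`, `survey_year`,
#'   `indicator`, `district`, `n_eff`, `depth`, `deff`.
#' @export
default_survey_plan <- function(geo, scenario = default_scenario(),
                                n_eff = 100, depth = 4, deff = 1.5) {
  stopifnot(depth >= 0, depth <= 5, deff >= 1, n_eff >= 1)
  ind <- scenario$indicators$indicator
  mal <- scenario$indicators$indicator[scenario$indicators$group == "malaria"]
  surveys <- list(
    dhs1992 = list(year = 1992, ind = setdiff(ind, c(mal, "penta"))),
    dhs1996 = list(year = 1996, ind = setdiff(ind, c(mal, "penta"))),
    mics1999 = list(year = 1999, ind = setdiff(ind, c(mal, "penta"))),
    lcms2002 = list(year = 2002, ind = setdiff(ind, c(mal, "penta"))),
    lcms2004 = list(year = 2004, ind = setdiff(ind, mal)),
    mis2006 = list(year = 2006, ind = ind),
    dhs2007 = list(year = 2007, ind = ind),
    mis2008 = list(year = 2008, ind = ind),
    mis2010 = list(year = 2010, ind = ind)
  )
  rows <- lapply(names(surveys), function(s) {
    expand.grid(source = s, survey_year = surveys[[s]]$year,
                indicator = surveys[[s]]$ind,
                district = geo$districts$district,
                KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  })
  plan <- do.call(rbind, rows)
  plan$n_eff <- n_eff
  plan$depth <- as.integer(depth)
  plan$deff <- deff
  class(plan) <- c("survey_plan", "data.frame")
  plan
}

#' Draw noisy sparse survey observations from the truth
#'
#' For each planned (source, indicator, district) cell, the survey year T
#' yields one observation per year T-depth .. T (intersected with the study
#' years), with the effective sample size split evenly across birth-years.
#' Observed proportions are binomial draws at that size; the reported
#' sampling variance is `phat * (1 - phat) / n` inflated by the design
#' effect.  Cells not in the plan are absent, giving the sparsity the
#' downstream model must handle.
#'
#' @param truth a [generate_truth()] object.
#' @param plan a [default_survey_plan()] data.frame.
#' @param seed integer seed.
#' @param exact if TRUE, observations equal the truth exactly with zero
#'   reported variance (the infinite-sample limit), used for recovery tests.
#' @return data.frame (class `observation_set`) with columns `indicator`,
#'   `district`, `province`, `year`, `source`, `estimate`, `variance`,
#'   `sample_size`.
#' @export
sample_observations <- function(truth, plan, seed = 1L, exact = FALSE) {
  d_ok <- plan$district %in% truth$geo$districts$district
  if (!all(d_ok)) {
    stop("plan references unknown districts: ",
         paste(unique(plan$district[!d_ok]), collapse = ", "), call. = FALSE)
  }
  i_ok <- plan$indicator %in% dimnames(truth$p)[[1]]
  if (!all(i_ok)) {
    stop("plan references unknown indicators: ",
         paste(unique(plan$indicator[!i_ok]), collapse = ", "), call. = FALSE)
  }

  years <- truth$years
  prov <- province_of(truth$geo)

  with_seed(seed, {
    # expand plan rows to retrospective years
    reps <- plan$depth + 1L
    idx <- rep(seq_len(nrow(plan)), reps)
    off <- unlist(lapply(plan$depth, function(k) k:0))
    yr <- plan$survey_year[idx] - off
    keep <- yr %in% years
    idx <- idx[keep]; yr <- yr[keep]

    n <- pmax(1, round(plan$n_eff[idx] / reps[idx]))
    p <- truth$p[cbind(match(plan$indicator[idx], dimnames(truth$p)[[1]]),
                       match(plan$district[idx], dimnames(truth$p)[[2]]),
                       match(yr, years))]
    if (exact) {
      phat <- p
      v <- rep(0, length(p))
      n <- rep(Inf, length(p))
    } else {
      x <- stats::rbinom(length(p), n, p)
      phat <- x / n
      v <- phat * (1 - phat) / n * plan$deff[idx]
    }

    out <- data.frame(
      indicator = plan$indicator[idx],
      district = plan$district[idx],
      province = unname(prov[plan$district[idx]]),
      year = as.integer(yr),
      source = plan$source[idx],
      estimate = phat,
      variance = v,
      sample_size = n,
      stringsAsFactors = FALSE
    )
    out <- out[order(out$indicator, out$district, out$year, out$source), ]
    rownames(out) <- NULL
    class(out) <- c("observation_set", "data.frame")
    out
  })
}

#' Exact saturated observations of the truth
#'
#' One noise-free observation per indicator-district-year cell (the
#' infinite-sample limit: estimate equals the truth, reported variance 0).
#' Used for recovery and end-to-end identity checks.
#'
#' @param truth a [generate_truth()] object.
#' @param indicators subset of indicator ids (default all).
#' @return an `observation_set`.
#' @export
saturated_observations <- function(truth, indicators = dimnames(truth$p)[[1]]) {
  prov <- province_of(truth$geo)
  keys <- expand.grid(indicator = indicators,
                      district = dimnames(truth$p)[[2]],
                      year = as.integer(truth$years),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out <- data.frame(
    keys[, c("indicator", "district")],
    province = unname(prov[keys$district]),
    year = keys$year,
    source = "exact",
    estimate = truth$p[cbind(match(keys$indicator, dimnames(truth$p)[[1]]),
                             match(keys$district, dimnames(truth$p)[[2]]),
                             match(keys$year, truth$years))],
    variance = 0,
    sample_size = Inf,
    stringsAsFactors = FALSE
  )
  class(out) <- c("observation_set", "data.frame")
  out
}

#' Simulate administrative spray-count reports
#'
#' Converts true IRS coverage into reported counts of structures sprayed:
#' `round(true coverage x households x lognormal noise)`, and zero strictly
#' before the program launch year.  The lognormal noise has mean 1 and
#' coefficient of variation approximately `noise`.
#'
#' @param truth a [generate_truth()] object containing an `irs` indicator.
#' @param pop a [generate_population()] table (household anchors are
#'   interpolated geometrically to all years).
#' @param noise relative error of the reports (0 disables noise).
#' @param indicator id of the spray indicator in the truth (default "irs").
#' @param seed integer seed.
#' @return data.frame district, year, sprayed, households.
#' @export
generate_admin_irs <- function(truth, pop, noise = 0.2, indicator = "irs",
                               seed = 1L) {
  if (!indicator %in% dimnames(truth$p)[[1]]) {
    stop(sprintf("indicator '%s' not present in truth", indicator), call. = FALSE)
  }
  hh <- interpolate_population(pop, truth$years)
  launch <- truth$launch[[indicator]]

  with_seed(seed, {
    key <- expand.grid(district = dimnames(truth$p)[[2]],
                       year = truth$years,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    key$households <- hh$households[match(paste(key$district, key$year),
                                          paste(hh$district, hh$year))]
    p <- truth$p[cbind(match(indicator, dimnames(truth$p)[[1]]),
                       match(key$district, dimnames(truth$p)[[2]]),
                       match(key$year, truth$years))]
    mult <- if (noise > 0) {
      exp(stats::rnorm(nrow(key), -noise^2 / 2, noise))
    } else {
      rep(1, nrow(key))
    }
    key$sprayed <- round(p * key$households * mult)
    if (!is.na(launch)) key$sprayed[key$year < launch] <- 0
    key
  })
}

#' Re-express post-split observations on the old geography
#'
#' Observations strictly before `cutoff_year` that refer to inheriting
#' districts of a split parent are aggregated back to the parent district by
#' a precision-weighted mean (weights 1/variance; equal weights when all
#' variances vanish), with the combined variance `1 / sum(1/variance)`.
#' Later observations are untouched.  Emulates surveys that sampled under
#' the pre-split administrative boundaries.
#'
#' @param obs an `observation_set`.
#' @param geo geography map.
#' @param cutoff_year observations with `year < cutoff_year` are recoded.
#' @return an `observation_set` whose pre-cutoff rows carry parent ids.
#' @export
recode_to_old_geography <- function(obs, geo, cutoff_year = 2000) {
  if (nrow(geo$splits) == 0) return(obs)
  pre <- obs$year < cutoff_year & obs$district %in% geo$splits$district
  if (!any(pre)) return(obs)

  parent_of <- stats::setNames(geo$splits$parent, geo$splits$district)
  sub <- obs[pre, ]
  sub$parent <- parent_of[sub$district]
  grp <- interaction(sub$indicator, sub$parent, sub$year, sub$source, drop = TRUE)

  agg <- lapply(split(sub, grp), function(g) {
    w <- if (all(g$variance > 0)) 1 / g$variance else rep(1, nrow(g))
    data.frame(
      indicator = g$indicator[1],
      district = g$parent[1],
      province = g$province[1],
      year = g$year[1],
      source = g$source[1],
      estimate = sum(w * g$estimate) / sum(w),
      variance = if (all(g$variance > 0)) 1 / sum(w) else 0,
      sample_size = sum(g$sample_size),
      stringsAsFactors = FALSE
    )
  })
  out <- rbind(obs[!pre, ], do.call(rbind, agg))
  out <- out[order(out$indicator, out$district, out$year, out$source), ]
  rownames(out) <- NULL
  class(out) <- class(obs)
  out
}
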