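#' Geometric interpolation of household (or population) counts
#'
#' Counts between consecutive census anchors (a, Ha) and (b, Hb) grow
#' geometrically: `H_t = Ha * (Hb/Ha)^((t-a)/(b-a))`.  Outside the anchor
#' range the nearest segment's growth rate is extrapolated.  Anchor years are
#' reproduced exactly.
#'
#' @param anchors a two-column data.frame (year, count) with at least two
#'   rows, strictly increasing years, positive counts.
#' @param years integer years wanted; defaults to every year spanned by the
#'   anchors.
#' @return data.frame with columns `year`, `count`.
#' @examples
#' interpolate_households(data.frame(year = c(1990, 2000),
#'                                   count = c(1000, 2000)))
#' @export
interpolate_households <- function(anchors, years = NULL) {
  a_year <- as.numeric(anchors[[1]])
  a_cnt <- as.numeric(anchors[[2]])
  if (length(a_year) < 2) stop("need at least two anchors", call. = FALSE)
  if (any(diff(a_year) <= 0)) stop("anchor years must be strictly increasing", call. = FALSE)
  if (any(a_cnt <= 0)) stop("anchor counts must be positive", call. = FALSE)
  if (is.null(years)) years <- seq(min(a_year), max(a_year))

  # log-linear interpolation == geometric growth; extrapolate nearest segment
  n <- length(a_year)
  interp <- stats::approx(a_year, log(a_cnt), xout = years, rule = 1)$y
  lo <- years < a_year[1]
  hi <- years > a_year[n]
  if (any(lo)) {
    r1 <- (log(a_cnt[2]) - log(a_cnt[1])) / (a_year[2] - a_year[1])
    interp[lo] <- log(a_cnt[1]) + r1 * (years[lo] - a_year[1])
  }
  if (any(hi)) {
    rn <- (log(a_cnt[n]) - log(a_cnt[n - 1])) / (a_year[n] - a_year[n - 1])
    interp[hi] <- log(a_cnt[n]) + rn * (years[hi] - a_year[n])
  }
  data.frame(year = as.integer(years), count = exp(interp))
}

#' IRS coverage from administrative spray counts
#'
#' Divides reported structures sprayed by the (interpolated) number of
#' households in each district-year.  Ratios above the cap are truncated
#' with a warning (administrative numerators can exceed census-derived
#' denominators).  Administrative reports carry no design-based variance, so
#' a fixed logit-space variance is assigned and stored on the proportion
#' scale via the delta method, ready for [to_logit()].
#'
#' @param admin data.frame district, year, sprayed (and optionally
#'   households).
#' @param households data.frame district, year, households; ignored if
#'   `admin` already carries a `households` column.
#' @param cap maximum admissible coverage (default 0.99).
#' @param logit_var fixed logit-space variance for administrative records.
#' @param eps boundary offset used in the variance transform.
#' @param source source label for the produced records.
#' @return an `observation_set` of IRS records.
#' @export
compute_irs_coverage <- function(admin, households = NULL, cap = 0.99,
                                 logit_var = 0.1, eps = 1e-4,
                                 source = "admin_irs") {
  df <- admin
  if (is.null(df$households)) {
    key <- paste(df$district, df$year)
    hkey <- paste(households$district, households$year)
    df$households <- households$households[match(key, hkey)]
  }
  if (any(is.na(df$households))) {
    miss <- df[is.na(df$households), c("district", "year")]
    stop("missing household denominator for: ",
         paste(paste(miss$district, miss$year), collapse = ", "), call. = FALSE)
  }
  if (any(df$sprayed < 0)) stop("negative sprayed counts", call. = FALSE)

  ratio <- df$sprayed / df$households
  over <- ratio > cap
  if (any(over)) {
    warning(sprintf("%d spray ratios exceed %g and were capped", sum(over), cap))
    ratio[over] <- cap
  }
  pc <- clamp(ratio, eps, 1 - eps)
  out <- data.frame(
    indicator = "irs",
    district = df$district,
    province = if (!is.null(df$province)) df$province else NA_character_,
    year = as.integer(df$year),
    source = source,
    estimate = ratio,
    variance = logit_var * (pc * (1 - pc))^2,
    sample_size = NA_real_,
    stringsAsFactors = FALSE
  )
  class(out) <- c("observation_set", "data.frame")
  out
}

#' Harmonize pre-split observations onto the new district geography
#'
#' Observations made on the old (pre-split) geography carry parent district
#' ids.  For each inheriting district d of parent P, a reference ratio
#' `r_d` is computed per indicator as the mean over reference-window years of
#' `estimate_d / parent-level estimate`, where the parent-level estimate is
#' the population-share-weighted mean over the inheritors observed that
#' year.  Each parent record is then replaced by one record per inheritor
#' with estimate `clip(estimate * r_d, 0, 0.99)` and variance inflated by
#' `inflation`.  Inheritors with no usable reference data get `r_d = 1`.
#'
#' @param obs an `observation_set` (may mix old and new district ids).
#' @param geo geography map.
#' @param reference_window years used to estimate the ratios (default
#'   2000:2010).
#' @param inflation variance inflation factor on split-adjusted records.
#' @return an `observation_set` entirely on the new geography, with a
#'   logical `flag_split_adjusted` column.
#' @export
harmonize_districts <- function(obs, geo, reference_window = 2000:2010,
                                inflation = 1.5) {
  known <- c(geo$districts$district, unique(geo$districts$parent))
  if (!all(obs$district %in% known)) {
    stop("observations on unknown district ids: ",
         paste(setdiff(unique(obs$district), known), collapse = ", "),
         call. = FALSE)
  }
  if (is.null(obs$flag_split_adjusted)) obs$flag_split_adjusted <- FALSE
  split_parents <- unique(geo$splits$parent)
  is_parent <- obs$district %in% split_parents
  if (!any(is_parent)) return(obs)

  prov <- province_of(geo)

  # reference ratios per (indicator, inheritor): mean of yearly ratios
  ref <- obs[!is_parent & obs$year %in% reference_window &
               obs$district %in% geo$splits$district, ]
  ratio_of <- function(indic, dd) {
    parent <- geo$splits$parent[match(dd, geo$splits$district)]
    sibs <- geo$splits$district[geo$splits$parent == parent]
    shares <- stats::setNames(geo$splits$share, geo$splits$district)[sibs]
    sub <- ref[ref$indicator == indic & ref$district %in% sibs, ]
    if (nrow(sub) == 0 || !dd %in% sub$district) return(1)
    # cell means per (district, year), then parent-level share-weighted mean
    # over years where every inheritor is observed
    cell <- stats::aggregate(estimate ~ district + year, data = sub, FUN = mean)
    ratios <- c()
    for (y in unique(cell$year)) {
      cy <- cell[cell$year == y, ]
      if (!all(sibs %in% cy$district)) next
      parent_est <- sum(shares[cy$district] * cy$estimate) / sum(shares[cy$district])
      if (parent_est <= 0) next
      ratios <- c(ratios, cy$estimate[cy$district == dd] / parent_est)
    }
    if (length(ratios) == 0) 1 else mean(ratios)
  }

  sub <- obs[is_parent, ]
  # cache ratios per (indicator, inheritor)
  ratio_cache <- new.env(parent = emptyenv())
  cached_ratio <- function(indic, dd) {
    key <- paste(indic, dd)
    if (is.null(ratio_cache[[key]])) ratio_cache[[key]] <- ratio_of(indic, dd)
    ratio_cache[[key]]
  }
  rows <- vector("list", nrow(sub))
  clipped <- 0L
  for (r in seq_len(nrow(sub))) {
    parent <- sub$district[r]
    inh <- geo$splits[geo$splits$parent == parent, ]
    est <- numeric(nrow(inh))
    for (q in seq_len(nrow(inh))) {
      rd <- cached_ratio(sub$indicator[r], inh$district[q])
      e <- sub$estimate[r] * rd
      if (e > 1) { clipped <- clipped + 1L; e <- 0.99 }
      est[q] <- max(0, e)
    }
    rows[[r]] <- data.frame(
      indicator = sub$indicator[r],
      district = inh$district,
      province = unname(prov[inh$district]),
      year = sub$year[r],
      source = sub$source[r],
      estimate = est,
      variance = sub$variance[r] * inflation,
      sample_size = sub$sample_size[r],
      flag_split_adjusted = TRUE,
      stringsAsFactors = FALSE
    )
  }
  if (clipped > 0) {
    warning(sprintf("%d split-adjusted estimates exceeded 1 and were clipped to 0.99",
                    clipped))
  }
  out <- rbind(obs[!is_parent, ], do.call(rbind, rows))
  out <- out[order(out$indicator, out$district, out$year, out$source), ]
  rownames(out) <- NULL
  class(out) <- c("observation_set", "data.frame")
  out
}

#' Pre-launch coverage floors
#'
#' Nationally coordinated programs (malaria control from 1997, pentavalent
#' immunization from 2004) had essentially no reach before launch, so
#' coverage of 0.01% is assumed for every district-year strictly before the
#' floor year.  By default existing pre-launch observations are overridden
#' (the assumption is a blanket one); with `override = FALSE` only missing
#' cells are filled.
#'
#' @param obs an `observation_set`.
#' @param launch_years named vector/list mapping indicator id to floor year;
#'   indicators absent from it are untouched.
#' @param geo geography map (defines the district frame for insertion).
#' @param years study years (defines the year frame).
#' @param floor_value the assumed coverage (default 1e-4, i.e. 0.01%).
#' @param floor_logit_var fixed logit-space variance attached to floor
#'   records (stored on the proportion scale via the delta method).
#' @param override replace observed pre-launch records too (default TRUE).
#' @param eps boundary offset for the variance transform.
#' @return an `observation_set` with a logical `flag_floor` column; the
#'   operation is idempotent.
#' @export
apply_prelaunch_floor <- function(obs, launch_years, geo, years,
                                  floor_value = 1e-4, floor_logit_var = 0.01,
                                  override = TRUE, eps = 1e-4) {
  if (is.null(obs$flag_floor)) obs$flag_floor <- FALSE
  if (is.null(obs$flag_split_adjusted)) obs$flag_split_adjusted <- FALSE
  prov <- province_of(geo)
  pc <- clamp(floor_value, eps, 1 - eps)
  fvar <- floor_logit_var * (pc * (1 - pc))^2

  for (indic in names(launch_years)) {
    fy <- launch_years[[indic]]
    if (is.na(fy) || !indic %in% obs$indicator) next
    pre_years <- years[years < fy]
    if (length(pre_years) == 0) next
    drop <- obs$indicator == indic & obs$year < fy
    if (override) {
      obs <- obs[!drop, ]
    }
    have <- unique(paste(obs$district[obs$indicator == indic & obs$year < fy],
                         obs$year[obs$indicator == indic & obs$year < fy]))
    grid <- expand.grid(district = geo$districts$district, year = pre_years,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    grid <- grid[!paste(grid$district, grid$year) %in% have, ]
    if (nrow(grid) == 0) next
    add <- data.frame(
      indicator = indic,
      district = grid$district,
      province = unname(prov[grid$district]),
      year = as.integer(grid$year),
      source = "floor",
      estimate = floor_value,
      variance = fvar,
      sample_size = NA_real_,
      flag_floor = TRUE,
      flag_split_adjusted = FALSE,
      stringsAsFactors = FALSE
    )
    obs <- rbind(obs, add)
  }
  obs <- obs[order(obs$indicator, obs$district, obs$year, obs$source), ]
  rownames(obs) <- NULL
  class(obs) <- c("observation_set", "data.frame")
  obs
}

#' Logit transform of an observation set
#'
#' Coverage is modeled in logit space to bound estimates between 0 and 1.
#' Proportions are clamped to `[eps, 1-eps]`, the point estimate becomes
#' `log(p/(1-p))`, and the sampling variance is propagated by the delta
#' method: `var_logit = var_p / (p (1-p))^2`.  Variances at or below zero
#' (degenerate proportions, infinite-sample records) are replaced by a
#' strictly positive floor, which the Gaussian process stage requires.
#'
#' Degenerate sampled proportions (an observed 0 or 1 from a finite sample)
#' report zero design-based variance; treating them as exact would falsely
#' pin the Gaussian process at the boundary.  When the effective sample size
#' is known, such records instead get the binomial logit-information
#' variance `1 / (n p* (1 - p*))` at the continuity-corrected proportion
#' `p* = (n phat + 0.5) / (n + 1)` — weakly informative, as a small
#' all-success sample should be.  Zero-variance records without a finite
#' sample size (exact/limit observations) fall back to `var_floor`.
#'
#' @param obs an `observation_set`.
#' @param eps boundary offset in (0, 0.01].
#' @param var_floor minimum logit-space variance.
#' @return data.frame with the original keys plus `logit`, `logit_var`.
#' @examples
#' obs <- data.frame(indicator = "x", district = "D", province = "P",
#'                   year = 2000L, source = "s", estimate = 0.5,
#'                   variance = 0.0025, sample_size = 100)
#' to_logit(obs)$logit_var   # 0.04
#' @export
to_logit <- function(obs, eps = 1e-4, var_floor = 1e-3) {
  if (eps <= 0 || eps > 0.01) stop("`eps` must be in (0, 0.01]", call. = FALSE)
  p <- clamp(obs$estimate, eps, 1 - eps)
  lv <- obs$variance / (p * (1 - p))^2
  degenerate <- obs$variance <= 0 &
    (obs$estimate <= 0 | obs$estimate >= 1) &
    !is.na(obs$sample_size) & is.finite(obs$sample_size)
  if (any(degenerate)) {
    n <- obs$sample_size[degenerate]
    pstar <- (n * obs$estimate[degenerate] + 0.5) / (n + 1)
    lv[degenerate] <- 1 / (n * pstar * (1 - pstar))
  }
  lv[!is.finite(lv) | lv < var_floor] <- var_floor
  out <- obs
  out$logit <- logit(p)
  out$logit_var <- lv
  out
}
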