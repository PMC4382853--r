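#' Generate census-anchored district populations
#'
#' Produces district population and household counts at a few census anchor
#' years.  The national total follows geometric growth from `base`; district
#' shares are drawn once (Gamma-normalized) and held fixed, so per-district
#' totals always sum to the national total.  Intermediate years are left to
#' [interpolate_households()] / [interpolate_population()], matching the
#' convention that counts between censuses are interpolated assuming
#' geometric growth.
#'
#' @param geo a [generate_geography()] map.
#' @param census_years at least two anchor years.
#' @param base national population at the first census year.
#' @param growth annual growth rate (> -1); national total at year y is
#'   `base * (1 + growth)^(y - min(census_years))`.
#' @param mean_household_size persons per household used to derive household
#'   counts.
#' @param seed integer seed (district shares).
#' @return object of class `population_table`: data.frame with columns
#'   `district`, `year`, `population`, `households`, plus attributes
#'   `census_years` and `shares`.
#' @export
generate_population <- function(geo, census_years = c(1990, 2000, 2010),
                                base = 8e6, growth = 0.028,
                                mean_household_size = 5,
                                seed = 1L) {
  if (length(census_years) < 2) stop("need >= 2 census years", call. = FALSE)
  if (growth <= -1) stop("`growth` must be > -1", call. = FALSE)
  if (base <= 0) stop("`base` must be positive", call. = FALSE)
  census_years <- sort(as.integer(census_years))

  with_seed(seed, {
    d <- geo$districts$district
    w <- stats::rgamma(length(d), shape = 2, rate = 1)
    w <- w / sum(w)
    out <- expand.grid(district = d, year = census_years,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    national <- base * (1 + growth)^(out$year - census_years[1])
    out$population <- w[match(out$district, d)] * national
    out$households <- out$population / mean_household_size
    structure(out, class = c("population_table", "data.frame"),
              census_years = census_years, shares = stats::setNames(w, d))
  })
}

#' Interpolate a population table to all study years
#'
#' Applies the geometric-growth interpolation rule district by district to
#' both population and household counts.
#'
#' @param pop a [generate_population()] table (census anchors).
#' @param years integer years wanted (may extend beyond the anchors;
#'   extrapolation uses the nearest segment's growth rate).
#' @return data.frame district, year, population, households.
#' @export
interpolate_population <- function(pop, years) {
  years <- as.integer(years)
  res <- lapply(split(pop, pop$district), function(df) {
    df <- df[order(df$year), ]
    data.frame(
      district = df$district[1],
      year = years,
      population = interpolate_households(df[, c("year", "population")],
                                          years = years)$count,
      households = interpolate_households(df[, c("year", "households")],
                                          years = years)$count,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
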