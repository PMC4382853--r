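#' Population-weighted national series
#'
#' Aggregates district draws to the national level draw by draw — the
#' national value of draw s is `sum(pop_d * x_{d,s}) / sum(pop_d)` — so that
#' national uncertainty intervals inherit the within-draw correlation
#' structure across districts.  Populations at non-census years come from
#' geometric interpolation.
#'
#' @param cube indicator x district x year x draw array (from
#'   [run_stgpr()]), or a 3-d district x year x draw array for one
#'   indicator.
#' @param pop a [generate_population()] table or an annual data.frame
#'   district, year, population.
#' @return list: `draws` (indicator x year x draw array), `summary`
#'   (data.frame indicator, year, mean, lower, upper).
#' @export
national_series <- function(cube, pop) {
  if (length(dim(cube)) == 3) {
    cube <- array(cube, c(1, dim(cube)),
                  dimnames = c(list("indicator"), dimnames(cube)))
  }
  dn <- dimnames(cube)
  years <- as.integer(dn[[3]])
  popw <- population_weights(pop, dn[[2]], years)

  ni <- dim(cube)[1]; ny <- dim(cube)[3]; ns <- dim(cube)[4]
  nat <- array(NA_real_, c(ni, ny, ns), dimnames = list(dn[[1]], dn[[3]], NULL))
  for (y in seq_len(ny)) {
    w <- popw[, y]
    w <- w / sum(w)
    for (i in seq_len(ni)) {
      nat[i, y, ] <- colSums(cube[i, , y, , drop = TRUE] * w)
    }
  }
  summ <- summarize_draws_national(nat)
  list(draws = nat, summary = summ)
}

# annual district x year population weight matrix
population_weights <- function(pop, districts, years) {
  annual <- if (all(years %in% unique(pop$year))) pop else interpolate_population(pop, years)
  m <- matrix(NA_real_, length(districts), length(years),
              dimnames = list(districts, years))
  m[cbind(match(annual$district, districts), match(annual$year, years))] <-
    annual$population
  if (anyNA(m)) {
    miss <- which(is.na(m), arr.ind = TRUE)
    stop("missing population for: ",
         paste(paste(districts[miss[, 1]], years[miss[, 2]]), collapse = ", "),
         call. = FALSE)
  }
  m
}

# summarize an indicator x year x draw array
summarize_draws_national <- function(nat) {
  keys <- expand.grid(indicator = dimnames(nat)[[1]],
                      year = as.integer(dimnames(nat)[[2]]),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  flat <- matrix(nat, prod(dim(nat)[1:2]), dim(nat)[3])
  q <- apply(flat, 1, stats::quantile, probs = c(0.025, 0.975), type = 7,
             names = FALSE)
  data.frame(keys, mean = rowMeans(flat), lower = q[1, ], upper = q[2, ],
             stringsAsFactors = FALSE)
}

#' Composite coverage across a basket of interventions
#'
#' The draw-wise weighted mean of the component indicators (equal weights by
#' default — the "simple average of the 10 interventions").  With a
#' population table, the national composite is the population-weighted
#' national of the component-averaged draws.
#'
#' @param cube indicator x district x year x draw array.
#' @param components indicator ids to average (default
#'   [composite_components()]).
#' @param weights non-negative weights summing to 1 (default equal).
#' @param pop optional population table for the national composite.
#' @return list: `cube` (district x year x draw composite array), `summary`
#'   (district-year data.frame), and when `pop` is given `national`
#'   (year-level data.frame) and `national_draws`.
#' @export
composite_coverage <- function(cube, components = composite_components(),
                               weights = NULL, pop = NULL) {
  miss <- setdiff(components, dimnames(cube)[[1]])
  if (length(miss)) {
    stop("missing composite components: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(components)) stop("component ids must be distinct", call. = FALSE)
  if (is.null(weights)) weights <- rep(1 / length(components), length(components))
  if (length(weights) != length(components) || any(weights < 0) ||
      abs(sum(weights) - 1) > 1e-9) {
    stop("weights must be non-negative and sum to 1", call. = FALSE)
  }

  comp <- array(0, dim(cube)[2:4], dimnames = dimnames(cube)[2:4])
  wsum <- 0
  for (i in seq_along(components)) {
    slice <- cube[components[i], , , , drop = FALSE]
    dim(slice) <- dim(cube)[2:4]
    comp <- comp + weights[i] * slice
    wsum <- wsum + weights[i]
  }
  # normalize by the identically-accumulated weight sum so an all-equal
  # basket is reproduced exactly (all components at 100% -> exactly 100%)
  comp <- comp / wsum
  out <- list(cube = comp, summary = summarize_draws(comp))
  if (!is.null(pop)) {
    nat <- national_series(comp, pop)
    out$national_draws <- nat$draws[1, , , drop = TRUE]
    ns <- nat$summary
    ns$indicator <- NULL
    out$national <- ns
  }
  out
}

#' Socioeconomic composite index
#'
#' A district-year socioeconomic score: each of four socio-demographic
#' components (mean adult education, improved sanitation, improved cooking
#' fuel, household electricity) is standardized to zero mean and unit
#' variance across all district-years, then averaged with equal weights.
#' Components with zero variance are excluded with a warning and the
#' weights renormalized.
#'
#' @param components named list of district x year matrices (or long
#'   data.frames district, year, mean) — typically adult education,
#'   sanitation, cooking fuel and electricity surfaces.
#' @return data.frame district, year, ses.
#' @export
ses_index <- function(components) {
  mats <- lapply(components, function(x) {
    if (is.data.frame(x)) {
      districts <- unique(x$district); years <- sort(unique(x$year))
      m <- matrix(NA_real_, length(districts), length(years),
                  dimnames = list(districts, years))
      val <- if (!is.null(x$mean)) x$mean else x$value
      m[cbind(match(x$district, districts), match(x$year, years))] <- val
      m
    } else {
      x
    }
  })
  keep <- vapply(mats, function(m) stats::sd(as.vector(m)) > 0, TRUE)
  if (!all(keep)) {
    warning("excluding zero-variance SES components: ",
            paste(names(mats)[!keep], collapse = ", "))
  }
  if (!any(keep)) {
    # every component constant: standardization nullity, score 0 everywhere
    s <- mats[[1]] * 0
  } else {
    mats <- mats[keep]
    z <- lapply(mats, function(m) (m - mean(m)) / stats::sd(as.vector(m)))
    s <- Reduce(`+`, z) / length(z)
  }
  keys <- expand.grid(district = rownames(s), year = as.integer(colnames(s)),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  data.frame(keys, ses = as.vector(s), stringsAsFactors = FALSE)
}

#' Pearson correlation with domain checks
#'
#' @param x,y equal-length numeric vectors (>= 3 finite pairs).
#' @return Pearson r in [-1, 1]; NaN with a warning when either vector has
#'   zero variance.
#' @export
pearson_corr <- function(x, y) {
  if (length(x) != length(y)) stop("lengths differ", call. = FALSE)
  if (length(x) < 3) stop("need >= 3 pairs", call. = FALSE)
  if (any(!is.finite(x)) || any(!is.finite(y))) stop("non-finite values", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("zero variance; correlation undefined")
    return(NaN)
  }
  stats::cor(x, y, method = "pearson")
}

#' Absolute change in coverage between two years
#'
#' Percentage-point change in the mean estimate per district,
#' `100 * (mean_y1 - mean_y0)`.  When the draw cube is supplied, draw-level
#' differences give a 95% interval for each district's change.
#'
#' @param summaries a summary data.frame (district, year, mean) for one
#'   indicator, e.g. a subset of `run_stgpr()$summary`.
#' @param y0,y1 baseline and comparison years.
#' @param cube optional district x year x draw array for the indicator.
#' @return data.frame district, change (pp), and with `cube` also
#'   `lower`, `upper` (pp).
#' @export
absolute_change <- function(summaries, y0, y1, cube = NULL) {
  s0 <- summaries[summaries$year == y0, ]
  s1 <- summaries[summaries$year == y1, ]
  if (nrow(s0) == 0 || nrow(s1) == 0) {
    stop(sprintf("years %s and %s must both be present", y0, y1), call. = FALSE)
  }
  m <- match(s0$district, s1$district)
  out <- data.frame(district = s0$district,
                    change = 100 * (s1$mean[m] - s0$mean),
                    stringsAsFactors = FALSE)
  if (!is.null(cube)) {
    dd <- 100 * (cube[out$district, as.character(y1), , drop = TRUE] -
                   cube[out$district, as.character(y0), , drop = TRUE])
    q <- apply(dd, 1, stats::quantile, probs = c(0.025, 0.975), type = 7,
               names = FALSE)
    out$lower <- q[1, ]
    out$upper <- q[2, ]
  }
  out
}

#' Gap between the highest- and lowest-performing districts
#'
#' @param summaries summary data.frame with district, year, mean (one
#'   indicator).
#' @param year the year examined.
#' @return list: `gap` (percentage points), `best`, `worst` (district ids;
#'   ties broken by district id order).
#' @export
range_gap <- function(summaries, year) {
  s <- summaries[summaries$year == year, ]
  if (nrow(s) < 2) stop("need >= 2 districts", call. = FALSE)
  s <- s[order(s$district), ]
  list(gap = 100 * (max(s$mean) - min(s$mean)),
       best = s$district[which.max(s$mean)],
       worst = s$district[which.min(s$mean)])
}

#' Count districts with declining coverage
#'
#' A decline is a strictly negative point-estimate change; districts whose
#' draw-level 95% interval of change lies entirely below zero are counted
#' separately as significant declines.
#'
#' @param changes an [absolute_change()] data.frame.
#' @return list: `n_declines`, `n_significant` (NA without draw-level
#'   intervals), `districts` (ids of declining districts).
#' @export
count_declines <- function(changes) {
  dec <- changes$change < 0
  nsig <- if (!is.null(changes$upper)) sum(changes$upper < 0) else NA_integer_
  list(n_declines = sum(dec), n_significant = nsig,
       districts = changes$district[dec])
}

#' Correlation between baseline level and subsequent change
#'
#' Pearson correlation across districts between the coverage level at `y0`
#' and the change from `y0` to `y1` — negative values indicate convergence
#' (low-baseline districts improving the most).
#'
#' @param summaries summary data.frame (district, year, mean) for one
#'   indicator.
#' @param y0,y1 baseline and comparison years.
#' @return Pearson r.
#' @export
corr_baseline_change <- function(summaries, y0, y1) {
  ch <- absolute_change(summaries, y0, y1)
  lev <- summaries[summaries$year == y0, ]
  m <- match(ch$district, lev$district)
  pearson_corr(lev$mean[m], ch$change)
}
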