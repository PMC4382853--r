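#' Read and write the long-format observation CSV
#'
#' The interchange format is a long table with columns `indicator`,
#' `district`, `province`, `year`, `source`, `estimate`, `variance`,
#' `sample_size` and, after preprocessing, `flag_floor` and
#' `flag_split_adjusted`.
#'
#' @param obs an `observation_set`.
#' @param path file path.
#' @return `read_observations()` returns an `observation_set`;
#'   `write_observations()` returns `path` invisibly.
#' @export
write_observations <- function(obs, path) {
  utils::write.csv(as.data.frame(obs), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_observations
#' @export
read_observations <- function(path) {
  obs <- utils::read.csv(path, stringsAsFactors = FALSE)
  class(obs) <- c("observation_set", "data.frame")
  obs
}

#' Read and write the geography CSV
#'
#' Columns: `district`, `province`, `parent_district`, `population_share`.
#'
#' @param geo a `geography_map`.
#' @param path file path.
#' @return `read_geography()` returns a `geography_map`.
#' @export
write_geography <- function(geo, path) {
  df <- geo$districts
  utils::write.csv(
    data.frame(district = df$district, province = df$province,
               parent_district = df$parent, population_share = df$share),
    path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_geography
#' @export
read_geography <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  districts <- data.frame(district = df$district, province = df$province,
                          parent = df$parent_district,
                          share = df$population_share,
                          stringsAsFactors = FALSE)
  splits <- districts[grepl("^S", districts$parent),
                      c("parent", "district", "share")]
  rownames(splits) <- NULL
  geo <- structure(list(districts = districts,
                        provinces = sort(unique(districts$province)),
                        splits = splits),
                   class = "geography_map")
  validate_geography(geo)
  geo
}

#' Write a synthetic truth to CSV plus a parameter manifest
#'
#' The true coverage surface goes to `<stem>_truth.csv` (long format:
#' indicator, district, province, year, p) and the generating parameters to
#' `<stem>_manifest.txt` as key-value lines (seed, years, shock scales,
#' per-indicator coefficients).
#'
#' @param truth a [generate_truth()] object.
#' @param stem path stem for the two files.
#' @return the two paths, invisibly.
#' @export
write_truth <- function(truth, stem) {
  csv <- paste0(stem, "_truth.csv")
  manifest <- paste0(stem, "_manifest.txt")
  utils::write.csv(truth_long(truth), csv, row.names = FALSE)
  sh <- truth$scenario$shocks
  lines <- c(
    sprintf("seed: %d", truth$seed),
    sprintf("years: %d-%d", min(truth$years), max(truth$years)),
    sprintf("district_shock_sd: %g", sh$district_sd),
    sprintf("province_shock_sd: %g", sh$province_sd),
    sprintf("shock_ar: %g", sh$ar),
    vapply(rownames(truth$beta), function(i) {
      sprintf("beta[%s]: %s", i,
              paste(signif(truth$beta[i, ], 8), collapse = " "))
    }, "")
  )
  writeLines(lines, manifest)
  invisible(c(csv, manifest))
}

#' Write an estimate summary CSV
#'
#' @param summary a summary data.frame (from [summarize_draws()] or the
#'   benchmark functions).
#' @param path file path.
#' @export
write_summary <- function(summary, path) {
  utils::write.csv(summary, path, row.names = FALSE)
  invisible(path)
}
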