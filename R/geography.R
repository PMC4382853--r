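#' Generate a synthetic administrative geography
#'
#' Builds a district/province map with an old-to-new split lineage, emulating
#' a country whose districts were subdivided at some point (for Zambia, 57
#' districts before 2000 became 72 afterwards).  Each split parent divides
#' into exactly two inheriting districts within the same province, so the old
#' geography has `n_districts - n_split_parents` units.
#'
#' @param n_provinces number of provinces (>= 1).
#' @param n_districts number of (new-geography) districts (>= n_provinces).
#' @param n_split_parents number of old districts that split in two
#'   (<= n_districts / 2).
#' @param seed integer seed; the map is a pure function of the arguments.
#' @return An object of class `geography_map`: a list with
#'   \describe{
#'     \item{districts}{data.frame with columns `district`, `province`,
#'       `parent` (the old-geography code; equals `district` for unsplit
#'       units) and `share` (population share of the district within its
#'       parent; 1 for unsplit units).}
#'     \item{provinces}{character vector of province ids.}
#'     \item{splits}{data.frame restricted to split lineages, with columns
#'       `parent`, `district`, `share`.}
#'   }
#' @examples
#' geo <- generate_geography(9, 72, 15, seed = 1)
#' nrow(geo$districts)        # 72
#' length(unique(geo$districts$parent))  # 57
#' @export
generate_geography <- function(n_provinces, n_districts, n_split_parents, seed = 1L) {
  stopifnot_count(n_provinces, "n_provinces", 1L)
  stopifnot_count(n_districts, "n_districts", 1L)
  stopifnot_count(n_split_parents, "n_split_parents", 0L)
  if (n_districts < n_provinces) {
    stop("`n_districts` must be >= `n_provinces`", call. = FALSE)
  }
  if (n_split_parents > n_districts / 2) {
    stop("`n_split_parents` must be <= n_districts / 2", call. = FALSE)
  }

  with_seed(seed, {
    provinces <- sprintf("P%02d", seq_len(n_provinces))
    districts <- sprintf("D%03d", seq_len(n_districts))

    # every province gets at least one district; remaining assigned at random
    prov_of <- character(n_districts)
    prov_of[seq_len(n_provinces)] <- provinces
    if (n_districts > n_provinces) {
      prov_of[(n_provinces + 1L):n_districts] <-
        sample(provinces, n_districts - n_provinces, replace = TRUE)
    }

    df <- data.frame(
      district = districts,
      province = prov_of,
      parent = paste0("O_", districts),
      share = 1,
      stringsAsFactors = FALSE
    )

    if (n_split_parents > 0L) {
      # pair districts within provinces: each split parent has two inheritors
      # in the same province
      remaining <- seq_len(n_districts)
      pairs <- list()
      k <- 0L
      for (p in sample(provinces, length(provinces))) {
        idx <- remaining[df$province[remaining] == p]
        while (length(idx) >= 2L && k < n_split_parents) {
          pick <- idx[seq_len(2L)]
          k <- k + 1L
          pairs[[k]] <- pick
          idx <- setdiff(idx, pick)
          remaining <- setdiff(remaining, pick)
        }
        if (k >= n_split_parents) break
      }
      if (k < n_split_parents) {
        stop("could not place all split parents within provinces; ",
             "increase districts per province", call. = FALSE)
      }
      for (j in seq_len(k)) {
        pick <- pairs[[j]]
        parent_id <- sprintf("S%03d", j)
        s <- stats::runif(1, 0.25, 0.75)
        df$parent[pick] <- parent_id
        df$share[pick] <- c(s, 1 - s)
      }
    }

    splits <- df[grepl("^S", df$parent), c("parent", "district", "share")]
    rownames(splits) <- NULL

    structure(
      list(districts = df, provinces = provinces, splits = splits),
      class = "geography_map"
    )
  })
}

#' @export
print.geography_map <- function(x, ...) {
  cat(sprintf(
    "<geography_map> %d districts in %d provinces; %d split parents (old geography: %d units)\n",
    nrow(x$districts), length(x$provinces),
    length(unique(x$splits$parent)),
    length(unique(x$districts$parent))
  ))
  invisible(x)
}

# Validity check used by tests and constructors.
validate_geography <- function(geo) {
  df <- geo$districts
  stopifnot(
    all(df$province %in% geo$provinces),
    !anyDuplicated(df$district),
    all(df$share > 0)
  )
  shares <- tapply(df$share, df$parent, sum)
  if (any(abs(shares - 1) > 1e-9)) {
    stop("population shares within a parent must sum to 1", call. = FALSE)
  }
  # inheritors of a parent must sit in one province
  np <- tapply(df$province, df$parent, function(z) length(unique(z)))
  if (any(np != 1)) stop("split inheritors must share a province", call. = FALSE)
  invisible(TRUE)
}

# province lookup vector: names are districts
province_of <- function(geo) {
  stats::setNames(geo$districts$province, geo$districts$district)
}
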