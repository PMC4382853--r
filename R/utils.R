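#' Logit and inverse-logit transforms
#'
#' Coverage proportions are modeled on the logit scale so that estimates are
#' bounded between 0 and 1.  `logit()` maps a proportion in (0, 1) to the
#' real line; `inv_logit()` is its inverse.
#'
#' @param p numeric vector of proportions in (0, 1).
#' @param x numeric vector on the logit scale.
#' @return numeric vector.
#' @examples
#' logit(0.5)          # 0
#' inv_logit(logit(0.2))
#' @export
logit <- function(p) log(p / (1 - p))

#' @rdname logit
#' @export
inv_logit <- function(x) {
  # stats::plogis is numerically stable for large |x| and never returns an
  # exact 0 or 1 for finite input short of double underflow
  stats::plogis(x)
}

# Clamp values into [lo, hi].
clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards so generators are pure functions of
# (inputs, seed).
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
      stop("`seed` must be a single integer", call. = FALSE)
    }
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Derive a stream seed from a base seed and an index, kept inside the 32-bit
# integer range.
derive_seed <- function(seed, i) {
  as.integer((as.double(seed) * 7919 + as.double(i) * 104729) %% 2147483647)
}

stopifnot_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != round(x)) {
    stop(sprintf("`%s` must be a single integer >= %d", name, min), call. = FALSE)
  }
  invisible(as.integer(x))
}
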