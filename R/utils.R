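#' @importFrom rlang abort warn inform %||%
#' @importFrom stats cor rnorm runif sd setNames
#' @importFrom utils head tail
NULL

# Internal argument checks ----------------------------------------------------

check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != floor(x)) {
    abort(sprintf("`%s` must be a single integer >= %d.", name, min),
          class = "degensim_invalid_argument")
  }
  as.integer(x)
}

check_fraction <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    abort(sprintf("`%s` must be a single number in [0, 1].", name),
          class = "degensim_invalid_argument")
  }
  as.numeric(x)
}

check_scalar_number <- function(x, name, min = -Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min) {
    abort(sprintf("`%s` must be a single number >= %s.", name, format(min)),
          class = "degensim_invalid_argument")
  }
  as.numeric(x)
}

#' Derive a child seed from a root seed
#'
#' Deterministic counter rule used throughout the package to split one root
#' seed into independent streams (prototype / train / test draws, replicate
#' initialisations, per-replicate injury courses). Kept below `2^31 - 1` so
#' the result is always a valid R integer seed.
#'
#' @param root Integer root seed.
#' @param offset Non-negative integer counter.
#' @return An integer seed.
#' @export
derive_seed <- function(root, offset) {
  root <- check_count(root, "root", min = 0L)
  offset <- check_count(offset, "offset", min = 0L)
  as.integer((as.double(root) + as.double(offset)) %% 2147483647)
}

# Round half away from zero (round() in R rounds half to even).
round_half_away <- function(x) {
  trunc(x + sign(x) * 0.5)
}
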