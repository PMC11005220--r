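# Internal helpers shared across modules.

#' Derive a reproducible sub-seed from integer components
#'
#' Combines a master seed with stream identifiers (animal index, fold index,
#' repeat index, ...) into a single seed below 2^31, so that every random
#' draw in the package is a pure function of the master seed and its position
#' in the pipeline, independent of evaluation order.
#'
#' @param ... integer components; the first is conventionally the master seed.
#' @return a single integer seed in [0, 2^31 - 1].
#' @keywords internal
mix_seed <- function(...) {
  parts <- as.numeric(c(...))
  stopifnot(length(parts) >= 1, all(is.finite(parts)))
  m <- 2147483647  # 2^31 - 1, keeps the result a valid 32-bit R integer
  acc <- 0
  for (p in parts) {
    # Knuth-style multiplicative mixing, all mod 2^31 - 1
    acc <- (acc * 69069 + (p %% m) * 2654435761 + 104729) %% m
  }
  as.integer(acc)
}

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Sidak adjustment of a vector of p-values
#'
#' @param p numeric vector of raw p-values.
#' @param m number of comparisons (defaults to `length(p)`).
#' @return adjusted p-values `1 - (1 - p)^m`, capped at 1.
#' @export
sidak_adjust <- function(p, m = length(p)) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE), m >= 1)
  pmin(1, 1 - (1 - p)^m)
}

# Fill interior NA runs by linear interpolation; leading/trailing NAs carry
# the nearest observed value. Used only for rhythm fitting, never for means.
interp_gaps <- function(x) {
  if (!anyNA(x)) return(x)
  idx <- seq_along(x)
  ok <- !is.na(x)
  if (!any(ok)) stop("cannot interpolate an all-missing series")
  stats::approx(idx[ok], x[ok], xout = idx, rule = 2)$y
}

gap_fraction <- function(x) mean(is.na(x))

`%||%` <- function(a, b) if (is.null(a)) b else a
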