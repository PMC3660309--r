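# Lightweight container for a uniformly sampled 1-D signal.

#' Create a uniformly sampled time series
#'
#' A minimal container holding the sample values and the sampling interval.
#' All estimator functions accept either a `hurst_ts` object or a bare
#' numeric vector (in which case `dt = 1` is assumed).
#'
#' @param values numeric vector of samples; must be finite.
#' @param dt sampling interval in seconds (for fMRI, the TR). Default 1.
#' @return An object of class `hurst_ts` with fields `values`, `dt`, `n`.
#' @examples
#' x <- hurst_ts(rnorm(128), dt = 2.1)
#' x$n
#' @export
hurst_ts <- function(values, dt = 1) {
  values <- as.numeric(values)
  if (anyNA(values) || any(!is.finite(values)))
    stop("time series values must be finite and non-missing")
  if (!is.numeric(dt) || length(dt) != 1L || dt <= 0)
    stop("dt must be a single positive number")
  structure(list(values = values, dt = dt, n = length(values)),
            class = "hurst_ts")
}

#' @export
print.hurst_ts <- function(x, ...) {
  cat(sprintf("<hurst_ts> n = %d, dt = %g s, range [%.4g, %.4g]\n",
              x$n, x$dt, min(x$values), max(x$values)))
  invisible(x)
}

#' @export
as.numeric.hurst_ts <- function(x, ...) x$values

as_hurst_ts <- function(x, dt = 1) {
  if (inherits(x, "hurst_ts")) return(x)
  hurst_ts(x, dt = dt)
}

# Extract values whether given a hurst_ts or a numeric vector.
ts_values <- function(x) if (inherits(x, "hurst_ts")) x$values else as.numeric(x)
ts_dt <- function(x, default = 1) if (inherits(x, "hurst_ts")) x$dt else default

# Run code under a temporary RNG state. seed = NULL leaves the global
# stream untouched so callers can manage reproducibility themselves.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Derive a child seed from a base seed, kept within 32-bit integer range.
child_seed <- function(seed, k) {
  if (is.null(seed)) return(NULL)
  as.integer((as.double(seed) * 48271 + k * 1299709) %% 2147483647)
}
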