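# Shared regression helpers for log-log scaling fits.

# Ordinary least squares of y on x, returning slope/intercept/r2.
# Used everywhere a scaling exponent is read off a log-log plot.
ols_fit <- function(x, y) {
  n <- length(x)
  mx <- mean(x); my <- mean(y)
  sxx <- sum((x - mx)^2)
  sxy <- sum((x - mx) * (y - my))
  slope <- sxy / sxx
  intercept <- my - slope * mx
  res <- y - intercept - slope * x
  syy <- sum((y - my)^2)
  r2 <- if (syy > 0) 1 - sum(res^2) / syy else NA_real_
  se <- if (n > 2 && sxx > 0) sqrt(sum(res^2) / (n - 2) / sxx) else NA_real_
  list(slope = slope, intercept = intercept, r2 = r2, slope_se = se, n = n)
}

# Fit log(y) against log(x), silently dropping non-positive or non-finite
# y with a diagnostic count (a zero value of a scaling function makes that
# scale point drop out rather than aborting the fit).
loglog_fit <- function(scales, y, min_points = 2L, log_base = exp(1),
                       what = "scaling function") {
  keep <- is.finite(y) & y > 0 & is.finite(scales) & scales > 0
  dropped <- sum(!keep)
  if (sum(keep) < min_points)
    stop(sprintf("degenerate input: fewer than %d usable points in %s",
                 min_points, what))
  f <- ols_fit(log(scales[keep], base = log_base), log(y[keep], base = log_base))
  f$scales <- scales[keep]
  f$dropped <- dropped
  f
}

# n integers approximately logarithmically spaced in [lo, hi], deduplicated.
log_int_grid <- function(lo, hi, n) {
  if (hi < lo) return(integer(0))
  unique(round(exp(seq(log(lo), log(hi), length.out = n))))
}

new_hurst_estimate <- function(estimator_id, H, scales, slope, r2,
                               diagnostics = list()) {
  structure(list(estimator_id = estimator_id, H = H,
                 scales = scales, slope = slope, r2 = r2,
                 diagnostics = diagnostics),
            class = "hurst_estimate")
}

#' @export
print.hurst_estimate <- function(x, ...) {
  cat(sprintf("<hurst_estimate> %s: H = %.4f (slope %.4f, r2 %s, %d scales)\n",
              x$estimator_id, x$H, x$slope,
              ifelse(is.na(x$r2), "NA", sprintf("%.3f", x$r2)),
              length(x$scales)))
  flags <- x$diagnostics
  if (isTRUE(flags$saturated)) cat("  note: estimate saturates (wrong input class?)\n")
  invisible(x)
}
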