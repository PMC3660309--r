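# Twenty Hurst-exponent estimators, all normalized to the Hurst scale.
#
# Conventions. A "walk-class" estimator expects a nonstationary fBm-like
# path (cumulative process); an "increments-class" estimator expects its
# stationary fGn-like increments. The mapping between the native scaling
# exponent of each method and H:
#   structure function  S(q,tau) ~ tau^(qH)          (walk)
#   aggregated variance var(X^(m)) ~ m^(2H-2)        (increments)
#   Higuchi             D = 2 - H                    (walk)
#   second derivative   H = 0.5 log2(E2/E1)          (walk)
#   wavelet variance    Var d_j ~ 2^(j(2H+1))        (walk)
#   spectral slope      H = (beta - 1)/2             (walk)
#   DFA                 H = alpha - 1                (walk; integrates again)
#   rescaled range      E[R/S] ~ n^H                 (increments)
# Estimates are reported unclipped; bounded behavior is a property of an
# algorithm, never enforced by post-hoc clamping.

#' Estimator registry
#'
#' The twenty estimator identifiers with their expected input class and
#' whether the estimate is intrinsically confined near \[0, 1\].
#'
#' @return data.frame with columns `estimator_id`, `signal_class`
#'   (`"walk"` or `"increments"`), `bounded`.
#' @export
estimator_specs <- function() {
  ids <- c("Q1a", "Q2a", "Q1b", "Q2b", "AV", "HFD5", "HFD10", "DD", "DDW",
           "db1", "db2", "db4", "db8", "db16", "FFT", "pWelch",
           "DFA", "DFA-S", "DFA-L", "RS")
  bounded <- ids %in% c("Q1a", "Q2a", "Q1b", "Q2b", "HFD5", "HFD10",
                        "DFA", "DFA-S", "DFA-L", "AV", "RS", "db1")
  cls <- ifelse(ids %in% c("AV", "RS"), "increments", "walk")
  data.frame(estimator_id = ids, signal_class = cls, bounded = bounded,
             stringsAsFactors = FALSE)
}

estimator_ids <- function() estimator_specs()$estimator_id

# ---------------------------------------------------------------------------
# Structure function (Q1a / Q2a)

sf_lag_grid <- function(n) {
  lags <- log_int_grid(1, n / 50, 10)
  lags[lags >= 1 & lags < n]
}

#' Structure-function (generalized Hurst) estimator
#'
#' Computes the q-th order structure function
#' `S(q, tau) = mean_t |x(t + tau) - x(t)|^q` over ten logarithmically
#' spaced integer lags between 1 and `n/50`, and reads H off the slope of
#' `log S(q, tau) / q` against `log tau`.
#'
#' @param x numeric vector or [hurst_ts()]; walk-class (fBm-like) input.
#' @param q moment order, 1 or 2.
#' @return A `hurst_estimate` (`Q1a` or `Q2a`).
#' @export
hurst_sf <- function(x, q = 2) {
  v <- ts_values(x)
  n <- length(v)
  stopifnot(q %in% c(1, 2))
  if (n < 100) stop("structure-function estimator needs n >= 100")
  lags <- sf_lag_grid(n)
  if (length(lags) < 4)
    stop("series too short: lag grid between 1 and n/50 has fewer than 4 distinct integer lags")
  S <- vapply(lags, function(tau)
    mean(abs(v[(1 + tau):n] - v[1:(n - tau)])^q), numeric(1))
  if (all(S == 0)) stop("degenerate input: structure function is zero (constant series)")
  fit <- loglog_fit(lags, S, min_points = 4, what = "structure function")
  new_hurst_estimate(if (q == 1) "Q1a" else "Q2a",
                     H = fit$slope / q, scales = fit$scales,
                     slope = fit$slope, r2 = fit$r2,
                     diagnostics = list(q = q, dropped = fit$dropped))
}

#' Generalized Hurst estimator with averaged maximum lag (Q1b / Q2b)
#'
#' For each maximum lag `tau_max` in `5..max_lag`, fits
#' `log S(q, tau) ~ log tau` over `tau = 1..tau_max` and averages the
#' resulting H across `tau_max` values (set `average = FALSE` to use the
#' single fit at `max_lag` instead). Per-`tau_max` fits are kept in the
#' diagnostics.
#'
#' @inheritParams hurst_sf
#' @param max_lag largest maximum lag (default 19).
#' @param average average the fits over `tau_max = 5..max_lag` (default)
#'   or return the single fit at `max_lag`.
#' @export
hurst_gen <- function(x, q = 2, max_lag = 19, average = TRUE) {
  v <- ts_values(x)
  n <- length(v)
  stopifnot(q %in% c(1, 2))
  if (n < 50) stop("generalized Hurst estimator needs n >= 50")
  taus <- seq_len(min(max_lag, n - 1))
  S <- vapply(taus, function(tau)
    mean(abs(v[(1 + tau):n] - v[1:(n - tau)])^q), numeric(1))
  if (all(S == 0)) stop("degenerate input: structure function is zero (constant series)")
  tmax_grid <- 5:max(5, max(taus))
  fits <- vapply(tmax_grid, function(tm) {
    f <- loglog_fit(taus[taus <= tm], S[taus <= tm], min_points = 3,
                    what = "structure function")
    f$slope / q
  }, numeric(1))
  H <- if (average) mean(fits) else fits[length(fits)]
  full <- loglog_fit(taus, S, min_points = 3, what = "structure function")
  new_hurst_estimate(if (q == 1) "Q1b" else "Q2b",
                     H = H, scales = taus, slope = full$slope, r2 = full$r2,
                     diagnostics = list(q = q, tau_max = tmax_grid,
                                        per_tau_max_H = fits))
}

# ---------------------------------------------------------------------------
# Aggregated variance (AV)

#' Aggregated-variance estimator
#'
#' Divides the series into blocks of size m, computes the variance of the
#' block means across a logarithmic grid of m (at least 4 blocks per
#' size), and estimates `H = 1 + slope/2` of `log var(X^(m))` vs `log m`.
#' Expects increments-class (fGn-like) input; a walk-class series passed
#' without differencing saturates and is flagged in the diagnostics.
#'
#' @param x numeric vector or [hurst_ts()]; increments-class input.
#' @export
hurst_aggvar <- function(x) {
  v <- ts_values(x)
  n <- length(v)
  if (n < 64) stop("aggregated-variance estimator needs n >= 64")
  ms <- log_int_grid(2, floor(n / 4), 20)
  ms <- ms[ms >= 2]
  vars <- vapply(ms, function(m) {
    nb <- n %/% m
    bm <- colMeans(matrix(v[seq_len(nb * m)], nrow = m))
    var(bm)
  }, numeric(1))
  if (all(vars == 0)) stop("degenerate input: constant series")
  fit <- loglog_fit(ms, vars, min_points = 4, what = "block-mean variance")
  H <- 1 + fit$slope / 2
  # a walk-class input gives a near-flat block-mean variance (slope ~ 0,
  # H ~ 1): flag it rather than report a spurious exponent
  new_hurst_estimate("AV", H = H, scales = fit$scales,
                     slope = fit$slope, r2 = fit$r2,
                     diagnostics = list(dropped = fit$dropped,
                                        saturated = H >= 0.95))
}

# ---------------------------------------------------------------------------
# Higuchi fractal dimension (HFD5 / HFD10)

#' Higuchi fractal-dimension estimator
#'
#' Standard Higuchi (1988) curve lengths: for each delay k and phase
#' offset m, the normalized absolute-increment sum along the subsampled
#' curve, with the `(N-1) / (floor((N-m)/k) * k)` length correction,
#' averaged over the k offsets. The fractal dimension D is minus the
#' slope of `log L(k)` vs `log k`, and `H = 2 - D`.
#'
#' @param x numeric vector or [hurst_ts()]; walk-class input.
#' @param kmax maximum delay (5 or 10 for the standard variants; any
#'   `kmax < n/10` is accepted).
#' @export
hurst_higuchi <- function(x, kmax = 10) {
  v <- ts_values(x)
  n <- length(v)
  if (kmax >= n / 10) stop("series too short for Higuchi estimator: kmax must be < n/10")
  L <- vapply(seq_len(kmax), function(k) {
    lm_k <- vapply(seq_len(k), function(m) {
      nk <- (n - m) %/% k
      if (nk < 1) return(NA_real_)
      idx <- m + (0:nk) * k
      sum(abs(diff(v[idx]))) * (n - 1) / (nk * k) / k
    }, numeric(1))
    mean(lm_k, na.rm = TRUE)
  }, numeric(1))
  if (all(L == 0)) stop("degenerate input: zero curve length (constant series)")
  fit <- loglog_fit(seq_len(kmax), L, min_points = 2, what = "Higuchi curve length")
  D <- -fit$slope
  id <- if (kmax %in% c(5, 10)) paste0("HFD", kmax) else sprintf("HFD%d", kmax)
  new_hurst_estimate(id, H = 2 - D, scales = fit$scales,
                     slope = fit$slope, r2 = fit$r2,
                     diagnostics = list(D = D, kmax = kmax))
}

# ---------------------------------------------------------------------------
# Discrete second derivative (DD / DDW)

# Valid-part linear convolution with a difference filter a, optionally
# dilated by inserting zeros (scale s keeps every s-th tap).
gqv_filter <- function(v, a, s) {
  if (s > 1) {
    a2 <- numeric((length(a) - 1) * s + 1)
    a2[seq(1, length(a2), by = s)] <- a
    a <- a2
  }
  n <- length(v)
  la <- length(a)
  out <- numeric(n - la + 1)
  for (i in seq_along(a)) out <- out + a[i] * v[i:(n - la + i)]
  out
}

#' Second-derivative (Istas-Lang) estimator
#'
#' Generalized quadratic variations at dyadic scales:
#' `H = 0.5 * log2(E2 / E1)` where `E1` and `E2` are the mean squared
#' outputs of a second-order difference filter at scales 1 and 2 (the
#' filter dilated by zero insertion). The `"fir"` variant uses the
#' discrete second difference `(1, -2, 1)`; the `"wavelet"` variant uses
#' the db2 wavelet (high-pass) filter, which has the same two vanishing
#' moments. Both annihilate linear trends and are unbounded.
#'
#' @param x numeric vector or [hurst_ts()]; walk-class input.
#' @param variant `"fir"` (plain finite differences) or `"wavelet"`
#'   (Daubechies-filtered difference).
#' @export
hurst_secderiv <- function(x, variant = c("fir", "wavelet")) {
  variant <- match.arg(variant)
  v <- ts_values(x)
  n <- length(v)
  if (n < 32) stop("second-derivative estimator needs n >= 32")
  a <- if (variant == "fir") c(1, -2, 1) else db_filter_pair(2)$g
  E1 <- mean(gqv_filter(v, a, 1)^2)
  E2 <- mean(gqv_filter(v, a, 2)^2)
  # energies at the level of squared rounding error count as zero
  tol <- 1e-24 * mean(v^2)
  if (E1 <= tol || E2 <= tol)
    stop("degenerate input: zero second-difference energy (linear or constant series)")
  H <- 0.5 * log2(E2 / E1)
  new_hurst_estimate(if (variant == "fir") "DD" else "DDW",
                     H = H, scales = c(1, 2), slope = log2(E2 / E1), r2 = NA_real_,
                     diagnostics = list(E1 = E1, E2 = E2, variant = variant))
}

# ---------------------------------------------------------------------------
# Wavelet-variance slope (db1 ... db16)

#' Wavelet detail-variance slope estimator
#'
#' Periodized Daubechies decomposition; per-level detail-coefficient
#' energies `V_j` are fitted as `log2 V_j ~ j` by unweighted least squares
#' over all levels holding at least 8 coefficients, and `H = (slope-1)/2`
#' (walk-class scaling `Var d_j ~ 2^(j(2H+1))`).
#'
#' @param x numeric vector or [hurst_ts()]; walk-class input.
#' @param order Daubechies order: 1, 2, 4, 8, or 16.
#' @export
hurst_wavvar <- function(x, order = 1) {
  v <- ts_values(x)
  w <- dwt_valid(v, order = order)
  nc <- vapply(w$details, length, integer(1))
  usable <- which(nc >= 8)
  if (length(usable) < 3)
    stop("series too short for wavelet-variance estimator: fewer than 3 levels with >= 8 coefficients")
  V <- vapply(w$details[usable], function(d) mean(d^2), numeric(1))
  # energies at the level of squared rounding error count as zero
  keep <- V > 1e-24 * mean(v^2)
  if (sum(keep) < 2)
    stop("degenerate input: all detail variances are zero (constant series)")
  fit <- ols_fit(usable[keep], log2(V[keep]))
  H <- (fit$slope - 1) / 2
  new_hurst_estimate(paste0("db", order), H = H, scales = usable[keep],
                     slope = fit$slope, r2 = fit$r2,
                     diagnostics = list(levels = usable, level_energy = V,
                                        dropped = sum(!keep)))
}

# ---------------------------------------------------------------------------
# Power spectral density slope (FFT / pWelch)

welch_psd <- function(v, dt) {
  n <- length(v)
  seg <- (2 * n) %/% 9            # eight 50%-overlapping segments
  seg <- seg - seg %% 2L          # even segment length
  hop <- seg %/% 2L
  starts <- seq(1, n - seg + 1, by = hop)
  win <- 0.5 - 0.5 * cos(2 * pi * seq_len(seg) / (seg + 1))  # Hann
  wnorm <- sum(win^2)
  acc <- numeric(seg %/% 2L)
  for (s in starts) {
    xs <- v[s:(s + seg - 1)]
    xs <- (xs - mean(xs)) * win
    P <- Mod(fft(xs))^2 / wnorm
    acc <- acc + P[2:(seg %/% 2L + 1L)]
  }
  list(freq = (1:(seg %/% 2L)) / (seg * dt), psd = acc / length(starts),
       n_segments = length(starts), segment_length = seg)
}

#' Power-spectral-density slope estimator
#'
#' Estimates the PSD either as the squared modulus of the discrete
#' Fourier transform (`"fft"`) or by Welch averaging with eight
#' 50%-overlapping Hann-tapered segments (`"welch"`), fits
#' `log PSD ~ log f` over `fit_band` (default: all positive frequencies,
#' DC excluded; band given as a closed-open interval `[f_lo, f_hi)` in
#' Hz), and returns `H = (beta - 1)/2` where `beta` is the negative
#' slope. Unbounded: estimates are not clipped.
#'
#' @param x numeric vector or [hurst_ts()]; walk-class input.
#' @param method `"fft"` or `"welch"`.
#' @param fit_band optional numeric length-2 frequency interval in Hz.
#' @param dt sampling interval in seconds when `x` is a bare vector.
#' @export
hurst_psd <- function(x, method = c("fft", "welch"), fit_band = NULL, dt = NULL) {
  method <- match.arg(method)
  v <- ts_values(x)
  if (is.null(dt)) dt <- ts_dt(x)
  n <- length(v)
  if (n < 64) stop("PSD estimator needs n >= 64")
  if (method == "fft") {
    P <- Mod(fft(v - mean(v)))^2
    nf <- n %/% 2L
    freq <- (1:nf) / (n * dt)
    psd <- P[2:(nf + 1L)]
  } else {
    wp <- welch_psd(v, dt)
    freq <- wp$freq
    psd <- wp$psd
  }
  if (!is.null(fit_band)) {
    stopifnot(length(fit_band) == 2, fit_band[1] < fit_band[2])
    keep <- freq >= fit_band[1] & freq < fit_band[2]
    if (sum(keep) < 4) stop("fit band contains fewer than 4 frequency bins")
    freq <- freq[keep]; psd <- psd[keep]
  }
  if (all(psd == 0)) stop("degenerate input: zero spectrum (constant series)")
  fit <- loglog_fit(freq, psd, min_points = 4, what = "power spectrum")
  beta <- -fit$slope
  new_hurst_estimate(if (method == "fft") "FFT" else "pWelch",
                     H = (beta - 1) / 2, scales = fit$scales,
                     slope = fit$slope, r2 = fit$r2,
                     diagnostics = list(beta = beta, method = method,
                                        dropped = fit$dropped))
}

# ---------------------------------------------------------------------------
# Detrended fluctuation analysis (DFA / DFA-S / DFA-L)

dfa_box_grid <- function(n) {
  smax <- floor(n / 4)
  s <- 4 * 2^((0:ceiling(8 * log2(smax / 4))) / 8)
  sort(unique(round(s[s <= smax & s >= 4])))
}

# Fluctuation function F(s) over all sliding windows of each box size,
# computed with rolling sums (closed-form linear-detrend residuals).
dfa_fluctuation <- function(v) {
  n <- length(v)
  y <- cumsum(v - mean(v))
  boxes <- dfa_box_grid(n)
  A <- c(0, cumsum(y))            # prefix sums
  B <- c(0, cumsum(y^2))
  D <- c(0, cumsum(seq_len(n) * y))
  Fb <- vapply(boxes, function(w) {
    a <- seq_len(n - w + 1)       # window starts
    S1 <- A[a + w] - A[a]
    S2 <- B[a + w] - B[a]
    St <- (D[a + w] - D[a]) - (a - 1) * S1
    stt <- w * (w^2 - 1) / 12
    sty <- St - S1 * (w + 1) / 2
    ssr <- S2 - S1^2 / w - sty^2 / stt
    ssr[ssr < 0] <- 0             # guard fp cancellation
    sqrt(mean(ssr) / w)
  }, numeric(1))
  list(boxes = boxes, F = Fb)
}

dfa_split_box <- function(boxes) {
  mid <- sqrt(min(boxes) * max(boxes))  # geometric midpoint of the range
  boxes[which.min(abs(log(boxes) - log(mid)))]
}

dfa_fit_subset <- function(fl, box_range) {
  boxes <- fl$boxes
  split <- dfa_split_box(boxes)
  keep <- switch(box_range,
                 full = rep(TRUE, length(boxes)),
                 small = boxes <= split,
                 large = boxes >= split)
  if (sum(keep) < 4) stop("fewer than 4 box sizes in the selected range")
  if (all(fl$F[keep] == 0))
    stop("degenerate input: zero fluctuation at every box size (linear series)")
  fit <- loglog_fit(boxes[keep], fl$F[keep], min_points = 4,
                    what = "DFA fluctuation")
  alpha <- fit$slope
  id <- switch(box_range, full = "DFA", small = "DFA-S", large = "DFA-L")
  new_hurst_estimate(id, H = alpha - 1, scales = fit$scales,
                     slope = alpha, r2 = fit$r2,
                     diagnostics = list(alpha = alpha, split_box = split,
                                        dropped = fit$dropped))
}

#' Detrended fluctuation analysis estimator
#'
#' Integrates the (demeaned) series, computes the root-mean-square
#' linear-detrend residual over all sliding windows for box sizes on a
#' log grid between 4 and n/4 with ratio 2^(1/8), and fits
#' `log F(s) ~ log s` over the selected subset of boxes. The scaling
#' exponent is alpha, and `H = alpha - 1` (walk-class input convention:
#' internal integration makes the profile one order smoother). The box
#' subset splits at the geometric midpoint of the log box-range snapped
#' to the grid (for a 1190-point series: small about 4-40, large about
#' 40-300).
#'
#' @param x numeric vector or [hurst_ts()]; walk-class input.
#' @param box_range `"full"`, `"small"`, or `"large"`.
#' @export
hurst_dfa <- function(x, box_range = c("full", "small", "large")) {
  box_range <- match.arg(box_range)
  v <- ts_values(x)
  if (length(v) < 100) stop("DFA needs n >= 100")
  dfa_fit_subset(dfa_fluctuation(v), box_range)
}

# ---------------------------------------------------------------------------
# Rescaled range (RS)

#' Rescaled-range estimator
#'
#' Classic R/S recipe over dyadic scales `L, L/2, L/4, ...` down to the
#' smallest scale of at least 8 points: each scale's segments are
#' zero-meaned, cumulatively summed, and the range of the cumulative sum
#' over the segment standard deviation is averaged to `E[R/S]`; H is the
#' slope of `log2 E[R/S]` vs `log2 scale`. Expects increments-class
#' input. Small-sample estimates carry a known upward bias (recorded in
#' the diagnostics).
#'
#' @param x numeric vector or [hurst_ts()]; increments-class input.
#' @export
hurst_rs <- function(x) {
  v <- ts_values(x)
  n <- length(v)
  if (n < 16) stop("rescaled-range estimator needs n >= 16")
  ks <- 0:floor(log2(n / 8))
  scales <- integer(0); ers <- numeric(0)
  for (k in ks) {
    nseg <- 2^k
    slen <- n %/% nseg
    if (slen < 8) break
    m <- matrix(v[seq_len(slen * nseg)], nrow = slen)
    rs <- apply(m, 2, function(seg) {
      s <- sd(seg)
      if (s == 0) stop("degenerate input: zero-variance segment in R/S")
      ycum <- cumsum(seg - mean(seg))
      (max(ycum) - min(ycum)) / s
    })
    scales <- c(scales, slen)
    ers <- c(ers, mean(rs))
  }
  fit <- ols_fit(log2(scales), log2(ers))
  new_hurst_estimate("RS", H = fit$slope, scales = sort(scales),
                     slope = fit$slope, r2 = fit$r2,
                     diagnostics = list(
                       ERS = ers,
                       note = "R/S carries a small-sample upward bias"))
}
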