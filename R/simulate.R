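# Generators for fractional Brownian motion, brown noise, and
# spike-contaminated series used by every benchmark.

# Closed-form fGn autocovariance at lags 0..n for unit variance.
fgn_autocov <- function(H, n) {
  k <- 0:n
  0.5 * (abs(k + 1)^(2 * H) - 2 * abs(k)^(2 * H) + abs(k - 1)^(2 * H))
}

# Exact fGn by circulant embedding (Davies-Harte). Returns an n x n_series
# matrix. Eigenvalues are computed once per (H, n), so batch generation is
# cheap.
fgn_circulant <- function(n, H, n_series = 1, seed = NULL) {
  stopifnot(H > 0, H < 1, n >= 2)
  g <- fgn_autocov(H, n)
  m <- 2L * n
  circ <- c(g, g[n:2])                 # gamma_0..gamma_n, gamma_{n-1}..gamma_1
  ev <- Re(fft(circ))
  ev[ev < 0 & ev > -1e-8] <- 0         # clamp tiny fp negatives
  if (any(ev < 0))
    stop("circulant embedding produced negative eigenvalues; cannot generate")
  with_seed(seed, {
    U <- matrix(rnorm(m * n_series), m, n_series)
    V <- matrix(rnorm(m * n_series), m, n_series)
    a <- matrix(complex(real = 0), m, n_series)
    half <- n                          # m/2
    sc_mid <- sqrt(ev[c(1, half + 1)] / m)
    a[1, ] <- sc_mid[1] * U[1, ]
    a[half + 1, ] <- sc_mid[2] * U[half + 1, ]
    idx <- 2:half
    sc <- sqrt(ev[idx] / (2 * m))
    a[idx, ] <- sc * complex(real = U[idx, , drop = FALSE],
                             imaginary = V[idx, , drop = FALSE])
    a[m + 2 - idx, ] <- Conj(a[idx, ])
    Re(mvfft(a))[1:n, , drop = FALSE]
  })
}

# Exact variance of the level-j detail coefficient of fBm(H) sampled at
# the integers, via the effective cascade filter f_j (scaling filter h
# cascaded j-1 times, then the wavelet filter g): since sum(f_j) = 0,
#   Var(d_j) = -0.5 * sum_d r_j[d] |d|^(2H),
# with r_j the autocorrelation of f_j and unit-lag increment variance 1.
wavelet_detail_sds <- function(H, J, order) {
  filt <- db_filter_pair(order)
  upsample <- function(f, s) {
    out <- numeric((length(f) - 1) * s + 1)
    out[seq(1, length(out), by = s)] <- f
    out
  }
  sds <- numeric(J)
  hcasc <- 1
  for (j in seq_len(J)) {
    fj <- convolve(hcasc, rev(upsample(filt$g, 2^(j - 1))), type = "open")
    r <- convolve(fj, fj, type = "open")       # autocorrelation, lag 0 center
    lags <- seq_along(r) - (length(fj))
    sds[j] <- sqrt(-0.5 * sum(r * abs(lags)^(2 * H)))
    hcasc <- convolve(hcasc, rev(upsample(filt$h, 2^(j - 1))), type = "open")
  }
  sds
}

# Approximate fBm by wavelet synthesis: an exact coarse-scale process is
# refined level by level with iid detail coefficients carrying the exact
# per-level fBm detail variance for the chosen filter. A path twice the
# requested length is synthesized and the first half kept, so the
# periodic boundary of the inverse transform does not fold back into the
# sample.
fbm_wavelet_one <- function(n, H, order = 8) {
  m <- 2^ceiling(log2(2 * n))
  J <- floor(log2(m)) - 4L             # leave 16 coarse coefficients
  J <- max(J, 1L)
  n_coarse <- m / 2^J
  coarse_path <- cumsum(fgn_circulant(n_coarse, H, 1)[, 1])
  sds <- wavelet_detail_sds(H, J, order)
  details <- vector("list", J)
  for (j in seq_len(J)) {
    nj <- m / 2^j
    details[[j]] <- rnorm(nj, sd = sds[j])
  }
  w <- list(details = details, approx = 2^(J * (H + 0.5)) * coarse_path,
            order = order)
  x <- idwt_periodic(w)[1:n]
  x - x[1]
}

#' Generate fractional Brownian motion
#'
#' Default generator is exact circulant embedding (Davies-Harte) of the
#' fGn covariance followed by cumulative summation; `"wavelet"` selects a
#' wavelet-synthesis construction (exact coarse-scale process refined
#' with scaled iid detail coefficients through the inverse Daubechies
#' transform). The generator matters experimentally: synthesis artifacts
#' such as a spectral ceiling are specific to the wavelet construction,
#' which is why it stays switchable.
#'
#' @param n series length (>= 64).
#' @param H true Hurst exponent in (0, 1).
#' @param seed integer seed for reproducibility (same seed, same path).
#' @param generator `"circulant"` or `"wavelet"`.
#' @return numeric vector of length `n` (walk class).
#' @export
fbm <- function(n, H, seed = NULL, generator = c("circulant", "wavelet")) {
  generator <- match.arg(generator)
  if (!is.numeric(H) || H <= 0 || H >= 1) stop("H must lie strictly in (0, 1)")
  if (n < 64) stop("fBm generator needs n >= 64")
  if (generator == "circulant") {
    cumsum(fgn_circulant(n, H, 1, seed = seed)[, 1])
  } else {
    with_seed(seed, fbm_wavelet_one(n, H))
  }
}

#' Generate a batch of fBm series
#'
#' Matrix version of [fbm()]; for the circulant generator the embedding
#' eigenvalues are factored out across series, which makes the simulation
#' benchmarks fast.
#'
#' @inheritParams fbm
#' @param n_series number of independent paths.
#' @return numeric matrix `n x n_series`, each column one path.
#' @export
fbm_batch <- function(n, H, n_series, seed = NULL,
                      generator = c("circulant", "wavelet")) {
  generator <- match.arg(generator)
  if (!is.numeric(H) || H <= 0 || H >= 1) stop("H must lie strictly in (0, 1)")
  if (n < 64) stop("fBm generator needs n >= 64")
  if (generator == "circulant") {
    inc <- fgn_circulant(n, H, n_series, seed = seed)
    apply(inc, 2, cumsum)
  } else {
    with_seed(seed, {
      vapply(seq_len(n_series), function(i) fbm_wavelet_one(n, H), numeric(n))
    })
  }
}

#' Generate fractional Gaussian noise
#'
#' Exact circulant-embedding fGn (the stationary increment process of
#' fBm) with unit marginal variance.
#'
#' @inheritParams fbm_batch
#' @return numeric matrix `n x n_series` (increments class).
#' @export
fgn_batch <- function(n, H, n_series = 1, seed = NULL) {
  if (!is.numeric(H) || H <= 0 || H >= 1) stop("H must lie strictly in (0, 1)")
  fgn_circulant(n, H, n_series, seed = seed)
}

#' Generate brown noise
#'
#' Cumulative sum of iid standard Gaussian draws (a random walk; H = 0.5
#' walk-class signal with spectral exponent beta = 2).
#'
#' @param n series length (>= 2).
#' @param seed integer seed.
#' @return numeric vector of length `n`.
#' @export
brown_noise <- function(n, seed = NULL) {
  if (n < 2) stop("brown noise needs n >= 2")
  with_seed(seed, cumsum(rnorm(n)))
}

#' Inject spike artifacts into a series
#'
#' Offsets a uniformly chosen subset of `round(fraction * n)` distinct
#' points by `sign * magnitude * sd(x)`, with independent equiprobable
#' signs per spike; the spike amplitude is scaled by the standard
#' deviation of the pre-spike series, and all untouched points are
#' bit-identical to the input. Spikes are additive offsets to the
#' existing values (preserving the local sample) rather than
#' replacements.
#'
#' @param x numeric vector or [hurst_ts()].
#' @param fraction share of points to spike, in `[0, 0.05]` typically.
#' @param magnitude spike magnitude in units of the series SD, `[0, 6]`
#'   typically.
#' @param seed integer seed (same seed, same spikes).
#' @return numeric vector with attributes `spike_index` and `spike_sign`.
#' @export
inject_spikes <- function(x, fraction, magnitude, seed = NULL) {
  v <- ts_values(x)
  n <- length(v)
  stopifnot(fraction >= 0, magnitude >= 0)
  k <- round(fraction * n)
  if (k > n) stop("fraction implies more spikes than points")
  if (k == 0 || magnitude == 0) {
    if (k == 0) {
      attr(v, "spike_index") <- integer(0)
      attr(v, "spike_sign") <- integer(0)
      return(v)
    }
  }
  s <- sd(v)
  with_seed(seed, {
    idx <- sample.int(n, k)
    signs <- sample(c(-1L, 1L), k, replace = TRUE)
    v[idx] <- v[idx] + signs * magnitude * s
    attr(v, "spike_index") <- idx
    attr(v, "spike_sign") <- signs
    v
  })
}
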