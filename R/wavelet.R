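# Periodized orthogonal discrete wavelet transform with Daubechies filters.
# Implemented in-package (decomposition/reconstruction pyramid); underlies
# the wavelet-variance Hurst estimators, the wavelet-prefiltered
# second-derivative estimator, and the wavelet fBm synthesizer.

# Daubechies scaling (low-pass decomposition) filters, standard published
# coefficients, extremal-phase family; dbN has 2N taps.
daubechies_filters <- list(
  db1 = c(0.7071067811865476, 0.7071067811865476),
  db2 = c(-0.12940952255126037, 0.2241438680420134, 0.8365163037378079,
          0.48296291314453416),
  db4 = c(-0.01059740178506903, 0.0328830116668852, 0.03084138183556076,
          -0.18703481171909309, -0.02798376941685985, 0.6308807679298589,
          0.7148465705529157, 0.2303778133088965),
  db8 = c(-0.00011747678412477, 0.00067544940645057, -0.00039174037337695,
          -0.00487035299345157, 0.00874609404740578, 0.01398102791739828,
          -0.04408825393079475, -0.01736930100180755, 0.12874742662047847,
          0.00047248457391328, -0.2840155429615469, -0.01582910525634931,
          0.5853546836542067, 0.6756307362972898, 0.31287159091429995,
          0.05441584224310401),
  db16 = c(-2.10933963e-08, 2.3087840869e-07, -7.3636567855e-07,
           -1.04357134231e-06, 1.133660866128e-05, -1.394566898821e-05,
           -6.103596621411e-05, 0.00017478724522534, 0.00011424152003872,
           -0.00094102174935957, 0.00040789698084971, 0.00312802338120627,
           -0.00364427962149839, -0.00699001456341392, 0.01399376885982873,
           0.01029765964095597, -0.03688839769173014, -0.00758897436885774,
           0.07592423604427631, -0.00623972275247487, -0.1323883055638104,
           0.02734026375271604, 0.2111906939471043, -0.02791820813302828,
           -0.3270633105279177, -0.08975108940248964, 0.4402902568863569,
           0.637356332083789, 0.4303127228460038, 0.16506428348885313,
           0.03490771432367334, 0.00318922092534774)
)

db_filter_pair <- function(order) {
  key <- paste0("db", order)
  h <- daubechies_filters[[key]]
  if (is.null(h)) stop("unsupported Daubechies order: ", order)
  # quadrature mirror high-pass
  g <- rev(h) * (-1)^(seq_along(h) - 1L)
  list(h = h, g = g)
}

# One periodized analysis step: circular inner products of the filter with
# windows starting at every second sample. Input length must be even.
dwt_step <- function(x, f) {
  n <- length(x)
  half <- n %/% 2L
  out <- numeric(half)
  idx0 <- (seq_len(half) - 1L) * 2L          # window starts (0-based)
  for (i in seq_along(f)) {
    out <- out + f[i] * x[(idx0 + (i - 1L)) %% n + 1L]
  }
  out
}

# Adjoint of dwt_step (used for synthesis); y has length n/2, returns n.
# Within one tap the wrapped positions are distinct (stride-2 values
# spanning a range < n), so plain indexed accumulation is exact.
idwt_step <- function(y, f, n) {
  out <- numeric(n)
  idx0 <- (seq_along(y) - 1L) * 2L
  for (i in seq_along(f)) {
    pos <- (idx0 + (i - 1L)) %% n + 1L
    out[pos] <- out[pos] + f[i] * y
  }
  out
}

#' Periodized Daubechies wavelet decomposition
#'
#' Pyramid decomposition with circular (periodic) boundary handling. At
#' each level an odd-length approximation is truncated by one sample
#' before filtering, so arbitrary input lengths are accepted.
#'
#' @param x numeric vector.
#' @param order Daubechies filter order: one of 1, 2, 4, 8, 16.
#' @param max_level deepest level to compute; default as deep as the data
#'   allow (approximation at least as long as the filter).
#' @return List with `details` (list of per-level detail coefficients),
#'   `approx` (coarsest approximation) and `order`.
#' @export
dwt_periodic <- function(x, order = 1, max_level = NULL) {
  filt <- db_filter_pair(order)
  x <- as.numeric(x)
  if (is.null(max_level)) max_level <- 64L  # limited by length below
  details <- list()
  a <- x
  lev <- 0L
  while (lev < max_level) {
    na <- length(a) - length(a) %% 2L    # even part only
    if (na < max(2L, length(filt$h))) break
    a_use <- a[seq_len(na)]
    d <- dwt_step(a_use, filt$g)
    a <- dwt_step(a_use, filt$h)
    lev <- lev + 1L
    details[[lev]] <- d
  }
  list(details = details, approx = a, order = order)
}

# Boundary-free analysis pyramid: valid-part decimated convolution at
# every level, so no wraparound coefficient ever mixes the (nonstationary)
# series end with its start. Used by the wavelet-variance estimators;
# coefficients touching the boundary are simply discarded, as is standard
# in wavelet scaling estimation.
dwt_valid <- function(x, order = 1, max_level = 64L) {
  filt <- db_filter_pair(order)
  lf <- length(filt$h)
  valid_step <- function(a, f) {
    n <- length(a)
    nk <- (n - lf) %/% 2L + 1L
    if (nk < 1L) return(numeric(0))
    out <- numeric(nk)
    idx0 <- (seq_len(nk) - 1L) * 2L
    for (i in seq_len(lf)) out <- out + f[i] * a[idx0 + i]
    out
  }
  a <- as.numeric(x)
  details <- list()
  lev <- 0L
  while (lev < max_level && length(a) >= lf + 1L) {
    d <- valid_step(a, filt$g)
    a2 <- valid_step(a, filt$h)
    if (length(d) < 1L) break
    lev <- lev + 1L
    details[[lev]] <- d
    a <- a2
  }
  list(details = details, approx = a, order = order)
}

# Inverse of dwt_periodic for lengths that are exact powers of two times
# the coarse length (synthesis use only).
idwt_periodic <- function(w) {
  filt <- db_filter_pair(w$order)
  a <- w$approx
  for (lev in rev(seq_along(w$details))) {
    d <- w$details[[lev]]
    n <- 2L * length(d)
    a <- idwt_step(a, filt$h, n) + idwt_step(d, filt$g, n)
  }
  a
}
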