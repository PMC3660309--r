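# Unit tests for the individual Hurst estimators: brute-force oracle
# equivalence on small fixed inputs, exact special cases, and general
# estimator properties.

test_that("structure-function estimator matches the brute-force oracle and is exact on a line", {
  set.seed(101)
  x <- cumsum(rnorm(250))
  for (q in 1:2) {
    est <- hurst_sf(x, q = q)
    orc <- oracle_structure_function(x, est$scales, q)
    expect_equal(est$H, orc$H, tolerance = 1e-10)
  }
  # |x(t+tau) - x(t)| = tau exactly for a straight line
  line <- seq_len(200)
  expect_equal(hurst_sf(line, q = 1)$H, 1, tolerance = 1e-10)
  expect_equal(hurst_sf(line, q = 2)$H, 1, tolerance = 1e-10)
  expect_error(hurst_sf(rep(2, 200)), "degenerate")
  expect_error(hurst_sf(rnorm(50)), "n >= 100")
})

test_that("generalized Hurst estimator averages per-tau_max fits and matches a direct reimplementation", {
  set.seed(102)
  x <- cumsum(rnorm(64))
  est <- hurst_gen(x, q = 2, max_lag = 5)
  # with max_lag = 5 only tau_max = 5 contributes: one OLS fit over tau 1..5
  S <- sapply(1:5, function(tau)
    mean(abs(x[(1 + tau):64] - x[1:(64 - tau)])^2))
  expect_equal(est$H, unname(coef(lm(log(S) ~ log(1:5)))[2]) / 2,
               tolerance = 1e-10)
  expect_equal(hurst_gen(seq_len(200), q = 1)$H, 1, tolerance = 1e-8)
  # averaging over tau_max = 5..19 equals the mean of the individual fits
  y <- cumsum(rnorm(300))
  full <- hurst_gen(y, q = 1)
  expect_length(full$diagnostics$per_tau_max_H, 15)
  expect_equal(full$H, mean(full$diagnostics$per_tau_max_H))
})

test_that("aggregated variance matches brute-force block variances and the iid closed form", {
  set.seed(103)
  x <- rnorm(16)
  vars <- oracle_aggvar_variances(x, c(2, 4))
  # same quantities as computed internally
  internal <- sapply(c(2, 4), function(m) {
    nb <- 16 %/% m
    var(colMeans(matrix(x[1:(nb * m)], nrow = m)))
  })
  expect_equal(internal, vars, tolerance = 1e-12)
  # var of block means of iid noise is sigma^2/m: slope -1, H = 0.5
  z <- rnorm(10000)
  expect_equal(hurst_aggvar(z)$H, 0.5, tolerance = 0.05)
  # walk-class input without differencing saturates and is flagged
  w <- hurst_aggvar(cumsum(rnorm(2000)))
  expect_true(w$diagnostics$saturated)
  expect_error(hurst_aggvar(rep(1, 100)), "degenerate|constant")
})

test_that("Higuchi estimator: oracle equivalence, identity, and length guard", {
  set.seed(105)
  x <- cumsum(rnorm(64))
  est <- hurst_higuchi(x, kmax = 3)
  L <- oracle_higuchi_lengths(x, 3)
  fit <- lm(log(L) ~ log(1:3))
  expect_equal(est$H, 2 + unname(coef(fit)[2]), tolerance = 1e-10)
  expect_equal(est$diagnostics$D + est$H, 2, tolerance = 1e-12)
  expect_error(hurst_higuchi(rnorm(40), kmax = 5), "too short")
})

test_that("second-derivative estimator matches brute-force energies and rejects linear input", {
  set.seed(106)
  x <- cumsum(rnorm(32))
  est <- hurst_secderiv(x, "fir")
  d1 <- sapply(1:30, function(t) x[t + 2] - 2 * x[t + 1] + x[t])
  d2 <- sapply(1:28, function(t) x[t + 4] - 2 * x[t + 2] + x[t])
  expect_equal(est$H, 0.5 * log2(mean(d2^2) / mean(d1^2)), tolerance = 1e-12)
  expect_error(hurst_secderiv(1:100, "fir"), "degenerate")
  expect_error(hurst_secderiv(1:100, "wavelet"), "degenerate")
})

test_that("wavelet-variance estimator rejects constants and short input", {
  expect_error(hurst_wavvar(rep(3, 512), 2), "degenerate|zero")
  expect_error(hurst_wavvar(rnorm(24), 8), "too short")
})

test_that("PSD estimator recovers the slope of an exact spectral construction", {
  # synthesize |X(f)|^2 proportional to f^-2 with random phases: beta = 2, H = 0.5
  set.seed(107)
  n <- 4096
  f <- 1:(n / 2)
  amp <- f^(-1)
  phases <- runif(n / 2 - 1, 0, 2 * pi)
  X <- complex(modulus = c(0, amp),
               argument = c(0, phases, 0))
  Xfull <- c(X, Conj(rev(X[2:(n / 2)])))
  x <- Re(fft(Xfull, inverse = TRUE)) / n
  expect_equal(hurst_psd(x, "fft")$H, 0.5, tolerance = 0.02)
  # white noise: flat spectrum, beta = 0, H = -0.5, reported unclipped
  set.seed(108)
  expect_equal(hurst_psd(rnorm(8192), "fft")$H, -0.5, tolerance = 0.1)
  expect_lt(hurst_psd(rnorm(8192), "welch")$H, -0.3)
  expect_error(hurst_psd(rnorm(512), "fft", fit_band = c(0.01, 0.012)),
               "fewer than 4")
})

test_that("DFA fluctuation function matches the sliding-window lm oracle", {
  set.seed(109)
  x <- rnorm(64)
  fl <- fmrihurst:::dfa_fluctuation(x)
  boxes <- c(4, 8, 16)
  orc <- oracle_dfa_F(x, boxes)
  got <- fl$F[match(boxes, fl$boxes)]
  expect_equal(got, orc, tolerance = 1e-10)
})

test_that("DFA box-range split brackets the documented ranges at n = 1190 and rejects linear input", {
  boxes <- fmrihurst:::dfa_box_grid(1190)
  expect_equal(min(boxes), 4)
  expect_true(max(boxes) <= 1190 / 4 & max(boxes) >= 270)
  split <- fmrihurst:::dfa_split_box(boxes)
  expect_gt(split, 28); expect_lt(split, 45)
  # a constant series has a flat (linear, after integration) profile:
  # detrending removes it entirely at every box size
  expect_error(hurst_dfa(rep(2.5, 200)), "degenerate|zero fluctuation")
})

test_that("rescaled range follows the six-step recipe exactly and guards short/degenerate input", {
  set.seed(110)
  x <- rnorm(16)
  est <- hurst_rs(x)
  orc <- oracle_rs(x)
  expect_equal(sort(est$scales), sort(orc$scales))
  expect_equal(est$H, orc$H, tolerance = 1e-10)
  expect_error(hurst_rs(rnorm(7)), "n >= 16")
  expect_error(hurst_rs(rep(1, 32)), "degenerate|zero")
})

test_that("R/S on iid Gaussian noise shows the documented small-sample upward bias", {
  hs <- sapply(1:50, function(i) {
    set.seed(2000 + i)
    hurst_rs(rnorm(4096))$H
  })
  expect_gt(mean(hs), 0.5)
  expect_lt(mean(hs), 0.65)
})

test_that("every estimator is scale-invariant and deterministic", {
  set.seed(111)
  x <- cumsum(rnorm(1190))
  b1 <- hurst_values(hurst_all(x, "walk"))
  b2 <- hurst_values(hurst_all(x * 37.5, "walk"))
  b3 <- hurst_values(hurst_all(x, "walk"))
  expect_equal(b1, b2, tolerance = 1e-9)
  expect_identical(b1, b3)
})

test_that("periodized wavelet transform reconstructs perfectly", {
  set.seed(112)
  x <- rnorm(128)
  for (ord in c(1, 2, 4, 8)) {
    w <- dwt_periodic(x, ord)
    expect_equal(fmrihurst:::idwt_periodic(w), x, tolerance = 1e-10)
  }
})
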