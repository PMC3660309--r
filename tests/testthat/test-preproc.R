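# Processing operators and the combination enumerator.

test_that("combination enumeration is complete, exclusive, and stable", {
  combos <- enumerate_combos()
  expect_equal(nrow(combos), 36)
  expect_true(all(c("o", "d-m-bcw-fhi", "d-m2-bcw-fbp", "d-bcw-fhi") %in%
                  combos$label))
  expect_equal(anyDuplicated(combos$label), 0)
  # exclusion rules: no fhi with fbp, no squares without linear motion
  expect_false(any(grepl("fhi", combos$label) & grepl("fbp", combos$label)))
  expect_false(any(combos$motion == "linear+squares" &
                   !grepl("m2", combos$label)))
  expect_false(any(grepl("m2", combos$label) &
                   combos$motion != "linear+squares"))
  # deterministic order
  expect_identical(enumerate_combos(), combos)
  expect_error(parse_combo("d-zzz"), "unknown")
})

test_that("linear detrending is exact, orthogonal, and idempotent", {
  line <- 3 + 0.5 * seq_len(200)
  expect_equal(detrend_linear(line), rep(0, 200), tolerance = 1e-10)
  set.seed(20)
  x <- rnorm(300) + 0.1 * seq_len(300)
  r <- detrend_linear(x)
  expect_lt(abs(sum(r)) / sqrt(sum(x^2)), 1e-9)
  expect_lt(abs(sum(r * seq_len(300))) / sqrt(sum(x^2)), 1e-9)
  expect_equal(detrend_linear(r), r, tolerance = 1e-12)
})

test_that("detrending restores the scaling of a drifting fGn series", {
  hs <- sapply(1:30, function(i) {
    g <- fgn_batch(1190, 0.7, 1, seed = 400 + i)[, 1]
    trended <- g + seq(0, 5, length.out = 1190)
    c(clean = estimate_hurst(g, "DFA", "increments")$H,
      detr = estimate_hurst(detrend_linear(trended), "DFA", "increments")$H)
  })
  expect_lt(abs(mean(hs["detr", ]) - mean(hs["clean", ])), 0.1)
})

test_that("nuisance regression removes design columns exactly", {
  set.seed(21)
  mot <- matrix(rnorm(200 * 6), 200, 6)
  design <- nuisance_design(mot)
  # a series that IS a motion column regresses to zero
  r <- regress_nuisance(mot[, 1], design)
  expect_lt(max(abs(r)), 1e-9)
  # residual orthogonal to every selected column
  x <- rnorm(200)
  r2 <- regress_nuisance(x, design, include_squares = TRUE)
  X <- cbind(1, mot, mot^2)
  expect_lt(max(abs(crossprod(X, r2))) / sqrt(sum(x^2)), 1e-9)
})

test_that("rank-deficient designs fail loudly, naming the collinear columns", {
  set.seed(22)
  mot <- matrix(rnorm(100 * 6), 100, 6)
  mot[, 2] <- 2 * mot[, 1]
  design <- nuisance_design(mot)
  expect_error(regress_nuisance(rnorm(100), design), "collinear")
  expect_error(regress_nuisance(rnorm(50), design), "rows")
  expect_error(regress_nuisance(rnorm(100), design, include_motion = FALSE,
                                include_squares = TRUE), "require the linear")
})

test_that("nuisance regression recovers a signal mixed with motion", {
  set.seed(23)
  mot <- sapply(1:6, function(j) cumsum(rnorm(1190, sd = 0.05)))
  sig <- fgn_batch(1190, 0.7, 1, seed = 9)[, 1]
  voxel <- sig + 0.8 * scale(mot[, 1])[, 1]
  r <- regress_nuisance(voxel, nuisance_design(mot))
  expect_gt(cor(r, sig), 0.95)
})

test_that("Butterworth filtering attenuates and passes the right bands", {
  tr <- 2.5
  t_sec <- (0:999) * tr
  slow <- sin(2 * pi * 0.001 * t_sec)
  hp <- butterworth_filter(slow, "highpass", tr_seconds = tr)
  expect_lt(max(abs(hp[100:900])), 0.05)
  mid <- sin(2 * pi * 0.05 * t_sec)
  bp <- butterworth_filter(mid, "bandpass", tr_seconds = tr)
  expect_gt(max(abs(bp[100:900])), 0.9)
  expect_length(hp, 1000)   # no edge trimming
  expect_error(butterworth_filter(rnorm(100), "bandpass", tr_seconds = 6),
               "Nyquist")
})

test_that("band-passed white noise keeps its spectral mass inside the band", {
  set.seed(24)
  tr <- 2.1
  y <- butterworth_filter(rnorm(1190), "bandpass", tr_seconds = tr)
  sp <- stats::spec.pgram(stats::ts(y, frequency = 1 / tr), spans = 15,
                          plot = FALSE, taper = 0.1)
  inband <- sp$freq >= 0.01 & sp$freq <= 0.1
  expect_lt(sum(sp$spec[!inband]) / sum(sp$spec), 0.02)
})

test_that("apply_combo composes operators in the documented order", {
  set.seed(25)
  x <- rnorm(300) + 0.02 * seq_len(300)
  expect_identical(apply_combo(x, "o"), x)
  lhs <- apply_combo(x, "d-fhi", tr_seconds = 2.1)
  rhs <- butterworth_filter(detrend_linear(x), "highpass", tr_seconds = 2.1)
  expect_equal(lhs, rhs, tolerance = 1e-12)
  expect_error(apply_combo(x, "d-m-fhi", tr_seconds = 2.1), "design")
})

test_that("all 36 combinations run end to end on a phantom voxel", {
  ph <- generate_phantom(phantom_spec(dim = c(4, 4, 2), n_volumes = 256,
                                      seed = 31))
  v <- fmrihurst:::voxel_series(ph$vol, 3, 3, 1)
  design <- nuisance_design(ph$vol$motion, global_regressors(ph$vol))
  for (lab in enumerate_combos()$label) {
    out <- apply_combo(v, lab, design = design,
                       tr_seconds = ph$vol$tr_seconds)
    expect_length(out, 256)
    expect_true(all(is.finite(out)))
  }
})

test_that("global regressors are per-volume mask means", {
  ph <- generate_phantom(phantom_spec(dim = c(4, 4, 2), n_volumes = 128,
                                      seed = 32))
  g <- global_regressors(ph$vol)
  expect_equal(dim(g), c(128, 3))
  # single-voxel mask returns that voxel's series exactly
  vol2 <- ph$vol
  m1 <- array(FALSE, dim = c(4, 4, 2)); m1[2, 2, 1] <- TRUE
  vol2$masks$csf <- m1
  g2 <- global_regressors(vol2)
  expect_identical(unname(g2[, "csf"]),
                   fmrihurst:::voxel_series(ph$vol, 2, 2, 1))
  # uniform data gives constant regressors
  vol3 <- ph$vol
  vol3$data[] <- 7
  g3 <- global_regressors(vol3)
  expect_true(all(g3 == 7))
  vol4 <- ph$vol
  vol4$masks$wm[] <- FALSE
  expect_error(global_regressors(vol4), "empty")
})
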