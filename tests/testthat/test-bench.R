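# Benchmark protocols at small sizes: definitional checks, provenance,
# and the plug-in calibration of the drop-off fit.

test_that("consistency benchmark reports the definitional mean absolute error", {
  res <- run_consistency(H_grid = 0.5, n_series = 8, n = 300, seed = 77,
                         include_transforms = FALSE, estimators = "HFD10")
  # recompute externally from the same generator stream
  paths <- fbm_batch(300, 0.5, 8, seed = fmrihurst:::child_seed(77, 1))
  hs <- sapply(1:8, function(i) hurst_higuchi(paths[, i], 10)$H)
  row <- res$table[res$table$estimator_id == "HFD10", ]
  expect_equal(row$mean_abs_error, mean(abs(hs - 0.5)), tolerance = 1e-12)
  expect_equal(row$mean_H, mean(hs), tolerance = 1e-12)
})

test_that("benchmark outputs are bit-identical under the same configuration", {
  a <- run_consistency(H_grid = c(0.3, 0.7), n_series = 5, n = 256, seed = 5,
                       include_transforms = FALSE,
                       estimators = c("HFD5", "FFT"))
  b <- run_consistency(H_grid = c(0.3, 0.7), n_series = 5, n = 256, seed = 5,
                       include_transforms = FALSE,
                       estimators = c("HFD5", "FFT"))
  expect_identical(a$table, b$table)
})

test_that("integral and derivative variants behave as the boundedness analysis predicts", {
  res <- run_consistency(H_grid = 0.5, n_series = 30, n = 1190, seed = 21,
                         include_transforms = TRUE,
                         estimators = c("FFT", "HFD10", "Q1a"))
  tab <- res$table
  sig <- function(id) tab$mean_H[tab$estimator_id == id & tab$variant == "signal"]
  der <- function(id) tab$mean_H[tab$estimator_id == id & tab$variant == "derivative"]
  int_ <- function(id) tab$mean_H[tab$estimator_id == id & tab$variant == "integral"]
  # unbounded FFT: derivative curve sits ~1 below the signal curve
  expect_equal(sig("FFT") - der("FFT"), 1, tolerance = 0.3)
  expect_equal(int_("FFT") - sig("FFT"), 1, tolerance = 0.3)
  # bounded estimators saturate instead of following the offset
  expect_true(all(tab$saturated[tab$estimator_id == "HFD10" &
                                tab$variant != "signal"]))
})

test_that("spike benchmark: zero cells are exactly zero and normalization spans [0, 1]", {
  sb <- run_spike_benchmark(n_series = 20, n = 300,
                            fraction_grid = c(0, 0.05),
                            magnitude_grid = c(0, 4), seed = 3,
                            estimators = c("FFT", "HFD10", "db8"))
  expect_true(all(sb$t[, "0", ] == 0))
  expect_true(all(sb$t[, , "0"] == 0))
  expect_equal(min(sb$normalized), 0)
  expect_equal(max(sb$normalized), 1)
  expect_true(all(is.finite(sb$volume)))
})

test_that("heavy spiking collapses estimates toward a measure-specific fixed point", {
  # each estimator has its own spike-dominated reference value; the
  # observable consequence is that estimates from strongly persistent
  # (H = 0.9) series drop, and the 0.1-vs-0.9 spread is compressed
  means <- lapply(c(0.1, 0.9), function(H) {
    paths <- fbm_batch(512, H, 25, seed = round(100 * H) + 7)
    ids <- c("RS", "HFD10", "FFT", "Q2a")
    clean <- rowMeans(sapply(1:25, function(i)
      hurst_values(hurst_all(paths[, i], "walk", estimators = ids))))
    spiked <- rowMeans(sapply(1:25, function(i)
      hurst_values(hurst_all(as.numeric(
        inject_spikes(paths[, i], 0.05, 6, seed = i)), "walk",
        estimators = ids))))
    list(clean = clean, spiked = spiked)
  })
  lo <- means[[1]]; hi <- means[[2]]
  # persistent series always lose apparent persistence
  expect_true(all(hi$spiked < hi$clean))
  # the increments-class R/S pull is two-sided (white-noise value ~0.5)
  expect_gt(lo$spiked["RS"], lo$clean["RS"])
  # spiking compresses the measurable H range for every estimator
  expect_true(all(hi$spiked - lo$spiked < hi$clean - lo$clean))
})

test_that("correlation benchmark matrices are symmetric with unit diagonal", {
  cb <- run_correlation_benchmark(n_series = 25, n = 300, seed = 8,
                                  estimators = c("Q1a", "Q2a", "HFD10", "FFT"))
  expect_equal(diag(cb$accuracy), rep(1, 4), ignore_attr = TRUE)
  expect_equal(diag(cb$precision), rep(1, 4), ignore_attr = TRUE)
  expect_equal(cb$accuracy, t(cb$accuracy))
  expect_equal(cb$precision, t(cb$precision))
})

test_that("drop-off rate is 0.5 for a plug-in root-n statistic (CLT calibration)", {
  res <- run_error_dropoff(n_reps = 60, seed = 12,
                           estimators = list(inc_mean = function(x) mean(diff(x))))
  row <- res$table[res$table$estimator_id == "inc_mean", ]
  expect_lt(abs(row$alpha - 0.5), 2 * row$alpha_se)
})

test_that("drop-off bootstrap comparison returns a valid probability", {
  res <- run_error_dropoff(lengths = round(10^seq(2, 3.3, length.out = 6)),
                           n_reps = 30, seed = 14,
                           estimators = c("FFT", "HFD10"))
  cmp <- dropoff_compare(res, "HFD10", "FFT", n_boot = 200, seed = 1)
  expect_true(cmp$p_value > 0 && cmp$p_value <= 1)
  expect_true(is.finite(cmp$delta))
})
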