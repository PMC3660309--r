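# Voxelwise maps, tissue contrast, ROC overlap, ISC, windowed profiles,
# and region-average PCA.

make_clean_phantom <- function(seed = 1, dim = c(6, 6, 2), n_volumes = 256,
                               ...) {
  generate_phantom(phantom_spec(dim = dim, n_volumes = n_volumes,
                                drift_amplitude = 0, motion_coupling = 0,
                                global_amplitude = 0, seed = seed, ...))
}

test_that("hurst_map covers the brain mask only and is reproducible", {
  ph <- make_clean_phantom(2)
  hm1 <- hurst_map(ph$vol, "o", "HFD10")
  hm2 <- hurst_map(ph$vol, "o", "HFD10")
  expect_identical(hm1, hm2)
  expect_true(all(is.na(hm1[!ph$vol$masks$brain])))
  expect_true(all(is.finite(hm1[ph$vol$masks$brain])))
  expect_gt(mean(hm1[ph$vol$masks$gm]), mean(hm1[ph$vol$masks$wm]))
})

test_that("gm_wm_contrast is antisymmetric in the masks and guards sample size", {
  ph <- make_clean_phantom(3)
  hm <- hurst_map(ph$vol, "o", "HFD5")
  ct <- gm_wm_contrast(hm, ph$vol$masks$gm, ph$vol$masks$wm, min_voxels = 20)
  ct_swap <- gm_wm_contrast(hm, ph$vol$masks$wm, ph$vol$masks$gm,
                            min_voxels = 20)
  expect_equal(ct$t, -ct_swap$t, tolerance = 1e-12)
  expect_gt(ct$t, 0)
  expect_error(gm_wm_contrast(hm, ph$vol$masks$gm, ph$vol$masks$csf,
                              min_voxels = 30), "valid voxels")
})

test_that("ROC AUC: perfect self-overlap, null behavior, and monotone invariance", {
  set.seed(4)
  ref <- array(rnorm(4000), dim = c(20, 20, 10))
  # the reference scored against itself is perfectly separable
  expect_equal(roc_auc_map(ref, ref, top_frac = 0.01)$auc, 1)
  # an independent score map carries no information
  perm <- array(sample(ref), dim = dim(ref))
  expect_lt(abs(roc_auc_map(perm, ref, top_frac = 0.05)$auc - 0.5), 0.1)
  # AUC is invariant under strictly monotone transforms of the score
  score <- array(rnorm(4000), dim = dim(ref)) + 0.5 * ref
  a1 <- roc_auc_map(score, ref, top_frac = 0.05)$auc
  a2 <- roc_auc_map(exp(score), ref, top_frac = 0.05)$auc
  expect_equal(a1, a2, tolerance = 1e-12)
  # constant score map: AUC 0.5 with a degeneracy flag
  const <- array(1, dim = dim(ref))
  r <- roc_auc_map(const, ref, top_frac = 0.05)
  expect_equal(r$auc, 0.5)
  expect_true(r$degenerate)
  expect_error(roc_auc_map(score, ref, top_frac = 0.001), "fewer than 10")
  expect_error(roc_auc_map(score, array(1, c(2, 2, 2))), "same grid")
})

test_that("ISC map: degenerate, null, and shared-signal behavior; subject-order invariance", {
  # identical subjects: r = 1 capped and flagged
  ph <- make_clean_phantom(5, dim = c(4, 4, 2), n_volumes = 128)
  same <- list(ph$vol, ph$vol, ph$vol)
  z <- isc_map(same, combo = "o")
  expect_true(all(abs(z[ph$vol$masks$brain] - atanh(0.999999)) < 1e-9))
  expect_gt(attr(z, "n_capped"), 0)
  # independent subjects: mean z near zero
  indep <- lapply(6:9, function(s) make_clean_phantom(s, dim = c(4, 4, 2),
                                                      n_volumes = 128)$vol)
  z0 <- isc_map(indep, combo = "o")
  vals <- z0[indep[[1]]$masks$brain]
  expect_lt(abs(mean(vals)), 3 * sd(vals) / sqrt(length(vals)) + 0.05)
  # permuting the subject list changes nothing
  z0p <- isc_map(rev(indep), combo = "o")
  expect_equal(z0, z0p, ignore_attr = TRUE, tolerance = 1e-12)
  expect_error(isc_map(indep[1:2]), "at least 3")
})

test_that("subjects sharing a task envelope show elevated ISC in the activated region", {
  subs <- lapply(1:4, function(s)
    generate_phantom(phantom_spec(dim = c(6, 6, 2), n_volumes = 256,
                                  drift_amplitude = 0, motion_coupling = 0,
                                  global_amplitude = 0,
                                  activation_amplitude = 1.5,
                                  seed = 40 + s)))
  z <- isc_map(lapply(subs, `[[`, "vol"), combo = "o")
  act <- subs[[1]]$truth$activation_mask
  bg <- subs[[1]]$vol$masks$brain & !act
  za <- z[act]; zb <- z[bg]
  se <- sqrt(var(za) / length(za) + var(zb) / length(zb))
  expect_gt(mean(za) - mean(zb), 5 * se)
})

test_that("window profile geometry reproduces the documented 77% overlap", {
  x <- fgn_batch(1190, 0.6, 1, seed = 10)[, 1]
  wp <- window_profile(x, tr_seconds = 2.1, n_windows = 15,
                       window_minutes = 10, estimators = "HFD10")
  expect_equal(wp$n_windows, 15)
  expect_lt(abs(wp$overlap_percent - 77), 1)
  # windows start at 0 and end at the series end, evenly spaced
  expect_equal(wp$starts[1], 0)
  expect_equal(wp$starts[15] + wp$window_samples, 1190)
  expect_lt(diff(range(diff(wp$starts))), 2)
  # single window: overlap undefined
  w1 <- window_profile(x, tr_seconds = 2.1, n_windows = 1)
  expect_true(is.na(w1$overlap_percent))
  expect_error(window_profile(x, tr_seconds = 2.1, window_minutes = 60),
               "longer than")
})

test_that("window H on a stationary series is stable across windows", {
  sds <- sapply(1:10, function(i) {
    g <- fgn_batch(1190, 0.7, 1, seed = 700 + i)[, 1]
    wp <- window_profile(g, tr_seconds = 2.1, estimators = "HFD10")
    sd(wp$H[, "HFD10"])
  })
  expect_lt(mean(sds), 0.15)
})

test_that("profile correlations recover exact and degenerate covariates", {
  x <- fgn_batch(1190, 0.6, 1, seed = 11)[, 1]
  wp <- window_profile(x, tr_seconds = 2.1, estimators = "HFD10")
  h <- wp$H[, "HFD10"]
  tab <- profile_correlations(wp, list(self = h, neg = -h,
                                       flat = rep(1, 15)))
  expect_equal(tab$r[tab$covariate == "self"], 1, tolerance = 1e-9)
  expect_equal(tab$r[tab$covariate == "neg"], -1, tolerance = 1e-9)
  expect_true(tab$constant_covariate[tab$covariate == "flat"])
  expect_true(is.na(tab$r[tab$covariate == "flat"]))
})

test_that("windowed H tracks a known modulation envelope", {
  # splice two fGn regimes in blocks at least one window long, so that
  # some windows sit in a pure regime
  lo <- fgn_batch(1190, 0.4, 1, seed = 12)[, 1]
  hi <- fgn_batch(1190, 0.85, 1, seed = 13)[, 1]
  gate <- rep(rep(c(0, 1), each = 300), length.out = 1190)
  x <- ifelse(gate == 1, hi, lo)
  wp <- window_profile(x, tr_seconds = 2.1, estimators = "HFD10")
  env <- sapply(seq_len(15), function(w) {
    rows <- (wp$starts[w] + 1):(wp$starts[w] + wp$window_samples)
    mean(gate[rows])
  })
  tab <- profile_correlations(wp, list(envelope = env))
  expect_gt(tab$r[1], 0.8)
})

test_that("region PCA separates groups with a global H offset and ignores region order", {
  atlas <- array(rep(1:12, length.out = 72), dim = c(6, 6, 2))
  mk <- function(H, seed) make_clean_phantom(seed, dim = c(6, 6, 2),
                                             n_volumes = 300,
                                             H_gm = H, H_wm = H, H_csf = H)$vol
  vols <- c(lapply(1:10, function(s) mk(0.5, 100 + s)),
            lapply(1:10, function(s) mk(0.65, 200 + s)))
  groups <- rep(c("A", "B"), each = 10)
  res <- region_pca_separation(vols, atlas, groups, combo = "o",
                               estimator_id = "HFD10")
  expect_lt(res$p, 0.01)
  # permuting region labels leaves the separation unchanged
  relab <- array(((atlas + 4) %% 12) + 1, dim = dim(atlas))
  res2 <- region_pca_separation(vols, relab, groups, combo = "o",
                                estimator_id = "HFD10")
  expect_equal(abs(res$t), abs(res2$t), tolerance = 1e-6)
  # identical groups: no separation (null calibration)
  vols0 <- c(lapply(1:4, function(s) mk(0.5, 300 + s)),
             lapply(1:4, function(s) mk(0.5, 400 + s)))
  res0 <- region_pca_separation(vols0, atlas, rep(c("A", "B"), each = 4),
                                combo = "o", estimator_id = "HFD10")
  expect_gt(res0$p, 0.05)
})

test_that("the full combination x estimator metric grid completes without failures", {
  ph <- generate_phantom(phantom_spec(dim = c(8, 8, 2), n_volumes = 360,
                                      seed = 77))
  ref <- with_ref_noise(ph$truth$activation_mask, seed = 78)
  grid <- metric_report_grid(ph$vol, ref, top_frac = 0.1)
  expect_equal(nrow(grid), 36 * 20)
  expect_true(all(is.finite(grid$gm_wm_t)))
  expect_true(all(is.finite(grid$auc_t)))
  expect_true(all(grid$auc_t >= 0 & grid$auc_t <= 1))
  expect_true(all(grid$n_failures == 0))
})

test_that("rank aggregation averages within-metric ranks with midrank ties", {
  tab <- data.frame(estimator_id = c("a", "b", "c"),
                    m1 = c(3, 2, 1), m2 = c(1, 2, 3))
  rk <- rank_measures(tab)
  expect_equal(rk$mean_rank, c(2, 2, 2))
  tab2 <- data.frame(estimator_id = c("a", "b", "c"),
                     m1 = c(5, 5, 1))
  rk2 <- rank_measures(tab2)
  expect_equal(rk2$mean_rank[rk2$estimator_id %in% c("a", "b")], c(1.5, 1.5))
})
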