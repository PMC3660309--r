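# Simulated-data evaluation protocols: consistency/boundedness, spike
# susceptibility, precision/accuracy correlation, and error drop-off.
# Every result object carries full provenance (seed, sizes, grids) so a
# re-run with the same configuration is bit-identical.

#' Consistency benchmark over a grid of true Hurst exponents
#'
#' For each grid value of H, generates fBm paths and runs the estimator
#' suite on the signal itself and (optionally) on its cumulative sum
#' ("integral") and first difference ("derivative"), then aggregates the
#' mean estimate and mean absolute error per estimator. Bounded
#' estimators whose integral/derivative estimates fail to follow the
#' unbounded +/-1 offset are flagged as saturated.
#'
#' @param H_grid true-H grid, strictly inside (0, 1).
#' @param n_series fBm paths per grid point (>= 50 for stable summaries).
#' @param n series length. Default 1190 samples, the longest acquisition
#'   the package's benchmarks are calibrated around.
#' @param seed integer seed.
#' @param generator fBm generator, see [fbm_batch()].
#' @param include_transforms also run the integral and derivative
#'   variants (default TRUE).
#' @param estimators estimator ids (default all twenty).
#' @return A `consistency_result`: list with `table` (one row per
#'   estimator x H x variant with `mean_H`, `mean_abs_error`, `n_ok`,
#'   `saturated`), `summary` (per-estimator mean absolute error on the
#'   signal variant), `grand_median_mae`, and the provenance fields.
#' @export
run_consistency <- function(H_grid = seq(0.05, 0.95, by = 0.05),
                            n_series = 200, n = 1190, seed = NULL,
                            generator = c("circulant", "wavelet"),
                            include_transforms = TRUE,
                            estimators = estimator_ids()) {
  generator <- match.arg(generator)
  stopifnot(all(H_grid > 0 & H_grid < 1), n_series >= 1)
  variants <- if (include_transforms) c("signal", "integral", "derivative")
              else "signal"
  rows <- list()
  for (gi in seq_along(H_grid)) {
    Ht <- H_grid[gi]
    paths <- fbm_batch(n, Ht, n_series, seed = child_seed(seed, gi),
                       generator = generator)
    for (variant in variants) {
      hmat <- vapply(seq_len(n_series), function(i) {
        x <- switch(variant,
                    signal = paths[, i],
                    integral = cumsum(paths[, i]),
                    derivative = diff(paths[, i]))
        hurst_values(hurst_all(x, "walk", estimators = estimators))
      }, numeric(length(estimators)))
      if (is.null(dim(hmat))) hmat <- matrix(hmat, nrow = 1)
      mean_H <- rowMeans(hmat, na.rm = TRUE)
      expected <- switch(variant, signal = Ht, integral = Ht + 1,
                         derivative = Ht - 1)
      mae <- rowMeans(abs(hmat - Ht), na.rm = TRUE)
      rows[[length(rows) + 1L]] <- data.frame(
        estimator_id = estimators, H_true = Ht, variant = variant,
        mean_H = mean_H, mean_abs_error = mae,
        n_ok = apply(hmat, 1, function(r) sum(!is.na(r))),
        # a bounded estimator saturates when the transformed series does
        # not move the estimate by the ~+/-1 an unbounded one would show
        # (unbounded estimators track the offset within ~0.2 here)
        saturated = variant != "signal" & abs(mean_H - expected) > 0.35,
        row.names = NULL, stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, rows)
  sig <- tab[tab$variant == "signal", ]
  summ <- aggregate(mean_abs_error ~ estimator_id, data = sig, FUN = mean)
  structure(list(
    table = tab, summary = summ,
    grand_median_mae = stats::median(summ$mean_abs_error),
    H_grid = H_grid, n_series = n_series, n = n, seed = seed,
    generator = generator
  ), class = "consistency_result")
}

#' @export
print.consistency_result <- function(x, ...) {
  cat(sprintf("<consistency_result> %d H values x %d series (n = %d, %s)\n",
              length(x$H_grid), x$n_series, x$n, x$generator))
  cat(sprintf("grand median of per-estimator mean |error|: %.4f\n",
              x$grand_median_mae))
  print(x$summary, digits = 3)
  invisible(x)
}

#' Spike-susceptibility benchmark
#'
#' Generates fBm paths at H = 0.5, injects spikes over a (fraction,
#' magnitude) grid (the same paths across cells, for variance
#' reduction), and summarizes the change in each estimator as a Welch
#' two-sample t of the spiked estimates against the clean ones: the
#' shift is measured in units of the estimator's own between-series
#' sampling spread, which is what makes susceptibility comparable across
#' estimators of very different precision. All t-scores across all
#' estimators are then jointly linearly rescaled to \[0, 1\], and each
#' estimator's volume is the total absolute deviation of its normalized
#' surface from the baseline plane (the normalized value of a zero
#' change). Cells where the fraction or the magnitude is zero leave the
#' series untouched and score t = 0 exactly.
#'
#' @param n_series paths per cell (paired across cells).
#' @param n series length.
#' @param fraction_grid spike-count grid (shares of points; includes 0).
#' @param magnitude_grid spike-magnitude grid (units of SD; includes 0).
#' @param seed integer seed.
#' @param estimators estimator ids.
#' @return A `spike_surface`: `t` and `normalized` arrays
#'   (estimator x fraction x magnitude), `volume` (named vector),
#'   `failures` counts, plus provenance.
#' @export
run_spike_benchmark <- function(n_series = 200, n = 1190,
                                fraction_grid = c(0, 0.01, 0.02, 0.05),
                                magnitude_grid = c(0, 2, 4, 6),
                                seed = NULL,
                                estimators = estimator_ids()) {
  stopifnot(0 %in% fraction_grid, 0 %in% magnitude_grid)
  paths <- fbm_batch(n, 0.5, n_series, seed = child_seed(seed, 1))
  base <- vapply(seq_len(n_series), function(i)
    hurst_values(hurst_all(paths[, i], "walk", estimators = estimators)),
    numeric(length(estimators)))
  if (is.null(dim(base))) base <- matrix(base, nrow = 1)

  nf <- length(fraction_grid); nm <- length(magnitude_grid)
  tarr <- array(0, dim = c(length(estimators), nf, nm),
                dimnames = list(estimators, fraction_grid, magnitude_grid))
  fails <- array(0L, dim = dim(tarr), dimnames = dimnames(tarr))
  cell <- 0L
  for (fi in seq_len(nf)) for (mi in seq_len(nm)) {
    f <- fraction_grid[fi]; m <- magnitude_grid[mi]
    cell <- cell + 1L
    if (f == 0 || m == 0) next   # untouched: paired difference is exactly 0
    spiked <- vapply(seq_len(n_series), function(i) {
      xs <- inject_spikes(paths[, i], f, m,
                          seed = child_seed(seed, 1000L * cell + i))
      hurst_values(hurst_all(xs, "walk", estimators = estimators))
    }, numeric(length(estimators)))
    if (is.null(dim(spiked))) spiked <- matrix(spiked, nrow = 1)
    for (ei in seq_along(estimators)) {
      sp <- spiked[ei, ]; cl <- base[ei, ]
      ok <- is.finite(sp) & is.finite(cl)
      fails[ei, fi, mi] <- sum(!ok)
      sp <- sp[ok]; cl <- cl[ok]
      tarr[ei, fi, mi] <-
        if (length(sp) < 2 || (sd(sp) == 0 && sd(cl) == 0) ||
            isTRUE(all.equal(sp, cl))) 0
        else unname(t.test(sp, cl)$statistic)
    }
  }
  rng <- range(tarr)
  norm <- if (diff(rng) > 0) (tarr - rng[1]) / diff(rng) else tarr * 0
  base_plane <- if (diff(rng) > 0) (0 - rng[1]) / diff(rng) else 0
  volume <- apply(abs(norm - base_plane), 1, sum)
  structure(list(
    t = tarr, normalized = norm, baseline_value = base_plane,
    volume = volume, failures = fails,
    fraction_grid = fraction_grid, magnitude_grid = magnitude_grid,
    n_series = n_series, n = n, seed = seed
  ), class = "spike_surface")
}

#' @export
print.spike_surface <- function(x, ...) {
  cat(sprintf("<spike_surface> %d x %d grid, %d series (n = %d)\n",
              length(x$fraction_grid), length(x$magnitude_grid),
              x$n_series, x$n))
  cat("volumes (surface minus baseline plane):\n")
  print(sort(x$volume), digits = 3)
  invisible(x)
}

#' Precision/accuracy correlation benchmark
#'
#' Accuracy: Pearson correlations between estimators across series whose
#' true H is drawn uniformly on (0, 1). Precision: the same correlations
#' across series all generated at H = 0.5, so only estimation noise is
#' shared. Estimator failures are handled pairwise-complete with a
#' logged count.
#'
#' @param n_series series per condition (>= 100 recommended).
#' @param n series length.
#' @param seed integer seed.
#' @param generator fBm generator.
#' @param estimators estimator ids.
#' @return A `correlation_benchmark`: `accuracy` and `precision`
#'   matrices (symmetric, unit diagonal), `H_true` (the accuracy draw),
#'   `n_failures`, provenance.
#' @export
run_correlation_benchmark <- function(n_series = 200, n = 1190, seed = NULL,
                                      generator = c("circulant", "wavelet"),
                                      estimators = estimator_ids()) {
  generator <- match.arg(generator)
  H_true <- with_seed(child_seed(seed, 1), runif(n_series, 0.01, 0.99))
  acc <- vapply(seq_len(n_series), function(i) {
    x <- fbm_batch(n, H_true[i], 1, seed = child_seed(seed, 100L + i),
                   generator = generator)[, 1]
    hurst_values(hurst_all(x, "walk", estimators = estimators))
  }, numeric(length(estimators)))
  prec_paths <- fbm_batch(n, 0.5, n_series, seed = child_seed(seed, 2),
                          generator = generator)
  prec <- vapply(seq_len(n_series), function(i)
    hurst_values(hurst_all(prec_paths[, i], "walk", estimators = estimators)),
    numeric(length(estimators)))
  mk <- function(m) {
    cm <- cor(t(m), use = "pairwise.complete.obs")
    diag(cm) <- 1
    cm
  }
  structure(list(
    accuracy = mk(acc), precision = mk(prec), H_true = H_true,
    n_failures = sum(!is.finite(acc)) + sum(!is.finite(prec)),
    n_series = n_series, n = n, seed = seed, generator = generator
  ), class = "correlation_benchmark")
}

mean_offdiag <- function(m) mean(m[upper.tri(m)], na.rm = TRUE)

#' @export
print.correlation_benchmark <- function(x, ...) {
  cat(sprintf("<correlation_benchmark> %d series, n = %d\n", x$n_series, x$n))
  cat(sprintf("mean off-diagonal accuracy r = %.3f, precision r = %.3f\n",
              mean_offdiag(x$accuracy), mean_offdiag(x$precision)))
  invisible(x)
}

#' Error drop-off rate with series length
#'
#' Generates brown noise at each length, estimates H per instance, and
#' fits `log SD(estimates) ~ log length`; the error drop-off rate alpha
#' is the negative slope (`sigma ~ L^-alpha`; alpha = 0.5 is the standard
#' one-over-square-root efficiency).
#'
#' @param lengths series lengths (default ten log-spaced in
#'   `[100, 10000]`), strictly increasing.
#' @param n_reps instances per length.
#' @param seed integer seed.
#' @param estimators either estimator ids (run through the usual
#'   walk-class adaptation) or a named list of functions
#'   `f(x) -> numeric` (e.g. a plug-in statistic for calibration).
#' @return A `dropoff_result`: `table` (per estimator: `alpha`,
#'   `alpha_se`), `sds` (length x estimator SD matrix), `estimates`
#'   (length x rep x estimator array), provenance.
#' @export
run_error_dropoff <- function(lengths = round(10^seq(2, 4, length.out = 10)),
                              n_reps = 100, seed = NULL,
                              estimators = estimator_ids()) {
  stopifnot(all(diff(lengths) > 0), n_reps >= 2)
  if (is.character(estimators)) {
    ids <- estimators
    funs <- lapply(ids, function(id) {
      function(x) {
        b <- hurst_all(x, "walk", estimators = id)
        unname(hurst_values(b)[id])
      }
    })
    names(funs) <- ids
  } else {
    stopifnot(is.list(estimators), !is.null(names(estimators)))
    funs <- estimators
    ids <- names(funs)
  }
  est <- array(NA_real_, dim = c(length(lengths), n_reps, length(ids)),
               dimnames = list(lengths, NULL, ids))
  for (li in seq_along(lengths)) {
    L <- lengths[li]
    for (r in seq_len(n_reps)) {
      x <- brown_noise(L, seed = child_seed(seed, 1000L * li + r))
      for (ei in seq_along(ids)) {
        est[li, r, ei] <- tryCatch(funs[[ei]](x), error = function(e) NA_real_)
      }
    }
  }
  sds <- apply(est, c(1, 3), sd, na.rm = TRUE)
  tab <- do.call(rbind, lapply(seq_along(ids), function(ei) {
    s <- sds[, ei]
    ok <- is.finite(s) & s > 0
    if (sum(ok) < 3)
      return(data.frame(estimator_id = ids[ei], alpha = NA_real_,
                        alpha_se = NA_real_, n_lengths = sum(ok)))
    f <- ols_fit(log(lengths[ok]), log(s[ok]))
    data.frame(estimator_id = ids[ei], alpha = -f$slope,
               alpha_se = f$slope_se, n_lengths = sum(ok))
  }))
  structure(list(table = tab, sds = sds, estimates = est,
                 lengths = lengths, n_reps = n_reps, seed = seed),
            class = "dropoff_result")
}

#' @export
print.dropoff_result <- function(x, ...) {
  cat(sprintf("<dropoff_result> lengths %d..%d, %d reps\n",
              min(x$lengths), max(x$lengths), x$n_reps))
  print(x$table, digits = 3)
  invisible(x)
}

#' Bootstrap comparison of adjacent error drop-off rates
#'
#' Resamples instances with replacement and recomputes alpha for two
#' estimators, returning the bootstrap probability that the first has a
#' smaller alpha than the second (two-sided p via the symmetric tail).
#'
#' @param result a `dropoff_result` (must contain both estimators).
#' @param id_a,id_b estimator ids to compare.
#' @param n_boot bootstrap resamples.
#' @param seed integer seed.
#' @return list with `delta` (alpha_a - alpha_b), `p_value`, `n_boot`.
#' @export
dropoff_compare <- function(result, id_a, id_b, n_boot = 1000, seed = NULL) {
  ea <- result$estimates[, , id_a]
  eb <- result$estimates[, , id_b]
  lengths <- result$lengths
  alpha_of <- function(m, idx) {
    s <- apply(m[, idx, drop = FALSE], 1, sd, na.rm = TRUE)
    ok <- is.finite(s) & s > 0
    -ols_fit(log(lengths[ok]), log(s[ok]))$slope
  }
  n_reps <- ncol(ea)
  with_seed(seed, {
    deltas <- vapply(seq_len(n_boot), function(b) {
      idx <- sample.int(n_reps, n_reps, replace = TRUE)
      alpha_of(ea, idx) - alpha_of(eb, idx)
    }, numeric(1))
    obs <- alpha_of(ea, seq_len(n_reps)) - alpha_of(eb, seq_len(n_reps))
    p <- 2 * min(mean(deltas >= 0), mean(deltas <= 0))
    list(delta = obs, p_value = max(p, 1 / n_boot), n_boot = n_boot)
  })
}
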