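# Sensitivity metrics relating voxelwise Hurst maps to tissue type and
# activation, inter-subject correlation mapping, windowed complexity
# profiles, and region-average PCA separation.

# Build the nuisance design a combo needs from what the dataset carries.
design_from_volume <- function(vol, combo) {
  combo <- as_combo(combo)
  if (combo$motion == "none" && !combo$global) return(NULL)
  if (is.null(vol$motion))
    stop("combination '", combo$label, "' needs motion parameters, ",
         "but the dataset carries none")
  gl <- if (combo$global) global_regressors(vol) else NULL
  nuisance_design(vol$motion, gl)
}

#' Voxelwise Hurst map
#'
#' Applies a processing combination and a single estimator to every
#' in-mask voxel series. Voxels outside the brain mask, and voxels where
#' the estimator fails, carry `NA` (failures are counted in the
#' `n_failures` attribute).
#'
#' @param vol a [volume_dataset()] with a `brain` mask.
#' @param combo processing combination label or row (default untouched).
#' @param estimator_id one estimator id (see [estimator_specs()]).
#' @param input_class signal class the voxel series are treated as;
#'   BOLD-like signals are `"increments"` (default).
#' @param design optional [nuisance_design()]; built from the dataset's
#'   motion record and masks when required and not supplied.
#' @return 3-D array of H values with attribute `n_failures`.
#' @export
hurst_map <- function(vol, combo = "o", estimator_id = "HFD10",
                      input_class = "increments", design = NULL) {
  stopifnot(inherits(vol, "volume_dataset"))
  if (is.null(vol$masks$brain)) stop("dataset has no brain mask")
  combo <- as_combo(combo)
  if (is.null(design)) design <- design_from_volume(vol, combo)
  grid <- dim(vol$data)[1:3]
  out <- array(NA_real_, dim = grid)
  idx <- which(vol$masks$brain)
  mat <- matrix(vol$data, prod(grid), dim(vol$data)[4])
  fails <- 0L
  for (v in idx) {
    h <- tryCatch({
      x <- apply_combo(mat[v, ], combo, design = design,
                       tr_seconds = vol$tr_seconds)
      estimate_hurst(x, estimator_id, input_class)$H
    }, error = function(e) NA_real_)
    if (is.na(h)) fails <- fails + 1L
    out[v] <- h
  }
  attr(out, "n_failures") <- fails
  attr(out, "estimator_id") <- estimator_id
  attr(out, "combo") <- combo$label
  out
}

#' Grey-to-white-matter contrast of a Hurst map
#'
#' Two-sample Welch t of in-mask grey-matter H values against
#' white-matter H values; positive t means grey matter scores higher.
#'
#' @param hmap 3-D H map (e.g. from [hurst_map()]).
#' @param gm_mask,wm_mask 3-D logical masks on the same grid.
#' @param min_voxels minimum valid voxels required per tissue.
#' @return list with `t`, `df`, `p`, `mean_gm`, `mean_wm`, `n_gm`, `n_wm`.
#' @export
gm_wm_contrast <- function(hmap, gm_mask, wm_mask, min_voxels = 30) {
  gm <- hmap[gm_mask]; gm <- gm[is.finite(gm)]
  wm <- hmap[wm_mask]; wm <- wm[is.finite(wm)]
  if (length(gm) < min_voxels || length(wm) < min_voxels)
    stop(sprintf("need >= %d valid voxels per tissue (got %d GM, %d WM)",
                 min_voxels, length(gm), length(wm)))
  tt <- t.test(gm, wm)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, mean_gm = mean(gm), mean_wm = mean(wm),
       n_gm = length(gm), n_wm = length(wm))
}

#' ROC overlap between a score map and a reference statistic map
#'
#' Positives are the voxels at or above the `1 - top_frac` quantile of
#' the reference map (top 1% of t-values by default). The ROC is swept
#' over thresholds of the score map with midrank tie handling, and the
#' AUC is the trapezoid area (equivalently the rank-sum statistic). A
#' constant score map yields AUC 0.5 with a degeneracy flag.
#'
#' @param hmap 3-D score map (H values).
#' @param reference_map 3-D reference map (e.g. a GLM t-map or ISC
#'   z-map), same grid.
#' @param top_frac share of reference voxels called positive.
#' @param mask optional logical mask restricting the comparison.
#' @return list with `auc`, `curve` (data.frame `fpr`, `tpr`), `n_pos`,
#'   `n_neg`, `degenerate`.
#' @export
roc_auc_map <- function(hmap, reference_map, top_frac = 0.01, mask = NULL) {
  if (!identical(dim(hmap), dim(reference_map)))
    stop("score and reference maps are not on the same grid")
  keep <- is.finite(hmap) & is.finite(reference_map)
  if (!is.null(mask)) keep <- keep & mask
  score <- hmap[keep]; ref <- reference_map[keep]
  n <- length(score)
  thr <- quantile(ref, 1 - top_frac)
  pos <- ref >= thr
  n_pos <- sum(pos); n_neg <- n - n_pos
  if (n_pos < 10) stop("fewer than 10 positive voxels at top_frac = ", top_frac)
  degenerate <- length(unique(score)) == 1L
  r <- rank(score)               # midranks
  auc <- (sum(r[pos]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  cuts <- sort(unique(score), decreasing = TRUE)
  if (length(cuts) > 512) cuts <- quantile(cuts, seq(0, 1, length.out = 512))
  curve <- data.frame(
    fpr = vapply(cuts, function(cc) mean(score[!pos] >= cc), numeric(1)),
    tpr = vapply(cuts, function(cc) mean(score[pos] >= cc), numeric(1)))
  curve <- rbind(data.frame(fpr = 0, tpr = 0), curve,
                 data.frame(fpr = 1, tpr = 1))
  list(auc = unname(auc), curve = curve, n_pos = n_pos, n_neg = n_neg,
       degenerate = degenerate)
}

# Fisher z with a finite cap at |r| = 0.999999 (flagged).
fisher_z <- function(r, cap = 0.999999) {
  capped <- abs(r) > cap
  atanh(pmin(pmax(r, -cap), cap))
}

#' Inter-subject correlation map
#'
#' Per voxel, the mean Fisher-z of all pairwise correlations between the
#' subjects' processed series. Correlations at |r| = 1 are capped at the
#' z of r = 0.999999 and flagged; zero-variance voxel series give a
#' missing value at that voxel.
#'
#' @param stack list of [volume_dataset()]s on the same grid with the
#'   same number of volumes (>= 3 subjects).
#' @param combo processing combination; the conventional ISC pipeline is
#'   detrend + motion + global regression + high-pass (default
#'   `"d-m-bcw-fhi"`).
#' @param mask optional 3-D logical mask (defaults to the first
#'   subject's brain mask, or all voxels).
#' @return 3-D array of mean Fisher-z values with attribute `n_capped`.
#' @export
isc_map <- function(stack, combo = "d-m-bcw-fhi", mask = NULL) {
  if (length(stack) < 3) stop("ISC needs at least 3 subjects")
  grids <- lapply(stack, function(v) dim(v$data))
  if (length(unique(vapply(grids, paste, character(1), collapse = "x"))) != 1)
    stop("subjects are not on identical grids")
  grid <- grids[[1]][1:3]; nt <- grids[[1]][4]
  if (is.null(mask)) mask <- stack[[1]]$masks$brain
  if (is.null(mask)) mask <- array(TRUE, dim = grid)
  combo <- as_combo(combo)
  idx <- which(mask)
  S <- length(stack)
  # process all in-mask series per subject once
  proc <- lapply(stack, function(vol) {
    design <- design_from_volume(vol, combo)
    mat <- matrix(vol$data, prod(grid), nt)
    t(vapply(idx, function(v)
      as.numeric(apply_combo(mat[v, ], combo, design = design,
                             tr_seconds = vol$tr_seconds)),
      numeric(nt)))
  })
  out <- array(NA_real_, dim = grid)
  n_capped <- 0L
  pairs <- utils::combn(S, 2)
  for (k in seq_along(idx)) {
    series <- vapply(proc, function(m) m[k, ], numeric(nt))
    sds <- apply(series, 2, sd)
    if (any(sds == 0)) next   # zero-variance voxel -> missing
    cm <- cor(series)
    rs <- cm[lower.tri(cm)]
    n_capped <- n_capped + sum(abs(rs) > 0.999999)
    out[idx[k]] <- mean(fisher_z(rs))
  }
  attr(out, "n_capped") <- n_capped
  attr(out, "combo") <- combo$label
  out
}

#' Windowed complexity (and ISC) profile
#'
#' Splits a series into `n_windows` equal windows of `window_minutes`
#' whose starts are evenly spaced so the first window begins at time 0
#' and the last ends at the series end; consecutive windows overlap by
#' `100 * (window - spacing) / window` percent. H is estimated per
#' window for each requested estimator. If `x` is a matrix (one subject
#' per column), per-window H is averaged across subjects and a
#' per-window mean pairwise Fisher-z ISC is also computed.
#'
#' @param x numeric vector, matrix (samples x subjects), or [hurst_ts()].
#' @param tr_seconds sampling interval in seconds.
#' @param n_windows number of windows (default 15).
#' @param window_minutes window length in minutes (default 10).
#' @param estimators estimator ids (default `"HFD10"`).
#' @param input_class signal class of the series (default
#'   `"increments"`).
#' @return A `window_profile`: list with `H` (windows x estimators
#'   matrix), `isc` (per-window mean Fisher z, or NULL), `centers_min`,
#'   `overlap_percent`, window bookkeeping.
#' @export
window_profile <- function(x, tr_seconds = NULL, n_windows = 15,
                           window_minutes = 10, estimators = "HFD10",
                           input_class = "increments") {
  if (inherits(x, "hurst_ts")) {
    if (is.null(tr_seconds)) tr_seconds <- x$dt
    x <- x$values
  }
  if (is.null(tr_seconds)) stop("tr_seconds is required")
  m <- if (is.matrix(x)) x else matrix(x, ncol = 1)
  n <- nrow(m)
  duration_min <- n * tr_seconds / 60
  if (window_minutes > duration_min)
    stop(sprintf("window (%g min) longer than the series (%.2f min)",
                 window_minutes, duration_min))
  wlen <- round(window_minutes * 60 / tr_seconds)
  if (n_windows == 1) {
    starts <- 0
    overlap <- NA_real_
  } else {
    spacing <- (n - wlen) / (n_windows - 1)
    starts <- round((seq_len(n_windows) - 1) * spacing)
    spacing_min <- spacing * tr_seconds / 60
    overlap <- 100 * (window_minutes - spacing_min) / window_minutes
  }
  H <- matrix(NA_real_, n_windows, length(estimators),
              dimnames = list(NULL, estimators))
  isc <- if (ncol(m) >= 2) rep(NA_real_, n_windows) else NULL
  for (w in seq_len(n_windows)) {
    rows <- (starts[w] + 1):(starts[w] + wlen)
    seg <- m[rows, , drop = FALSE]
    for (e in seq_along(estimators)) {
      hs <- apply(seg, 2, function(col)
        tryCatch(estimate_hurst(col, estimators[e], input_class)$H,
                 error = function(err) NA_real_))
      H[w, e] <- mean(hs, na.rm = TRUE)
    }
    if (!is.null(isc)) {
      cm <- cor(seg)
      isc[w] <- mean(fisher_z(cm[lower.tri(cm)]))
    }
  }
  centers <- (starts + wlen / 2) * tr_seconds / 60
  structure(list(H = H, isc = isc, centers_min = centers,
                 overlap_percent = overlap, window_minutes = window_minutes,
                 n_windows = n_windows, window_samples = wlen,
                 starts = starts, tr_seconds = tr_seconds),
            class = "window_profile")
}

#' @export
print.window_profile <- function(x, ...) {
  cat(sprintf("<window_profile> %d windows of %g min (%.1f%% overlap)\n",
              x$n_windows, x$window_minutes,
              ifelse(is.na(x$overlap_percent), NA, x$overlap_percent)))
  invisible(x)
}

#' Correlate a windowed complexity profile with covariates
#'
#' Pearson r and p per (estimator, covariate) pair; covariates are
#' z-scored first. A constant covariate gives an undefined correlation
#' and is flagged.
#'
#' @param profile a [window_profile()].
#' @param covariates data.frame or named list of per-window series.
#' @return data.frame with columns `estimator_id`, `covariate`, `r`,
#'   `p`, `constant_covariate`.
#' @export
profile_correlations <- function(profile, covariates) {
  stopifnot(inherits(profile, "window_profile"))
  covariates <- as.data.frame(covariates)
  if (nrow(covariates) != profile$n_windows)
    stop("covariates must have one row per window")
  rows <- list()
  for (e in colnames(profile$H)) {
    h <- profile$H[, e]
    for (cv in names(covariates)) {
      z <- covariates[[cv]]
      const <- sd(z) == 0
      if (const) {
        rows[[length(rows) + 1L]] <- data.frame(
          estimator_id = e, covariate = cv, r = NA_real_, p = NA_real_,
          constant_covariate = TRUE)
        next
      }
      z <- (z - mean(z)) / sd(z)
      ct <- cor.test(h, z)
      rows[[length(rows) + 1L]] <- data.frame(
        estimator_id = e, covariate = cv, r = unname(ct$estimate),
        p = ct$p.value, constant_covariate = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Region-average PCA separation between groups
#'
#' For every subject, the mean series of each atlas region is processed
#' with the given combination and its Hurst exponent estimated (H is
#' computed on the averaged series, not averaged over voxel H). The
#' subjects x regions matrix is column-standardized, decomposed by PCA,
#' and the two groups compared by a two-sample t on the first principal
#' component scores. Regions with no voxels are dropped with a
#' diagnostic.
#'
#' @param vols list of [volume_dataset()]s, one per subject.
#' @param atlas 3-D integer array of region labels (0 = outside);
#'   at least 10 distinct regions.
#' @param groups factor/vector of length `length(vols)` with two levels.
#' @param combo processing combination (default `"d-m-bcw-fhi"`).
#' @param estimator_id estimator for the region series.
#' @param input_class signal class (default `"increments"`).
#' @return list with `scores` (subjects x PCs), `t`, `p` (group contrast
#'   on PC1), `region_H` (subjects x regions), `dropped_regions`,
#'   `groups`.
#' @export
region_pca_separation <- function(vols, atlas, groups,
                                  combo = "d-m-bcw-fhi",
                                  estimator_id = "HFD10",
                                  input_class = "increments") {
  groups <- as.factor(groups)
  if (nlevels(groups) != 2) stop("groups must have exactly two levels")
  if (min(table(groups)) < 2) stop("need at least 2 subjects per group")
  labels <- sort(setdiff(unique(as.vector(atlas)), 0))
  if (length(labels) < 10) stop("atlas must cover at least 10 regions")
  combo <- as_combo(combo)
  H <- matrix(NA_real_, length(vols), length(labels),
              dimnames = list(NULL, paste0("region", labels)))
  dropped <- character(0)
  for (s in seq_along(vols)) {
    vol <- vols[[s]]
    design <- design_from_volume(vol, combo)
    grid <- dim(vol$data)[1:3]
    mat <- matrix(vol$data, prod(grid), dim(vol$data)[4])
    for (ri in seq_along(labels)) {
      vox <- which(as.vector(atlas) == labels[ri])
      if (!length(vox)) {
        dropped <- union(dropped, paste0("region", labels[ri]))
        next
      }
      series <- colMeans(mat[vox, , drop = FALSE])
      H[s, ri] <- tryCatch({
        x <- apply_combo(series, combo, design = design,
                         tr_seconds = vol$tr_seconds)
        estimate_hurst(x, estimator_id, input_class)$H
      }, error = function(e) NA_real_)
    }
  }
  keep <- colSums(is.na(H)) == 0 & apply(H, 2, sd, na.rm = TRUE) > 0
  if (sum(keep) < 2) stop("fewer than 2 usable regions for PCA")
  Z <- scale(H[, keep, drop = FALSE])
  pc <- prcomp(Z, center = FALSE, scale. = FALSE)
  pc1 <- pc$x[, 1]
  tt <- t.test(pc1 ~ groups)
  list(scores = pc$x, t = unname(tt$statistic), p = tt$p.value,
       region_H = H, dropped_regions = dropped, groups = groups,
       sdev = pc$sdev, loadings = pc$rotation)
}

#' Full metric grid over processing combinations and estimators
#'
#' Computes the tissue-contrast and (optionally) activation-overlap
#' metrics for every requested combination x estimator pair on one
#' dataset. Voxel series are processed once per combination and the
#' whole estimator suite is evaluated on each processed series, so the
#' grid costs little more than one map per combination.
#'
#' @param vol a [volume_dataset()] with `brain`, `gm`, `wm` masks.
#' @param reference_map optional 3-D reference statistic map for the ROC
#'   overlap (e.g. a t-map); when absent only `gm_wm_t` is reported.
#' @param combos combination labels (default: all 36).
#' @param estimators estimator ids (default: all twenty).
#' @param top_frac positive fraction for the ROC (default 0.01; use 0.10
#'   for the coarser overlap protocol).
#' @param input_class signal class of the voxel series.
#' @return data.frame with one row per (combo, estimator): `combo_label`,
#'   `estimator_id`, `gm_wm_t`, `auc_t` (NA without a reference),
#'   `n_failures`.
#' @export
metric_report_grid <- function(vol, reference_map = NULL,
                               combos = enumerate_combos()$label,
                               estimators = estimator_ids(),
                               top_frac = 0.01,
                               input_class = "increments") {
  stopifnot(inherits(vol, "volume_dataset"))
  grid <- dim(vol$data)[1:3]
  idx <- which(vol$masks$brain)
  mat <- matrix(vol$data, prod(grid), dim(vol$data)[4])
  rows <- list()
  for (lab in combos) {
    combo <- as_combo(lab)
    design <- design_from_volume(vol, combo)
    # estimator x voxel matrix of H values under this combination
    hv <- vapply(idx, function(v) {
      x <- apply_combo(mat[v, ], combo, design = design,
                       tr_seconds = vol$tr_seconds)
      hurst_values(hurst_all(x, input_class, estimators = estimators))
    }, numeric(length(estimators)))
    if (is.null(dim(hv))) hv <- matrix(hv, nrow = 1)
    for (ei in seq_along(estimators)) {
      hmap <- array(NA_real_, dim = grid)
      hmap[idx] <- hv[ei, ]
      ct <- tryCatch(gm_wm_contrast(hmap, vol$masks$gm, vol$masks$wm),
                     error = function(e) NULL)
      auc <- if (!is.null(reference_map)) {
        tryCatch(roc_auc_map(hmap, reference_map, top_frac = top_frac,
                             mask = vol$masks$brain)$auc,
                 error = function(e) NA_real_)
      } else NA_real_
      rows[[length(rows) + 1L]] <- data.frame(
        combo_label = lab, estimator_id = estimators[ei],
        gm_wm_t = if (is.null(ct)) NA_real_ else ct$t,
        auc_t = auc, n_failures = sum(!is.finite(hv[ei, ])),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Aggregate estimator rankings across sensitivity metrics
#'
#' Ranks estimators within each metric column (larger is better) and
#' averages the ranks, with average ranks on ties.
#'
#' @param metric_table data.frame with an `estimator_id` column and one
#'   or more numeric metric columns.
#' @param metrics names of the metric columns to aggregate (default: all
#'   numeric columns).
#' @return data.frame sorted best-first with `estimator_id`, `mean_rank`,
#'   and the per-metric ranks.
#' @export
rank_measures <- function(metric_table, metrics = NULL) {
  stopifnot("estimator_id" %in% names(metric_table))
  if (is.null(metrics))
    metrics <- names(metric_table)[vapply(metric_table, is.numeric,
                                          logical(1))]
  ranks <- vapply(metrics, function(m)
    rank(-metric_table[[m]], ties.method = "average", na.last = "keep"),
    numeric(nrow(metric_table)))
  out <- data.frame(estimator_id = metric_table$estimator_id,
                    mean_rank = rowMeans(ranks, na.rm = TRUE))
  out <- cbind(out, as.data.frame(ranks))
  out[order(out$mean_rank), , drop = FALSE]
}
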