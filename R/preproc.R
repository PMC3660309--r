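# Signal-processing operators for BOLD time series and the enumeration of
# their valid combinations.

#' Enumerate the valid signal-processing combinations
#'
#' All combinations of linear detrending (`d`), motion regression (`m`)
#' optionally with squared terms (`m2`), global-signal regression
#' (`bcw`: whole-brain, CSF, and white-matter mean regressors), and
#' high-pass (`fhi`, 0.01 Hz) or band-pass (`fbp`, 0.01-0.1 Hz)
#' filtering. Squared motion terms without the linear terms are excluded,
#' as is the redundant `fhi`+`fbp` pairing, which leaves 36 combinations
#' including the untouched baseline, labelled `"o"`.
#'
#' @return data.frame of class `preproc_combos` with logical/character
#'   columns `d`, `motion` (`"none"/"linear"/"linear+squares"`), `global`,
#'   `filter` (`"none"/"highpass"/"bandpass"`), and the canonical `label`,
#'   in a deterministic order.
#' @examples
#' combos <- enumerate_combos()
#' nrow(combos)  # 36
#' @export
enumerate_combos <- function() {
  grid <- expand.grid(
    filter = c("none", "highpass", "bandpass"),
    global = c(FALSE, TRUE),
    motion = c("none", "linear", "linear+squares"),
    d = c(FALSE, TRUE),
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  )[, c("d", "motion", "global", "filter")]
  grid$label <- vapply(seq_len(nrow(grid)), function(i)
    combo_label(grid$d[i], grid$motion[i], grid$global[i], grid$filter[i]),
    character(1))
  # canonical order: baseline first, then by number of active steps, label
  nsteps <- (grid$d) + (grid$motion != "none") + (grid$motion == "linear+squares") +
    grid$global + (grid$filter != "none")
  grid <- grid[order(nsteps, grid$label), ]
  rownames(grid) <- NULL
  class(grid) <- c("preproc_combos", "data.frame")
  grid
}

combo_label <- function(d, motion, global, filter) {
  tokens <- c(
    if (d) "d",
    switch(motion, none = NULL, linear = "m", `linear+squares` = "m2"),
    if (global) "bcw",
    switch(filter, none = NULL, highpass = "fhi", bandpass = "fbp")
  )
  if (length(tokens) == 0) "o" else paste(tokens, collapse = "-")
}

#' Parse a combination label
#'
#' @param label canonical label such as `"d-m-bcw-fhi"` or `"o"`.
#' @return one-row data.frame with fields `d`, `motion`, `global`,
#'   `filter`, `label`.
#' @export
parse_combo <- function(label) {
  combos <- enumerate_combos()
  hit <- combos[combos$label == label, ]
  if (nrow(hit) != 1) stop("unknown processing combination label: ", label)
  hit
}

as_combo <- function(combo) {
  if (is.character(combo)) return(parse_combo(combo))
  stopifnot(is.data.frame(combo), nrow(combo) == 1)
  combo
}

#' Remove a linear trend
#'
#' Subtracts the least-squares line, leaving a zero-mean residual
#' orthogonal to both the intercept and the time index.
#'
#' @param x numeric vector or [hurst_ts()] with at least 3 samples.
#' @return numeric vector (or `hurst_ts` if given one).
#' @export
detrend_linear <- function(x) {
  v <- ts_values(x)
  n <- length(v)
  if (n < 3) stop("detrending needs n >= 3")
  t_idx <- seq_len(n)
  f <- ols_fit(t_idx, v)
  out <- v - f$intercept - f$slope * t_idx
  if (inherits(x, "hurst_ts")) hurst_ts(out, x$dt) else out
}

#' Assemble a nuisance design
#'
#' @param motion n x 6 matrix of realignment parameters (columns 1-3
#'   translations in mm, 4-6 rotations in radians).
#' @param global optional n x 3 matrix of mean series (whole-brain, CSF,
#'   white matter), e.g. from [global_regressors()].
#' @return A `nuisance_design`: list with `motion`, `motion_sq`
#'   (element-wise squares), `global`, `n`.
#' @export
nuisance_design <- function(motion, global = NULL) {
  motion <- as.matrix(motion)
  if (ncol(motion) != 6) stop("motion must have exactly 6 columns")
  if (anyNA(motion)) stop("motion parameters contain missing values")
  if (!is.null(global)) {
    global <- as.matrix(global)
    if (ncol(global) != 3) stop("global must have 3 columns (brain, csf, wm)")
    if (nrow(global) != nrow(motion))
      stop("global and motion must have the same number of rows")
    colnames(global) <- c("brain", "csf", "wm")
  }
  colnames(motion) <- paste0("mot", 1:6)
  structure(list(motion = motion, motion_sq = motion^2, global = global,
                 n = nrow(motion)),
            class = "nuisance_design")
}

#' Regress nuisance signals out of a series
#'
#' OLS residual of the series on the selected design columns plus an
#' intercept. The residual is returned without re-adding the mean
#' (complexity estimators are location-invariant).
#'
#' @param x numeric vector or [hurst_ts()].
#' @param design a [nuisance_design()] whose length matches `x`.
#' @param include_motion include the six motion columns (default TRUE).
#' @param include_squares also include their element-wise squares.
#' @param include_global include the three global-signal columns.
#' @return residual series, same type as `x`.
#' @export
regress_nuisance <- function(x, design, include_motion = TRUE,
                             include_squares = FALSE, include_global = FALSE) {
  v <- ts_values(x)
  stopifnot(inherits(design, "nuisance_design"))
  if (design$n != length(v))
    stop(sprintf("design has %d rows but series has %d samples",
                 design$n, length(v)))
  X <- cbind(intercept = rep(1, length(v)))
  if (include_motion) X <- cbind(X, design$motion)
  if (include_squares) {
    if (!include_motion)
      stop("squared motion terms require the linear motion terms")
    X <- cbind(X, sq = design$motion_sq)
  }
  if (include_global) {
    if (is.null(design$global)) stop("design carries no global regressors")
    X <- cbind(X, design$global)
  }
  # drop constant-zero columns, then insist on full rank
  keep <- colSums(abs(X)) > 0
  X <- X[, keep, drop = FALSE]
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    bad <- colnames(X)[qx$pivot[(qx$rank + 1):ncol(X)]]
    stop("rank-deficient nuisance design; collinear columns: ",
         paste(bad, collapse = ", "))
  }
  out <- as.numeric(qr.resid(qx, v))
  if (inherits(x, "hurst_ts")) hurst_ts(out, x$dt) else out
}

#' Zero-phase Butterworth filter
#'
#' Forward-backward (zero-phase) application of a 10th-order Butterworth
#' design: high-pass at 0.01 Hz or band-pass over 0.01-0.1 Hz, with
#' cutoffs interpreted in Hz against the repetition time. The effective
#' magnitude response is the squared design response; filtering preserves
#' length with no edge trimming.
#'
#' @param x numeric vector or [hurst_ts()].
#' @param band `"highpass"` or `"bandpass"`.
#' @param tr_seconds sampling interval in seconds (defaults to the `dt`
#'   of a `hurst_ts` input).
#' @param cutoff_low,cutoff_high band edges in Hz.
#' @param order filter order of the design (default 10).
#' @return filtered series, same type as `x`.
#' @export
butterworth_filter <- function(x, band = c("highpass", "bandpass"),
                               tr_seconds = NULL, cutoff_low = 0.01,
                               cutoff_high = 0.1, order = 10) {
  band <- match.arg(band)
  v <- ts_values(x)
  if (is.null(tr_seconds)) tr_seconds <- ts_dt(x)
  fs <- 1 / tr_seconds
  nyq <- fs / 2
  upper <- if (band == "bandpass") cutoff_high else cutoff_low
  if (upper >= nyq)
    stop(sprintf("cutoff %.3g Hz is at or above the Nyquist frequency %.3g Hz",
                 upper, nyq))
  bf <- if (band == "highpass") {
    signal::butter(order, cutoff_low / nyq, type = "high")
  } else {
    signal::butter(order, c(cutoff_low, cutoff_high) / nyq, type = "pass")
  }
  out <- as.numeric(signal::filtfilt(bf, v))
  if (inherits(x, "hurst_ts")) hurst_ts(out, x$dt) else out
}

#' Global-signal regressors from a 4-D dataset
#'
#' Per-volume mean over the whole-brain, CSF, and white-matter masks.
#'
#' @param vol a [volume_dataset()] with masks named `brain`, `csf`, `wm`.
#' @return n_volumes x 3 matrix with columns `brain`, `csf`, `wm`.
#' @export
global_regressors <- function(vol) {
  stopifnot(inherits(vol, "volume_dataset"))
  need <- c("brain", "csf", "wm")
  missing_masks <- setdiff(need, names(vol$masks))
  if (length(missing_masks))
    stop("missing masks: ", paste(missing_masks, collapse = ", "))
  out <- vapply(need, function(nm) {
    m <- vol$masks[[nm]]
    if (!any(m)) stop("mask '", nm, "' is empty")
    mat <- matrix(vol$data, prod(dim(vol$data)[1:3]), dim(vol$data)[4])
    colMeans(mat[as.vector(m), , drop = FALSE])
  }, numeric(dim(vol$data)[4]))
  colnames(out) <- need
  out
}

#' Apply a signal-processing combination to one series
#'
#' Operators are applied in the fixed order detrend, nuisance
#' regression, filtering (set `filter_first = TRUE` to filter before the
#' regression instead). The baseline combination `"o"` returns the input
#' unchanged.
#'
#' @param x numeric vector or [hurst_ts()].
#' @param combo combination label (see [enumerate_combos()]) or a row of
#'   the combo table.
#' @param design a [nuisance_design()] (required when the combo includes
#'   motion or global regression).
#' @param tr_seconds sampling interval in seconds (required for the
#'   filtering step when `x` is a bare vector).
#' @param filter_first apply the filter before the nuisance regression.
#' @return processed series, same type and length as `x`.
#' @export
apply_combo <- function(x, combo, design = NULL, tr_seconds = NULL,
                        filter_first = FALSE) {
  combo <- as_combo(combo)
  needs_design <- combo$motion != "none" || combo$global
  if (needs_design && is.null(design))
    stop("combination '", combo$label, "' requires a nuisance design")
  if (combo$global && (is.null(design$global)))
    stop("combination '", combo$label,
         "' requires global regressors in the design")
  out <- x
  regress <- function(z) {
    if (!needs_design) return(z)
    regress_nuisance(z, design,
                     include_motion = combo$motion != "none",
                     include_squares = combo$motion == "linear+squares",
                     include_global = combo$global)
  }
  filt <- function(z) {
    if (combo$filter == "none") return(z)
    butterworth_filter(z, band = combo$filter, tr_seconds = tr_seconds)
  }
  if (combo$d) out <- detrend_linear(out)
  if (filter_first) out <- regress(filt(out)) else out <- filt(regress(out))
  out
}
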