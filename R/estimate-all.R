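# Run the full estimator suite on one series with signal-class adaptation.
#
# Adaptation policy (simulation-protocol normalization):
#  * increments-class estimators (AV, RS) on a walk-class input are run on
#    the first difference; H of an fGn equals H of its fBm, so no offset.
#  * walk-class estimators on an increments-class input are run on the
#    cumulative sum, again with no offset.
#  * spectral-slope estimators (FFT, pWelch) are always run on the
#    increments with +1 added to the estimate: on an increments-class
#    process the spectral exponent is beta = 2H - 1, so (beta - 1)/2 + 1
#    recovers H, and differencing first sidesteps the nonstationarity of
#    the raw walk (and any generator-specific spectral ceiling).

# Map estimator_id -> function(values_walk, values_increments, dt) so that
# shared intermediates (DFA fluctuation function) are computed only once
# by hurst_all().
single_estimator_fun <- function(id) {
  switch(id,
    "Q1a"    = function(w, d, dt) hurst_sf(w, q = 1),
    "Q2a"    = function(w, d, dt) hurst_sf(w, q = 2),
    "Q1b"    = function(w, d, dt) hurst_gen(w, q = 1),
    "Q2b"    = function(w, d, dt) hurst_gen(w, q = 2),
    "AV"     = function(w, d, dt) hurst_aggvar(d),
    "HFD5"   = function(w, d, dt) hurst_higuchi(w, kmax = 5),
    "HFD10"  = function(w, d, dt) hurst_higuchi(w, kmax = 10),
    "DD"     = function(w, d, dt) hurst_secderiv(w, "fir"),
    "DDW"    = function(w, d, dt) hurst_secderiv(w, "wavelet"),
    "db1"    = function(w, d, dt) hurst_wavvar(w, 1),
    "db2"    = function(w, d, dt) hurst_wavvar(w, 2),
    "db4"    = function(w, d, dt) hurst_wavvar(w, 4),
    "db8"    = function(w, d, dt) hurst_wavvar(w, 8),
    "db16"   = function(w, d, dt) hurst_wavvar(w, 16),
    "FFT"    = function(w, d, dt) offset_estimate(hurst_psd(d, "fft", dt = dt), 1),
    "pWelch" = function(w, d, dt) offset_estimate(hurst_psd(d, "welch", dt = dt), 1),
    "DFA"    = function(w, d, dt) hurst_dfa(w, "full"),
    "DFA-S"  = function(w, d, dt) hurst_dfa(w, "small"),
    "DFA-L"  = function(w, d, dt) hurst_dfa(w, "large"),
    stop("unknown estimator_id: ", id)
  )
}

offset_estimate <- function(est, offset) {
  est$H <- est$H + offset
  est$diagnostics$offset <- offset
  est
}

adaptation_label <- function(id, input_class) {
  cls <- estimator_specs()
  native <- cls$signal_class[match(id, cls$estimator_id)]
  if (id %in% c("FFT", "pWelch")) {
    if (input_class == "walk") "differenced, offset +1" else "offset +1"
  } else if (native == input_class) {
    "none"
  } else if (input_class == "walk") {
    "differenced"
  } else {
    "integrated"
  }
}

#' Run all twenty Hurst estimators on one series
#'
#' Applies the full estimator suite, adapting each estimator to the
#' declared input class: increments-class estimators (AV, RS) see the
#' first difference of a walk-class input, walk-class estimators see the
#' cumulative sum of an increments-class input, and the spectral-slope
#' estimators (FFT, pWelch) are always computed on the increments with a
#' +1 offset. Per-estimator failures are recorded as error messages
#' without aborting the batch.
#'
#' @param x numeric vector or [hurst_ts()].
#' @param input_class `"walk"` (fBm-like path) or `"increments"`
#'   (fGn-like stationary signal, e.g. a processed BOLD series).
#' @param estimators character vector of estimator ids to run (default:
#'   all twenty, see [estimator_specs()]).
#' @return A `hurst_batch`: list with `estimates` (named list of
#'   `hurst_estimate`), `adaptations`, `errors`, `input_class`. Convert
#'   with [as.data.frame.hurst_batch()].
#' @examples
#' x <- fbm(256, H = 0.7, seed = 1)
#' head(as.data.frame(hurst_all(x, "walk", estimators = c("HFD10", "FFT"))))
#' @export
hurst_all <- function(x, input_class = c("walk", "increments"),
                      estimators = estimator_ids()) {
  input_class <- match.arg(input_class)
  v <- ts_values(x)
  dt <- ts_dt(x)
  if (length(v) < 100) stop("hurst_all needs n >= 100")
  bad <- setdiff(estimators, estimator_ids())
  if (length(bad)) stop("unknown estimator ids: ", paste(bad, collapse = ", "))
  if (input_class == "walk") {
    w <- v; d <- diff(v)
  } else {
    d <- v; w <- cumsum(v)
  }

  estimates <- vector("list", length(estimators))
  names(estimates) <- estimators
  errors <- setNames(rep(NA_character_, length(estimators)), estimators)
  dfa_cache <- NULL
  for (id in estimators) {
    res <- tryCatch({
      if (id %in% c("DFA", "DFA-S", "DFA-L")) {
        if (is.null(dfa_cache)) {
          if (length(w) < 100) stop("DFA needs n >= 100")
          dfa_cache <- dfa_fluctuation(w)
        }
        dfa_fit_subset(dfa_cache,
                       switch(id, "DFA" = "full", "DFA-S" = "small",
                              "DFA-L" = "large"))
      } else if (id == "RS") {
        hurst_rs(d)
      } else {
        single_estimator_fun(id)(w, d, dt)
      }
    }, error = function(e) conditionMessage(e))
    if (is.character(res)) errors[[id]] <- res else estimates[[id]] <- res
  }
  structure(list(
    estimates = estimates,
    adaptations = setNames(vapply(estimators, adaptation_label,
                                  character(1), input_class = input_class),
                           estimators),
    errors = errors,
    input_class = input_class
  ), class = "hurst_batch")
}

#' Coerce a batch of Hurst estimates to a data frame
#'
#' @param x a `hurst_batch` from [hurst_all()].
#' @param ... unused.
#' @return data.frame with columns `estimator_id`, `H`, `slope`, `r2`,
#'   `n_scales`, `adaptation`, `error`.
#' @export
as.data.frame.hurst_batch <- function(x, ...) {
  ids <- names(x$estimates)
  data.frame(
    estimator_id = ids,
    H = vapply(ids, function(i)
      if (is.null(x$estimates[[i]])) NA_real_ else x$estimates[[i]]$H, numeric(1)),
    slope = vapply(ids, function(i)
      if (is.null(x$estimates[[i]])) NA_real_ else x$estimates[[i]]$slope, numeric(1)),
    r2 = vapply(ids, function(i)
      if (is.null(x$estimates[[i]])) NA_real_ else x$estimates[[i]]$r2, numeric(1)),
    n_scales = vapply(ids, function(i)
      if (is.null(x$estimates[[i]])) NA_integer_
      else length(x$estimates[[i]]$scales), integer(1)),
    adaptation = unname(x$adaptations[ids]),
    error = unname(x$errors[ids]),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' @export
print.hurst_batch <- function(x, ...) {
  df <- as.data.frame(x)
  cat(sprintf("<hurst_batch> %d estimators on %s-class input (%d failed)\n",
              nrow(df), x$input_class, sum(!is.na(df$error))))
  print(df[, c("estimator_id", "H", "r2", "adaptation")], digits = 4)
  invisible(x)
}

#' Hurst estimate H values from a batch as a named vector
#'
#' @param batch a `hurst_batch`.
#' @return named numeric vector (NA where an estimator failed).
#' @export
hurst_values <- function(batch) {
  vapply(batch$estimates, function(e)
    if (is.null(e)) NA_real_ else e$H, numeric(1))
}

#' Estimate H with a single named estimator (with class adaptation)
#'
#' Convenience wrapper around the adaptation machinery of [hurst_all()]
#' for voxelwise or windowed use.
#'
#' @inheritParams hurst_all
#' @param estimator_id one estimator id.
#' @return a `hurst_estimate`.
#' @export
estimate_hurst <- function(x, estimator_id, input_class = c("walk", "increments")) {
  input_class <- match.arg(input_class)
  b <- hurst_all(x, input_class, estimators = estimator_id)
  if (!is.na(b$errors[[estimator_id]])) stop(b$errors[[estimator_id]])
  b$estimates[[estimator_id]]
}
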