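# Synthetic 4-D fMRI phantom with known ground truth, so every
# fMRI-facing operation is testable without real acquisitions.
#
# Each voxel series is stationary fractional Gaussian noise with its
# tissue's Hurst exponent (the increments-class view of BOLD scaling),
# plus linear drift, motion-coupled nuisance, a shared global signal,
# task-locked activation in a subset of grey-matter voxels, and white
# measurement noise.

#' Specify a synthetic fMRI phantom
#'
#' Defaults emulate a long naturalistic acquisition: 1190 volumes at
#' TR 2.1 s, grey matter scaling markedly more persistent than white
#' matter, modest measurement noise, and nuisance amplitudes comparable
#' to the fractal signal of interest.
#'
#' @param dim spatial grid dimensions (3 integers).
#' @param n_volumes number of time points (>= 100).
#' @param tr_seconds repetition time in seconds.
#' @param H_gm,H_wm,H_csf tissue Hurst exponents in (0, 1).
#' @param gm_frac,wm_frac,csf_frac tissue shares of the voxel grid (the
#'   remainder is background outside the brain mask).
#' @param activation_frac share of grey-matter voxels in the activated
#'   region.
#' @param activation_amplitude gain of the task envelope, in units of
#'   the unit-variance fGn signal (additive mode).
#' @param activation_mode `"additive"` (amplitude envelope added to the
#'   series) or `"hurst"` (activated voxels carry `H_activation` instead
#'   of `H_gm`; envelope not added).
#' @param H_activation Hurst exponent of activated voxels in `"hurst"`
#'   mode.
#' @param drift_amplitude total linear drift over the run (signal-SD
#'   units).
#' @param motion_coupling SD of the motion-coupled nuisance contribution
#'   per voxel (signal-SD units; per-voxel weights are random).
#' @param global_amplitude amplitude of the shared global signal.
#' @param noise_sd white measurement-noise SD.
#' @param seed integer seed.
#' @return object of class `phantom_spec`.
#' @export
phantom_spec <- function(dim = c(10, 10, 4), n_volumes = 1190,
                         tr_seconds = 2.1,
                         H_gm = 0.8, H_wm = 0.5, H_csf = 0.35,
                         gm_frac = 0.4, wm_frac = 0.4, csf_frac = 0.1,
                         activation_frac = 0.15,
                         activation_amplitude = 1,
                         activation_mode = c("additive", "hurst"),
                         H_activation = 0.9,
                         drift_amplitude = 1,
                         motion_coupling = 0.5,
                         global_amplitude = 0.5,
                         noise_sd = 0.2,
                         seed = 1L) {
  activation_mode <- match.arg(activation_mode)
  stopifnot(length(dim) == 3, all(dim >= 1), n_volumes >= 100,
            all(c(H_gm, H_wm, H_csf, H_activation) > 0),
            all(c(H_gm, H_wm, H_csf, H_activation) < 1),
            gm_frac + wm_frac + csf_frac <= 1)
  structure(list(dim = as.integer(dim), n_volumes = as.integer(n_volumes),
                 tr_seconds = tr_seconds,
                 H_gm = H_gm, H_wm = H_wm, H_csf = H_csf,
                 gm_frac = gm_frac, wm_frac = wm_frac, csf_frac = csf_frac,
                 activation_frac = activation_frac,
                 activation_amplitude = activation_amplitude,
                 activation_mode = activation_mode,
                 H_activation = H_activation,
                 drift_amplitude = drift_amplitude,
                 motion_coupling = motion_coupling,
                 global_amplitude = global_amplitude,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "phantom_spec")
}

# Smoothed boxcar task envelope: 40 s on / 40 s off, Gaussian-smoothed
# with a 6 s kernel (a coarse stand-in for hemodynamic sluggishness; full
# HRF modelling is out of scope).
phantom_envelope <- function(n_volumes, tr_seconds) {
  t_sec <- (seq_len(n_volumes) - 1) * tr_seconds
  box <- as.numeric((t_sec %% 80) < 40)
  sigma <- 6 / tr_seconds
  half <- ceiling(3 * sigma)
  kern <- exp(-0.5 * ((-half):half / sigma)^2)
  kern <- kern / sum(kern)
  padded <- c(rep(box[1], half), box, rep(box[n_volumes], half))
  env <- as.numeric(stats::filter(padded, kern, sides = 2))[half + seq_len(n_volumes)]
  env - mean(env)
}

#' Generate a ground-truth fMRI phantom
#'
#' Each voxel is built as
#' `fGn(H_tissue) + drift * t + sum(coupling * motion) + global + activation + noise`,
#' with disjoint tissue masks, a six-column motion record (smooth random
#' walks), and full ground truth returned alongside the data. The same
#' seed reproduces the dataset bit-identically.
#'
#' @param spec a [phantom_spec()].
#' @return list with `vol` (a [volume_dataset()] with masks `brain`,
#'   `gm`, `wm`, `csf` and the motion matrix) and `truth` (spec,
#'   activation mask, envelope, global series, drift, per-voxel motion
#'   weights).
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  nvox <- prod(spec$dim)
  nt <- spec$n_volumes
  n_csf <- round(spec$csf_frac * nvox)
  n_wm <- round(spec$wm_frac * nvox)
  n_gm <- round(spec$gm_frac * nvox)
  if (n_csf + n_wm + n_gm > nvox) stop("tissue fractions exceed the grid")
  lab <- rep("bg", nvox)
  lab[seq_len(n_csf)] <- "csf"
  lab[n_csf + seq_len(n_wm)] <- "wm"
  lab[n_csf + n_wm + seq_len(n_gm)] <- "gm"
  gm_idx <- which(lab == "gm")
  n_act <- round(spec$activation_frac * n_gm)
  act_idx <- gm_idx[seq_len(n_act)]

  env <- phantom_envelope(nt, spec$tr_seconds)
  data <- matrix(0, nvox, nt)
  truth_weights <- matrix(0, nvox, 6)

  with_seed(spec$seed, {
    # nuisance sources
    motion <- vapply(1:6, function(j) {
      w <- cumsum(rnorm(nt, sd = 0.02))
      if (j > 3) w / 50 else w        # rotations in radians, smaller scale
    }, numeric(nt))
    colnames(motion) <- paste0("mot", 1:6)
    global_sig <- fgn_circulant(nt, 0.9, 1)[, 1]
    global_sig <- global_sig / sd(global_sig)
    drift <- seq(-0.5, 0.5, length.out = nt)
    mot_std <- scale(motion)

    for (tissue in c("csf", "wm", "gm")) {
      idx <- which(lab == tissue)
      if (!length(idx)) next
      H <- switch(tissue, gm = spec$H_gm, wm = spec$H_wm, csf = spec$H_csf)
      sig <- fgn_circulant(nt, H, length(idx))
      data[idx, ] <- t(sig)
    }
    if (spec$activation_mode == "hurst" && n_act > 0) {
      sig <- fgn_circulant(nt, spec$H_activation, n_act)
      data[act_idx, ] <- t(sig)
    }
    in_brain <- which(lab != "bg")
    truth_weights[in_brain, ] <- matrix(
      rnorm(length(in_brain) * 6, sd = spec$motion_coupling / sqrt(6)),
      length(in_brain), 6)
    data[in_brain, ] <- data[in_brain, ] +
      truth_weights[in_brain, , drop = FALSE] %*% t(mot_std) +
      spec$global_amplitude * matrix(global_sig, length(in_brain), nt,
                                     byrow = TRUE) +
      spec$drift_amplitude * matrix(drift, length(in_brain), nt, byrow = TRUE)
    if (spec$activation_mode == "additive" && n_act > 0) {
      data[act_idx, ] <- data[act_idx, ] +
        spec$activation_amplitude * matrix(env, n_act, nt, byrow = TRUE)
    }
    data[in_brain, ] <- data[in_brain, ] +
      matrix(rnorm(length(in_brain) * nt, sd = spec$noise_sd),
             length(in_brain), nt)

    arr <- array(data, dim = c(spec$dim, nt))
    mk <- function(which_lab) array(lab %in% which_lab, dim = spec$dim)
    vol <- volume_dataset(arr, spec$tr_seconds,
                          masks = list(brain = mk(c("gm", "wm", "csf")),
                                       gm = mk("gm"), wm = mk("wm"),
                                       csf = mk("csf")),
                          motion = motion)
    act_mask <- array(seq_len(nvox) %in% act_idx, dim = spec$dim)
    list(vol = vol,
         truth = list(spec = spec, activation_mask = act_mask,
                      envelope = env, global_signal = global_sig,
                      drift = drift, motion = motion,
                      motion_weights = truth_weights,
                      tissue_labels = array(lab, dim = spec$dim)))
  })
}

#' Write a phantom to disk (NIfTI + motion text + JSON sidecar)
#'
#' @param phantom result of [generate_phantom()].
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_phantom <- function(phantom, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- write_volume(phantom$vol, file.path(dir, "phantom.nii.gz"),
                        mask_dir = dir)
  mp <- file.path(dir, "rp_phantom.txt")
  write_motion(phantom$truth$motion, mp)
  ap <- file.path(dir, "mask_activation.nii.gz")
  RNifti::writeNifti(RNifti::asNifti(phantom$truth$activation_mask * 1L), ap)
  sp <- file.path(dir, "truth.json")
  side <- phantom$truth$spec
  class(side) <- NULL
  jsonlite::write_json(list(spec = side,
                            envelope = phantom$truth$envelope,
                            global_signal = phantom$truth$global_signal),
                       sp, auto_unbox = TRUE, digits = NA)
  invisible(c(paths, mp, ap, sp))
}
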