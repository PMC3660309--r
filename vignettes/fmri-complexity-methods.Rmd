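---
title: "Estimating the Hurst exponent of fMRI time series: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating the Hurst exponent of fMRI time series: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

The package treats a BOLD-like signal as a realization of a process with
long-range dependence characterized by a single Hurst exponent
H ∈ (0, 1). Two representations matter:

* **fractional Brownian motion (fBm)** — a nonstationary self-similar
  "walk" B_H(t) with Var B_H(t) ∝ t^{2H};
* **fractional Gaussian noise (fGn)** — its stationary increments, with
  autocovariance γ(k) = ½(|k+1|^{2H} − 2|k|^{2H} + |k−1|^{2H}).

Both carry the *same* H. Every estimator assumes one of the two classes
(its `signal_class` in `estimator_specs()`), and misclassifying the
input shifts or saturates the estimate. Processed BOLD series are
treated as increments-class by default throughout the fMRI layer, which
is the standard reading of resting BOLD scaling; the `input_class`
argument makes the assumption explicit and overridable everywhere.

## Estimator conventions

All native exponents are mapped to the Hurst scale: D = 2 − H for the
Higuchi fractal dimension, H = (β − 1)/2 for the spectral slope β,
H = α − 1 for the DFA exponent of a walk-class input (DFA integrates
internally, so its profile is one order smoother than the input), and
H = 1 + slope/2 for the aggregated-variance slope. Estimates are
reported **unclipped**; boundedness is a property of an algorithm, never
enforced afterwards. Fit diagnostics (`scales`, `slope`, `r2`) are
carried on every estimate.

Numerical choices that required a decision:

* **Structure-function lag grid** (`Q1a`/`Q2a`): ten logarithmically
  spaced lags between 1 and n/50, rounded to distinct integers. The
  n/50 ceiling keeps at least 50 increment pairs at the longest lag; if
  fewer than four distinct integer lags survive (n below roughly 350),
  the estimator refuses rather than fit a 2-point line.
* **Averaged generalized Hurst** (`Q1b`/`Q2b`): fits over τ = 1..τ_max
  for every τ_max in 5..19 and averages the per-fit H values (the single
  τ_max = 19 fit is available via `average = FALSE`); the per-τ_max fits
  stay in the diagnostics.
* **Higuchi**: the standard curve-length construction with the
  (N−1)/(⌊(N−m)/k⌋·k) normalization, averaged over the k phase offsets.
* **Second derivative** (`DD`/`DDW`): the dyadic energy ratio
  H = ½ log₂(E₂/E₁) of a second-order difference filter at scales 1 and
  2 (dilation by zero insertion). `DD` uses (1, −2, 1); `DDW` uses the
  db2 wavelet filter, which has the same two vanishing moments. Both
  annihilate linear trends exactly, so a linear input is a degenerate
  case by construction.
* **Wavelet variance** (`db1`–`db16`): a *boundary-free* decimated
  pyramid (valid-part convolutions; coefficients touching the series
  ends are discarded, the standard practice in wavelet scaling
  analysis). A periodized transform is wrong here: the circular wrap
  mixes the end of a nonstationary path with its beginning and the
  spurious jump energy destroys the level-variance slope at high H. The
  fit is unweighted least squares of log₂ V_j on the level index over
  all levels with at least 8 coefficients (a minimum of 3 levels is
  required).
* **Welch periodogram**: segment length ⌊2n/9⌋ rounded down to even, so
  exactly eight 50%-overlapping segments fit; Hann taper; per-segment
  mean removal. The spectral fit always excludes the DC bin; an explicit
  `fit_band` is interpreted as the closed–open interval [f_lo, f_hi).
* **DFA**: box sizes from 4 to n/4 at ratio 2^{1/8}; *sliding* windows
  (step one sample) with closed-form linear-detrend residuals via
  rolling sums, so the exact fluctuation function costs O(n) per box
  size. The small/large split point is the geometric midpoint of the
  log box range snapped to the grid — about 35 of 4…297 at n = 1190, so
  the subsets bracket roughly 4–40 and 40–300 samples.
* **R/S**: dyadic scales L, L/2, … down to a minimum segment of 8
  points, sample standard deviation in the denominator. The estimator
  carries the well-known small-sample upward bias on white noise
  (mean ≈ 0.55–0.6 at n = 4096); this is a property of the method and is
  recorded in the diagnostics, not corrected.
* **Degenerate scale points**: a zero value of any scaling function
  (structure function, block variance, curve length, detail variance,
  fluctuation) drops that scale from the fit with a diagnostic count; an
  all-zero scaling function is an error. Energies at the level of
  squared rounding error (≤ 10⁻²⁴ of the mean square of the input) count
  as zero, so constant and linear inputs fail loudly instead of fitting
  floating-point noise.
* **Regression**: ordinary least squares on log-transformed coordinates
  everywhere, no weighting.

## Signal-class adaptation in `hurst_all()`

The batch runner matches every estimator to the declared input class:

* `AV` and `RS` (increments-class) see the first difference of a
  walk-class input — no offset, because fGn and its fBm share H;
* walk-class estimators see the cumulative sum of an increments-class
  input — again no offset;
* `FFT` and `pWelch` are always computed on the increments with +1 added
  to the estimate. On increments the spectral exponent is β = 2H − 1, so
  (β − 1)/2 + 1 recovers H, and working on increments avoids both the
  spectral leakage of a raw periodogram on a very smooth path and any
  generator-specific spectral ceiling.

The applied adaptation is recorded per estimator, and per-estimator
failures are contained as error entries without aborting the batch.

### Boundedness and the ±1 offset

Integrating or differentiating the input shifts the true regularity by
±1. Unbounded estimators (`FFT`, `pWelch`, `DD`, `DDW`, `db2`–`db16`)
track that shift; bounded ones (the structure-function family, Higuchi,
DFA, AV, RS, and Haar `db1`) saturate near the [0, 1] edges, which is a
real loss of sensitivity when data are unusually smooth or rough. One
asymmetry deserves note: the second-derivative estimators measure
regularity through a fixed pair of dyadic quadratic variations and
cannot represent *negative* regularity, so on an increments-class input
(regularity H − 1 < 0) they floor near 0 instead of shifting by −1. The
spectral and wavelet estimators have no such floor. The consistency
benchmark flags saturation whenever a transformed-input estimate misses
the expected ±1 offset by more than 0.35, a threshold that cleanly
separates the two regimes (unbounded estimators track the offset within
about 0.2 at n = 1190).

## Simulators

* **Circulant embedding (default)**: exact Davies–Harte sampling of the
  fGn covariance, cumulated to fBm. Embedding eigenvalues are computed
  once per (H, n), so batches are cheap; tiny negative eigenvalues from
  floating-point rounding are clamped at zero.
* **Wavelet synthesis**: an exact coarse-scale process (16 scaling
  coefficients built from circulant fGn) refined level by level with
  independent detail coefficients through the inverse Daubechies
  transform. The per-level detail variances are computed *exactly* for
  the chosen filter from the fBm covariance kernel (autocorrelation of
  the cascade filter against |d|^{2H}), which removes the low-H bias a
  naive 2^{j(2H+1)} scaling constant would introduce. A path twice the
  requested length is synthesized and the first half kept so the
  periodic boundary of the inverse transform cannot fold back into the
  sample. The generator stays switchable because synthesis artifacts —
  e.g. a spectral ceiling — are properties of the generator, not of the
  estimators under study.
* **Brown noise**: cumulative sums of iid standard Gaussians.
* **Spikes**: additive offsets of ± magnitude × SD(pre-spike series) at
  a uniformly chosen subset of points, independent equiprobable signs.
  Additive offsets (rather than value replacement) preserve the local
  sample; the choice matters for interpretation: a spike in the path is
  a *doublet* in the increments, so the spike-dominated limit of each
  estimator is measure-specific (≈0 for curve-length measures, ≈0.5 for
  R/S, below 0 for the spectral pipeline). What is common to all
  estimators is that heavy spiking compresses the measurable H range
  toward that fixed point.

## Benchmark designs

**Consistency** (`run_consistency`): per grid-H, estimates on the
signal, its cumulative sum, and its first difference; mean estimate and
mean absolute error per estimator; saturation flags as above. With the
default conditions (length 1190, exact generator) the grand median of
per-estimator mean absolute errors lands near 0.05, with the wavelet
family and `DFA-L` showing the largest errors.

**Spike susceptibility** (`run_spike_benchmark`): the same fBm paths
(H = 0.5) are spiked over a (fraction ≤ 5%, magnitude ≤ 6 SD) grid. Each
cell is summarized by a **Welch two-sample t** of spiked vs clean
estimates: the shift is measured in units of the estimator's own
between-series sampling spread, which is what makes susceptibility
comparable across estimators of very different precision. (A paired
one-sample t on the same-seed differences was considered and rejected:
its denominator is the spread of the nearly deterministic paired
differences, so it rewards consistency of the artifact response and
ranks the imprecise-but-stable wavelet estimators as *more* susceptible
than the spectral ones, inverting the meaningful ordering.) All t-scores
are jointly rescaled to [0, 1] and each estimator's **volume** is the
total absolute deviation of its normalized surface from the zero-change
plane, so "least susceptible" is smallest volume. Cells with zero
fraction or magnitude leave the series bit-identical and score exactly
t = 0.

**Precision/accuracy correlations** (`run_correlation_benchmark`):
accuracy correlates estimators across series with H uniform on (0, 1)
(shared true variation dominates, correlations near 1); precision does
the same at fixed H = 0.5 (only estimation noise is shared, correlations
much lower, clustering by algorithmic family). Failures are handled
pairwise-complete with a logged count.

**Error drop-off** (`run_error_dropoff`): SD of estimates over 100
instances of brown noise at ten log-spaced lengths in [100, 10000];
α is the negative OLS slope of log SD vs log length, with its standard
error. A plug-in root-n statistic (the mean of the increments)
calibrates the protocol at α = 0.5. Neighbor comparisons use a bootstrap
over instances (`dropoff_compare`), since no analytic test applies to
the fitted slopes.

Benchmark defaults are 200 series; every result object records its
seed, sizes, and grids, and re-running with the same configuration is
bit-identical.

## The processing pipeline

The 36 combinations come from detrend (d) × motion regression
(none/m/m2) × global-signal regression (bcw) × filter (none/fhi/fbp),
minus squares-without-linear-motion and the redundant fhi+fbp pairing.
Operators apply in the fixed order **detrend → nuisance regression →
filter**; the order is not dictated by the science, but regressing
before filtering keeps the nuisance fit from being distorted by drift,
and it is switchable (`filter_first`) and recorded. Filtering is a
10th-order Butterworth design applied forward–backward (zero phase —
phase distortion would corrupt windowed profiles), high-pass 0.01 Hz or
band-pass 0.01–0.1 Hz against the TR. Nuisance regression always
includes an intercept and returns the plain OLS residual; complexity
estimators are location-invariant, so the mean is not restored. Motion
files follow the six-column realignment dialect (mm, radians).

## The phantom

`generate_phantom()` builds each voxel as
fGn(H_tissue) + drift·t + Σ w_j·motion_j + global + activation + white
noise, with disjoint tissue masks, smooth random-walk motion, an fGn
(H = 0.9) global signal, and a smoothed 40 s on/off boxcar envelope
added in a grey-matter subregion (or, in `"hurst"` mode, activated
voxels carry a different H outside the additive path). Defaults emulate
a long naturalistic acquisition: 1190 volumes at TR 2.1 s, H 0.8/0.5/0.35
for GM/WM/CSF, nuisance amplitudes comparable to the unit-variance
fractal signal. What it deliberately does **not** model: hemodynamic
response shapes, spatial correlation (optional smoothing is off by
default for test speed), k-space/scanner noise physics, or
physiological cardiac/respiratory cycles. Passing phantom tests
therefore demonstrates correct recovery of the *generative* model — the
scaling exponents and nuisance structure — not fidelity to every
property of real BOLD data.

## fMRI metrics

Tissue contrast is a two-sample Welch t of grey- vs white-matter voxel
H values. Activation overlap is the ROC AUC of the H map against the top
`top_frac` (default 1%, 10% for the coarser protocol) of a reference
statistic map, with midrank tie handling (the AUC equals the rank-sum
statistic; tie handling only matters for degenerate maps). ISC is the
mean Fisher z of all pairwise between-subject correlations per voxel,
with |r| = 1 capped at the z of 0.999999 and flagged, and zero-variance
voxels set missing. Windowed profiles place `n_windows` equal windows so
the first starts at 0 and the last ends at the series end; fifteen
10-minute windows on a 1190-sample TR 2.1 s series overlap by ≈77%.
Region-level group separation estimates H on each atlas region's
*average* series after processing (not the average of voxel H), stacks
subjects × regions, column-standardizes, and compares groups by a
two-sample t on the first principal component; the PC sign is arbitrary,
so only |t| and p are meaningful.

## Problem sizes in the test suite

The shipped tests run the benchmarks at the sizes the package's own
validation used: the full 0.05-step H grid with 200 series of length
1190 for the consistency summary, 100 instances for the drop-off rate,
200 series for the spike and correlation benchmarks, 100 seeds for the
monotonicity sweep, and small (6–10 voxels per side) phantoms for the
fMRI metrics. Oracle-equivalence checks compare against brute-force
reimplementations (explicit loops and `lm` fits) at 16–250 points to
1e−10.

## Known limitations

* The wavelet-variance estimators are strongly biased low below H ≈ 0.3
  and carry the largest errors overall; they are retained for their
  spike robustness.
* `DD`/`DDW` cannot measure negative regularity (see above) and are the
  most spike-sensitive family together with the spectral estimators.
* R/S is biased upward at realistic lengths; DFA-L (large boxes only)
  has few effective degrees of freedom below ~1200 samples.
* The raw-periodogram FFT fit has a per-bin noise floor (low r²) and
  relies on the increments pipeline to avoid leakage on smooth paths.
* The circulant generator is exact for fGn/fBm but cannot produce
  multifractal or nonstationary-H signals; windowed-profile tests splice
  regimes instead.
```{r}
# A compact end-to-end check, runnable after installation:
library(fmrihurst)
x <- fbm(1190, H = 0.7, seed = 42)
as.data.frame(hurst_all(x, "walk"))[, c("estimator_id", "H", "adaptation")]
```
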