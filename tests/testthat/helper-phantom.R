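# Synthetic reference statistic map: strong activation t-values over a
# noisy background, mimicking what a GLM contrast would hand the ROC
# analysis.
with_ref_noise <- function(activation_mask, t_active = 8, noise_sd = 0.8,
                           seed = 1) {
  fmrihurst:::with_seed(seed, {
    array(rnorm(length(activation_mask), sd = noise_sd),
          dim = dim(activation_mask)) + t_active * activation_mask
  })
}
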