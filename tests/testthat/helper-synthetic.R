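# Shared fixture builders. Everything is generated in code at test time.

# a desk-scale configuration: few small regions, small cohorts
tiny_config <- function(seed = 1L, ...) {
  synthetic_config(
    n_hc_train = 60L, n_hc_test = 30L, n_scz = 30L,
    voxels_per_region = 30L,
    n_regions = list(GM = 4L, FC = 4L, FA = 2L),
    seed = seed, ...
  )
}

# subject x voxel matrix with a known informative set:
# informative voxels follow baseline + slope*age, the rest are pure noise
signal_matrix <- function(n, V, informative, age, slope = -0.005,
                          noise_sd = 0.125, baseline = 0.6) {
  X <- matrix(rnorm(n * V, baseline, noise_sd), n, V)
  if (length(informative)) {
    X[, informative] <- X[, informative] +
      outer(slope * age, rep(1, length(informative)))
  }
  X
}

# population correlation between an informative voxel and age under the
# uniform age model: r = |slope| sd(age) / sqrt(slope^2 var(age) + noise^2)
population_r <- function(slope, noise_sd, age_range = c(20, 84)) {
  sd_age <- diff(age_range) / sqrt(12)
  abs(slope) * sd_age / sqrt(slope^2 * sd_age^2 + noise_sd^2)
}
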