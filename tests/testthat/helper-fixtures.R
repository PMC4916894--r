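# Shared fixtures: small, fast synthetic specs used across test files.

# Noiseless nucleus with the test channel identical in pattern to the
# reference.
fixture_uniform_spec <- function(seed = 1L)
  synthetic_spec(noise = "none", seed = seed)

fixture_punctate_spec <- function(seed = 1L)
  synthetic_spec(n_foci = 6L, focus_contrast = 5, baseline_fraction = 0.05,
                 noise = "none", seed = seed)

# Profiles of the full pipeline on one stack: refined contour + both
# channel profiles.
pipeline_profiles <- function(img, config = segment_config()) {
  ct <- segment_nuclei(img$stack, config)[[1]]
  list(contour = ct,
       ref = sample_contour_intensity(
         max_intensity_projection(img$stack, "reference"), ct),
       test = sample_contour_intensity(
         max_intensity_projection(img$stack, "test"), ct))
}

# Random circular profile pair with punctate-like structure for oracle
# cross-checks: smooth base + spikes, arbitrary scales.
random_profile_pair <- function(n, rng) {
  base <- 100 + 40 * sin(seq(0, 2 * pi, length.out = n + 1)[-(n + 1)] * rng$k)
  ref <- round(base + stats::rnorm(n, 0, rng$sd))
  test <- round(base * rng$gain + stats::rnorm(n, 0, rng$sd))
  spikes <- sample.int(n, rng$n_spikes)
  test[spikes] <- test[spikes] + rng$spike
  list(ref = ref, test = test)
}
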