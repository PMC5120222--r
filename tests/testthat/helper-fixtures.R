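# Shared fixtures: small, fast configurations used across test files.
# All randomness is seeded so the suite is reproducible.

TEST_SEED <- 1L

small_cfg <- function(seed = TEST_SEED, n_per_bin = 4L, ...) {
  generator_config(seed = seed, n_per_bin = n_per_bin, ...)
}

# a noiseless, decay-free configuration: intensities equal the emission
# means exactly
degenerate_cfg <- function(seed = TEST_SEED, decay_mean = 0, ...) {
  generator_config(seed = seed, noise_sd = 0, decay_mean = decay_mean,
                   decay_sd = 0, decay_channel_jitter_sd = 0,
                   emission = default_emission(sd_log = 0), ...)
}

# run decay fitting, shrinkage, correction and k-means classification
corrected_cohort <- function(cfg, classify = TRUE, ...) {
  coh <- generate_cohort(cfg)
  shr <- eb_shrink(fit_decay_cohort(coh))
  coh <- correct_z(coh, shr)
  if (classify) {
    m <- fit_centers(coh, seed = cfg$seed, ...)
    coh <- assign_by_centers(coh, m)
  }
  coh
}

# terminal-stage cohort: every embryo has more than 100 cells
terminal_bins <- data.frame(label = c("101-120", "120-150", ">150"),
                            lower = c(101, 120, 150),
                            upper = c(120, 150, Inf),
                            stringsAsFactors = FALSE)
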