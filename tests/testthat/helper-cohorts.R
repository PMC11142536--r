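# Small cohort configurations reused across tests.  Sizes are kept tiny;
# the synthetic signal scales are the package defaults.

tiny_cohort_config <- function(seed = 1, n_patients = 12, ...) {
  cohort_config(n_patients = n_patients, spots_per_patient_mean = 5,
                n_axis_bins = 150, n_signal_peaks = 8, patch_px = 32,
                seed = seed, ...)
}

tiny_pipeline_config <- function(seed = 1, ...) {
  pipeline_config(n_axis_bins = 150, baseline_window = 21, k_outer = 3,
                  k_inner = 2, grid = c(0.1, 1),
                  embedder = embedder_spec(embed_dim = 32, input_side = 32),
                  seed = seed, ...)
}

# flat-spectrum helper on an arbitrary axis
flat_spectrum <- function(value, n = 50, id = "flat") {
  ims_spectrum(seq(700, 800, length.out = n), rep(value, n), spot_id = id)
}
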