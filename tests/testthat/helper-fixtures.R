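# Small simulation designs used across test files.

small_design <- function(seed = 42, interferent_level = 0, noise_sd = 0.002,
                         drift = TRUE, scatter = TRUE, n_base = 3L,
                         spike_volumes = seq(50, 400, by = 70),
                         n_replicates = 1L, grid = seq(650, 2100, by = 2)) {
  bs <- default_band_sets()
  sim_design(
    analyte_bands = bs$analytes,
    interferent_bands = bs$interferent,
    matrix_bands = bs$matrix,
    base_levels = c(daidzin = 0.025, genistin = 0.048, glycitin = 0.012),
    spike_volumes = spike_volumes,
    n_base = n_base,
    n_replicates = n_replicates,
    interferent_level = interferent_level,
    baseline_drift = if (drift) list(intercept = c(-0.02, 0.02),
                                     slope = c(-1e-5, 1e-5))
                     else list(intercept = c(0, 0), slope = c(0, 0)),
    scatter_range = if (scatter) c(0.97, 1.03) else c(1, 1),
    noise_sd = noise_sd,
    grid = grid,
    seed = seed
  )
}

# 15-sample, perfectly linear (noise/drift/scatter/interferent free) design:
# exactly rank 3 after centering.
noiseless_design <- function(seed = 7) {
  small_design(seed = seed, interferent_level = 0, noise_sd = 0,
               drift = FALSE, scatter = FALSE, n_base = 3L,
               spike_volumes = c(100, 250, 400))
}
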