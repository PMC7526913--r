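# Shared study-condition fixtures. Tests use a coarser voxel pitch than
# the acquisition default so full embryos stay small; geometry and signal
# levels are otherwise the standard conditions.

coarse_spec <- function(seed, n_cells = 24, n_round_cells = 0) {
  embryo_spec(n_cells = n_cells, voxel_size_um = c(0.4, 0.4, 0.8),
              membrane_thickness_vox = 2, n_round_cells = n_round_cells,
              seed = seed)
}

# Deterministic low-discrepancy-ish values in [0, 1] without touching RNG.
det_values <- function(n, phase = 0) (sin(seq_len(n) * 12.9898 + phase) + 1) / 2
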