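# small phantom layouts used across tests; full-size defaults are exercised
# only where the test needs them

# single central vial on a tiny grid
tiny_layout <- function(grid = c(1, 32, 32), radius_mm = 6, s0 = 1000) {
  make_phantom_layout(n_ring = 0, grid_shape = grid,
                      vial_radius_mm = radius_mm, s0 = s0)
}

# central vial + 6-vial ring with distinct diffusivities, 2 slices
small_layout <- function() {
  make_phantom_layout(n_ring = 6, grid_shape = c(2, 48, 48),
                      vial_radius_mm = 5, ring_radius_mm = 15)
}

qiba_b <- c(0, 500, 1000, 1500, 2000)
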