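# Shared fixtures: the phantom-study parameter set used throughout the tests
# (tissue-mimicking block, Cy5-like fluorophore) and small helpers.

study_medium <- function() optical_medium(mua = 0.01, mus = 2.63, g = 0.62,
                                          n = 1.521)
study_fluor <- function() fluorophore_props(muaf = 0.01, gamma = 0.2,
                                            tau = 900)

# Strategy velocities (mm/ps)
v_strategy1 <- c(0.0165, 0.011, 0.0055)
v_strategy2 <- c(0.0165, 0.011, 0.033)

# Reduced validation grid: 60 x 60 x 45 voxels of 0.25 mm (15 x 15 x 11.25 mm)
desk_grid <- function() voxel_grid(c(60L, 60L, 45L), 0.25)

# Desk phantom: 2-mm cylinder along x, axis 4.4 mm deep, centred in y.
desk_phantom <- function() {
  make_phantom(desk_grid(), study_medium(), study_fluor(),
               cylinder_shape(c(0, 7.5, 4.4), radius = 1, axis = 1L))
}

# A centred 1.1-mm link over the cylinder on the desk grid (source and
# detector straddle the grid mid-plane x = 7.5).
centered_link <- function(R = 1.1) {
  list(sx = 7.5 - R / 2, sy = 7.5, dx = 7.5 + R / 2, dy = 7.5,
       sr_distance = R)
}

# Small uniform time grid helper.
tc_grid <- function(values, bin_width = 2, t0 = 0, kind = "FTPSF") {
  time_curve(seq(t0, by = bin_width, length.out = length(values) + 1L),
             values, kind)
}
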