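# shared fixtures for the test suite: everything is generated in code

geom <- default_geometry()

# expected sizing-pulse depth (nA) for a diameter at the default baseline
expected_depth <- function(d_um, baseline_na = 250, g = geom) {
  baseline_na * relative_blockade(d_um, g$sizing_width_um, g$height_um,
                                  g$sizing_length_um)
}

# simulate a calibration-bead run at a given signal-to-noise ratio
bead_simulation <- function(n, snr = 50, seed = 1, mean_um = 2,
                            sd_um = 0.05) {
  beads <- nucleus_population(n, mean_um, sd_um, softness = 0,
                              label = "bead", seed = seed)
  simulate_nps_trace(geom, beads, noise_sd_na = expected_depth(mean_um) / snr,
                     seed = seed + 1)
}

# simulate a nucleus run (diameters straddle the contraction width unless
# explicit diameters are given)
nucleus_simulation <- function(n, snr = 50, seed = 1, softness = 0,
                               diameters = NULL) {
  pop <- if (is.null(diameters)) {
    nucleus_population(n, 3.41, 0.3, softness = softness, seed = seed)
  } else {
    data.frame(diameter_um = diameters, softness = softness, label = "nucleus")
  }
  simulate_nps_trace(geom, pop,
                     noise_sd_na = expected_depth(3.41) / snr, seed = seed + 1)
}

# solid sphere as a 3D intensity array (foreground value fg)
sphere_stack <- function(radius_vox, half_size = NULL, fg = 1000,
                         center = NULL) {
  if (is.null(half_size)) half_size <- ceiling(radius_vox) + 3
  n <- 2 * half_size + 1
  if (is.null(center)) center <- rep(half_size + 1, 3)
  idx <- expand.grid(i = seq_len(n), j = seq_len(n), k = seq_len(n))
  d2 <- (idx$i - center[1])^2 + (idx$j - center[2])^2 + (idx$k - center[3])^2
  array(ifelse(d2 <= radius_vox^2, fg, 0), dim = c(n, n, n))
}
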