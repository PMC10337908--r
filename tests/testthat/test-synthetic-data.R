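test_that("all generators are reproducible from (spec, seed)", {
  p <- nucleus_population(5, seed = 3)
  expect_identical(simulate_nps_trace(geom, p, seed = 9),
                   simulate_nps_trace(geom, p, seed = 9))
  rs <- ring_spec(n_patches = 4, cap_amplitude = 50, noise_sd = 2)
  expect_identical(simulate_ring_image(rs, 101, seed = 4),
                   simulate_ring_image(rs, 101, seed = 4))
  cs <- collapse_spec()
  expect_identical(simulate_collapse_series(cs, seed = 5),
                   simulate_collapse_series(cs, seed = 5))
  ls <- layout_spec(n_nuclei = 100)
  expect_identical(simulate_gonad_layout(ls, seed = 6),
                   simulate_gonad_layout(ls, seed = 6))
  expect_identical(simulate_tracks(3, n_frames = 5, seed = 7),
                   simulate_tracks(3, n_frames = 5, seed = 7))
  # different seed, different noise
  expect_false(identical(simulate_nps_trace(geom, p, seed = 9)$trace$current_na,
                         simulate_nps_trace(geom, p, seed = 10)$trace$current_na))
})

test_that("empty particle list gives a flat noisy baseline and empty truth", {
  sim <- simulate_nps_trace(geom, nucleus_population(0, seed = 1),
                            noise_sd_na = 1e-3, baseline_na = 250, seed = 2)
  expect_equal(nrow(sim$truth), 0)
  expect_true(all(sim$clean == 250))
  expect_equal(mean(sim$trace$current_na), 250,
               tolerance = 1e-4)
  expect_equal(nrow(detect_events(preprocess_trace(sim$trace))), 0)
})

test_that("a rigid sub-contraction particle transits at the free-flow speed", {
  sim <- simulate_nps_trace(geom, particle_spec(2.0, softness = 0), seed = 1)
  expect_equal(nrow(sim$truth), 1)
  # no strain, so t_c/t_s is the segment length ratio exactly
  expect_equal(sim$truth$t_c_s / sim$truth$t_s_s,
               geom$contraction_length_um / geom$sizing_length_um)
  expect_equal(sim$truth$strain, 0)
})

test_that("softness shortens the contraction transit at equal size", {
  pop <- rbind(particle_spec(3.4, softness = 0, label = "stiff"),
               particle_spec(3.4, softness = 2, label = "soft"))
  sim <- simulate_nps_trace(geom, pop, seed = 1)
  expect_equal(sim$truth$delta_i_s_na[1], sim$truth$delta_i_s_na[2])
  # stiffer nuclei take longer than softer ones
  expect_gt(sim$truth$t_c_s[1], sim$truth$t_c_s[2])
})

test_that("overlapping start times and oversized particles are rejected", {
  p <- rbind(particle_spec(3.0), particle_spec(3.0))
  expect_error(simulate_nps_trace(geom, p, start_times_s = c(0.1, 0.12)),
               "overlap")
  expect_error(simulate_nps_trace(geom, particle_spec(6.5)),
               "sizing segment width")
  expect_error(simulate_nps_trace(geom, particle_spec(3.0),
                                  sampling_rate_hz = 500),
               "20 samples")
})

test_that("trace minus the clean template leaves pure noise", {
  sim <- nucleus_simulation(10, snr = 50, seed = 2)
  resid <- sim$trace$current_na - sim$clean
  expect_equal(mean(resid), 0, tolerance = 5 * sim$noise_sd_na / sqrt(length(resid)))
  expect_equal(sd(resid), sim$noise_sd_na, tolerance = 0.05)
})

test_that("featureless ring specs produce a constant angular profile", {
  rs <- ring_spec(n_patches = 0, cap_amplitude = 0, noise_sd = 0,
                  base_intensity = 80)
  sim <- simulate_ring_image(rs, 101, seed = 1)
  expect_true(all(sim$truth$intensity == 80))
  on_ring <- sample_ring_profile(sim$image, sim$center, rs$radius_px,
                                 rs$ring_width_px)
  expect_lt(diff(range(on_ring$intensity)) / mean(on_ring$intensity), 0.02)
})

test_that("a concentrated cap puts the profile argmax at the cap angle", {
  rs <- ring_spec(cap_amplitude = 200, cap_angle_deg = 247,
                  cap_concentration = 20, noise_sd = 0)
  sim <- simulate_ring_image(rs, 101, seed = 1)
  expect_lte(abs(sim$truth$angle_deg[which.max(sim$truth$intensity)] - 247), 1)
})

test_that("sampled ring profile tracks the generator ground truth", {
  rs <- ring_spec(n_patches = 6, patch_concentration = 8, noise_sd = 0)
  sim <- simulate_ring_image(rs, 121, seed = 3)
  prof <- sample_ring_profile(sim$image, sim$center, rs$radius_px,
                              rs$ring_width_px)
  expect_gt(cor(prof$intensity, sim$truth$intensity), 0.95)
})

test_that("ring image total intensity matches the analytic integral", {
  rs <- ring_spec(radius_px = 30, ring_width_px = 6, n_patches = 3,
                  patch_concentration = 5, cap_amplitude = 60, noise_sd = 0)
  sim <- simulate_ring_image(rs, 121, seed = 2)
  # sum f(theta) r dr dtheta with a Gaussian radial window of SD sigma_r
  analytic <- sum(sim$truth$intensity) * (pi / 180) * rs$radius_px *
    sim$sigma_r * sqrt(2 * pi)
  expect_equal(sum(sim$image), analytic, tolerance = 0.02)
})

test_that("rings that do not fit in the frame are rejected", {
  expect_error(simulate_ring_image(ring_spec(radius_px = 45), 101), "fit")
})

test_that("collapse series follows its piecewise-linear construction", {
  # NE constant before contact when rate_pre = 0
  cs0 <- simulate_collapse_series(
    collapse_spec(rate_pre = 0, noise_sd = 0), seed = 1)
  cf <- attr(cs0, "contact_frame")
  expect_true(all(cs0$ne_size[seq_len(cf)] == cs0$ne_size[1]))
  # exact finite-difference slope at zero noise
  cs <- simulate_collapse_series(collapse_spec(noise_sd = 0), seed = 1)
  expect_equal(unique(round(diff(cs$ne_size[seq_len(cf)]), 12)), -0.05)
  # first NE-SC meeting is the nominal contact frame (default construction)
  expect_equal(min(which(cs$ne_size - cs$sc_size <= 1e-9)), cf)
  # SC constant until contact
  expect_true(all(cs$sc_size[seq_len(cf)] == cs$sc_size[1]))
})

test_that("rates that drive sizes negative are clipped with a warning", {
  sp <- collapse_spec(rate_post = -0.5, rate_post_sc = -0.5, noise_sd = 0)
  expect_warning(cs <- simulate_collapse_series(sp, seed = 1), "clipping")
  expect_true(all(cs$ne_size >= 0) && all(cs$sc_size >= 0))
})

test_that("gonad layout respects per-zone collapse probabilities", {
  nz <- 6
  all0 <- simulate_gonad_layout(
    layout_spec(n_nuclei = 200, zone_collapse_probs = rep(0, nz)), seed = 1)
  expect_equal(sum(all0$collapsed), 0)
  all1 <- simulate_gonad_layout(
    layout_spec(n_nuclei = 200, zone_collapse_probs = rep(1, nz)), seed = 1)
  expect_equal(mean(all1$collapsed), 1)

  probs <- c(0, 0, 0, 0.2, 0.6, 0.9)
  lay <- simulate_gonad_layout(
    layout_spec(n_nuclei = 600, zone_collapse_probs = probs), seed = 7)
  frac <- tapply(lay$collapsed, lay$zone, mean)
  n_z <- tapply(lay$collapsed, lay$zone, length)
  se <- sqrt(pmax(probs, 0.5 / n_z) * (1 - pmin(probs, 1 - 0.5 / n_z)) / n_z)
  expect_true(all(abs(frac - probs) <= 3 * se))
})

test_that("layout stage labels follow the axial boundaries", {
  lay <- simulate_gonad_layout(layout_spec(n_nuclei = 300), seed = 2)
  expect_true(all(lay$stage[lay$position < 10] == "PM"))
  expect_true(all(lay$stage[lay$position > 50] == "Dip"))
})

test_that("track generator honours its motion models and drift", {
  st <- simulate_tracks(3, motion = list(model = "stationary"), n_frames = 6,
                        seed = 1)
  for (p in split(st$truth, st$truth$particle)) {
    expect_equal(max(dist(p[, c("x_um", "y_um", "z_um")])), 0)
  }
  dirm <- simulate_tracks(3, motion = list(model = "directed",
                                           speed_um_per_frame = 1),
                          n_frames = 6, seed = 2)
  for (p in split(dirm$truth, dirm$truth$particle)) {
    p <- p[order(p$frame), ]
    steps <- sqrt(diff(p$x_um)^2 + diff(p$y_um)^2 + diff(p$z_um)^2)
    expect_equal(steps, rep(1, 5))
  }
  dr <- simulate_tracks(3, motion = list(model = "stationary"),
                        drift_um_per_frame = c(2, 0, 0), n_frames = 6,
                        seed = 3)
  p <- split(dr$truth, dr$truth$particle)[[1]]
  p <- p[order(p$frame), ]
  expect_equal(diff(p$x_um), rep(2, 5))
  # subtracting the known drift restores stationarity
  expect_equal(diff(p$x_um - 2 * (p$frame - 1)), rep(0, 5))
})
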