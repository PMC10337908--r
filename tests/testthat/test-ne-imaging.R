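test_that("ring sampling reproduces the generator profile up to scale", {
  rs <- ring_spec(n_patches = 5, patch_concentration = 6, cap_amplitude = 40,
                  cap_angle_deg = 300, noise_sd = 0)
  sim <- simulate_ring_image(rs, 121, seed = 8)
  prof <- sample_ring_profile(sim$image, sim$center, rs$radius_px,
                              rs$ring_width_px)
  a <- prof$intensity / mean(prof$intensity)
  b <- sim$truth$intensity / mean(sim$truth$intensity)
  expect_true(all(abs(a - b) / b < 0.03))
})

test_that("ring sampling is equivariant under image rotation", {
  rs <- ring_spec(cap_amplitude = 120, cap_angle_deg = 0,
                  cap_concentration = 4, noise_sd = 0)
  sim <- simulate_ring_image(rs, 101, seed = 1)
  rot90 <- t(sim$image)[rev(seq_len(nrow(sim$image))), ] # +90 deg rotation
  p0 <- sample_ring_profile(sim$image, sim$center, rs$radius_px,
                            rs$ring_width_px)
  p90 <- sample_ring_profile(rot90, sim$center, rs$radius_px,
                             rs$ring_width_px)
  expect_equal(p90$intensity, p0$intensity[((0:359 - 90) %% 360) + 1],
               tolerance = 0.02)
})

test_that("sampling outside the frame is rejected", {
  img <- matrix(0, 50, 50)
  expect_error(sample_ring_profile(img, c(60, 25), 10, 2), "outside")
  expect_error(sample_ring_profile(img, c(25, 25), 30, 2), "outside")
})

test_that("clustering index equals the CV and is scale/rotation invariant", {
  expect_equal(clustering_index(rep(7, 36)), 0)
  # hand-computed: sample SD of (1,1,1,3) is 1, mean 1.5
  expect_equal(clustering_index(c(1, 1, 1, 3)), 1 / 1.5)
  x <- withr::with_seed(4, runif(90, 1, 5))
  expect_equal(clustering_index(3.7 * x), clustering_index(x))
  rot <- c(x[31:90], x[1:30])
  expect_equal(clustering_index(rot), clustering_index(x))
  expect_error(clustering_index(rep(0, 10)), "positive")
})

test_that("mean ring intensity is normalized against the reference stage", {
  df <- data.frame(nucleus_id = 1:6,
                   stage = c("TZ", "TZ", "TZ", "MP", "MP", "LP"),
                   mean_intensity = c(9, 10, 11, 20, 20, 5))
  out <- normalized_mean_intensity(df)
  expect_equal(mean(out$normalized[out$stage == "TZ"]), 1)
  expect_equal(out$normalized[out$stage == "MP"], c(2, 2))
  expect_equal(out$normalized[out$stage == "LP"], 0.5)
  same <- data.frame(nucleus_id = 1:4, stage = c("TZ", "TZ", "MP", "MP"),
                     mean_intensity = rep(6, 4))
  expect_true(all(normalized_mean_intensity(same)$normalized == 1))
  expect_error(normalized_mean_intensity(df, reference_stage = "Dip"),
               "no nuclei")
})

test_that("polarization profile puts the peak at 180 and unity at 0", {
  # constant profile: every value 1 at every angle
  pc <- polarization_profile(rep(4, 360))
  expect_true(all(pc$intensity == 1))
  # synthetic cap lands on the convention exactly
  rs <- ring_spec(cap_amplitude = 150, cap_angle_deg = 37,
                  cap_concentration = 3, noise_sd = 0)
  sim <- simulate_ring_image(rs, 121, seed = 2)
  prof <- sample_ring_profile(sim$image, sim$center, rs$radius_px,
                              rs$ring_width_px)
  pol <- polarization_profile(prof)
  expect_identical(pol$intensity[pol$angle_deg == 0], 1)
  # raw argmax within half a grid step of the 180-degree convention
  expect_lte(abs(pol$angle_deg[which.max(pol$intensity)] - 180), 1)
  expect_error(polarization_profile(rep(0, 360)), "all-zero")
})

test_that("polarization is idempotent and invariant to pre-rotation", {
  rs <- ring_spec(cap_amplitude = 150, cap_angle_deg = 211,
                  cap_concentration = 3, noise_sd = 0)
  sim <- simulate_ring_image(rs, 121, seed = 3)
  prof <- sample_ring_profile(sim$image, sim$center, rs$radius_px,
                              rs$ring_width_px)
  p1 <- polarization_profile(prof)
  p2 <- polarization_profile(ring_profile(p1$angle_deg, p1$intensity))
  expect_equal(p2$intensity, p1$intensity)
  # circularly shifting the input does not change the aligned output
  shifted <- c(tail(prof$intensity, 100), head(prof$intensity, 260))
  p3 <- polarization_profile(ring_profile(prof$angle_deg, shifted))
  expect_equal(p3$intensity, p1$intensity)
})

test_that("folding averages symmetric halves onto [0, 180]", {
  theta <- 0:359
  sym <- 1 + exp(2 * (cos((theta - 180) * pi / 180) - 1))  # symmetric peak
  pf <- polarization_profile(sym, fold = TRUE)
  expect_equal(pf$angle_deg, 0:180)
  # profile already symmetric about 180: folding must reproduce either half
  pu <- polarization_profile(sym)
  expect_equal(pf$intensity, pu$intensity[1:181])
})

test_that("peak-region statistic is monotone in cap amplitude", {
  expect_equal(peak_region_stat(polarization_profile(rep(2, 360))), 1)
  stats <- vapply(c(0.5, 1, 2, 4), function(a) {
    rs <- ring_spec(cap_amplitude = a * 100, cap_angle_deg = 90,
                    cap_concentration = 3, noise_sd = 0)
    sim <- simulate_ring_image(rs, 121, seed = 5)
    prof <- sample_ring_profile(sim$image, sim$center, rs$radius_px,
                                rs$ring_width_px)
    peak_region_stat(polarization_profile(prof))
  }, numeric(1))
  expect_true(all(diff(stats) > 0))
})

test_that("stronger caps separate groups in the peak-window t test", {
  stat_for <- function(amp, seed) {
    rs <- ring_spec(cap_amplitude = amp, cap_angle_deg = 45,
                    cap_concentration = 3, noise_sd = 3)
    sim <- simulate_ring_image(rs, 101, seed = seed)
    prof <- sample_ring_profile(sim$image, sim$center, rs$radius_px,
                                rs$ring_width_px)
    peak_region_stat(polarization_profile(prof))
  }
  g0 <- vapply(1:20, function(s) stat_for(0, s), numeric(1))
  g2 <- vapply(1:20, function(s) stat_for(200, s + 100), numeric(1))
  res <- standard_tests("welch-t",
                        data.frame(group = rep(c("flat", "cap"), each = 20),
                                   value = c(g0, g2)))
  expect_lt(res$p_value, 0.01)
  expect_gt(mean(g2), mean(g0))
})

test_that("greedy linking recovers well-separated tracks without swaps", {
  ts <- simulate_tracks(1, motion = list(model = "stationary"), n_frames = 8,
                        seed = 1)
  tr <- link_tracks(ts$detections, max_displacement = 1, frame_interval_s = 5)
  expect_equal(length(tr), 1)
  expect_equal(nrow(tr[[1]]$positions), 8)

  # two distant particles never swap identity
  det <- rbind(data.frame(frame = rep(1:6, each = 1), x_um = 0, y_um = 0,
                          z_um = 0),
               data.frame(frame = 1:6, x_um = 50, y_um = 0, z_um = 0))
  tr2 <- link_tracks(det, max_displacement = 5, frame_interval_s = 5)
  expect_equal(length(tr2), 2)
  expect_true(all(vapply(tr2, function(t) length(unique(t$positions$x_um)) == 1,
                         logical(1))))
})

test_that("drift correction restores the drift-free tracks", {
  base <- simulate_tracks(4, motion = list(model = "directed",
                                           speed_um_per_frame = 0.5),
                          n_frames = 8, box_um = 40, seed = 9)
  drifted <- simulate_tracks(4, motion = list(model = "directed",
                                              speed_um_per_frame = 0.5),
                             drift_um_per_frame = c(3, -1, 0),
                             n_frames = 8, box_um = 40, seed = 9)
  t0 <- link_tracks(base$detections, max_displacement = 2,
                    frame_interval_s = 5)
  t1 <- link_tracks(drifted$detections, max_displacement = 2,
                    reference_drift = c(3, -1, 0), frame_interval_s = 5)
  expect_equal(length(t1), length(t0))
  p0 <- do.call(rbind, lapply(t0, function(t) t$positions))
  p1 <- do.call(rbind, lapply(t1, function(t) t$positions))
  expect_equal(p1[order(p1$frame, p1$x_um), ],
               p0[order(p0$frame, p0$x_um), ], ignore_attr = TRUE)
})

test_that("linking is >= 95% correct for spaced directed motion", {
  ts <- simulate_tracks(6, motion = list(model = "directed",
                                         speed_um_per_frame = 1),
                        n_frames = 10, box_um = 60, seed = 12)
  tr <- link_tracks(ts$detections, max_displacement = 2.5,
                    frame_interval_s = 5)
  # map every linked position back to its true particle
  key <- function(df) paste(df$frame, round(df$x_um, 6), round(df$y_um, 6))
  truth_map <- setNames(ts$truth$particle, key(ts$truth))
  purity <- vapply(tr, function(t) {
    ids <- truth_map[key(t$positions)]
    max(table(ids)) / length(ids)
  }, numeric(1))
  n_links <- vapply(tr, function(t) nrow(t$positions) - 1, numeric(1))
  expect_gte(sum(purity * (n_links + 1)) / sum(n_links + 1), 0.95)
})

test_that("track mean speed matches closed-form and Monte Carlo oracles", {
  still <- data.frame(frame = 1:5, x_um = 1, y_um = 2, z_um = 3)
  expect_equal(track_mean_speed(still, frame_interval_s = 5), 0)
  # 1 um per 5-s frame = 0.2 um/s
  straight <- data.frame(frame = 1:5, x_um = 1:5, y_um = 0, z_um = 0)
  expect_equal(track_mean_speed(straight, frame_interval_s = 5), 0.2)
  expect_true(is.na(track_mean_speed(still[1, ], frame_interval_s = 5)))
  # random walk: mean speed ~ E|step| / dt
  sigma <- 0.4
  ts <- simulate_tracks(1, motion = list(model = "random-walk",
                                         speed_um_per_frame = sigma),
                        n_frames = 4000, frame_interval_s = 5, seed = 3)
  p <- ts$truth[order(ts$truth$frame), ]
  v_hat <- track_mean_speed(p, frame_interval_s = 5)
  steps <- withr::with_seed(99, {
    m <- matrix(rnorm(3 * 2e5, 0, sigma), ncol = 3)
    sqrt(rowSums(m^2))
  })
  se <- sd(steps / 5) / sqrt(4000)
  expect_lt(abs(v_hat - mean(steps) / 5), 3 * se)
})

test_that("sphere volumes are recovered by threshold + 3D labelling", {
  st <- sphere_stack(5)
  v <- segment_nucleus_volume(st)
  expect_equal(nrow(v), 1)
  expect_equal(v$volume_um3, 4 / 3 * pi * 125, tolerance = 0.05)
  expect_false(v$touches_boundary)
  # empty stack
  expect_equal(nrow(segment_nucleus_volume(array(0, dim = c(8, 8, 8)))), 0)
})

test_that("disjoint spheres are measured separately and boundary flagged", {
  n <- 31
  a <- array(0, dim = c(n, n, n))
  grid <- expand.grid(i = 1:n, j = 1:n, k = 1:n)
  d1 <- (grid$i - 8)^2 + (grid$j - 8)^2 + (grid$k - 16)^2
  d2 <- (grid$i - 24)^2 + (grid$j - 24)^2 + (grid$k - 16)^2
  a[d1 <= 16 | d2 <= 36] <- 500
  v <- segment_nucleus_volume(a, voxel_size_um = c(0.5, 0.5, 0.5))
  expect_equal(nrow(v), 2)
  expect_equal(sort(v$volume_um3),
               sort(c(4 / 3 * pi * 4^3, 4 / 3 * pi * 6^3)) * 0.125,
               tolerance = 0.06)
  b <- array(0, dim = c(9, 9, 9))
  b[1, 5, 5] <- 10
  expect_true(segment_nucleus_volume(b, threshold_method = "fixed",
                                     threshold = 5)$touches_boundary)
})

test_that("volume error shrinks as the voxel grid is refined", {
  err <- function(r) {
    v <- segment_nucleus_volume(sphere_stack(r))$volume_um3
    abs(v - 4 / 3 * pi * r^3) / (4 / 3 * pi * r^3)
  }
  expect_lt(err(10), err(5))
})

test_that("collapse alignment finds contact and normalizes the final frame", {
  cs <- simulate_collapse_series(collapse_spec(noise_sd = 0.005), seed = 2)
  al <- align_collapse_series(cs, contact_tol = 0.02)
  expect_equal(attr(al, "contact_frame"), attr(cs, "contact_frame"),
               tolerance = 0)
  expect_identical(al$ne_norm[nrow(al)], 1)
  expect_identical(al$sc_norm[nrow(al)], 1)
  cf <- attr(al, "contact_frame")
  # SC flat before contact (noise-free check)
  cs0 <- simulate_collapse_series(collapse_spec(noise_sd = 0), seed = 2)
  al0 <- align_collapse_series(cs0, contact_tol = 1e-9)
  expect_true(all(al0$sc_norm[seq_len(cf)] == al0$sc_norm[1]))
  # no contact -> informative error
  expect_error(align_collapse_series(c(5, 4.9, 4.8, 4.7), c(1, 1, 1, 1),
                                     contact_tol = 0.1),
               "no NE-SC contact")
})

test_that("collapse rates are exact on noise-free lines and ordered", {
  cs <- simulate_collapse_series(collapse_spec(noise_sd = 0), seed = 1)
  al <- align_collapse_series(cs, contact_tol = 1e-9)
  r <- collapse_rates(al)
  ne_final <- cs$ne_size[nrow(cs)]
  expect_equal(r$rate_pre_per_frame, -0.05 / ne_final, tolerance = 1e-10)
  expect_equal(r$rate_post_per_frame, -0.08 / ne_final, tolerance = 1e-10)
  expect_gt(abs(r$rate_post), abs(r$rate_pre))
  # constant pre-contact NE -> zero pre rate
  cs0 <- simulate_collapse_series(collapse_spec(rate_pre = 0, noise_sd = 0),
                                  seed = 1)
  al0 <- align_collapse_series(cs0, contact_frame = attr(cs0, "contact_frame"))
  expect_equal(collapse_rates(al0)$rate_pre, 0, tolerance = 1e-12)
})
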