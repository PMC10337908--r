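#' Particle specification for NPS simulation
#'
#' One simulated particle (nucleus or calibration bead). `softness` is a
#' dimensionless deformability: 0 is a rigid sphere; larger values shorten
#' the contraction transit (softer objects squeeze through faster, while
#' stiffer ones take longer). The strain actually applied depends on the
#' particle diameter and the contraction width of the device.
#'
#' `nucleus_population()` draws a population of nuclei with normally
#' distributed diameters; the defaults describe the oocyte nuclei the
#' device was designed for (mean diameter 3.41 um).
#'
#' @param diameter_um Particle diameter (um), > 0.
#' @param softness Dimensionless softness, >= 0 (0 = rigid).
#' @param label Free-text label.
#' @return A one-row data frame with columns `diameter_um`, `softness`,
#'   `label`; rows can be `rbind`ed into a population.
#' @export
particle_spec <- function(diameter_um, softness = 0, label = "") {
  stopifnot(length(diameter_um) == 1, length(softness) == 1)
  if (!is.finite(diameter_um) || diameter_um <= 0) stop("diameter must be > 0")
  if (!is.finite(softness) || softness < 0) stop("softness must be >= 0")
  data.frame(diameter_um = diameter_um, softness = softness, label = label,
             stringsAsFactors = FALSE)
}

#' @rdname particle_spec
#' @param n Number of particles.
#' @param mean_diameter_um,sd_diameter_um Diameter distribution (um).
#' @param seed Integer seed.
#' @export
nucleus_population <- function(n, mean_diameter_um = 3.41,
                               sd_diameter_um = 0.3, softness = 0,
                               label = "nucleus", seed = 1) {
  d <- withr::with_seed(seed, rnorm(n, mean_diameter_um, sd_diameter_um))
  d <- pmax(d, 0.2)  # diameters are physical lengths
  data.frame(diameter_um = d, softness = rep_len(softness, n),
             label = rep_len(label, n), stringsAsFactors = FALSE)
}

as_particle_table <- function(particles) {
  if (is.data.frame(particles)) return(particles)
  if (is.list(particles)) return(do.call(rbind, particles))
  stop("particles must be a data frame or list of particle_spec() rows")
}

#' Simulate a mechano-NPS current trace
#'
#' Builds a baseline current record and subtracts, for each particle in
#' sequence, a sizing sub-pulse (depth from the blockade relation of the
#' sizing segment, duration `L_s / flow_speed`), a recovery to baseline
#' while the particle crosses the node, and a deeper contraction sub-pulse
#' whose duration is `(L_c / flow_speed) * (1 + strain_gain * strain /
#' (1 + softness))` — so at fixed strain, stiffer (less soft) particles take
#' strictly longer to cross the contraction segment, and rigid particles
#' smaller than the contraction width transit at the free-flow speed.
#' i.i.d. Gaussian noise is added last.
#'
#' @param geometry A [channel_geometry()].
#' @param particles Data frame from [particle_spec()] /
#'   [nucleus_population()] (possibly zero rows).
#' @param flow_speed_um_s Free-flow particle speed (um/s).
#' @param sampling_rate_hz Sampling rate of the simulated electronics (Hz).
#' @param noise_sd_na Gaussian noise SD (nA).
#' @param baseline_na Baseline current (nA).
#' @param gap_s Baseline gap inserted between consecutive transits (s).
#' @param lead_s Baseline lead-in/out at the trace ends (s).
#' @param start_times_s Optional explicit transit start times (s); must be
#'   sorted and non-overlapping, otherwise an error is raised.
#' @param strain_gain Dimensionless gain converting applied strain into
#'   contraction slow-down for a rigid particle.
#' @param seed Integer seed; the only source of randomness.
#' @return A list of class `nps_simulation`: `trace` (a [current_trace()]),
#'   `truth` (per-particle ground truth: diameter, strain, softness,
#'   `delta_i_s_na`, `t_s_s`, `t_c_s`, `start_s`), and `clean` (the
#'   noise-free current vector).
#' @export
simulate_nps_trace <- function(geometry, particles,
                               flow_speed_um_s = 1e4,
                               sampling_rate_hz = 1e4,
                               noise_sd_na = 5e-4,
                               baseline_na = 250,
                               gap_s = 0.3, lead_s = 0.1,
                               start_times_s = NULL,
                               strain_gain = 2,
                               seed = 1) {
  stopifnot(inherits(geometry, "channel_geometry"))
  particles <- as_particle_table(particles)
  n_p <- nrow(particles)
  fs <- sampling_rate_hz
  v <- flow_speed_um_s

  if (n_p > 0 && any(particles$diameter_um >= geometry$sizing_width_um)) {
    stop("particle diameter must be smaller than the sizing segment width")
  }

  t_s <- geometry$sizing_length_um / v
  t_node <- geometry$node_length_um / v
  eps <- vapply(particles$diameter_um, applied_strain, numeric(1),
                geometry = geometry)
  t_c <- (geometry$contraction_length_um / v) *
    (1 + strain_gain * eps / (1 + particles$softness))
  span <- t_s + t_node + t_c

  if (n_p > 0) {
    shortest <- min(t_s, t_node, t_c)
    if (shortest * fs < 20) {
      stop("sampling_rate too low: shortest sub-pulse spans < 20 samples")
    }
  }

  if (is.null(start_times_s)) {
    start <- if (n_p > 0) lead_s + c(0, cumsum(span[-n_p] + gap_s)) else numeric(0)
  } else {
    start <- as.numeric(start_times_s)
    if (length(start) != n_p) stop("start_times_s length must match particles")
    if (is.unsorted(start, strictly = TRUE) ||
        (n_p > 1 && any(diff(start) <= span[-n_p]))) {
      stop("events overlap at the requested spacing; increase the gaps ",
           "between start times")
    }
  }

  dur <- if (n_p > 0) max(start + span) + lead_s else 2 * lead_s
  n <- ceiling(dur * fs)
  clean <- rep(baseline_na, n)

  depth_s <- baseline_na * relative_blockade(
    particles$diameter_um, geometry$sizing_width_um,
    geometry$height_um, geometry$sizing_length_um)
  depth_c <- baseline_na * relative_blockade(
    particles$diameter_um, geometry$contraction_width_um,
    geometry$height_um, geometry$contraction_length_um)

  for (i in seq_len(n_p)) {
    i0 <- floor(start[i] * fs) + 1
    is_end <- i0 + round(t_s * fs) - 1
    c0 <- is_end + round(t_node * fs) + 1
    c_end <- c0 + round(t_c[i] * fs) - 1
    clean[i0:is_end] <- clean[i0:is_end] - depth_s[i]
    clean[c0:c_end] <- clean[c0:c_end] - depth_c[i]
  }

  noise <- withr::with_seed(seed, rnorm(n, 0, noise_sd_na))
  trace <- current_trace(time_s = (seq_len(n) - 1) / fs,
                         current_na = clean + noise,
                         sampling_rate_hz = fs,
                         baseline_na = baseline_na)
  truth <- data.frame(
    particle = seq_len(n_p),
    label = if (n_p > 0) particles$label else character(0),
    diameter_um = particles$diameter_um,
    softness = particles$softness,
    strain = eps,
    delta_i_s_na = depth_s,
    delta_i_c_na = depth_c,
    t_s_s = rep(t_s, n_p),
    t_c_s = t_c,
    start_s = start,
    stringsAsFactors = FALSE
  )
  structure(list(trace = trace, truth = truth, clean = clean,
                 geometry = geometry, noise_sd_na = noise_sd_na),
            class = "nps_simulation")
}

#' Ring specification for synthetic NE images
#'
#' Parameters of a synthetic nuclear-envelope ring: a circle of given radius
#' and radial width (Gaussian radial profile, FWHM = `ring_width_px`) whose
#' angular intensity is a constant base plus `n_patches` von Mises bumps
#' (patch positions drawn uniformly, concentration `patch_concentration`,
#' amplitude equal to the base intensity) plus a single polar "cap" bump of
#' amplitude `cap_amplitude` at `cap_angle_deg`. Angles are degrees in
#' [0, 360), counterclockwise from the +x image axis.
#'
#' @param radius_px Ring radius (px).
#' @param ring_width_px Radial FWHM of the ring (px).
#' @param base_intensity Baseline angular intensity (a.u.).
#' @param n_patches Number of von Mises patches.
#' @param patch_concentration von Mises concentration of the patches.
#' @param cap_amplitude Cap amplitude (a.u., >= 0).
#' @param cap_angle_deg Cap centre angle (degrees, [0, 360)).
#' @param cap_concentration von Mises concentration of the cap.
#' @param noise_sd Pixel noise SD (a.u.).
#' @return A list of class `ring_spec`.
#' @export
ring_spec <- function(radius_px = 30, ring_width_px = 6, base_intensity = 100,
                      n_patches = 0, patch_concentration = 8,
                      cap_amplitude = 0, cap_angle_deg = 0,
                      cap_concentration = 2, noise_sd = 0) {
  if (radius_px <= ring_width_px / 2) stop("radius must exceed ring_width/2")
  if (base_intensity < 0 || cap_amplitude < 0) stop("intensities must be >= 0")
  if (patch_concentration < 0 || cap_concentration < 0) {
    stop("von Mises concentrations must be >= 0")
  }
  if (cap_angle_deg < 0 || cap_angle_deg >= 360) {
    stop("cap_angle_deg must lie in [0, 360)")
  }
  structure(list(radius_px = radius_px, ring_width_px = ring_width_px,
                 base_intensity = base_intensity, n_patches = n_patches,
                 patch_concentration = patch_concentration,
                 cap_amplitude = cap_amplitude, cap_angle_deg = cap_angle_deg,
                 cap_concentration = cap_concentration, noise_sd = noise_sd),
            class = "ring_spec")
}

# peak-normalized von Mises bump, angles in degrees
vm_bump <- function(theta_deg, mu_deg, kappa) {
  exp(kappa * (cos((theta_deg - mu_deg) * pi / 180) - 1))
}

#' Simulate a nuclear-envelope ring image
#'
#' Renders the angular intensity model of a [ring_spec()] onto a square
#' image with a Gaussian radial profile, and returns the noise-free ground
#' truth on a 1-degree grid.
#'
#' @param spec A [ring_spec()].
#' @param image_size Image side (px).
#' @param seed Integer seed (patch placement and pixel noise).
#' @return A list of class `ring_simulation`: `image` (matrix, rows = y),
#'   `truth` (data frame `angle_deg`, `intensity`), `center` (x, y in
#'   pixels, 1-based), plus the spec.
#' @export
simulate_ring_image <- function(spec, image_size = 101, seed = 1) {
  stopifnot(inherits(spec, "ring_spec"))
  cx <- (image_size + 1) / 2
  cy <- (image_size + 1) / 2
  sigma_r <- spec$ring_width_px / (2 * sqrt(2 * log(2)))
  if (spec$radius_px + 3 * sigma_r > min(cx, cy) - 1) {
    stop("ring does not fit inside the image")
  }

  out <- withr::with_seed(seed, {
    patch_mu <- if (spec$n_patches > 0) runif(spec$n_patches, 0, 360) else numeric(0)
    profile_fun <- function(theta) {
      f <- rep(spec$base_intensity, length(theta))
      for (mu in patch_mu) {
        f <- f + spec$base_intensity *
          vm_bump(theta, mu, spec$patch_concentration)
      }
      if (spec$cap_amplitude > 0) {
        f <- f + spec$cap_amplitude *
          vm_bump(theta, spec$cap_angle_deg, spec$cap_concentration)
      }
      f
    }
    xs <- matrix(rep(seq_len(image_size), each = image_size),
                 nrow = image_size)            # column index = x
    ys <- matrix(rep(seq_len(image_size), times = image_size),
                 nrow = image_size)            # row index = y
    dx <- xs - cx
    dy <- ys - cy
    r <- sqrt(dx^2 + dy^2)
    theta <- (atan2(-dy, dx) * 180 / pi) %% 360  # CCW with y pointing down
    img <- profile_fun(theta) * exp(-(r - spec$radius_px)^2 / (2 * sigma_r^2))
    if (spec$noise_sd > 0) {
      img <- img + rnorm(length(img), 0, spec$noise_sd)
    }
    grid <- 0:359
    list(img = matrix(img, nrow = image_size),
         truth = data.frame(angle_deg = grid, intensity = profile_fun(grid)))
  })

  structure(list(image = out$img, truth = out$truth,
                 center = c(x = cx, y = cy), spec = spec,
                 sigma_r = sigma_r),
            class = "ring_simulation")
}

#' Collapse-series specification
#'
#' Time course of a collapsing nucleus: the nuclear envelope (NE) shrinks
#' linearly at `rate_pre` per frame until it contacts the synaptonemal
#' complex (SC) at `contact_frame`, then both shrink at the post-contact
#' rates. The SC is constant before contact. Sizes are equivalent diameters
#' in micrometres. The defaults are chosen so that the NE meets the SC
#' exactly at the contact frame.
#'
#' @param ne_size0,sc_size0 Initial NE and SC sizes (um), `ne_size0 > sc_size0 > 0`.
#' @param contact_frame Frame (1-based) of first NE-SC contact,
#'   strictly inside `(1, n_frames)`.
#' @param rate_pre,rate_post NE size change per frame before/after contact (um).
#' @param rate_post_sc SC size change per frame after contact (um).
#' @param frame_interval_s Seconds between frames.
#' @param n_frames Number of frames.
#' @param noise_sd Gaussian noise SD on sizes (um).
#' @return A list of class `collapse_spec`.
#' @export
collapse_spec <- function(ne_size0 = 3.5, sc_size0 = 1.5, contact_frame = 41,
                          rate_pre = -0.05, rate_post = -0.08,
                          rate_post_sc = -0.08, frame_interval_s = 10,
                          n_frames = 52, noise_sd = 0.07) {
  if (!(ne_size0 > sc_size0 && sc_size0 > 0)) {
    stop("require ne_size0 > sc_size0 > 0")
  }
  if (!(contact_frame > 1 && contact_frame < n_frames)) {
    stop("contact_frame must lie strictly inside (1, n_frames)")
  }
  structure(list(ne_size0 = ne_size0, sc_size0 = sc_size0,
                 contact_frame = contact_frame, rate_pre = rate_pre,
                 rate_post = rate_post, rate_post_sc = rate_post_sc,
                 frame_interval_s = frame_interval_s, n_frames = n_frames,
                 noise_sd = noise_sd),
            class = "collapse_spec")
}

#' Simulate an NE/SC collapse time series
#'
#' @param spec A [collapse_spec()].
#' @param seed Integer seed.
#' @return Data frame with columns `frame`, `time_s`, `ne_size`, `sc_size`
#'   and attribute `contact_frame`. Sizes that would go negative are
#'   clipped at 0 with a warning.
#' @export
simulate_collapse_series <- function(spec, seed = 1) {
  stopifnot(inherits(spec, "collapse_spec"))
  f <- seq_len(spec$n_frames)
  cf <- spec$contact_frame
  ne <- ifelse(f <= cf,
               spec$ne_size0 + spec$rate_pre * (f - 1),
               (spec$ne_size0 + spec$rate_pre * (cf - 1)) +
                 spec$rate_post * (f - cf))
  sc <- ifelse(f <= cf, spec$sc_size0,
               spec$sc_size0 + spec$rate_post_sc * (f - cf))
  # NE encloses the SC until contact
  ne[f <= cf] <- pmax(ne[f <= cf], sc[f <= cf])
  if (any(ne < 0) || any(sc < 0)) {
    warning("collapse rates drive sizes below zero; clipping at 0")
    ne <- pmax(ne, 0)
    sc <- pmax(sc, 0)
  }
  if (spec$noise_sd > 0) {
    noise <- withr::with_seed(seed, rnorm(2 * spec$n_frames, 0, spec$noise_sd))
    ne <- pmax(ne + noise[f], 0)
    sc <- pmax(sc + noise[spec$n_frames + f], 0)
  }
  out <- data.frame(frame = f, time_s = (f - 1) * spec$frame_interval_s,
                    ne_size = ne, sc_size = sc)
  attr(out, "contact_frame") <- cf
  attr(out, "frame_interval_s") <- spec$frame_interval_s
  out
}

#' Gonad layout specification
#'
#' A linear gonad of given length with nuclei placed uniformly along the
#' distal-to-proximal axis, split across animals. Collapse, pairing and
#' synapsis status are drawn per zone from the given probability vectors
#' (zone 1 is the most distal). Stage labels are assigned from the ordered
#' axial `stage_boundaries`.
#'
#' @param gonad_length Axis length (a.u.).
#' @param n_nuclei Total number of nuclei.
#' @param zone_collapse_probs Per-zone collapse probabilities; its length
#'   sets the number of zones.
#' @param zone_paired_probs,zone_synapsed_probs Per-zone probabilities for
#'   X-chromosome pairing and complete synapsis (same length as
#'   `zone_collapse_probs`); defaults emulate progressive pairing/synapsis
#'   along the axis.
#' @param stage_boundaries Ordered axial positions separating stages.
#' @param stage_labels One more label than boundaries.
#' @param n_animals Number of animals the nuclei are split across.
#' @return A list of class `layout_spec`.
#' @export
layout_spec <- function(gonad_length = 60, n_nuclei = 600,
                        zone_collapse_probs = c(0, 0, 0, 0.2, 0.6, 0.9),
                        zone_paired_probs = NULL,
                        zone_synapsed_probs = NULL,
                        stage_boundaries = c(10, 20, 30, 40, 50),
                        stage_labels = c("PM", "TZ", "EP", "MP", "LP", "Dip"),
                        n_animals = 3) {
  nz <- length(zone_collapse_probs)
  ramp <- pmin(1, (seq_len(nz) - 0.5) / (0.6 * nz))
  if (is.null(zone_paired_probs)) zone_paired_probs <- ramp
  if (is.null(zone_synapsed_probs)) zone_synapsed_probs <- ramp
  probs <- c(zone_collapse_probs, zone_paired_probs, zone_synapsed_probs)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (length(zone_paired_probs) != nz || length(zone_synapsed_probs) != nz) {
    stop("zone probability vectors must share one length (the zone count)")
  }
  b <- stage_boundaries
  if (is.unsorted(b, strictly = TRUE) || any(b <= 0) || any(b >= gonad_length)) {
    stop("stage_boundaries must be strictly increasing within (0, gonad_length)")
  }
  if (length(stage_labels) != length(b) + 1) {
    stop("need one more stage label than boundaries")
  }
  structure(list(gonad_length = gonad_length, n_nuclei = n_nuclei,
                 zone_collapse_probs = zone_collapse_probs,
                 zone_paired_probs = zone_paired_probs,
                 zone_synapsed_probs = zone_synapsed_probs,
                 stage_boundaries = b, stage_labels = stage_labels,
                 n_animals = n_animals),
            class = "layout_spec")
}

#' Simulate a gonad layout table
#'
#' @param spec A [layout_spec()].
#' @param seed Integer seed.
#' @return Data frame (class `gonad_layout`) with columns `nucleus_id`,
#'   `animal_id`, `position`, `zone`, `stage`, `collapsed`, `him8_foci`,
#'   `coloc_fraction`; attribute `gonad_length` records the axis length.
#' @export
simulate_gonad_layout <- function(spec, seed = 1) {
  stopifnot(inherits(spec, "layout_spec"))
  nz <- length(spec$zone_collapse_probs)
  out <- withr::with_seed(seed, {
    pos <- runif(spec$n_nuclei, 0, spec$gonad_length)
    zone <- partition_zones(pos, n_zones = nz,
                            gonad_length = spec$gonad_length)
    collapsed <- rbinom(spec$n_nuclei, 1, spec$zone_collapse_probs[zone]) == 1
    paired <- rbinom(spec$n_nuclei, 1, spec$zone_paired_probs[zone]) == 1
    synapsed <- rbinom(spec$n_nuclei, 1, spec$zone_synapsed_probs[zone]) == 1
    him8 <- ifelse(paired, 1L, 2L)
    coloc <- ifelse(synapsed, runif(spec$n_nuclei, 0.96, 1),
                    runif(spec$n_nuclei, 0, 0.9))
    stage <- spec$stage_labels[
      findInterval(pos, spec$stage_boundaries) + 1L]
    data.frame(
      nucleus_id = seq_len(spec$n_nuclei),
      animal_id = rep_len(seq_len(spec$n_animals), spec$n_nuclei),
      position = pos, zone = zone, stage = stage,
      collapsed = collapsed, him8_foci = him8, coloc_fraction = coloc,
      stringsAsFactors = FALSE
    )
  })
  attr(out, "gonad_length") <- spec$gonad_length
  class(out) <- c("gonad_layout", class(out))
  out
}

#' Simulate particle detections for tracking
#'
#' Particles move in 3D under one of three motion models and share a common
#' per-frame stage drift. Detections are returned id-free (and shuffled
#' within each frame); the ground-truth identities are kept separately.
#' For `"random-walk"`, `speed_um_per_frame` is the per-axis step SD.
#'
#' @param n_particles Number of particles.
#' @param motion List with `model` in `"stationary"`, `"directed"`,
#'   `"random-walk"` and `speed_um_per_frame`.
#' @param drift_um_per_frame Length-3 numeric: common drift per frame (um).
#' @param n_frames Number of frames (>= 2).
#' @param frame_interval_s Seconds per frame.
#' @param box_um Side of the cube initial positions are drawn from (um).
#' @param seed Integer seed.
#' @return List of class `track_simulation`: `detections` (data frame
#'   `frame`, `x_um`, `y_um`, `z_um`), `truth` (the same rows with a
#'   `particle` column), `frame_interval_s`, `drift_um_per_frame`.
#' @export
simulate_tracks <- function(n_particles,
                            motion = list(model = "stationary",
                                          speed_um_per_frame = 0),
                            drift_um_per_frame = c(0, 0, 0),
                            n_frames = 10, frame_interval_s = 5,
                            box_um = 20, seed = 1) {
  if (n_frames < 2) stop("need at least 2 frames")
  model <- match.arg(motion$model, c("stationary", "directed", "random-walk"))
  speed <- if (is.null(motion$speed_um_per_frame)) 0 else motion$speed_um_per_frame
  drift <- rep_len(as.numeric(drift_um_per_frame), 3)

  truth <- withr::with_seed(seed, {
    p0 <- matrix(runif(3 * n_particles, 0, box_um), ncol = 3)
    pos <- array(0, dim = c(n_frames, n_particles, 3))
    pos[1, , ] <- p0
    dir <- NULL
    if (model == "directed") {
      dir <- matrix(rnorm(3 * n_particles), ncol = 3)
      dir <- dir / sqrt(rowSums(dir^2))
    }
    for (f in 2:n_frames) {
      step <- switch(model,
        stationary = matrix(0, n_particles, 3),
        directed = speed * dir,
        `random-walk` = matrix(rnorm(3 * n_particles, 0, speed),
                               ncol = 3))
      pos[f, , ] <- pos[f - 1, , ] + step
    }
    rows <- lapply(seq_len(n_frames), function(f) {
      data.frame(frame = f, particle = seq_len(n_particles),
                 x_um = pos[f, , 1] + drift[1] * (f - 1),
                 y_um = pos[f, , 2] + drift[2] * (f - 1),
                 z_um = pos[f, , 3] + drift[3] * (f - 1))
    })
    tr <- do.call(rbind, rows)
    # shuffle within frames so linking cannot rely on row order
    ord <- unlist(lapply(split(seq_len(nrow(tr)), tr$frame),
                         function(ix) ix[sample.int(length(ix))]),
                  use.names = FALSE)
    tr[ord, , drop = FALSE]
  })
  rownames(truth) <- NULL
  detections <- truth[, c("frame", "x_um", "y_um", "z_um")]
  structure(list(detections = detections, truth = truth,
                 frame_interval_s = frame_interval_s,
                 drift_um_per_frame = drift),
            class = "track_simulation")
}
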