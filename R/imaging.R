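#' Bilinear interpolation into an image
#'
#' @param image Numeric matrix, rows = y, columns = x.
#' @param x,y Sample coordinates (1-based pixel centres); vectorized.
#' @return Interpolated intensities; samples outside the image error.
#' @keywords internal
bilinear_sample <- function(image, x, y) {
  nr <- nrow(image)
  nc <- ncol(image)
  if (any(x < 1 | x > nc | y < 1 | y > nr)) {
    stop("sample coordinates fall outside the image")
  }
  x0 <- pmin(floor(x), nc - 1)
  y0 <- pmin(floor(y), nr - 1)
  fx <- x - x0
  fy <- y - y0
  i00 <- image[cbind(y0, x0)]
  i01 <- image[cbind(y0, x0 + 1)]
  i10 <- image[cbind(y0 + 1, x0)]
  i11 <- image[cbind(y0 + 1, x0 + 1)]
  (1 - fy) * ((1 - fx) * i00 + fx * i01) + fy * ((1 - fx) * i10 + fx * i11)
}

# intensity mode via a 256-bin histogram (background estimator)
intensity_mode <- function(x) {
  if (diff(range(x)) == 0) return(x[1])
  h <- graphics::hist(x, breaks = 256, plot = FALSE)
  h$mids[which.max(h$counts)]
}

#' Ring profile container
#'
#' Angularly sampled nuclear-envelope intensity on a uniform grid in
#' [0, 360).
#'
#' @param angle_deg Angles (degrees), uniform grid starting at 0.
#' @param intensity Intensities (a.u., >= 0), same length.
#' @param nucleus_id,stage Optional identifiers (stage is typically one of
#'   TZ, MP, LP, Dip).
#' @return Object of class `ring_profile`.
#' @export
ring_profile <- function(angle_deg, intensity, nucleus_id = NA, stage = NA) {
  if (length(angle_deg) != length(intensity)) stop("length mismatch")
  step <- diff(angle_deg)
  if (length(step) > 0 && (any(abs(step - step[1]) > 1e-9) || angle_deg[1] != 0)) {
    stop("angles must form a uniform grid starting at 0")
  }
  structure(list(angle_deg = angle_deg, intensity = intensity,
                 nucleus_id = nucleus_id, stage = stage),
            class = "ring_profile")
}

#' Fit a ring centre by maximizing mean ring intensity
#'
#' Small exhaustive grid search around an initial guess; stands in for the
#' manual periphery tracing of an interactive tool.
#'
#' @param image Numeric matrix.
#' @param center Initial centre `c(x, y)` (px).
#' @param radius Ring radius (px).
#' @param search Half-width of the search grid (px).
#' @param step Grid step (px).
#' @return Refined centre `c(x, y)`.
#' @export
fit_ring_center <- function(image, center, radius, search = 3, step = 0.5) {
  offs <- seq(-search, search, by = step)
  ang <- seq(0, 358, by = 2)
  best <- center
  best_val <- -Inf
  for (ox in offs) for (oy in offs) {
    cx <- center[1] + ox
    cy <- center[2] + oy
    x <- cx + radius * cos(ang * pi / 180)
    y <- cy - radius * sin(ang * pi / 180)
    if (any(x < 1 | x > ncol(image) | y < 1 | y > nrow(image))) next
    v <- mean(bilinear_sample(image, x, y))
    if (v > best_val) {
      best_val <- v
      best <- c(cx, cy)
    }
  }
  best
}

#' Sample an angular intensity profile around a ring
#'
#' At each angle the intensity is the mean of bilinear samples taken across
#' `ring_width` radially (centred on `radius`). The image background (its
#' intensity mode) is subtracted and the profile floored at 0. Angles are
#' counterclockwise from the +x axis with y pointing down (image
#' convention), matching [simulate_ring_image()].
#'
#' @param image Numeric matrix (rows = y).
#' @param center Ring centre `c(x, y)` in 1-based pixel coordinates.
#' @param radius Ring radius (px).
#' @param ring_width Radial averaging width (px).
#' @param angular_step Angular grid step (degrees; must divide 360).
#' @param n_radial Radial samples per angle.
#' @param background Background level; defaults to the image mode.
#' @param nucleus_id,stage Passed to the [ring_profile()].
#' @return A [ring_profile()].
#' @export
sample_ring_profile <- function(image, center, radius, ring_width,
                                angular_step = 1, n_radial = 7,
                                background = NULL, nucleus_id = NA,
                                stage = NA) {
  if (center[1] < 1 || center[1] > ncol(image) ||
      center[2] < 1 || center[2] > nrow(image)) {
    stop("ring centre lies outside the image")
  }
  if (360 %% angular_step != 0) stop("angular_step must divide 360")
  if (is.null(background)) background <- intensity_mode(image)
  angles <- seq(0, 360 - angular_step, by = angular_step)
  radii <- radius + seq(-ring_width / 2, ring_width / 2, length.out = n_radial)
  th <- angles * pi / 180
  vals <- vapply(th, function(t) {
    x <- center[1] + radii * cos(t)
    y <- center[2] - radii * sin(t)
    mean(bilinear_sample(image, x, y))
  }, numeric(1))
  ring_profile(angles, pmax(vals - background, 0),
               nucleus_id = nucleus_id, stage = stage)
}

#' Clustering index of a peripheral intensity profile
#'
#' Ratio of the sample standard deviation to the mean of the intensity
#' around the nuclear periphery. High values indicate patchy (clustered)
#' LINC-complex distribution; a uniform ring scores 0. Invariant to
#' intensity scaling and to circular rotation of the profile.
#'
#' @param profile A [ring_profile()] or numeric intensity vector.
#' @return Dimensionless coefficient of variation.
#' @export
clustering_index <- function(profile) {
  x <- if (inherits(profile, "ring_profile")) profile$intensity else profile
  m <- mean(x)
  if (m <= 0) stop("mean intensity must be positive")
  sd(x) / m
}

#' Per-nucleus mean ring intensity normalized to a reference stage
#'
#' Each nucleus's mean peripheral intensity is divided by the mean over the
#' nuclei of the reference stage (transition zone by default).
#'
#' @param profiles List of [ring_profile()]s carrying `stage` (and
#'   optionally `nucleus_id`), or a data frame with columns `nucleus_id`,
#'   `stage`, `mean_intensity`.
#' @param reference_stage Stage label used as the unit (default `"TZ"`).
#' @return Data frame `nucleus_id`, `stage`, `mean_intensity`, `normalized`.
#' @export
normalized_mean_intensity <- function(profiles, reference_stage = "TZ") {
  if (is.data.frame(profiles)) {
    df <- profiles
  } else {
    df <- do.call(rbind, lapply(seq_along(profiles), function(i) {
      p <- profiles[[i]]
      data.frame(nucleus_id = if (is.na(p$nucleus_id)) i else p$nucleus_id,
                 stage = p$stage, mean_intensity = mean(p$intensity),
                 stringsAsFactors = FALSE)
    }))
  }
  ref <- df$mean_intensity[df$stage == reference_stage]
  if (length(ref) == 0) stop("reference stage '", reference_stage,
                             "' has no nuclei")
  df$normalized <- df$mean_intensity / mean(ref)
  df
}

#' Rotate and normalize an angular profile into a polarization profile
#'
#' The brightest point (argmax of the profile after a 5-degree circular
#' moving average; ties broken toward the smallest angle) is rotated to
#' 180 degrees and the raw rotated profile is divided by its value at 0
#' degrees, which therefore equals 1 exactly. With `fold = TRUE`,
#' intensities at `theta` and `360 - theta` are averaged onto [0, 180]
#' (the distribution is symmetric about the peak).
#'
#' @param profile A [ring_profile()] or numeric intensity vector on a
#'   uniform grid over [0, 360) whose step divides 180.
#' @param fold Fold the profile about 180 degrees.
#' @return Object of class `polarization_profile`: `angle_deg`,
#'   `intensity` (normalized), `folded`, `shift_deg` (rotation applied).
#' @export
polarization_profile <- function(profile, fold = FALSE) {
  if (inherits(profile, "ring_profile")) {
    angles <- profile$angle_deg
    x <- profile$intensity
  } else {
    x <- profile
    angles <- seq(0, 360 - 360 / length(x), length.out = length(x))
  }
  n <- length(x)
  step <- 360 / n
  if (180 %% step != 0) stop("grid step must divide 180")
  if (all(x == 0)) stop("all-zero profile cannot be normalized")

  k <- round(5 / step)
  if (k %% 2 == 0) k <- k + 1
  sm <- if (k >= 3) {
    half <- (k - 1) / 2
    xx <- c(tail(x, half), x, head(x, half))
    cs <- cumsum(xx)
    (cs[k:length(xx)] - c(0, cs[seq_len(length(xx) - k)])) / k
  } else x

  idx_max <- which.max(sm)              # first max = smallest angle
  idx_180 <- 180 / step + 1
  shift <- (idx_180 - idx_max) %% n
  rotated <- x[((seq_len(n) - 1 - shift) %% n) + 1]
  if (rotated[1] <= 0) {
    stop("intensity at the post-rotation 0-degree position is not positive")
  }
  normalized <- rotated / rotated[1]

  if (fold) {
    half_n <- 180 / step
    ang_f <- seq(0, 180, by = step)
    mirror <- c(1, n + 1 - seq_len(half_n))   # indices of 360 - theta
    folded <- (normalized[seq_len(half_n + 1)] + normalized[mirror]) / 2
    out <- list(angle_deg = ang_f, intensity = folded, folded = TRUE,
                shift_deg = shift * step)
  } else {
    out <- list(angle_deg = angles, intensity = normalized, folded = FALSE,
                shift_deg = shift * step)
  }
  structure(out, class = "polarization_profile")
}

#' Mean normalized intensity in the peak window
#'
#' Mean of the normalized polarization profile over the closed angular
#' window about the 180-degree peak (170 to 190 degrees by default). For
#' folded profiles the window maps onto [170, 180]. Group comparisons of
#' the resulting per-nucleus statistics are done with [standard_tests()].
#'
#' @param profiles A [polarization_profile()] or list of them.
#' @param window Closed angular window (degrees).
#' @return Numeric vector, one mean per profile.
#' @export
peak_region_stat <- function(profiles, window = c(170, 190)) {
  if (inherits(profiles, "polarization_profile")) profiles <- list(profiles)
  vapply(profiles, function(p) {
    w <- window
    if (p$folded) w <- c(min(window[1], 360 - window[2]), 180)
    sel <- p$angle_deg >= w[1] & p$angle_deg <= w[2]
    if (!any(sel)) stop("angular grid does not cover the requested window")
    mean(p$intensity[sel])
  }, numeric(1))
}

# cumulative drift offset at each frame
drift_offsets <- function(reference_drift, frames) {
  if (is.null(reference_drift)) {
    return(matrix(0, length(frames), 3))
  }
  if (is.numeric(reference_drift) && length(reference_drift) == 3) {
    return(outer(frames - 1, reference_drift))
  }
  if (is.data.frame(reference_drift)) {
    m <- as.matrix(reference_drift[match(frames, reference_drift$frame),
                                   c("x_um", "y_um", "z_um")])
    m[is.na(m)] <- 0
    return(m)
  }
  stop("reference_drift must be NULL, a length-3 numeric (per-frame drift) ",
       "or a data frame (frame, x_um, y_um, z_um) of cumulative offsets")
}

#' Link detections into tracks (greedy nearest neighbour)
#'
#' Frame-to-frame linking: after subtracting the reference drift, pairs of
#' (open track head, next-frame detection) are linked greedily in order of
#' increasing distance while the distance stays below `max_displacement`.
#' Unmatched detections start new tracks; tracks not extended within
#' `max_gap` frames are closed.
#'
#' @param detections Data frame `frame`, `x_um`, `y_um`, `z_um` (z optional).
#' @param max_displacement Maximum link distance (um).
#' @param reference_drift `NULL`, a length-3 per-frame drift (um/frame), or
#'   a data frame `frame`, `x_um`, `y_um`, `z_um` of cumulative offsets to
#'   subtract.
#' @param frame_interval_s Seconds per frame, stored on each track.
#' @param max_gap Frames a track may skip and still be extended (default 0).
#' @return List of `track` objects: `id`, `positions` (drift-corrected data
#'   frame `frame`, `x_um`, `y_um`, `z_um`), `frame_interval_s`.
#' @export
link_tracks <- function(detections, max_displacement,
                        reference_drift = NULL, frame_interval_s = 1,
                        max_gap = 0) {
  det <- as.data.frame(detections)
  if (is.null(det$z_um)) det$z_um <- 0
  frames <- sort(unique(det$frame))
  if (length(frames) < 2) stop("need detections in at least 2 frames")
  offs <- drift_offsets(reference_drift, frames)
  pos <- as.matrix(det[, c("x_um", "y_um", "z_um")])
  pos <- pos - offs[match(det$frame, frames), , drop = FALSE]

  tracks <- list()   # each: list(rows, last_frame)
  open <- integer(0) # indices into tracks
  for (fi in seq_along(frames)) {
    f <- frames[fi]
    rows_f <- which(det$frame == f)
    if (fi == 1) {
      for (r in rows_f) {
        tracks[[length(tracks) + 1]] <- list(rows = r, last_frame = f)
      }
      open <- seq_along(tracks)
      next
    }
    open <- open[vapply(tracks[open], function(t) f - t$last_frame <= max_gap + 1,
                        logical(1))]
    matched_det <- logical(length(rows_f))
    if (length(open) > 0 && length(rows_f) > 0) {
      heads <- t(vapply(tracks[open], function(t) pos[tail(t$rows, 1), ],
                        numeric(3)))
      dmat <- sqrt(outer(heads[, 1], pos[rows_f, 1], "-")^2 +
                   outer(heads[, 2], pos[rows_f, 2], "-")^2 +
                   outer(heads[, 3], pos[rows_f, 3], "-")^2)
      repeat {
        m <- which.min(dmat)
        if (length(m) == 0 || dmat[m] > max_displacement) break
        ti <- (m - 1) %% nrow(dmat) + 1
        di <- (m - 1) %/% nrow(dmat) + 1
        tr <- open[ti]
        tracks[[tr]]$rows <- c(tracks[[tr]]$rows, rows_f[di])
        tracks[[tr]]$last_frame <- f
        matched_det[di] <- TRUE
        dmat[ti, ] <- Inf
        dmat[, di] <- Inf
        if (all(!is.finite(dmat))) break
      }
    }
    for (di in which(!matched_det)) {
      tracks[[length(tracks) + 1]] <- list(rows = rows_f[di], last_frame = f)
      open <- c(open, length(tracks))
    }
  }

  lapply(seq_along(tracks), function(i) {
    r <- tracks[[i]]$rows
    structure(list(id = i,
                   positions = data.frame(frame = det$frame[r],
                                          x_um = pos[r, 1],
                                          y_um = pos[r, 2],
                                          z_um = pos[r, 3]),
                   frame_interval_s = frame_interval_s),
              class = "track")
  })
}

#' Mean speed of a track
#'
#' Mean over consecutive linked positions of the 3D displacement divided by
#' the elapsed time. Singleton tracks have no displacement and return `NA`.
#'
#' @param track A `track` from [link_tracks()], or a data frame `frame`,
#'   `x_um`, `y_um`, `z_um`.
#' @param frame_interval_s Seconds per frame; taken from the track if absent.
#' @return Mean speed (um/s), or `NA` for singleton tracks.
#' @export
track_mean_speed <- function(track, frame_interval_s = NULL) {
  if (inherits(track, "track")) {
    if (is.null(frame_interval_s)) frame_interval_s <- track$frame_interval_s
    p <- track$positions
  } else {
    p <- as.data.frame(track)
    if (is.null(frame_interval_s)) stop("frame_interval_s required")
  }
  if (nrow(p) < 2) return(NA_real_)
  if (is.null(p$z_um)) p$z_um <- 0
  dp <- sqrt(diff(p$x_um)^2 + diff(p$y_um)^2 + diff(p$z_um)^2)
  dt <- diff(p$frame) * frame_interval_s
  mean(dp / dt)
}

# global Otsu threshold (between-class variance maximization, 256 bins)
otsu_threshold <- function(x, n_bins = 256) {
  rng <- range(x)
  if (diff(rng) == 0) return(rng[1])
  br <- seq(rng[1], rng[2], length.out = n_bins + 1)
  h <- tabulate(findInterval(x, br, rightmost.closed = TRUE), nbins = n_bins)
  p <- h / sum(h)
  mids <- (br[-1] + br[-length(br)]) / 2
  w0 <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[n_bins]
  between <- (mu_t * w0 - mu)^2 / (w0 * (1 - w0))
  between[!is.finite(between)] <- 0
  br[which.max(between) + 1]
}

# 6-connected component labelling of a 3D logical array
label_components_3d <- function(mask) {
  dims <- dim(mask)
  nx <- dims[1]; ny <- dims[2]; nz <- dims[3]
  labels <- integer(length(mask))
  fg <- which(mask)
  in_fg <- logical(length(mask))
  in_fg[fg] <- TRUE
  next_label <- 0L
  for (seed in fg) {
    if (labels[seed] != 0L) next
    next_label <- next_label + 1L
    frontier <- seed
    labels[seed] <- next_label
    while (length(frontier) > 0) {
      i <- ((frontier - 1L) %% nx) + 1L
      j <- (((frontier - 1L) %/% nx) %% ny) + 1L
      k <- ((frontier - 1L) %/% (nx * ny)) + 1L
      nb <- c(frontier[i > 1] - 1L, frontier[i < nx] + 1L,
              frontier[j > 1] - nx, frontier[j < ny] + nx,
              frontier[k > 1] - nx * ny, frontier[k < nz] + nx * ny)
      nb <- unique(nb[in_fg[nb] & labels[nb] == 0L])
      labels[nb] <- next_label
      frontier <- nb
    }
  }
  array(labels, dim = dims)
}

#' Segment nuclei in a 3D stack and measure volumes
#'
#' Global threshold (Otsu on the full stack by default, or a fixed value),
#' 6-connected 3D component labelling, and per-component volume as voxel
#' count times voxel volume. Components touching the stack boundary are
#' flagged (their volume is truncated).
#'
#' @param stack 3D numeric array (x, y, z) or a matrix (treated as one
#'   slice).
#' @param threshold_method `"otsu"` or `"fixed"`.
#' @param voxel_size_um Length-3 voxel edge lengths (um).
#' @param threshold Threshold value when `threshold_method = "fixed"`.
#' @return Data frame `component`, `n_voxels`, `volume_um3`,
#'   `touches_boundary`; zero rows if nothing is above threshold.
#' @export
segment_nucleus_volume <- function(stack, threshold_method = c("otsu", "fixed"),
                                   voxel_size_um = c(1, 1, 1),
                                   threshold = NULL) {
  threshold_method <- match.arg(threshold_method)
  if (is.matrix(stack)) stack <- array(stack, dim = c(dim(stack), 1))
  thr <- if (threshold_method == "fixed") {
    if (is.null(threshold)) stop("threshold required for method 'fixed'")
    threshold
  } else {
    otsu_threshold(as.vector(stack))
  }
  mask <- stack > thr
  if (!any(mask)) {
    return(data.frame(component = integer(0), n_voxels = integer(0),
                      volume_um3 = numeric(0), touches_boundary = logical(0)))
  }
  labels <- label_components_3d(mask)
  dims <- dim(labels)
  ids <- sort(unique(labels[labels > 0]))
  vox_vol <- prod(voxel_size_um)
  boundary <- array(FALSE, dims)
  boundary[c(1, dims[1]), , ] <- TRUE
  boundary[, c(1, dims[2]), ] <- TRUE
  if (dims[3] > 1) boundary[, , c(1, dims[3])] <- TRUE
  do.call(rbind, lapply(ids, function(id) {
    sel <- labels == id
    data.frame(component = id, n_voxels = sum(sel),
               volume_um3 = sum(sel) * vox_vol,
               touches_boundary = any(sel & boundary))
  }))
}

#' Align an NE/SC collapse time course at the contact point
#'
#' The contact frame is the first frame at which the NE size exceeds the SC
#' size by no more than `contact_tol`; alternatively a known contact frame
#' (e.g. identified from the images, as in time-lapse annotation) may be
#' supplied directly. Both series are divided by their final-frame values
#' (final frame = 1 exactly) and time is re-indexed relative to contact.
#'
#' @param ne_series,sc_series Numeric size series (um), equal length, >= 4
#'   frames. Alternatively `ne_series` may be a data frame with columns
#'   `ne_size`, `sc_size` (and optionally `frame`, `time_s`), e.g. from
#'   [simulate_collapse_series()].
#' @param contact_tol Contact tolerance (um).
#' @param frame_interval_s Seconds per frame (used when no `time_s` column
#'   is supplied).
#' @param contact_frame Optional known contact frame (1-based); when given,
#'   threshold detection is skipped.
#' @return Data frame of class `collapse_series`: `frame`, `time_rel_s`,
#'   `ne_size`, `sc_size`, `ne_norm`, `sc_norm`; attributes
#'   `contact_frame`, `frame_interval_s`.
#' @export
align_collapse_series <- function(ne_series, sc_series = NULL,
                                  contact_tol = 0.1, frame_interval_s = 1,
                                  contact_frame = NULL) {
  if (is.data.frame(ne_series)) {
    df <- ne_series
    ne <- df$ne_size
    sc <- df$sc_size
    if (!is.null(df$time_s) && nrow(df) > 1) {
      frame_interval_s <- df$time_s[2] - df$time_s[1]
    }
  } else {
    ne <- ne_series
    sc <- sc_series
  }
  n <- length(ne)
  if (is.null(sc) || length(sc) != n) stop("NE and SC series must have equal length")
  if (n < 4) stop("need at least 4 frames")
  if (!is.null(contact_frame)) {
    cf <- as.integer(contact_frame)
    if (cf < 1 || cf > n) stop("contact_frame outside the series")
  } else {
    contact <- which(ne - sc <= contact_tol)
    if (length(contact) == 0) {
      stop("no NE-SC contact found: min(ne - sc) = ",
           signif(min(ne - sc), 4), " exceeds contact_tol = ", contact_tol)
    }
    cf <- contact[1]
  }
  if (ne[n] <= 0 || sc[n] <= 0) stop("final-frame sizes must be positive")
  out <- data.frame(frame = seq_len(n),
                    time_rel_s = (seq_len(n) - cf) * frame_interval_s,
                    ne_size = ne, sc_size = sc,
                    ne_norm = ne / ne[n], sc_norm = sc / sc[n])
  attr(out, "contact_frame") <- cf
  attr(out, "frame_interval_s") <- frame_interval_s
  class(out) <- c("collapse_series", "data.frame")
  out
}

#' Pre- and post-contact collapse rates
#'
#' Ordinary least-squares slope of the normalized NE size against time,
#' fitted separately before and after contact (the contact frame belongs to
#' both fits). Rates are per second and, for convenience, per frame.
#'
#' @param series A `collapse_series` from [align_collapse_series()].
#' @param min_frames Minimum frames per side (default 2); a side with fewer
#'   frames gets `NA`.
#' @return One-row data frame: `rate_pre`, `rate_post` (normalized size per
#'   second), `rate_pre_per_frame`, `rate_post_per_frame`, `n_pre`, `n_post`.
#' @export
collapse_rates <- function(series, min_frames = 2) {
  stopifnot(inherits(series, "collapse_series"))
  cf <- attr(series, "contact_frame")
  dt <- attr(series, "frame_interval_s")
  fit_side <- function(sel) {
    if (sum(sel) < min_frames) return(NA_real_)
    unname(coef(lm(ne_norm ~ time_rel_s, data = series[sel, ]))[2])
  }
  pre <- fit_side(series$frame <= cf)
  post <- fit_side(series$frame >= cf)
  data.frame(rate_pre = pre, rate_post = post,
             rate_pre_per_frame = pre * dt, rate_post_per_frame = post * dt,
             n_pre = sum(series$frame <= cf), n_post = sum(series$frame >= cf))
}
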