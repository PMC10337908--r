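#' Smooth and down-sample a current trace
#'
#' Rectangular (boxcar) moving average followed by decimation, mirroring
#' the standard first step of node-pore-sensing software. The average is
#' taken over windows fully inside the trace (`n - window + 1` output
#' samples before decimation), then every `downsample_factor`-th sample is
#' kept starting at the first. The baseline is re-estimated afterwards.
#'
#' @param trace A [current_trace()].
#' @param window_samples Boxcar window length (samples, >= 1).
#' @param downsample_factor Decimation stride (>= 1).
#' @return A [current_trace()] with updated sampling rate and baseline.
#' @export
preprocess_trace <- function(trace, window_samples = 5, downsample_factor = 1) {
  stopifnot(inherits(trace, "current_trace"))
  w <- as.integer(window_samples)
  f <- as.integer(downsample_factor)
  if (w < 1 || f < 1) stop("window and factor must be >= 1")
  x <- trace$current_na
  n <- length(x)
  if (w > n) stop("smoothing window longer than trace")
  if (w == 1) {
    sm <- x
    tm <- trace$time_s
  } else {
    cs <- cumsum(x)
    sm <- (cs[w:n] - c(0, cs[seq_len(n - w)])) / w
    tm <- trace$time_s[seq_len(n - w + 1)] + (w - 1) / (2 * trace$sampling_rate_hz)
  }
  keep <- seq(1, length(sm), by = f)
  out <- current_trace(time_s = tm[keep], current_na = sm[keep],
                       sampling_rate_hz = trace$sampling_rate_hz / f)
  out$baseline_na <- estimate_baseline(out$current_na)
  out
}

#' Detect transit events in a current trace
#'
#' Finds contiguous runs of samples below `baseline - threshold_k *
#' noise_sd` (noise SD from the median absolute deviation of the trace,
#' which is robust to the pulses themselves). Runs separated by a recovery
#' shorter than `gap_factor` times the preceding run (the node crossing)
#' are merged into one event. Within each event the first run is the sizing
#' sub-pulse and the last is the contraction sub-pulse; `delta_i_s` is the
#' baseline minus the mean over the central 50% of the sizing run, and the
#' transit times are the run durations.
#'
#' Events truncated by the trace edges are dropped with a warning;
#' single-run events (no contraction sub-pulse) are returned flagged with
#' `ok = FALSE`.
#'
#' @param trace A [current_trace()]; the baseline is estimated if missing.
#' @param threshold_k Detection threshold in noise SDs (default 5).
#' @param gap_factor Maximum within-event recovery, as a fraction of the
#'   preceding sub-pulse duration (default 0.5; the node is much shorter
#'   than either flanking segment, while separate transits are spaced
#'   farther apart).
#' @return Data frame of class `pulse_events`, one row per event:
#'   `event`, `start_idx`, `end_idx`, `delta_i_s_na`, `delta_i_c_na`,
#'   `t_s_s`, `t_c_s`, `n_subpulses`, `ok`. Attributes carry the baseline
#'   and noise SD used.
#' @export
detect_events <- function(trace, threshold_k = 5, gap_factor = 0.5) {
  stopifnot(inherits(trace, "current_trace"))
  x <- trace$current_na
  fs <- trace$sampling_rate_hz
  baseline <- trace$baseline_na
  if (!is.finite(baseline)) baseline <- estimate_baseline(x)
  noise_sd <- mad(x)
  thr <- baseline - threshold_k * noise_sd

  below <- x < thr
  r <- rle(below)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  runs <- data.frame(start = starts[r$values], end = ends[r$values])
  empty <- data.frame(event = integer(0), start_idx = integer(0),
                      end_idx = integer(0), delta_i_s_na = numeric(0),
                      delta_i_c_na = numeric(0), t_s_s = numeric(0),
                      t_c_s = numeric(0), n_subpulses = integer(0),
                      ok = logical(0))
  if (nrow(runs) == 0) {
    return(structure(empty, class = c("pulse_events", "data.frame"),
                     baseline_na = baseline, noise_sd_na = noise_sd))
  }

  # merge runs whose gap is short relative to the preceding run (node)
  grp <- integer(nrow(runs))
  grp[1] <- 1L
  if (nrow(runs) > 1) {
    for (i in 2:nrow(runs)) {
      gap <- runs$start[i] - runs$end[i - 1] - 1
      prev_len <- runs$end[i - 1] - runs$start[i - 1] + 1
      grp[i] <- if (gap <= gap_factor * prev_len) grp[i - 1] else grp[i - 1] + 1L
    }
  }

  plateau_mean <- function(i0, i1) {
    len <- i1 - i0 + 1
    lo <- i0 + floor(len / 4)
    hi <- i1 - floor(len / 4)
    mean(x[lo:hi])
  }

  n_dropped <- 0L
  rows <- lapply(split(seq_len(nrow(runs)), grp), function(ix) {
    s <- runs$start[ix]
    e <- runs$end[ix]
    if (min(s) == 1 || max(e) == length(x)) {
      n_dropped <<- n_dropped + 1L
      return(NULL)
    }
    k <- length(ix)
    siz <- c(s[1], e[1])
    con <- c(s[k], e[k])
    data.frame(
      start_idx = min(s), end_idx = max(e),
      delta_i_s_na = baseline - plateau_mean(siz[1], siz[2]),
      delta_i_c_na = if (k >= 2) baseline - plateau_mean(con[1], con[2]) else NA_real_,
      t_s_s = (siz[2] - siz[1] + 1) / fs,
      t_c_s = if (k >= 2) (con[2] - con[1] + 1) / fs else NA_real_,
      n_subpulses = k,
      ok = k >= 2
    )
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (n_dropped > 0) {
    warning(sprintf("%d event(s) truncated by the trace edge were dropped",
                    n_dropped))
  }
  ev <- if (length(rows) > 0) do.call(rbind, rows) else empty[-1]
  if (nrow(ev) > 0) {
    ev <- cbind(event = seq_len(nrow(ev)), ev)
    rownames(ev) <- NULL
    if (any(!ev$ok)) {
      warning(sprintf("%d event(s) lacked a contraction sub-pulse (flagged ok = FALSE)",
                      sum(!ev$ok)))
    }
  } else {
    ev <- empty
  }
  structure(ev, class = c("pulse_events", "data.frame"),
            baseline_na = baseline, noise_sd_na = noise_sd)
}

#' Invert the sizing relation: current drop to particle diameter
#'
#' Solves `delta_i / baseline = calibration * d^3 / (D_e^2 L_s) /
#' (1 - 0.8 (d/D_e)^3)` for `d` by bracketed root finding on the strictly
#' monotone forward relation (tolerance 1e-9 um).
#'
#' @param delta_i_na Sizing-pulse depth(s), nA (> 0); vectorized.
#' @param baseline_na Baseline current (nA).
#' @param geometry A [channel_geometry()].
#' @param calibration_constant Multiplicative constant from
#'   [calibrate_with_beads()] (default 1).
#' @return Diameter(s) in um.
#' @export
size_from_pulse <- function(delta_i_na, baseline_na, geometry,
                            calibration_constant = 1) {
  stopifnot(inherits(geometry, "channel_geometry"))
  if (any(delta_i_na <= 0)) stop("delta_i must be > 0")
  de <- effective_diameter(geometry$sizing_width_um, geometry$height_um)
  d_max <- min(geometry$sizing_width_um, de * 0.8^(-1 / 3) * (1 - 1e-9))
  vapply(delta_i_na, function(di) {
    target <- di / baseline_na
    fn <- function(d) {
      relative_blockade(d, geometry$sizing_width_um, geometry$height_um,
                        geometry$sizing_length_um, calibration_constant) - target
    }
    if (fn(d_max) < 0) {
      stop("delta_i too large: no diameter below the sizing width ",
           "reproduces it (delta_i/baseline = ", signif(target, 4), ")")
    }
    uniroot(fn, c(1e-6, d_max), tol = 1e-9)$root
  }, numeric(1))
}

#' Applied strain in the contraction segment
#'
#' `strain = (d_n - w_c) / d_n` for a nucleus of diameter `d_n` in a
#' contraction channel of width `w_c`; nuclei no larger than the channel
#' are not deformed and get strain 0.
#'
#' @param d_n_um Nuclear diameter(s), um (> 0); vectorized.
#' @param geometry A [channel_geometry()].
#' @return Strain value(s) in [0, 1).
#' @export
applied_strain <- function(d_n_um, geometry) {
  if (any(d_n_um <= 0)) stop("diameter must be > 0")
  wc <- geometry$contraction_width_um
  ifelse(d_n_um > wc, (d_n_um - wc) / d_n_um, 0)
}

#' Calibrate the sizing relation with beads of known diameter
#'
#' Finds the multiplicative constant for the sizing relation such that the
#' mean diameter recovered from the bead events equals the certified bead
#' diameter. A warning is raised if the bead pulse depths scatter by more
#' than 20% of their mean (suspect calibration run).
#'
#' @param bead_events A `pulse_events` data frame (or any data frame with
#'   `delta_i_s_na`), >= 5 events.
#' @param true_diameter_um Certified bead diameter (um).
#' @param geometry A [channel_geometry()].
#' @param baseline_na Baseline current (nA); taken from the events'
#'   attribute when omitted.
#' @return Calibration constant (dimensionless, ~1 for a well-modelled
#'   device), to pass to [size_from_pulse()].
#' @export
calibrate_with_beads <- function(bead_events, true_diameter_um, geometry,
                                 baseline_na = NULL) {
  di <- bead_events$delta_i_s_na
  if (!is.null(bead_events$ok)) di <- di[bead_events$ok]
  di <- di[is.finite(di) & di > 0]
  if (length(di) < 5) stop("need at least 5 bead events to calibrate")
  if (is.null(baseline_na)) baseline_na <- attr(bead_events, "baseline_na")
  if (is.null(baseline_na) || !is.finite(baseline_na)) {
    stop("baseline_na required (not carried by the supplied events)")
  }
  if (sd(di) / mean(di) > 0.2) {
    warning("bead pulse depths scatter by > 20% of their mean; ",
            "calibration may be unreliable")
  }
  fn <- function(log_c) {
    mean(size_from_pulse(di, baseline_na, geometry, exp(log_c))) -
      true_diameter_um
  }
  # the small-particle limit d ~ (dI / c)^(1/3) gives a starting constant;
  # the recovered diameter decreases monotonically as the constant grows
  c0 <- mean(di) / baseline_na /
    relative_blockade(true_diameter_um, geometry$sizing_width_um,
                      geometry$height_um, geometry$sizing_length_um)
  exp(uniroot(fn, log(c0) + c(-log(4), log(4)), tol = 1e-12,
              extendInt = "downX")$root)
}

#' Default whole-cell deformability index formula
#'
#' `wCDI = (L_c * h * t_s) / (d_n^2 * t_c)`: a dimensionless,
#' size-normalized inverse contraction transit time. Larger values mean
#' softer objects (the index is inversely related to the Young's modulus).
#' The formula is a pluggable strategy in [compute_wcdi()]; every analysis
#' in this package binds only to its monotonicity (decreasing in `t_c`,
#' normalized by size), so an alternative formula with the same contract
#' can be swapped in.
#'
#' @param d_n_um Nuclear diameter (um).
#' @param t_c_s,t_s_s Contraction and sizing transit times (s).
#' @param geometry A [channel_geometry()].
#' @return wCDI value(s).
#' @export
wcdi_default <- function(d_n_um, t_c_s, t_s_s, geometry) {
  (geometry$contraction_length_um * geometry$height_um * t_s_s) /
    (d_n_um^2 * t_c_s)
}

#' Compute the whole-cell deformability index (wCDI)
#'
#' Nuclei whose diameter does not exceed the contraction width are not
#' deformed (strain 0) and are excluded: their wCDI is `NA`.
#'
#' @inheritParams wcdi_default
#' @param formula Function `(d_n_um, t_c_s, t_s_s, geometry) -> wCDI`;
#'   defaults to [wcdi_default()].
#' @return wCDI value(s); `NA` where `d_n <= w_c` or a transit time is
#'   missing.
#' @export
compute_wcdi <- function(d_n_um, t_c_s, t_s_s, geometry,
                         formula = wcdi_default) {
  if (any(stats::na.omit(c(t_c_s, t_s_s)) <= 0)) {
    stop("transit times must be > 0")
  }
  out <- formula(d_n_um, t_c_s, t_s_s, geometry)
  out[!is.na(d_n_um) & d_n_um <= geometry$contraction_width_um] <- NA_real_
  out
}

#' Analyze a full mechano-NPS run
#'
#' Composition of the pipeline: [preprocess_trace()] -> [detect_events()]
#' -> [size_from_pulse()] -> [applied_strain()] -> [compute_wcdi()] ->
#' exclusion filter. A nucleus is `included` when its event has both
#' sub-pulses and its diameter exceeds the contraction width.
#'
#' @param trace A [current_trace()].
#' @param geometry A [channel_geometry()].
#' @param config Optional list overriding `window_samples`,
#'   `downsample_factor`, `threshold_k`, `gap_factor`,
#'   `calibration_constant`, `wcdi_formula`.
#' @return Data frame of class `nucleus_measurements`, one row per detected
#'   event: `event`, `delta_i_s_na`, `t_s_s`, `t_c_s`, `d_n_um`, `strain`,
#'   `wcdi`, `included`; attribute `summary` holds `n_events`,
#'   `n_included`, `mean_strain`, `mean_wcdi`, and the baseline.
#' @export
analyze_run <- function(trace, geometry = default_geometry(), config = list()) {
  cfg <- modifyList(list(window_samples = 5, downsample_factor = 1,
                         threshold_k = 5, gap_factor = 0.5,
                         calibration_constant = 1,
                         wcdi_formula = wcdi_default),
                    config)
  pp <- preprocess_trace(trace, cfg$window_samples, cfg$downsample_factor)
  ev <- detect_events(pp, cfg$threshold_k, cfg$gap_factor)
  baseline <- attr(ev, "baseline_na")

  if (nrow(ev) == 0) {
    out <- data.frame(event = integer(0), delta_i_s_na = numeric(0),
                      t_s_s = numeric(0), t_c_s = numeric(0),
                      d_n_um = numeric(0), strain = numeric(0),
                      wcdi = numeric(0), included = logical(0))
  } else {
    d_n <- rep(NA_real_, nrow(ev))
    valid <- ev$ok & ev$delta_i_s_na > 0
    if (any(valid)) {
      d_n[valid] <- size_from_pulse(ev$delta_i_s_na[valid], baseline,
                                    geometry, cfg$calibration_constant)
    }
    strain <- ifelse(is.na(d_n), NA_real_, applied_strain(pmax(d_n, 1e-9), geometry))
    wcdi <- rep(NA_real_, nrow(ev))
    ok_w <- valid & !is.na(d_n) & !is.na(ev$t_c_s)
    if (any(ok_w)) {
      wcdi[ok_w] <- compute_wcdi(d_n[ok_w], ev$t_c_s[ok_w], ev$t_s_s[ok_w],
                                 geometry, cfg$wcdi_formula)
    }
    included <- valid & !is.na(d_n) & d_n > geometry$contraction_width_um &
      !is.na(wcdi)
    out <- data.frame(event = ev$event, delta_i_s_na = ev$delta_i_s_na,
                      t_s_s = ev$t_s_s, t_c_s = ev$t_c_s, d_n_um = d_n,
                      strain = strain, wcdi = wcdi, included = included)
  }
  attr(out, "summary") <- list(
    n_events = nrow(out),
    n_included = sum(out$included),
    mean_strain = if (any(out$included)) mean(out$strain[out$included]) else NA_real_,
    mean_wcdi = if (any(out$included)) mean(out$wcdi[out$included]) else NA_real_,
    baseline_na = baseline
  )
  class(out) <- c("nucleus_measurements", "data.frame")
  out
}
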