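#' Current trace container
#'
#' A sampled current-vs-time record on a uniform grid, with the sampling
#' rate and (optionally) an estimated baseline attached.
#'
#' @param time_s Time stamps (s), strictly increasing, uniform grid.
#' @param current_na Current samples (nA), same length as `time_s`.
#' @param sampling_rate_hz Sampling rate (Hz); inferred from `time_s` if
#'   missing.
#' @param baseline_na Estimated baseline current (nA), or `NA` if not yet
#'   estimated.
#' @return An object of class `current_trace`.
#' @seealso [estimate_baseline()], [preprocess_trace()], [detect_events()]
#' @export
current_trace <- function(time_s, current_na, sampling_rate_hz = NULL,
                          baseline_na = NA_real_) {
  if (length(time_s) != length(current_na)) {
    stop("time and current must have the same length")
  }
  if (length(time_s) >= 2) {
    dt <- diff(time_s)
    if (any(dt <= 0)) stop("time must be strictly increasing")
    if (is.null(sampling_rate_hz)) sampling_rate_hz <- 1 / median(dt)
  } else if (is.null(sampling_rate_hz)) {
    stop("sampling_rate_hz required for traces shorter than 2 samples")
  }
  if (any(!is.finite(current_na))) stop("current contains non-finite values")
  structure(
    list(time_s = as.numeric(time_s), current_na = as.numeric(current_na),
         sampling_rate_hz = sampling_rate_hz, baseline_na = baseline_na),
    class = "current_trace"
  )
}

#' @export
print.current_trace <- function(x, ...) {
  cat(sprintf("current_trace: %d samples at %.6g Hz (%.3f s)\n",
              length(x$current_na), x$sampling_rate_hz,
              length(x$current_na) / x$sampling_rate_hz))
  if (is.finite(x$baseline_na)) {
    cat(sprintf("  baseline: %.6g nA\n", x$baseline_na))
  }
  invisible(x)
}

#' Estimate the baseline current of a trace
#'
#' Robust baseline for traces in which transit pulses are downward and
#' sparse: the median of all samples in the upper half of the observed
#' current range. Pulses occupy the lower range and are excluded by the
#' range cut; the median then resists the residual noise tail.
#'
#' @param current_na Numeric vector of current samples (nA).
#' @return Baseline estimate (nA).
#' @export
estimate_baseline <- function(current_na) {
  lo <- min(current_na)
  hi <- max(current_na)
  cut <- lo + 0.5 * (hi - lo)
  median(current_na[current_na >= cut])
}
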