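#' Mechano-NPS channel geometry
#'
#' Describes the segmented microfluidic channel: a sizing segment that
#' measures nuclear diameter from the current blockade, a wide node that
#' lets the current recover, and a narrower contraction segment that applies
#' a fixed strain to every nucleus larger than its width. Lengths and widths
#' are in micrometres, the channel height is shared by all segments.
#'
#' `default_geometry()` returns the device used for oocyte nuclei:
#' 9.9-um-high channel; sizing segment 700.4 x 5.9 um (L x W); node
#' 80.4 x 50.4 um; contraction segment 700.4 x 2.9 um; driven at 6 V DC
#' under 7 kPa non-pulsatile pressure.
#'
#' @param height_um Channel height (um), common to all segments.
#' @param sizing_length_um,sizing_width_um Sizing segment length and width (um).
#' @param node_length_um,node_width_um Node length and width (um).
#' @param contraction_length_um,contraction_width_um Contraction segment
#'   length and width (um).
#' @param voltage_v Applied DC voltage (V).
#' @param pressure_kpa Driving pressure (kPa).
#' @return An object of class `channel_geometry` (a named list).
#' @examples
#' geom <- default_geometry()
#' geom$contraction_width_um
#' @export
channel_geometry <- function(height_um,
                             sizing_length_um, sizing_width_um,
                             node_length_um, node_width_um,
                             contraction_length_um, contraction_width_um,
                             voltage_v = NA_real_, pressure_kpa = NA_real_) {
  g <- list(
    height_um = height_um,
    sizing_length_um = sizing_length_um,
    sizing_width_um = sizing_width_um,
    node_length_um = node_length_um,
    node_width_um = node_width_um,
    contraction_length_um = contraction_length_um,
    contraction_width_um = contraction_width_um,
    voltage_v = voltage_v,
    pressure_kpa = pressure_kpa
  )
  dims <- unlist(g[1:7])
  if (any(!is.finite(dims)) || any(dims <= 0)) {
    stop("all channel dimensions must be positive and finite")
  }
  if (g$contraction_width_um >= g$sizing_width_um) {
    stop("contraction width must be smaller than sizing width")
  }
  structure(g, class = "channel_geometry")
}

#' @rdname channel_geometry
#' @export
default_geometry <- function() {
  channel_geometry(
    height_um = 9.9,
    sizing_length_um = 700.4, sizing_width_um = 5.9,
    node_length_um = 80.4, node_width_um = 50.4,
    contraction_length_um = 700.4, contraction_width_um = 2.9,
    voltage_v = 6, pressure_kpa = 7
  )
}

#' @export
print.channel_geometry <- function(x, ...) {
  cat("mechano-NPS channel geometry (um):\n")
  cat(sprintf("  height       %6.2f\n", x$height_um))
  cat(sprintf("  sizing       %6.1f x %4.2f (L x W)\n",
              x$sizing_length_um, x$sizing_width_um))
  cat(sprintf("  node         %6.1f x %4.2f\n",
              x$node_length_um, x$node_width_um))
  cat(sprintf("  contraction  %6.1f x %4.2f\n",
              x$contraction_length_um, x$contraction_width_um))
  if (is.finite(x$voltage_v)) cat(sprintf("  drive: %g V, %g kPa\n",
                                          x$voltage_v, x$pressure_kpa))
  invisible(x)
}

#' Effective diameter of a rectangular channel segment
#'
#' For a rectangular cross-section of width `w` and height `h`, the
#' equivalent circular pore has diameter `D_e = sqrt(4 w h / pi)` (equal
#' cross-sectional area). Used by the sizing relation.
#'
#' @param width_um,height_um Segment width and height (um).
#' @return Effective diameter (um).
#' @export
effective_diameter <- function(width_um, height_um) {
  sqrt(4 * width_um * height_um / pi)
}

#' Relative current blockade of a particle in a channel segment
#'
#' The resistive-pulse (Coulter-type) sizing relation used throughout:
#' `dI/I = d^3 / (D_e^2 * L)` with the large-particle correction factor
#' `1 / (1 - 0.8 (d/D_e)^3)`, where `d` is particle diameter, `D_e` the
#' effective segment diameter and `L` the segment length. Strictly
#' increasing in `d` on its domain. `calibration` multiplies the relation
#' (see [calibrate_with_beads()]).
#'
#' @param d_um Particle diameter (um); vectorized.
#' @param width_um,height_um,length_um Segment dimensions (um).
#' @param calibration Multiplicative calibration constant (default 1).
#' @return Relative blockade dI/I (dimensionless).
#' @export
relative_blockade <- function(d_um, width_um, height_um, length_um,
                              calibration = 1) {
  de <- effective_diameter(width_um, height_um)
  x <- (d_um / de)^3
  corr <- 1 - 0.8 * x
  if (any(corr <= 0)) {
    stop("particle too large for the blockade relation (correction factor <= 0)")
  }
  calibration * d_um^3 / (de^2 * length_um) / corr
}
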