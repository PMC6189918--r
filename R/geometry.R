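# vacuum permittivity, F/m
.eps0 <- 8.8541878128e-12

#' Channel and electrode-array geometry
#'
#' Describes the cross-section of a microfluidic channel of width `L` (y axis)
#' and height `h` (z axis) carrying one planar electrode array on each wall.
#' Each array of `N` electrodes tiles the width with strips of pitch
#' `lambda = L / (2N - 1)`: electrode width equals gap width equals `lambda`,
#' so `N` electrodes and `N - 1` gaps cover `[0, L]` exactly.
#'
#' Two coordinate frames are used by the field model:
#' * single-array frame: `z` in `[0, h]`, electrodes at `z = 0`, grounded
#'   plane at `z = h`;
#' * dual-array frame: `z` in `[-h/2, +h/2]`, arrays at `z = -h/2` (bottom)
#'   and `z = +h/2` (top).
#'
#' All lengths are SI metres.
#'
#' @param width_L Channel width in metres (y extent), positive.
#' @param height_h Channel height in metres (z extent), positive.
#' @param n_bottom Number of electrodes on the bottom wall, at least 2.
#' @param n_top Number of electrodes on the top wall, at least 2. Defaults to
#'   `n_bottom`.
#'
#' @return An object of class `channel_geometry`: a list with elements
#'   `width_L`, `height_h`, `n_top`, `n_bottom`, `pitch_top`, `pitch_bottom`.
#'
#' @examples
#' geo <- channel_geometry(width_L = 150e-6, height_h = 80e-6, n_bottom = 8)
#' geo$pitch_bottom  # 10 micrometres
#' @export
channel_geometry <- function(width_L, height_h, n_bottom, n_top = n_bottom) {
  stopifnot(is.numeric(width_L), length(width_L) == 1L, is.finite(width_L),
            is.numeric(height_h), length(height_h) == 1L, is.finite(height_h))
  if (width_L <= 0 || height_h <= 0)
    stop("channel dimensions must be positive", call. = FALSE)
  n_bottom <- .check_count(n_bottom, "n_bottom")
  n_top <- .check_count(n_top, "n_top")
  if (n_bottom < 2L || n_top < 2L)
    stop("each array needs at least 2 electrodes ",
         "(first and last electrodes are distinguished)", call. = FALSE)
  structure(list(
    width_L = width_L, height_h = height_h,
    n_top = n_top, n_bottom = n_bottom,
    pitch_top = electrode_pitch(width_L, n_top),
    pitch_bottom = electrode_pitch(width_L, n_bottom)
  ), class = "channel_geometry")
}

.check_count <- function(n, what) {
  if (!is.numeric(n) || length(n) != 1L || !is.finite(n) || n != round(n))
    stop(what, " must be a single integer", call. = FALSE)
  as.integer(n)
}

#' @export
print.channel_geometry <- function(x, ...) {
  cat(sprintf("<channel_geometry> L = %.6g um, h = %.6g um\n",
              x$width_L * 1e6, x$height_h * 1e6))
  cat(sprintf("  bottom array: N = %d electrodes, pitch %.6g um\n",
              x$n_bottom, x$pitch_bottom * 1e6))
  cat(sprintf("  top array:    N = %d electrodes, pitch %.6g um\n",
              x$n_top, x$pitch_top * 1e6))
  invisible(x)
}

#' Electrode pitch of a uniformly spaced array
#'
#' For `N` electrodes of equal width separated by gaps of the same width and
#' tiling the channel width exactly, the pitch is `L / (2N - 1)`.
#'
#' @param width_L Channel width in metres, positive.
#' @param n_electrodes Electrode count, at least 1 (`N = 1` is the degenerate
#'   single strip spanning the channel).
#' @return Pitch in metres.
#' @examples
#' electrode_pitch(150e-6, 8)  # 10e-6
#' @export
electrode_pitch <- function(width_L, n_electrodes) {
  if (!is.numeric(width_L) || length(width_L) != 1L || !is.finite(width_L) ||
      width_L <= 0)
    stop("invalid geometry: width_L must be a positive length", call. = FALSE)
  n_electrodes <- .check_count(n_electrodes, "n_electrodes")
  if (n_electrodes < 1L)
    stop("invalid geometry: n_electrodes must be >= 1", call. = FALSE)
  width_L / (2 * n_electrodes - 1)
}

#' y-extent of one electrode
#'
#' Electrode `n` (0-based, as the electrodes are indexed in order of
#' increasing y on both walls) occupies `[2 n lambda, (2 n + 1) lambda]`;
#' the gap that follows it occupies `[(2 n + 1) lambda, (2 n + 2) lambda]`.
#'
#' @param geometry A [channel_geometry()].
#' @param n 0-based electrode index.
#' @param which_array `"bottom"` or `"top"`.
#' @return Numeric length-2 vector `c(y_left, y_right)` in metres.
#' @export
electrode_span <- function(geometry, n, which_array = c("bottom", "top")) {
  stopifnot(inherits(geometry, "channel_geometry"))
  which_array <- match.arg(which_array)
  n_el <- if (which_array == "bottom") geometry$n_bottom else geometry$n_top
  lam <- if (which_array == "bottom") geometry$pitch_bottom else geometry$pitch_top
  n <- .check_count(n, "n")
  if (n < 0L || n > n_el - 1L)
    stop("electrode index out of range [0, ", n_el - 1L, "]", call. = FALSE)
  c(2 * n * lam, (2 * n + 1) * lam)
}

#' Suspension-medium dielectric properties
#'
#' @param rel_permittivity Relative permittivity of the medium (dimensionless,
#'   default 78, aqueous).
#' @param conductivity Medium conductivity in S/m (default 0).
#' @param wall_rel_permittivity Relative permittivity of the channel side
#'   walls (default 4, SU-8 photoresist); used only to quantify how well the
#'   lateral walls approximate mirror planes, see [reflection_coefficient()].
#' @return Object of class `medium_properties`.
#' @export
medium_properties <- function(rel_permittivity = 78, conductivity = 0,
                              wall_rel_permittivity = 4) {
  stopifnot(rel_permittivity > 0, wall_rel_permittivity > 0, conductivity >= 0)
  structure(list(rel_permittivity = rel_permittivity,
                 conductivity = conductivity,
                 wall_rel_permittivity = wall_rel_permittivity),
            class = "medium_properties")
}

#' Particle (cell) properties
#'
#' @param radius Particle radius in metres, positive. The dipole
#'   approximation behind the DEP force formula assumes the radius is small
#'   compared with the channel height.
#' @param rel_permittivity Relative permittivity of the particle.
#' @param conductivity Particle conductivity in S/m.
#' @return Object of class `particle_properties`.
#' @export
particle_properties <- function(radius = 4e-6, rel_permittivity = 2.5,
                                conductivity = 0) {
  stopifnot(radius > 0, rel_permittivity > 0, conductivity >= 0)
  structure(list(radius = radius, rel_permittivity = rel_permittivity,
                 conductivity = conductivity),
            class = "particle_properties")
}

#' Electrical drive condition
#'
#' Either the angular frequency of the applied field (from which the
#' Clausius-Mossotti factor is computed via the complex permittivities) or a
#' direct override of its real part. The real part of the Clausius-Mossotti
#' factor of a homogeneous sphere is bounded by \[-0.5, 1\].
#'
#' @param angular_frequency Angular frequency of the drive in rad/s
#'   (positive), or `NULL` when `cm_real` is given.
#' @param cm_real Optional direct value for `Re(beta)`, in `[-0.5, 1]`;
#'   bypasses the permittivity-based computation.
#' @return Object of class `drive_condition`.
#' @examples
#' drive_condition(cm_real = -0.5)   # strong negative DEP
#' @export
drive_condition <- function(angular_frequency = NULL, cm_real = NULL) {
  if (is.null(cm_real)) {
    if (is.null(angular_frequency) || !is.numeric(angular_frequency) ||
        angular_frequency <= 0)
      stop("angular_frequency must be positive when cm_real is not given",
           call. = FALSE)
  } else {
    if (!is.numeric(cm_real) || length(cm_real) != 1L ||
        cm_real < -0.5 || cm_real > 1)
      stop("cm_real override must lie in [-0.5, 1]", call. = FALSE)
  }
  structure(list(angular_frequency = angular_frequency, cm_real = cm_real),
            class = "drive_condition")
}

#' Per-electrode voltage pattern
#'
#' The control input of the system: one voltage per electrode, bottom array
#' first. Electrodes are indexed in order of increasing y on both walls.
#'
#' @param u_bottom Numeric vector of bottom-array voltages (V).
#' @param u_top Numeric vector of top-array voltages (V), or `NULL` for a
#'   single-array (bottom-only) configuration.
#' @param geometry Optional [channel_geometry()]; when given, vector lengths
#'   are checked against the electrode counts.
#' @return Object of class `voltage_pattern`.
#' @export
voltage_pattern <- function(u_bottom, u_top = NULL, geometry = NULL) {
  stopifnot(is.numeric(u_bottom), all(is.finite(u_bottom)))
  if (!is.null(u_top)) stopifnot(is.numeric(u_top), all(is.finite(u_top)))
  if (!is.null(geometry)) {
    stopifnot(inherits(geometry, "channel_geometry"))
    if (length(u_bottom) != geometry$n_bottom)
      stop("u_bottom has ", length(u_bottom), " entries but geometry has ",
           geometry$n_bottom, " bottom electrodes", call. = FALSE)
    if (!is.null(u_top) && length(u_top) != geometry$n_top)
      stop("u_top has ", length(u_top), " entries but geometry has ",
           geometry$n_top, " top electrodes", call. = FALSE)
  }
  structure(list(u_bottom = as.numeric(u_bottom),
                 u_top = if (is.null(u_top)) NULL else as.numeric(u_top)),
            class = "voltage_pattern")
}

#' @export
print.voltage_pattern <- function(x, ...) {
  cat("<voltage_pattern>\n  bottom:", signif(x$u_bottom, 4), "V\n")
  if (!is.null(x$u_top)) cat("  top:   ", signif(x$u_top, 4), "V\n")
  invisible(x)
}

#' Dielectric reflection coefficient of the side walls
#'
#' `(em - ew) / (em + ew)` for the medium/wall permittivity pair. A value
#' close to 1 means the lateral no-flux walls act almost as perfect mirror
#' planes for the field, which is what justifies replacing them by a symmetry
#' (even periodic extension) boundary condition in the Fourier model. For
#' water against SU-8 (78 vs 4) it is 0.90.
#'
#' @param medium A [medium_properties()].
#' @return Dimensionless reflection coefficient.
#' @export
reflection_coefficient <- function(medium) {
  stopifnot(inherits(medium, "medium_properties"))
  em <- medium$rel_permittivity
  ew <- medium$wall_rel_permittivity
  if (em + ew <= 0) stop("permittivities must sum to a positive value",
                         call. = FALSE)
  (em - ew) / (em + ew)
}
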