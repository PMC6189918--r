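# Validation protocol for the analytical model: boundary-series convergence,
# force error maps against the finite-difference oracle, orientation-error
# statistics over random voltage draws, and the channel-height power-law scan.

#' Rectangular region of interest in the channel cross-section
#'
#' The analytical model's boundary approximations degrade next to the
#' electrodes and the lateral walls, so validation statistics are collected
#' over a central region of interest. Ranges are fractions of the channel
#' width (`y_range`, inside `(0, 1)`) and of the height measured from the
#' mid-plane in the dual frame (`z_range`, inside `(-0.5, 0.5)`). The default
#' keeps the central half of each axis.
#'
#' @param y_range Length-2 increasing fraction of `[0, L]`.
#' @param z_range Length-2 increasing fraction of `h`, dual-frame centred.
#' @return Object of class `roi_spec`.
#' @export
roi_spec <- function(y_range = c(0.25, 0.75), z_range = c(-0.25, 0.25)) {
  stopifnot(length(y_range) == 2L, length(z_range) == 2L,
            y_range[1] < y_range[2], z_range[1] < z_range[2],
            y_range[1] > 0, y_range[2] < 1,
            z_range[1] > -0.5, z_range[2] < 0.5)
  structure(list(y_range = y_range, z_range = z_range), class = "roi_spec")
}

# evaluation grid over an ROI, in dual-frame coordinates
.roi_grid <- function(roi, geometry, grid_step) {
  L <- geometry$width_L; h <- geometry$height_h
  ys <- seq(roi$y_range[1] * L, roi$y_range[2] * L, by = grid_step)
  zs <- seq(roi$z_range[1] * h, roi$z_range[2] * h, by = grid_step)
  expand.grid(y = ys, z = zs, KEEP.OUT.ATTRS = FALSE)
}

# wrap angle differences (degrees) to (-180, 180]
.wrap_deg <- function(d) {
  w <- d - 360 * floor((d + 180) / 360)
  w[w <= -180] <- 180
  w
}

#' Seeded random voltage patterns
#'
#' Emulates the validation draws: independent uniform voltages on
#' `[-amplitude, +amplitude]` for every electrode of both arrays.
#' Orientation and relative-error metrics downstream are invariant to the
#' amplitude (force direction is unchanged under a global voltage scaling),
#' so only the distribution shape matters.
#'
#' @param n_draws Number of patterns.
#' @param geometry A [channel_geometry()].
#' @param amplitude Half-width of the uniform draw in volts (default 1).
#' @param seed Optional integer seed for reproducibility.
#' @return List of [voltage_pattern()] objects.
#' @export
random_voltage_patterns <- function(n_draws, geometry, amplitude = 1,
                                    seed = NULL) {
  stopifnot(inherits(geometry, "channel_geometry"),
            n_draws >= 1, amplitude > 0)
  if (!is.null(seed)) set.seed(seed)
  lapply(seq_len(n_draws), function(i) {
    voltage_pattern(
      u_bottom = stats::runif(geometry$n_bottom, -amplitude, amplitude),
      u_top = stats::runif(geometry$n_top, -amplitude, amplitude),
      geometry = geometry
    )
  })
}

#' Convergence of the truncated series toward the boundary potential
#'
#' For each truncation order `P`, evaluates the Fourier series at the
#' electrode plane (`z = 0`, where every vertical profile equals 1) on a fine
#' y-grid and reports the relative RMS error against the piecewise-linear
#' boundary potential it represents. The boundary function is continuous and
#' piecewise-C1, so the error decreases toward 0 as `P` grows (no Gibbs
#' plateau).
#'
#' @param geometry A [channel_geometry()].
#' @param u Voltage vector for the bottom array (V).
#' @param P_values Increasing positive truncation orders.
#' @param n_points Number of uniformly spaced y samples (default 2001).
#' @return Data frame with columns `P` and `rel_rms_error_pct`.
#' @export
boundary_convergence <- function(geometry, u, P_values, n_points = 2001) {
  stopifnot(inherits(geometry, "channel_geometry"),
            all(P_values >= 1), n_points >= 2)
  y <- seq(0, geometry$width_L, length.out = n_points)
  target <- boundary_potential(y, u, geometry, "bottom")
  scale <- sqrt(mean(target^2))
  err <- vapply(P_values, function(P) {
    A <- coefficient_matrix(geometry$n_bottom, P)
    cv <- drop(A %*% u)
    om <- wavenumber(seq.int(-P, P), geometry$width_L)
    series <- drop(cos(outer(y, om)) %*% cv)
    e <- sqrt(mean((series - target)^2))
    if (scale > 0) 100 * e / scale else 100 * e
  }, numeric(1))
  data.frame(P = as.integer(P_values), rel_rms_error_pct = err)
}

# shared per-draw force-field comparison on a fixed point set.
# Returns per-point data frame of analytical vs reference forces and errors.
.compare_forces <- function(model, op, pattern, pts, particle, medium, drive,
                            force_floor = 1e-20) {
  sol <- solve_laplace_fd(op, pattern)
  f_ref <- dep_force(reference_field_sample(sol, pts$y, pts$z),
                     particle, medium, drive)
  f_ana <- dep_force(field_sample(model, pattern, pts$y, pts$z),
                     particle, medium, drive)
  mag_ref <- sqrt(f_ref$f_y^2 + f_ref$f_z^2)
  dmag <- sqrt((f_ana$f_y - f_ref$f_y)^2 + (f_ana$f_z - f_ref$f_z)^2)
  ang <- .wrap_deg((atan2(f_ana$f_z, f_ana$f_y) -
                      atan2(f_ref$f_z, f_ref$f_y)) * 180 / pi)
  excluded <- mag_ref < force_floor
  data.frame(
    y = pts$y, z = pts$z,
    f_y_model = f_ana$f_y, f_z_model = f_ana$f_z,
    f_y_ref = f_ref$f_y, f_z_ref = f_ref$f_z,
    abs_error_y = f_ana$f_y - f_ref$f_y,
    abs_error_z = f_ana$f_z - f_ref$f_z,
    rel_mag_error_pct = ifelse(excluded, NA_real_, 100 * dmag / mag_ref),
    orientation_error_deg = ang,
    excluded = excluded
  )
}

#' Force error maps against the numerical oracle
#'
#' Computes the DEP force on an ROI grid from both the analytical model and
#' the exact-boundary-condition finite-difference solution, for one or many
#' voltage patterns, and summarises per-point errors: relative
#' vector-difference magnitude (percent), absolute per-component differences
#' (newtons) and wrapped orientation differences (degrees). Points where the
#' reference force magnitude falls below `force_floor` are flagged and
#' excluded from relative (not absolute or orientation) statistics, since
#' dividing by a near-zero force inflates the relative error without a
#' matching absolute error.
#'
#' @param geometry A [channel_geometry()].
#' @param patterns A [voltage_pattern()] or a list of them.
#' @param particle,medium,drive Material and drive descriptions (see
#'   [dep_force()]).
#' @param truncation_P Fourier truncation order (default `2 N`).
#' @param roi A [roi_spec()] (default: central half of each axis).
#' @param grid_step Spacing of the ROI evaluation grid in metres.
#' @param spacing Reference-solver grid spacing in metres.
#' @param force_floor Reference-force magnitude below which a point is
#'   excluded from relative statistics (N).
#' @return Object of class `dep_error_summary`: list with `points` (pooled
#'   per-point data frame, one block per pattern) and `summary` (medians,
#'   quantiles, RMS orientation error, counts).
#' @export
error_maps <- function(geometry, patterns, particle = particle_properties(),
                       medium = medium_properties(),
                       drive = drive_condition(cm_real = -0.5),
                       truncation_P = NULL, roi = roi_spec(),
                       grid_step = 2.5e-6, spacing = 0.5e-6,
                       force_floor = 1e-20) {
  stopifnot(inherits(geometry, "channel_geometry"))
  if (inherits(patterns, "voltage_pattern")) patterns <- list(patterns)
  model <- fourier_model(geometry, truncation_P, frame = "dual")
  op <- laplace_operator(geometry, spacing = spacing, frame = "dual")
  pts <- .roi_grid(roi, geometry, grid_step)
  blocks <- lapply(seq_along(patterns), function(i) {
    d <- .compare_forces(model, op, patterns[[i]], pts, particle, medium,
                         drive, force_floor)
    d$draw <- i
    d
  })
  points <- do.call(rbind, blocks)
  ok <- !points$excluded
  rel <- points$rel_mag_error_pct[ok]
  summary <- list(
    median_rel_mag_error_pct = stats::median(rel),
    rel_mag_error_quantiles_pct = stats::quantile(
      rel, c(0.25, 0.5, 0.75, 0.9), names = TRUE),
    median_abs_orientation_error_deg =
      stats::median(abs(points$orientation_error_deg)),
    rms_orientation_error_deg =
      sqrt(mean(points$orientation_error_deg^2)),
    median_abs_error_y = stats::median(abs(points$abs_error_y)),
    median_abs_error_z = stats::median(abs(points$abs_error_z)),
    n_points = nrow(points), n_excluded = sum(points$excluded),
    n_draws = length(patterns), truncation_P = model$truncation_P
  )
  structure(list(points = points, summary = summary),
            class = "dep_error_summary")
}

#' @export
print.dep_error_summary <- function(x, ...) {
  s <- x$summary
  cat("<dep_error_summary>",
      sprintf("%d points x %d draw(s), P = %d, %d excluded (near-zero force)",
              s$n_points / s$n_draws, s$n_draws, s$truncation_P,
              s$n_excluded), "\n")
  cat(sprintf("  median |dF|/|F_ref|: %.2f %%\n", s$median_rel_mag_error_pct))
  cat(sprintf("  median |orientation error|: %.2f deg (RMS %.2f deg)\n",
              s$median_abs_orientation_error_deg,
              s$rms_orientation_error_deg))
  invisible(x)
}

#' Orientation-error statistics versus truncation order
#'
#' For each requested truncation order, draws random voltage patterns,
#' computes the DEP force orientation over an ROI grid with both the
#' analytical model and the finite-difference oracle, takes the RMS of the
#' wrapped per-point angle differences for each draw, and averages over
#' draws. The statistic stops improving once `P` reaches about twice the
#' electrode count, and decreases as the electrode count grows (finer
#' boundary features are better resolved by the linear-gap approximation).
#'
#' All points enter the RMS: where the in-plane force components are both
#' small the angle is ill-conditioned and isolated near-180-degree
#' differences occur, which inflates the average well above the typical
#' per-point error.
#'
#' @param n_electrodes Electrode count per wall (same on both).
#' @param truncation_P Vector of truncation orders to evaluate (default
#'   `2 * n_electrodes`). The reference solve is shared across orders.
#' @param n_draws Number of random voltage patterns (default 50).
#' @param seed Optional integer seed.
#' @param width_L,height_h Channel dimensions in metres.
#' @param roi A [roi_spec()].
#' @param grid_step ROI grid spacing (m).
#' @param spacing Reference-solver spacing (m).
#' @param amplitude Voltage draw amplitude (V); the statistic is invariant
#'   to it.
#' @return Data frame with columns `n_electrodes`, `truncation_P`,
#'   `mean_rms_orientation_deg`, `n_draws`.
#' @export
orientation_error_study <- function(n_electrodes, truncation_P = NULL,
                                    n_draws = 50, seed = NULL,
                                    width_L = 150e-6, height_h = 80e-6,
                                    roi = roi_spec(), grid_step = 2.5e-6,
                                    spacing = 0.8e-6, amplitude = 1) {
  geometry <- channel_geometry(width_L, height_h, n_electrodes)
  if (is.null(truncation_P)) truncation_P <- 2L * n_electrodes
  models <- lapply(truncation_P, function(P)
    fourier_model(geometry, P, frame = "dual"))
  op <- laplace_operator(geometry, spacing = spacing, frame = "dual")
  pts <- .roi_grid(roi, geometry, grid_step)
  patterns <- random_voltage_patterns(n_draws, geometry, amplitude, seed)
  # fixed protocol properties; orientation is invariant to their scalars
  particle <- particle_properties(radius = 4e-6)
  medium <- medium_properties(rel_permittivity = 78)
  drive <- drive_condition(cm_real = -0.5)
  rms <- matrix(NA_real_, n_draws, length(truncation_P))
  for (d in seq_len(n_draws)) {
    sol <- solve_laplace_fd(op, patterns[[d]])
    f_ref <- dep_force(reference_field_sample(sol, pts$y, pts$z),
                       particle, medium, drive)
    ang_ref <- atan2(f_ref$f_z, f_ref$f_y)
    for (k in seq_along(models)) {
      f_ana <- dep_force(field_sample(models[[k]], patterns[[d]],
                                      pts$y, pts$z),
                         particle, medium, drive)
      dang <- .wrap_deg((atan2(f_ana$f_z, f_ana$f_y) - ang_ref) * 180 / pi)
      rms[d, k] <- sqrt(mean(dang^2))
    }
  }
  data.frame(n_electrodes = n_electrodes,
             truncation_P = as.integer(truncation_P),
             mean_rms_orientation_deg = colMeans(rms),
             n_draws = n_draws)
}

#' Channel-height power-law scan of the DEP force
#'
#' Scales the whole cross-section uniformly (`L = h` at every height),
#' keeps the voltage pattern fixed, and records the mean quadratic norm of
#' the DEP force along the mid-plane segment `y` in `[L/3, 2L/3]`, `z = 0`.
#' Dimensional analysis of the field model makes the force scale as `h^-3`
#' when all lengths scale together, so the fitted log-log slope is -3.
#'
#' @param heights Channel heights in metres (at least two; a decade span
#'   recommended).
#' @param u_bottom,u_top Fixed voltage vectors (V), one per electrode.
#' @param n_electrodes Electrode count per wall.
#' @param truncation_P Fourier truncation order (default `2 N`).
#' @param n_points Number of sample points on the segment (default 201).
#' @param particle,medium,drive See [dep_force()].
#' @return List with `table` (data frame `height_m`, `mean_force_N`),
#'   `exponent` (fitted slope of `log mean force` vs `log h`) and `fit`
#'   (the `lm` object).
#' @export
height_scan <- function(heights, u_bottom, u_top, n_electrodes = 8,
                        truncation_P = NULL, n_points = 201,
                        particle = particle_properties(),
                        medium = medium_properties(),
                        drive = drive_condition(cm_real = -0.5)) {
  stopifnot(length(heights) >= 2, all(heights > 0),
            length(u_bottom) == n_electrodes, length(u_top) == n_electrodes,
            n_points >= 2)
  mean_force <- vapply(heights, function(h) {
    geo <- channel_geometry(width_L = h, height_h = h, n_bottom = n_electrodes)
    model <- fourier_model(geo, truncation_P, frame = "dual")
    pat <- voltage_pattern(u_bottom, u_top, geo)
    y <- seq(h / 3, 2 * h / 3, length.out = n_points)
    f <- dep_force_at(model, pat, y, 0, particle, medium, drive)
    mean(sqrt(f$f_y^2 + f$f_z^2))
  }, numeric(1))
  tab <- data.frame(height_m = heights, mean_force_N = mean_force)
  fit <- stats::lm(log(mean_force_N) ~ log(height_m), data = tab)
  list(table = tab, exponent = unname(stats::coef(fit)[2]), fit = fit)
}
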