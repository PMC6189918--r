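# Dielectrophoretic force on a small spherical particle: the classical
# dipole-approximation formula F = 2 pi eps0 em r^3 Re(beta) grad(grad phi)^2,
# applied to field samples from either the analytical Fourier model or the
# finite-difference reference solution.

#' Clausius-Mossotti polarization factor
#'
#' `beta = (ep* - em*) / (ep* + 2 em*)` with complex relative permittivities
#' `e* = e - i sigma / v` at angular drive frequency `v`. The common vacuum
#' permittivity factor cancels in the ratio, so relative permittivities are
#' used directly (conductivities in S/m are divided by `eps0 * v` to stay in
#' relative units). The real part sets the sign of the DEP force: negative
#' values push the particle toward field-intensity minima (negative DEP).
#' If the drive carries a `cm_real` override, it is returned as-is.
#'
#' @param particle A [particle_properties()].
#' @param medium A [medium_properties()].
#' @param drive A [drive_condition()].
#' @return Object of class `polarization_factor` with elements `beta`
#'   (complex) and `re_beta`.
#' @examples
#' # index-matched particle: beta = 0
#' m <- medium_properties(rel_permittivity = 78)
#' p <- particle_properties(rel_permittivity = 78)
#' clausius_mossotti(p, m, drive_condition(angular_frequency = 1e6))$re_beta
#' @export
clausius_mossotti <- function(particle, medium, drive) {
  stopifnot(inherits(particle, "particle_properties"),
            inherits(medium, "medium_properties"),
            inherits(drive, "drive_condition"))
  if (!is.null(drive$cm_real)) {
    return(structure(list(beta = complex(real = drive$cm_real),
                          re_beta = drive$cm_real),
                     class = "polarization_factor"))
  }
  v <- drive$angular_frequency
  # conductivity converted to relative-permittivity units
  ep <- complex(real = particle$rel_permittivity,
                imaginary = -particle$conductivity / (.eps0 * v))
  em <- complex(real = medium$rel_permittivity,
                imaginary = -medium$conductivity / (.eps0 * v))
  den <- ep + 2 * em
  if (Mod(den) == 0)
    stop("singular polarization: ep* + 2 em* = 0", call. = FALSE)
  beta <- (ep - em) / den
  structure(list(beta = beta, re_beta = Re(beta)),
            class = "polarization_factor")
}

#' Gradient of the squared field intensity
#'
#' `grad((grad phi)^2) = 2 * (phi_yy phi_y + phi_yz phi_z,
#'                            phi_zy phi_y + phi_zz phi_z)`,
#' the spatial part of the DEP force, computed from the first and second
#' derivatives carried by a field sample. Quadratic in the voltages.
#'
#' @param sample A `field_sample` data frame (from [field_sample()] or
#'   [reference_field_sample()]).
#' @return Data frame with columns `g_y`, `g_z` in V^2/m^3.
#' @export
grad_e2 <- function(sample) {
  need <- c("dphi_dy", "dphi_dz", "d2phi_dy2", "d2phi_dydz", "d2phi_dz2")
  if (!all(need %in% names(sample)))
    stop("sample lacks first/second derivative columns", call. = FALSE)
  data.frame(
    g_y = 2 * (sample$d2phi_dy2 * sample$dphi_dy +
                 sample$d2phi_dydz * sample$dphi_dz),
    g_z = 2 * (sample$d2phi_dydz * sample$dphi_dy +
                 sample$d2phi_dz2 * sample$dphi_dz)
  )
}

#' Dielectrophoretic force from a field sample
#'
#' `F = 2 pi eps0 em r^3 Re(beta) grad((grad phi)^2)` with `eps0` the vacuum
#' permittivity and `em` the relative medium permittivity. Works on samples
#' from either the analytical model or the numerical reference solution, so
#' both validation paths share one force formula.
#'
#' @inheritParams grad_e2
#' @param particle A [particle_properties()].
#' @param medium A [medium_properties()].
#' @param drive A [drive_condition()].
#' @return Data frame of class `force_vector` with columns `y`, `z`, `f_y`,
#'   `f_z` (newtons).
#' @export
dep_force <- function(sample, particle, medium, drive) {
  stopifnot(inherits(particle, "particle_properties"),
            inherits(medium, "medium_properties"))
  g <- grad_e2(sample)
  cm <- clausius_mossotti(particle, medium, drive)
  k <- 2 * pi * .eps0 * medium$rel_permittivity * particle$radius^3 *
    cm$re_beta
  out <- data.frame(y = sample$y, z = sample$z,
                    f_y = k * g$g_y, f_z = k * g$g_z)
  class(out) <- c("force_vector", "data.frame")
  out
}

#' Dielectrophoretic force at positions, end to end
#'
#' Convenience wrapper: evaluates the analytical field sample at the given
#' positions and applies [dep_force()].
#'
#' @param model A [fourier_model()].
#' @param voltages A [voltage_pattern()].
#' @param y,z Positions in metres (vectorised).
#' @inheritParams dep_force
#' @return See [dep_force()].
#' @export
dep_force_at <- function(model, voltages, y, z, particle, medium, drive) {
  dep_force(field_sample(model, voltages, y, z), particle, medium, drive)
}
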