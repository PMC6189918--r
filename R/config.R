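# Config parsing shared by the command-line entry points, plus tidy map
# exports. Internally everything is SI; config lengths may carry an explicit
# unit suffix ("150 um", "0.5 mm", "80e-6 m") and are converted on load,
# which keeps vacuum-permittivity scale bugs out of user inputs.

.length_units <- c(m = 1, mm = 1e-3, um = 1e-6, "µm" = 1e-6, nm = 1e-9)

#' Parse a length with unit suffix
#'
#' Accepts a bare number (metres) or a string `"<value> <unit>"` with unit
#' one of `m`, `mm`, `um`, `nm`.
#'
#' @param x Number or string (vectorised).
#' @return Length(s) in metres.
#' @export
parse_length <- function(x) {
  if (is.numeric(x)) return(as.numeric(x))
  vapply(as.character(x), function(s) {
    s <- trimws(s)
    m <- regmatches(s, regexec("^([-+0-9.eE]+)\\s*([a-zµ]*m)?$", s))[[1]]
    if (length(m) == 0 || m[2] == "")
      stop("cannot parse length: '", s, "'", call. = FALSE)
    val <- suppressWarnings(as.numeric(m[2]))
    if (is.na(val)) stop("cannot parse length: '", s, "'", call. = FALSE)
    unit <- if (m[3] == "") "m" else m[3]
    if (!unit %in% names(.length_units))
      stop("unknown length unit '", unit, "' in '", s, "'", call. = FALSE)
    val * .length_units[[unit]]
  }, numeric(1), USE.NAMES = FALSE)
}

#' Read a run configuration file
#'
#' Loads a YAML configuration holding the geometry, medium, particle, drive
#' and voltage sections used by the command-line tools (see
#' `inst/extdata/example_config.yaml` and the JSON schema
#' `inst/extdata/run_config_schema.json` for the field layout and units) and
#' builds the corresponding package objects.
#'
#' @param path Path to a YAML file.
#' @return List of class `run_config` with elements `geometry`, `medium`,
#'   `particle`, `drive`, `voltages` (may be `NULL`), `model`
#'   (list: `truncation_P`), `solver` (list: `spacing`), `roi`, `seed`, and
#'   the raw parsed list as `raw`.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw$geometry))
    stop("config lacks a 'geometry' section", call. = FALSE)
  g <- raw$geometry
  geometry <- channel_geometry(
    width_L = parse_length(g$width),
    height_h = parse_length(g$height),
    n_bottom = g$n_bottom %||% g$n_electrodes,
    n_top = g$n_top %||% g$n_bottom %||% g$n_electrodes
  )
  medium <- if (is.null(raw$medium)) medium_properties() else
    medium_properties(
      rel_permittivity = raw$medium$rel_permittivity %||% 78,
      conductivity = raw$medium$conductivity %||% 0,
      wall_rel_permittivity = raw$medium$wall_rel_permittivity %||% 4
    )
  particle <- if (is.null(raw$particle)) particle_properties() else
    particle_properties(
      radius = parse_length(raw$particle$radius %||% 4e-6),
      rel_permittivity = raw$particle$rel_permittivity %||% 2.5,
      conductivity = raw$particle$conductivity %||% 0
    )
  drive <- if (is.null(raw$drive)) drive_condition(cm_real = -0.5) else
    drive_condition(
      angular_frequency = raw$drive$angular_frequency,
      cm_real = raw$drive$cm_real
    )
  voltages <- if (!is.null(raw$voltages)) {
    voltage_pattern(u_bottom = as.numeric(raw$voltages$bottom),
                    u_top = if (!is.null(raw$voltages$top))
                      as.numeric(raw$voltages$top),
                    geometry = geometry)
  }
  roi <- if (is.null(raw$roi)) roi_spec() else
    roi_spec(y_range = as.numeric(raw$roi$y_range),
             z_range = as.numeric(raw$roi$z_range))
  structure(list(
    geometry = geometry, medium = medium, particle = particle,
    drive = drive, voltages = voltages,
    model = list(truncation_P = raw$model$truncation_P),
    solver = list(spacing = parse_length(raw$solver$spacing %||% 0.5e-6)),
    roi = roi, seed = raw$seed, raw = raw
  ), class = "run_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Gridded potential and field map
#'
#' Tidy cross-section map of the potential and its first derivatives,
#' suitable for CSV export or plotting. Dual-frame coordinates.
#'
#' @param model A [fourier_model()].
#' @param voltages A [voltage_pattern()].
#' @param n_y,n_z Grid resolution (default 151 x 81).
#' @return Data frame with columns `y`, `z` (m), `phi` (V), `dphi_dy`,
#'   `dphi_dz` (V/m), `e2` (squared field magnitude, V^2/m^2).
#' @export
field_map <- function(model, voltages, n_y = 151, n_z = 81) {
  geo <- model$geometry
  zr <- if (model$frame == "dual")
    c(-geo$height_h / 2, geo$height_h / 2) else c(0, geo$height_h)
  g <- expand.grid(y = seq(0, geo$width_L, length.out = n_y),
                   z = seq(zr[1], zr[2], length.out = n_z),
                   KEEP.OUT.ATTRS = FALSE)
  s <- field_sample(model, voltages, g$y, g$z)
  data.frame(y = s$y, z = s$z, phi = s$phi,
             dphi_dy = s$dphi_dy, dphi_dz = s$dphi_dz,
             e2 = s$dphi_dy^2 + s$dphi_dz^2)
}

#' Gridded DEP force map
#'
#' @inheritParams field_map
#' @param particle,medium,drive See [dep_force()].
#' @param margin Fraction of each dimension excluded at the walls (the force
#'   needs interior points; default 0.05).
#' @return Data frame with columns `y`, `z`, `f_y`, `f_z`, `f_mag` (N) and
#'   `angle_deg`.
#' @export
force_map <- function(model, voltages, particle = particle_properties(),
                      medium = medium_properties(),
                      drive = drive_condition(cm_real = -0.5),
                      n_y = 151, n_z = 81, margin = 0.05) {
  geo <- model$geometry
  zr <- if (model$frame == "dual")
    c(-geo$height_h / 2, geo$height_h / 2) else c(0, geo$height_h)
  dy <- margin * geo$width_L
  dz <- margin * (zr[2] - zr[1])
  g <- expand.grid(y = seq(dy, geo$width_L - dy, length.out = n_y),
                   z = seq(zr[1] + dz, zr[2] - dz, length.out = n_z),
                   KEEP.OUT.ATTRS = FALSE)
  f <- dep_force_at(model, voltages, g$y, g$z, particle, medium, drive)
  data.frame(y = f$y, z = f$z, f_y = f$f_y, f_z = f$f_z,
             f_mag = sqrt(f$f_y^2 + f$f_z^2),
             angle_deg = atan2(f$f_z, f$f_y) * 180 / pi)
}
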