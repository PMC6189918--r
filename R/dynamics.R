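# Minimal particle-motion model: DEP force plus gravity/buoyancy and Stokes
# drag. At micrometre scale the Reynolds and Stokes numbers are tiny, so the
# default integrator is overdamped (velocity slaved to force); a full
# inertial Euler step is available behind a flag.

.g_accel <- 9.80665  # m/s^2

#' Carrier-fluid mechanical properties
#'
#' @param dynamic_viscosity Dynamic viscosity in Pa s (default `1e-3`,
#'   water at room temperature).
#' @param density Fluid density in kg/m^3 (default 1000).
#' @return Object of class `fluid_properties`.
#' @export
fluid_properties <- function(dynamic_viscosity = 1e-3, density = 1000) {
  stopifnot(dynamic_viscosity > 0, density > 0)
  structure(list(dynamic_viscosity = dynamic_viscosity, density = density),
            class = "fluid_properties")
}

#' Particle state in the channel cross-section
#'
#' @param y,z Position in metres (dual-frame coordinates).
#' @param v_y,v_z Velocity in m/s.
#' @param time Time in seconds.
#' @return Object of class `particle_state`.
#' @export
particle_state <- function(y, z, v_y = 0, v_z = 0, time = 0) {
  stopifnot(is.finite(y), is.finite(z), is.finite(v_y), is.finite(v_z))
  structure(list(y = y, z = z, v_y = v_y, v_z = v_z, time = time),
            class = "particle_state")
}

#' Net force on a suspended particle
#'
#' Sum of the DEP force at the particle position, the buoyancy-corrected
#' weight `(rho_p - rho_f) (4/3) pi r^3 g` acting along `-z`, and Stokes drag
#' `-6 pi eta r v` opposing the velocity.
#'
#' @param state A [particle_state()] inside the channel cross-section.
#' @param model A [fourier_model()] (dual frame).
#' @param voltages A [voltage_pattern()].
#' @param particle A [particle_properties()].
#' @param medium A [medium_properties()].
#' @param drive A [drive_condition()].
#' @param fluid A [fluid_properties()].
#' @param particle_density Particle density in kg/m^3; defaults to the fluid
#'   density (neutral buoyancy).
#' @return Data frame row with columns `f_y`, `f_z` (N).
#' @export
net_force <- function(state, model, voltages, particle, medium, drive,
                      fluid = fluid_properties(),
                      particle_density = fluid$density) {
  stopifnot(inherits(state, "particle_state"),
            inherits(fluid, "fluid_properties"))
  geo <- model$geometry
  half_h <- geo$height_h / 2
  if (state$y < 0 || state$y > geo$width_L ||
      state$z < -half_h || state$z > half_h)
    stop("particle state outside the channel cross-section", call. = FALSE)
  fd <- dep_force_at(model, voltages, state$y, state$z,
                     particle, medium, drive)
  vol <- 4 / 3 * pi * particle$radius^3
  w <- (particle_density - fluid$density) * vol * .g_accel
  drag <- 6 * pi * fluid$dynamic_viscosity * particle$radius
  data.frame(f_y = fd$f_y - drag * state$v_y,
             f_z = fd$f_z - w - drag * state$v_z)
}

#' Simulate a particle trajectory under a voltage schedule
#'
#' Explicit first-order integration of the force balance. The default
#' `"overdamped"` method slaves the velocity to the non-drag force,
#' `v = (F_DEP + F_gravity) / (6 pi eta r)`, which is the physically relevant
#' regime at these scales; `"inertial"` integrates the full Newton equation
#' (symplectic Euler) for completeness. Integration stops early, with the
#' `wall_contact` attribute set, if the particle reaches a wall (within one
#' particle radius); a step that moves the particle by more than a channel
#' dimension raises a step-size error.
#'
#' @param model A dual-frame [fourier_model()].
#' @param schedule Either a single [voltage_pattern()] (held constant) or a
#'   function of time returning one.
#' @param state0 Initial [particle_state()].
#' @param duration Total simulated time (s).
#' @param dt Time step (s).
#' @param particle,medium,drive,fluid,particle_density See [net_force()].
#' @param method `"overdamped"` (default) or `"inertial"`.
#' @return Data frame with columns `t`, `y`, `z`, `v_y`, `v_z`, `f_y`, `f_z`
#'   (one row per step, including the initial state), with attribute
#'   `wall_contact` (logical).
#' @export
simulate_trajectory <- function(model, schedule, state0, duration, dt,
                                particle = particle_properties(),
                                medium = medium_properties(),
                                drive = drive_condition(cm_real = -0.5),
                                fluid = fluid_properties(),
                                particle_density = fluid$density,
                                method = c("overdamped", "inertial")) {
  method <- match.arg(method)
  stopifnot(inherits(state0, "particle_state"), dt > 0, duration >= dt)
  sched <- if (is.function(schedule)) schedule else function(t) schedule
  geo <- model$geometry
  half_h <- geo$height_h / 2
  r <- particle$radius
  drag <- 6 * pi * fluid$dynamic_viscosity * r
  vol <- 4 / 3 * pi * r^3
  w <- (particle_density - fluid$density) * vol * .g_accel
  mass <- particle_density * vol
  n_steps <- floor(duration / dt)
  out <- matrix(NA_real_, n_steps + 1L, 7L,
                dimnames = list(NULL, c("t", "y", "z", "v_y", "v_z",
                                        "f_y", "f_z")))
  y <- state0$y; z <- state0$z; vy <- state0$v_y; vz <- state0$v_z
  t <- state0$time
  wall <- FALSE
  last <- n_steps + 1L
  for (k in seq_len(n_steps + 1L)) {
    volts <- sched(t)
    fd <- dep_force_at(model, volts, y, z, particle, medium, drive)
    fy <- fd$f_y; fz <- fd$f_z - w
    if (method == "overdamped") {
      vy <- fy / drag; vz <- fz / drag
    }
    out[k, ] <- c(t, y, z, vy, vz, fy, fz)
    if (k > n_steps) break
    if (method == "inertial") {
      vy <- vy + dt * (fy - drag * vy) / mass
      vz <- vz + dt * (fz - drag * vz) / mass
    }
    dy <- vy * dt; dz <- vz * dt
    if (abs(dy) > geo$width_L || abs(dz) > geo$height_h)
      stop("unstable integration: displacement exceeds a channel ",
           "dimension in one step; reduce dt", call. = FALSE)
    y <- y + dy; z <- z + dz; t <- t + dt
    if (y < r || y > geo$width_L - r || z < -half_h + r || z > half_h - r) {
      # clip to the wall and stop
      y <- min(max(y, r), geo$width_L - r)
      z <- min(max(z, -half_h + r), half_h - r)
      wall <- TRUE
      volts <- sched(t)
      fd <- dep_force_at(model, volts, y, z, particle, medium, drive)
      out[k + 1L, ] <- c(t, y, z, vy, vz, fd$f_y, fd$f_z - w)
      last <- k + 1L
      break
    }
  }
  traj <- as.data.frame(out[seq_len(last), , drop = FALSE])
  attr(traj, "wall_contact") <- wall
  traj
}
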