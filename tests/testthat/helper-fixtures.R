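# Shared fixtures: the standard validation chip (150 x 80 um, 8 electrodes
# per wall, 10 um strips and gaps) and a tiny coarse geometry for fast
# finite-difference runs.

std_chip <- function() channel_geometry(150e-6, 80e-6, 8)

tiny_chip <- function() channel_geometry(30e-6, 20e-6, 2)

std_materials <- function() {
  list(particle = particle_properties(radius = 4e-6),
       medium = medium_properties(rel_permittivity = 78),
       drive = drive_condition(cm_real = -0.5))
}

# random interior points of a model's frame, away from the walls
interior_points <- function(geometry, n, frame = "dual", margin = 0.05) {
  h <- geometry$height_h; L <- geometry$width_L
  y <- runif(n, margin * L, (1 - margin) * L)
  z <- if (frame == "dual")
    runif(n, -(0.5 - margin) * h, (0.5 - margin) * h)
  else runif(n, margin * h, (1 - margin) * h)
  list(y = y, z = z)
}
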