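# Example run configuration: the 150 x 80 um validation chip.
# Lengths accept a unit suffix (m, mm, um, nm); bare numbers are metres.
geometry:
  width: 150 um
  height: 80 um
  n_bottom: 8
  n_top: 8
medium:
  rel_permittivity: 78
  conductivity: 0.0        # S/m
  wall_rel_permittivity: 4
particle:
  radius: 4 um
  rel_permittivity: 2.5
  conductivity: 0.0        # S/m
drive:
  cm_real: -0.5            # Re(beta) override; or give angular_frequency (rad/s)
voltages:
  bottom: [1.0, -0.5, 0.8, -1.0, 0.3, 0.6, -0.2, 0.9]
  top:    [-0.7, 0.4, -0.9, 0.2, 1.0, -0.3, 0.5, -0.6]
model:
  truncation_P: 16         # positive harmonics; default 2N
solver:
  spacing: 0.5 um          # reference-solver grid target spacing
roi:
  y_range: [0.25, 0.75]    # fraction of the width
  z_range: [-0.25, 0.25]   # fraction of the height, centred (dual frame)
seed: 1
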