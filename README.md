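# depfield

Analytical dielectrophoretic (DEP) force fields from planar electrode
arrays, for microfluidic cell sorting and closed-loop particle control.

## The problem

DEP cell sorters steer cells through a fluidic channel by applying voltages
to strip electrodes patterned on the channel walls: a polarisable particle
in a non-uniform field feels a force along the gradient of the squared
field. Closed-loop control — recomputing the voltages from the observed
cell positions in real time — needs the force at a *point* in
sub-millisecond time, which a numerical field solve cannot deliver.

`depfield` implements a Fourier-series solution of the Laplace equation for
the cross-section of a channel bounded by one or two parallel electrode
arrays, factored as

```
phi(y, z, U) = te(y, z) · A · U
```

* `te(y, z)` — position basis: cosines in `y` times `sinh`-decay profiles
  in `z` (computed analytically together with all first and second
  derivatives);
* `A` — geometry matrix of Fourier coefficients, a pure function of the
  electrode count `N` and truncation order `P` (closed form, precomputed
  and cached);
* `U` — the per-electrode voltage vector, the control input.

The DEP force on a small sphere then follows from the classical dipole
formula `F = 2 pi eps0 em r^3 Re(beta) grad((grad phi)^2)` with `beta` the
Clausius–Mossotti factor of the particle/medium pair.

The package also contains an independent finite-difference solver of the
*exact* mixed boundary-value problem (Dirichlet electrode strips, zero-flux
gaps and side walls) used as a validation oracle, validation studies
(boundary-series convergence, force error maps, orientation statistics,
channel-height power-law scan), a minimal overdamped trajectory simulator,
and a thin command-line front end (`inst/cli/depfield.R`).

## Worked example

```r
library(depfield)

geo <- channel_geometry(width_L = 150e-6, height_h = 80e-6, n_bottom = 8)
model <- fourier_model(geo)            # dual arrays, P = 2N = 16
pat <- voltage_pattern(
  u_bottom = c(1, -0.5, 0.8, -1, 0.3, 0.6, -0.2, 0.9),
  u_top    = c(-0.7, 0.4, -0.9, 0.2, 1, -0.3, 0.5, -0.6),
  geometry = geo)

dep_force_at(model, pat, y = 75e-6, z = 0,
             particle = particle_properties(radius = 4e-6),
             medium = medium_properties(rel_permittivity = 78),
             drive = drive_condition(cm_real = -0.5))
#>         y z          f_y           f_z
#> 1 7.5e-05 0 3.514485e-15 -5.644865e-14
```

At the channel centre this pattern pushes a 4 µm negative-DEP particle
(`Re(beta) = -0.5`) downward with about 56 fN and slightly rightward with
3.5 fN; forces scale with the voltage squared and with the particle radius
cubed.

Comparing the analytical force field against the finite-difference oracle
over the central region of interest:

```r
error_maps(geo, pat, truncation_P = 16, spacing = 0.5e-6)
#> <dep_error_summary> 527 points x 1 draw(s), P = 16, 0 excluded (near-zero force)
#>   median |dF|/|F_ref|: 15.64 %
#>   median |orientation error|: 0.66 deg (RMS 1.93 deg)
```

The analytical model trades the exact gap/wall boundary conditions for
closed-form speed; mid-channel it keeps the force magnitude within ~15%
and the direction within a degree, which is the operating region of
negative-DEP devices. See the vignette
(`vignettes/dep-field-model.Rmd`) for the model derivation, the numerical
choices and the validation protocol.

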