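---
title: "An analytical Fourier-series model of dielectrophoretic force fields"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{An analytical Fourier-series model of dielectrophoretic force fields}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(depfield)
```

## The problem

Dielectrophoresis (DEP) moves polarisable particles — typically biological
cells — through the gradient of a non-uniform electric field. Microfluidic
cell sorters create that field with planar arrays of strip electrodes on the
channel walls and steer cells by choosing the voltage on each electrode.
Closed-loop control of such a device needs the force at the *current* cell
position recomputed every few milliseconds, which rules out solving the whole
field numerically at each step.

`depfield` implements an analytical alternative: the electric potential in
the channel cross-section is written as a truncated Fourier series whose
coefficients depend only on the chip geometry, so that

$$\phi(y, z, U) \;=\; t_e(y, z)\; A \; U,$$

with $t_e$ a row vector of harmonic basis terms evaluated at the query
position, $A$ a precomputable geometry matrix, and $U$ the vector of
electrode voltages (the control input). A force evaluation is then two small
matrix products — microseconds, not seconds — and the model is linear in
$U$, which is what a future control law needs.

## Geometry and boundary conditions

The channel cross-section is $[0, L] \times [-h/2, h/2]$ with an array of
$N^+$ electrodes on the top wall and $N^-$ on the bottom wall. Each array
tiles the width with strips of pitch $\lambda = L/(2N-1)$: electrode
$n \in \{0, \dots, N-1\}$ occupies $[2n\lambda, (2n+1)\lambda]$ and gaps of
the same width separate the strips, so $N$ strips and $N-1$ gaps cover
$[0, L]$ exactly.

The potential obeys the Laplace equation in the quasi-static regime (at DEP
drive frequencies the spatial field shape and the time dependence decouple).
The exact boundary conditions are: prescribed voltage on each electrode
strip, zero normal electric displacement ("no charge accumulation") on the
insulating gaps and on the lateral channel walls. Two approximations make
the problem separable:

1. **Linear gap potential.** Between two electrodes the boundary potential
   is taken to interpolate linearly between the neighbouring electrode
   voltages.
2. **Mirror side walls.** Water against an SU-8 wall has dielectric
   reflection coefficient $(\varepsilon_m-\varepsilon_w)/(\varepsilon_m+
   \varepsilon_w) = 74/82 \approx 0.90$ ([reflection_coefficient()]), close
   to a perfect mirror, so the no-flux side walls are replaced by a symmetry
   condition: the boundary data is extended evenly across $y = 0$ and
   $y = L$, making it $2L$-periodic.

The resulting boundary function is continuous and piecewise linear, so its
Fourier series converges uniformly and there is no Gibbs plateau; the
truncation error at the electrode plane decreases monotonically with the
series length (see `boundary_convergence()`).

## The coefficient matrix and the vertical profiles

With wavenumbers $\omega_p = p\pi/L$, the coefficient $a_{p,n}$ weighting
electrode $n$'s voltage in harmonic $p$ has a closed form
(`fourier_coefficient()`, `coefficient_matrix()`). Writing
$\gamma_p = p\pi/(2N-1)$:

* $p = 0$: $\tfrac{3}{2}/(2N-1)$ for the first and last electrode,
  $2/(2N-1)$ for middle electrodes;
* $p \neq 0$: $\dfrac{2N-1}{p^2\pi^2}$ times a short combination of cosines
  of multiples of $\gamma_p$ (first/middle/last forms differ; the last
  electrode carries an extra $(-1)^p$).

We re-derived these coefficients from the defining integrals before
implementing them; the oscillatory boundary terms cancel pairwise between
each electrode and its adjacent gap ramps, which is why only the
$1/(p^2\pi^2)$ gap curvature terms survive. Two identities follow and are
enforced as tests:

* **Row sums**: $\sum_n a_{p,n} = \delta_{p,0}$ — a uniform voltage
  reproduces a constant boundary exactly, so a uniformly energised single
  array yields the exact linear potential $u\,(h-z)/h$ and *zero* DEP force.
* **Evenness**: $a_{-p,n} = a_{p,n}$, because the boundary extension is
  even. This is what lets the complex exponentials fold into a real cosine
  basis (below).

Each harmonic decays away from its array with the vertical profile
$Z_p(\zeta) = \sinh(|\omega_p|(h-\zeta))/\sinh(|\omega_p| h)$ (linear
$(h-\zeta)/h$ for $p = 0$), with $Z_p(0) = 1$ at the array and
$Z_p(h) = 0$ at the far wall. Two facing arrays at $z = \pm h/2$ superpose:
each array's block is a single-array solution anchored at its own wall and
grounded at the opposite wall, so the dual basis is the concatenation of the
two blocks and the geometry matrix is block-diagonal.

## Numerical choices

* **Real cosine basis.** Because $A$ is even in $p$, the sum over
  $p = -P..P$ of $a_{p,n} e^{i\omega_p y}$ collapses to cosines. The
  production path is entirely real; a complex-exponential path is retained
  (unexported) purely as a test oracle and agrees to $10^{-12}$.
* **Overflow-safe profiles.** The textbook exponential-ratio form of
  $Z_p$ overflows once $\omega_p h \gtrsim 700$; it is computed as
  $e^{-m\zeta}(1 - e^{-2m(h-\zeta)})/(1 - e^{-2mh})$ with $m = |\omega_p|$,
  which is algebraically identical and stable for any truncation order.
* **Truncation default $P = 2N$.** The force-orientation accuracy improves
  up to about twice the electrode count and plateaus beyond (measured by
  `orientation_error_study()`); $P$ is user-overridable.
* **Caching.** $A$ is a pure function of $(N, P)$ and is cached per
  session; building a model for a known geometry costs microseconds.
* **Positions outside $[0, L]$** are valid: the cosine basis is itself the
  even $2L$-periodic extension, so the lateral mirror symmetry is automatic.
* **Derivatives are analytic**, term-by-term: no finite differencing enters
  the force. Each $p \neq 0$ basis function is exactly harmonic, so the
  Laplacian residual of a field sample measures pure rounding noise.

## The DEP force

For a sphere of radius $r$ small compared with the channel height (dipole
approximation), the time-averaged DEP force is

$$F = 2\pi\varepsilon_0\varepsilon_m r^3\,\mathrm{Re}(\beta)\,
      \nabla\left(\nabla\phi\right)^2,\qquad
  \beta = \frac{\varepsilon_p^* - \varepsilon_m^*}
               {\varepsilon_p^* + 2\varepsilon_m^*},$$

with complex relative permittivities $\varepsilon^* = \varepsilon -
i\sigma/(\varepsilon_0\upsilon)$ at angular frequency $\upsilon$. The
vacuum-permittivity factor cancels inside $\beta$, so relative
permittivities are used there directly — documented to prevent
double-scaling. $\mathrm{Re}(\beta) \in [-1/2, 1]$; negative values push
particles toward field-intensity minima (negative DEP), away from the
electrodes, which is the regime sorters use. `drive_condition(cm_real = )`
bypasses the permittivity computation when only the factor's value matters.
Since the force depends on $(\nabla\phi)^2$, the sign convention relating
the field to the potential gradient is immaterial.

The force is quadratic in the voltages; its *direction* is invariant under
a global voltage scaling, which makes orientation-based validation metrics
scale-free.

## The validation oracle

`solve_laplace_fd()` solves the *exact* boundary-value problem — Dirichlet
strips, zero-flux gaps and side walls, no linear-gap or mirror
approximation — with a 5-point finite-difference stencil and second-order
ghost-node Neumann conditions. Design choices:

* **Pitch-aligned grid.** The y-spacing is $\lambda/m$ with
  $m = \lceil\lambda/\text{spacing}\rceil$ (least common multiple of the
  two walls' strip counts when they differ), so every electrode edge falls
  exactly on a node for *every* electrode count — no snapping or staircase
  ambiguity. The z-spacing divides $h$ evenly.
* **One factorization, many solves.** The operator depends only on the
  geometry; it is LU-factorized once and voltage patterns enter through a
  precomputed sparse right-hand-side map, so validation studies over many
  random patterns cost one factorization plus cheap triangular solves.
* **Verification.** The solver is checked against a frozen, independently
  implemented dense-matrix solve of the same discretization on a tiny
  fixture, against Richardson grid-refinement behaviour, and against the
  discrete maximum principle. Note that under the exact conditions a
  uniformly energised single array does *not* give the linear profile —
  the insulating gaps forbid the uniform flux — so the uniform-voltage
  closed form is an identity of the analytical model only. The interior
  convergence order sits slightly below 2 because the Dirichlet/Neumann
  junctions at electrode edges are weakly singular.
* Reference derivatives are central differences on the grid, bilinearly
  interpolated; query points must stay two cells clear of boundaries.

## Validation studies and their conditions

All random voltage patterns are independent uniforms on $[-1, 1]$ V per
electrode (`random_voltage_patterns()`). The distribution is a modelling
choice — the draws emulate arbitrary control inputs — and the relative and
orientation metrics are invariant to the amplitude, so only the shape
matters. The generator emulates only the electrical input; it does not
emulate fabrication tolerances, electrode double layers, medium conductivity
gradients, or hydrodynamics, so passing validation says nothing about those
effects.

* `error_maps()` compares analytical and reference forces on a grid over a
  central region of interest, default $y \in [L/4, 3L/4]$,
  $z \in [-h/4, h/4]$. The central half of each axis is our choice: the
  model's boundary approximations degrade next to the electrodes and side
  walls, negative-DEP particles do not operate there, and the dipole force
  formula itself fails near walls. Points where the reference force falls
  below $10^{-20}$ N are flagged and excluded from *relative* statistics
  only: dividing by a near-zero force produces spurious hundreds of
  percent without a matching absolute error.
* Orientation differences use `atan2` per point, wrapped to
  $(-180°, 180°]$, then RMS per draw and mean over draws — this avoids the
  quadrant loss of a plain arctangent of $F_z/F_y$ while keeping the same
  meaning. Where both in-plane force components are small the angle is
  ill-conditioned and isolated large differences occur; they stay in the
  statistic deliberately, so RMS values sit well above the typical
  per-point error. A caveat for cross-study comparisons: this statistic is
  extremely sensitive to the *reference* field's own noise near force
  zeros. Mesh-based references differentiated twice (e.g. FEM solutions)
  scatter the orientation there, inflating the RMS by an order of
  magnitude relative to the consistent finite-difference oracle used here.
* `height_scan()` scales the whole cross-section uniformly ($L = h$) with
  a fixed voltage pattern and fits the log-log slope of the mean force
  norm on the mid-plane segment $y \in [L/3, 2L/3]$. Dimensional analysis
  of the factorized model gives exactly $h^{-3}$ — position terms are
  dimensionless in $y/L$, gradients contribute $h^{-1}$ each, and
  $\nabla(\nabla\phi)^2$ contributes three — so the fitted slope is a
  strong end-to-end consistency check.

Problem sizes used by the test-suite and the acceptance script — our
choices for a desk-scale study: magnitude/orientation error maps pool 10
random patterns at 0.5 µm reference spacing and a 2.5 µm region-of-interest
grid step (about 5000 point comparisons); the truncation-order study runs
50 patterns per electrode count at ≤ 0.8 µm-equivalent spacing; the height
scan spans one decade with 8 heights and 201 segment points. The electrode
counts, channel dimensions, particle radius (4 µm), medium permittivity
(78) and $\mathrm{Re}(\beta) = -0.5$ follow the standard validation chip.

## Particle dynamics

`simulate_trajectory()` integrates the force balance — DEP force,
buoyancy-corrected weight, Stokes drag $6\pi\eta r v$ — with an explicit
first-order scheme. The default is the overdamped limit (velocity slaved to
the non-drag force): at these scales the particle Reynolds and Stokes
numbers are far below one, so inertia is negligible; a full Newton
integrator is available behind `method = "inertial"`. Gravity acts along
$-z$; the default densities are neutral buoyancy since the application
fixes no particular particle. Axial flow along the channel is outside the
2-D cross-section model and is not simulated. Under constant voltages and
negative $\mathrm{Re}(\beta)$, overdamped trajectories descend the
field-intensity landscape monotonically (up to integrator tolerance), which
is tested as an invariant.

## Conventions that were genuinely open

* **Top-array indexing.** Nothing fixes whether the top array is indexed
  left-to-right or mirrored; both arrays here index electrodes in order of
  increasing $y$. Documented because a mirrored convention relabels
  voltages.
* **Series length bookkeeping.** The coefficient matrix stores $2P+1$ rows
  for $p = -P..P$; "$P$" in this package always means the positive-harmonic
  count.
* **Frames.** The single-array frame puts the array at $z = 0$ and the
  grounded plane at $z = h$; the dual frame puts the arrays at
  $z = \pm h/2$. The conversion is the affine map
  $z_\text{single} = z_\text{dual} + h/2$ (bottom array), and is tested.
* **$N = 1$** is accepted by `electrode_pitch()` as a geometric identity
  but not by model construction: the coefficient formulas distinguish
  first, middle and last electrodes, which requires $N \ge 2$.

## Known limitations

The model is 2-D (infinitely long electrodes), quasi-static, and
dipole-level: no travelling-wave phase gradients, no multipole corrections,
no electrode double layer, no electrothermal or AC-electro-osmotic flow,
no near-wall force corrections, and no particle–particle interactions.
Accuracy degrades within a few micrometres of the electrode plane, where
the linear-gap approximation bites; quantitative use should stay in the
central region of interest. Wall-clock speed ratios against the reference
solver are hardware-dependent and are logged informationally, never
asserted as values.

## A worked example

```{r example}
geo <- channel_geometry(width_L = 150e-6, height_h = 80e-6, n_bottom = 8)
model <- fourier_model(geo)            # dual arrays, P = 2N = 16
pat <- voltage_pattern(
  u_bottom = c(1, -0.5, 0.8, -1, 0.3, 0.6, -0.2, 0.9),
  u_top    = c(-0.7, 0.4, -0.9, 0.2, 1, -0.3, 0.5, -0.6),
  geometry = geo)
f <- dep_force_at(model, pat, y = 75e-6, z = 0,
                  particle = particle_properties(radius = 4e-6),
                  medium = medium_properties(rel_permittivity = 78),
                  drive = drive_condition(cm_real = -0.5))
f
```

A negative `f_z` at the mid-plane means this pattern pushes a negative-DEP
cell toward the bottom of the channel at that position; scaling all
voltages by $c$ scales the force by $c^2$ without turning it.
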