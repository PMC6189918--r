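Package: depfield
Title: Analytical Dielectrophoretic Force Fields from Planar Electrode Arrays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Fourier-series model of the electric potential and the
    dielectrophoretic (DEP) force generated by one or two parallel planar
    electrode arrays in a microfluidic channel. The potential is factored as
    (position basis) x (precomputable geometry matrix) x (voltage vector), so
    the field and force at a particle position are evaluated in sub-millisecond
    time without solving the whole field, as needed for real-time closed-loop
    particle control. Includes the Clausius-Mossotti polarization factor, an
    independent finite-difference Laplace solver with the exact mixed boundary
    conditions as a validation oracle, validation studies (boundary-series
    convergence, force error maps, orientation-error statistics, channel-height
    power-law scan), and a minimal overdamped particle-trajectory simulator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
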