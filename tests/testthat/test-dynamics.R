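test_that("net force balances DEP, buoyant weight and Stokes drag", {
  geo <- std_chip()
  model <- fourier_model(geo)
  mats <- std_materials()
  zero <- voltage_pattern(rep(0, 8), rep(0, 8), geo)
  # neutrally buoyant, zero field, at rest: no force
  st <- particle_state(75e-6, 0)
  f <- net_force(st, model, zero, mats$particle, mats$medium, mats$drive)
  expect_equal(c(f$f_y, f$f_z), c(0, 0))
  # drag opposes the velocity
  mv <- particle_state(75e-6, 0, v_y = 1e-4, v_z = -2e-4)
  fd <- net_force(mv, model, zero, mats$particle, mats$medium, mats$drive)
  expect_lte(fd$f_y * mv$v_y + fd$f_z * mv$v_z, 0)
  drag <- 6 * pi * 1e-3 * mats$particle$radius
  expect_equal(fd$f_y, -drag * 1e-4)
  expect_error(
    net_force(particle_state(200e-6, 0), model, zero,
              mats$particle, mats$medium, mats$drive),
    "outside")
})

test_that("overdamped sedimentation reaches the Stokes terminal velocity", {
  geo <- std_chip()
  model <- fourier_model(geo)
  mats <- std_materials()
  zero <- voltage_pattern(rep(0, 8), rep(0, 8), geo)
  fluid <- fluid_properties()
  rho_p <- 1050
  traj <- simulate_trajectory(model, zero, particle_state(75e-6, 30e-6),
                              duration = 0.2, dt = 0.02,
                              particle = mats$particle, medium = mats$medium,
                              drive = mats$drive, fluid = fluid,
                              particle_density = rho_p)
  r <- mats$particle$radius
  w <- (rho_p - fluid$density) * 4 / 3 * pi * r^3 * 9.80665
  v_term <- -w / (6 * pi * fluid$dynamic_viscosity * r)
  expect_equal(traj$v_z[2], v_term, tolerance = 1e-10)
  expect_true(all(diff(traj$z) < 0))
})

test_that("trajectories are stationary without forcing and first-order in dt", {
  geo <- std_chip()
  model <- fourier_model(geo)
  mats <- std_materials()
  zero <- voltage_pattern(rep(0, 8), rep(0, 8), geo)
  still <- simulate_trajectory(model, zero, particle_state(60e-6, -10e-6),
                               duration = 0.1, dt = 0.01,
                               particle = mats$particle,
                               medium = mats$medium, drive = mats$drive)
  expect_equal(still$y, rep(60e-6, nrow(still)))
  expect_equal(still$z, rep(-10e-6, nrow(still)))
  expect_false(attr(still, "wall_contact"))
  # explicit first-order convergence: halving dt shrinks the endpoint shift
  set.seed(79)
  pat <- random_voltage_patterns(1, geo, amplitude = 3, seed = 79)[[1]]
  run <- function(dt) {
    tr <- simulate_trajectory(model, pat, particle_state(70e-6, 10e-6),
                              duration = 2, dt = dt,
                              particle = mats$particle,
                              medium = mats$medium, drive = mats$drive)
    unlist(tr[nrow(tr), c("y", "z")])
  }
  e1 <- sqrt(sum((run(0.2) - run(0.025))^2))
  e2 <- sqrt(sum((run(0.1) - run(0.025))^2))
  expect_lt(e2, e1)
})

test_that("negative-DEP particles descend the field-intensity landscape", {
  geo <- std_chip()
  model <- fourier_model(geo)
  mats <- std_materials()
  set.seed(83)
  pat <- random_voltage_patterns(1, geo, amplitude = 2, seed = 83)[[1]]
  tr <- simulate_trajectory(model, pat, particle_state(70e-6, 15e-6),
                            duration = 5, dt = 0.01,
                            particle = mats$particle, medium = mats$medium,
                            drive = mats$drive)
  e2_along <- vapply(seq_len(nrow(tr)), function(k) {
    s <- field_sample(model, pat, tr$y[k], tr$z[k])
    s$dphi_dy^2 + s$dphi_dz^2
  }, numeric(1))
  expect_lte(e2_along[length(e2_along)], e2_along[1])
  expect_true(all(diff(e2_along) <= 1e-6 * max(e2_along)))
})

test_that("oversized steps raise a step-size error", {
  geo <- std_chip()
  model <- fourier_model(geo)
  mats <- std_materials()
  pat <- voltage_pattern(rep(c(-60, 60), 4), rep(c(60, -60), 4), geo)
  expect_error(
    simulate_trajectory(model, pat, particle_state(74e-6, 30e-6),
                        duration = 1000, dt = 500,
                        particle = mats$particle, medium = mats$medium,
                        drive = mats$drive),
    "reduce dt")
})
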