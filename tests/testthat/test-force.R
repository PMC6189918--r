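test_that("Clausius-Mossotti factor covers the classical limits", {
  drv <- drive_condition(angular_frequency = 2 * pi * 1e5)
  med <- medium_properties(rel_permittivity = 78, conductivity = 1e-3)
  # index-matched particle: beta = 0
  matched <- particle_properties(radius = 1e-6, rel_permittivity = 78,
                                 conductivity = 1e-3)
  expect_equal(clausius_mossotti(matched, med, drv)$re_beta, 0)
  # void limit ep* -> 0: beta -> -1/2
  void <- particle_properties(radius = 1e-6, rel_permittivity = 1e-12,
                              conductivity = 0)
  expect_equal(clausius_mossotti(void, medium_properties(78), drv)$re_beta,
               -0.5, tolerance = 1e-10)
  # lossless case reduces to the real ratio
  p <- particle_properties(radius = 1e-6, rel_permittivity = 2.5)
  expect_equal(clausius_mossotti(p, medium_properties(78), drv)$re_beta,
               (2.5 - 78) / (2.5 + 2 * 78))
  # override bypasses the permittivities entirely
  expect_equal(
    clausius_mossotti(p, med, drive_condition(cm_real = -0.5))$re_beta,
    -0.5)
})

test_that("grad of squared field vanishes for a uniform field and is
           quadratic in the voltages", {
  geo <- std_chip()
  single <- fourier_model(geo, 16, frame = "single")
  set.seed(31)
  pts <- interior_points(geo, 30, frame = "single")
  # uniform voltage -> linear potential -> zero second derivatives, up to
  # rounding in the telescoping coefficient sums; compare against the scale
  # of a generic pattern at the same points
  g0 <- grad_e2(field_sample(single, voltage_pattern(rep(1.5, 8)),
                             pts$y, pts$z))
  gref <- grad_e2(field_sample(single, voltage_pattern(runif(8, -1, 1)),
                               pts$y, pts$z))
  expect_lt(max(abs(g0$g_y), abs(g0$g_z)),
            1e-8 * max(abs(gref$g_y), abs(gref$g_z)))
  model <- fourier_model(geo)
  ub <- runif(8, -1, 1); ut <- runif(8, -1, 1)
  pts <- interior_points(geo, 30)
  g1 <- grad_e2(field_sample(model, voltage_pattern(ub, ut, geo),
                             pts$y, pts$z))
  g2 <- grad_e2(field_sample(model, voltage_pattern(2 * ub, 2 * ut, geo),
                             pts$y, pts$z))
  expect_equal(g2$g_y, 4 * g1$g_y)
  expect_equal(g2$g_z, 4 * g1$g_z)
  expect_error(grad_e2(data.frame(dphi_dy = 1)), "derivative")
})

test_that("grad of squared field matches a finite-difference oracle", {
  geo <- std_chip()
  model <- fourier_model(geo)
  set.seed(37)
  pat <- voltage_pattern(runif(8, -1, 1), runif(8, -1, 1), geo)
  pts <- interior_points(geo, 5, margin = 0.2)
  g <- grad_e2(field_sample(model, pat, pts$y, pts$z))
  e2 <- function(y, z) {
    s <- field_sample(model, pat, y, z)
    s$dphi_dy^2 + s$dphi_dz^2
  }
  d <- 1e-8
  gy <- (e2(pts$y + d, pts$z) - e2(pts$y - d, pts$z)) / (2 * d)
  gz <- (e2(pts$y, pts$z + d) - e2(pts$y, pts$z - d)) / (2 * d)
  expect_equal(g$g_y, gy, tolerance = 1e-4)
  expect_equal(g$g_z, gz, tolerance = 1e-4)
})

test_that("DEP force obeys the radius, sign and voltage-square laws", {
  geo <- std_chip()
  model <- fourier_model(geo)
  mats <- std_materials()
  set.seed(41)
  pat <- voltage_pattern(runif(8, -1, 1), runif(8, -1, 1), geo)
  pts <- interior_points(geo, 25)
  f <- dep_force_at(model, pat, pts$y, pts$z,
                    mats$particle, mats$medium, mats$drive)
  # r -> 2r multiplies the force by 8
  big <- particle_properties(radius = 8e-6)
  f8 <- dep_force_at(model, pat, pts$y, pts$z, big, mats$medium, mats$drive)
  expect_equal(f8$f_y, 8 * f$f_y)
  # Re(beta) > 0 reverses the direction relative to Re(beta) < 0
  fp <- dep_force_at(model, pat, pts$y, pts$z, mats$particle, mats$medium,
                     drive_condition(cm_real = 0.5))
  expect_equal(fp$f_y, -f$f_y)
  expect_equal(fp$f_z, -f$f_z)
  # ||F(cU)|| = c^2 ||F(U)|| and the direction is unchanged
  pat2 <- voltage_pattern(3 * pat$u_bottom, 3 * pat$u_top, geo)
  f9 <- dep_force_at(model, pat2, pts$y, pts$z,
                     mats$particle, mats$medium, mats$drive)
  expect_equal(sqrt(f9$f_y^2 + f9$f_z^2), 9 * sqrt(f$f_y^2 + f$f_z^2))
  expect_equal(atan2(f9$f_z, f9$f_y), atan2(f$f_z, f$f_y))
  # negative Re(beta): force points down-gradient of the field intensity
  g <- grad_e2(field_sample(model, pat, pts$y, pts$z))
  expect_true(all(f$f_y * g$g_y + f$f_z * g$g_z <= 0))
})

test_that("uniform voltages on one array produce zero force everywhere", {
  geo <- std_chip()
  model <- fourier_model(geo, 16, frame = "single")
  mats <- std_materials()
  set.seed(43)
  pts <- interior_points(geo, 100, frame = "single")
  f <- dep_force_at(model, voltage_pattern(rep(2, 8)), pts$y, pts$z,
                    mats$particle, mats$medium, mats$drive)
  fref <- dep_force_at(model, voltage_pattern(runif(8, -1, 1)), pts$y, pts$z,
                       mats$particle, mats$medium, mats$drive)
  expect_lt(max(abs(f$f_y), abs(f$f_z)),
            1e-8 * max(abs(fref$f_y), abs(fref$f_z)))
})
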