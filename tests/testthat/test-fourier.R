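test_that("wavenumbers are p*pi/L and odd in p", {
  expect_equal(wavenumber(0, 1e-4), 0)
  expect_equal(wavenumber(1, 150e-6), pi / 150e-6)  # ~2.094e4 rad/m
  expect_equal(wavenumber(-3:3, 2e-4), -wavenumber(3:-3, 2e-4))
})

test_that("Fourier coefficients match their closed forms", {
  # p = 0: edge electrodes carry 1.5/(2N-1), middle ones 2/(2N-1)
  expect_equal(fourier_coefficient(0, 0, 8), 0.1)
  expect_equal(fourier_coefficient(0, 7, 8), 0.1)
  expect_equal(fourier_coefficient(0, 3, 8), 2 / 15)
  # p != 0 rows sum to zero over electrodes (verified by direct summation)
  for (p in c(1, 3, 7, 12)) {
    s <- sum(vapply(0:7, function(n) fourier_coefficient(p, n, 8),
                    numeric(1)))
    expect_equal(s, 0, tolerance = 1e-14)
  }
  expect_error(fourier_coefficient(1, 0, 1), ">= 2")
  expect_error(fourier_coefficient(1, 8, 8), "out of range")
})

test_that("coefficient matrix satisfies row-sum and evenness identities", {
  for (N in c(2, 5, 8, 13)) {
    P <- 3 * N
    A <- coefficient_matrix(N, P)
    expect_identical(dim(A), as.integer(c(2 * P + 1, N)))
    rs <- rowSums(A)
    expect_equal(unname(rs[P + 1]), 1, tolerance = 1e-12)
    expect_lt(max(abs(rs[-(P + 1)])), 1e-12)
    # rows p and -p identical
    expect_equal(unname(A[1:P, ]), unname(A[(2 * P + 1):(P + 2), ]))
    # matrix agrees with the scalar coefficient function
    for (p in c(-P, -1, 0, 2)) for (n in c(0, N - 1))
      expect_equal(unname(A[p + P + 1, n + 1]),
                   fourier_coefficient(p, n, N))
  }
  expect_error(coefficient_matrix(1, 4), ">= 2")
  expect_error(coefficient_matrix(4, 0), ">= 1")
})

test_that("boundary potential interpolates electrodes linearly and reflects", {
  geo <- std_chip()
  set.seed(5)
  u <- runif(8, -2, 2)
  lam <- geo$pitch_bottom
  mid_el <- (2 * (0:7) + 0.5) * lam
  expect_equal(boundary_potential(mid_el, u, geo), u)
  mid_gap <- (2 * (0:6) + 1.5) * lam
  expect_equal(boundary_potential(mid_gap, u, geo),
               (u[1:7] + u[2:8]) / 2)
  y <- runif(20, 0, geo$width_L)
  expect_equal(boundary_potential(-y, u, geo),
               boundary_potential(y, u, geo))
  expect_equal(boundary_potential(y + 2 * geo$width_L, u, geo),
               boundary_potential(y, u, geo))
})

test_that("vertical profiles hit 1 at the array and 0 at the far plane", {
  geo <- std_chip()
  h <- geo$height_h
  for (p in c(0, 1, 4, 40)) {
    expect_equal(z_profile(p, 0, geo), 1)
    expect_equal(z_profile(p, h, geo), 0)
  }
  # overflow-safe sinh form equals the raw exponential ratio where the
  # latter is representable
  z <- seq(0, h, length.out = 21)
  for (p in c(1, 3, 9)) {
    w <- wavenumber(p, geo$width_L)
    raw <- (exp(w * (2 * h - z)) - exp(w * z)) / (exp(2 * w * h) - 1)
    expect_equal(z_profile(p, z, geo), raw, tolerance = 1e-12)
  }
  expect_error(z_profile(1, -1e-6, geo), "outside")
  expect_error(z_profile(1, h + 1e-6, geo), "outside")
})

test_that("potential is linear in voltages and zero for zero input", {
  geo <- std_chip()
  model <- fourier_model(geo)
  set.seed(7)
  pts <- interior_points(geo, 40)
  zero <- voltage_pattern(rep(0, 8), rep(0, 8), geo)
  expect_equal(field_potential(model, zero, pts$y, pts$z), rep(0, 40))
  u1 <- voltage_pattern(runif(8, -1, 1), runif(8, -1, 1), geo)
  u2 <- voltage_pattern(runif(8, -1, 1), runif(8, -1, 1), geo)
  usum <- voltage_pattern(u1$u_bottom + u2$u_bottom, u1$u_top + u2$u_top, geo)
  expect_equal(field_potential(model, usum, pts$y, pts$z),
               field_potential(model, u1, pts$y, pts$z) +
                 field_potential(model, u2, pts$y, pts$z))
  u3 <- voltage_pattern(3.5 * u1$u_bottom, 3.5 * u1$u_top, geo)
  expect_equal(field_potential(model, u3, pts$y, pts$z),
               3.5 * field_potential(model, u1, pts$y, pts$z))
})

test_that("uniform single-array voltage gives the exact linear profile", {
  geo <- std_chip()
  model <- fourier_model(geo, 16, frame = "single")
  u <- 2.3
  pat <- voltage_pattern(rep(u, 8))
  set.seed(11)
  pts <- interior_points(geo, 200, frame = "single")
  expect_equal(field_potential(model, pat, pts$y, pts$z),
               u * (geo$height_h - pts$z) / geo$height_h,
               tolerance = 1e-12)
  s <- field_sample(model, pat, pts$y, pts$z)
  expect_equal(s$dphi_dz, rep(-u / geo$height_h, 200), tolerance = 1e-10)
  expect_equal(max(abs(s$dphi_dy)), 0, tolerance = 1e-9)
})

test_that("folded real cosine basis equals the complex-exponential sum", {
  geo <- std_chip()
  model <- fourier_model(geo, 12)
  set.seed(13)
  pat <- voltage_pattern(runif(8, -1, 1), runif(8, -1, 1), geo)
  pts <- interior_points(geo, 25)
  zc <- depfield:::.potential_complex(model, pat, pts$y, pts$z)
  expect_lt(max(abs(Im(zc))), 1e-12)
  expect_equal(field_potential(model, pat, pts$y, pts$z), Re(zc),
               tolerance = 1e-12)
})

test_that("dual-frame superposition reduces to single arrays at the walls", {
  geo <- std_chip()
  dual <- fourier_model(geo, 16, frame = "dual")
  single <- fourier_model(geo, 16, frame = "single")
  set.seed(17)
  ub <- runif(8, -1, 1); ut <- runif(8, -1, 1)
  pts <- interior_points(geo, 30)
  # top array off: dual potential equals the bottom single-array solution
  # under the frame map z_single = z_dual + h/2
  expect_equal(
    field_potential(dual, voltage_pattern(ub, rep(0, 8), geo), pts$y, pts$z),
    field_potential(single, voltage_pattern(ub), pts$y,
                    pts$z + geo$height_h / 2))
  # uniform top array alone: phi = u (1/2 + z/h); value u/2 at mid-plane
  u <- 1.7
  top_only <- voltage_pattern(rep(0, 8), rep(u, 8), geo)
  expect_equal(field_potential(dual, top_only, pts$y, pts$z),
               u * (0.5 + pts$z / geo$height_h), tolerance = 1e-12)
  expect_equal(field_potential(dual, top_only, pts$y, rep(0, 30)),
               rep(u / 2, 30), tolerance = 1e-12)
})

test_that("analytic derivatives agree with central differences", {
  geo <- std_chip()
  model <- fourier_model(geo)
  set.seed(19)
  pat <- voltage_pattern(runif(8, -1, 1), runif(8, -1, 1), geo)
  pts <- interior_points(geo, 5, margin = 0.15)
  s <- field_sample(model, pat, pts$y, pts$z)
  d <- 5e-9
  fy <- (field_potential(model, pat, pts$y + d, pts$z) -
           field_potential(model, pat, pts$y - d, pts$z)) / (2 * d)
  fz <- (field_potential(model, pat, pts$y, pts$z + d) -
           field_potential(model, pat, pts$y, pts$z - d)) / (2 * d)
  expect_equal(s$dphi_dy, fy, tolerance = 1e-6)
  expect_equal(s$dphi_dz, fz, tolerance = 1e-6)
  fyy <- (field_potential(model, pat, pts$y + d, pts$z) -
            2 * field_potential(model, pat, pts$y, pts$z) +
            field_potential(model, pat, pts$y - d, pts$z)) / d^2
  expect_equal(s$d2phi_dy2, fyy, tolerance = 1e-4)
})

test_that("interior samples are harmonic to truncation tolerance", {
  geo <- std_chip()
  model <- fourier_model(geo)
  set.seed(23)
  for (rep in 1:5) {
    pat <- voltage_pattern(runif(8, -1, 1), runif(8, -1, 1), geo)
    pts <- interior_points(geo, 50)
    s <- field_sample(model, pat, pts$y, pts$z)
    scale <- max(abs(s$phi)) * max(model$omega)^2
    expect_lt(max(abs(s$d2phi_dy2 + s$d2phi_dz2)), 1e-6 * scale)
  }
})

test_that("series reproduces electrode-midpoint voltages within 2% at P=4N", {
  geo <- std_chip()
  model <- fourier_model(geo, 32, frame = "single")
  set.seed(29)
  u <- runif(8, 0.5, 2)   # bounded away from zero for a relative check
  pat <- voltage_pattern(u)
  mids <- (2 * (0:7) + 0.5) * geo$pitch_bottom
  phi <- field_potential(model, pat, mids, rep(0, 8))
  expect_lt(max(abs(phi - u) / abs(u)), 0.02)
})
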