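# Fourier-series solution of the Laplace equation above one or two planar
# electrode arrays. The potential is phi(y, z) = te(y, z) . A . U where A
# depends only on the geometry (precomputable), U is the per-electrode
# voltage vector and te is a position basis of harmonic terms, so a single
# point evaluation never requires a whole-field solve.

# cache of coefficient matrices keyed on "N:P" (pure functions of N and P)
.coeff_cache <- new.env(parent = emptyenv())

#' Angular spatial frequency of harmonic p
#'
#' The boundary potential is extended evenly across the lateral walls, making
#' it 2L-periodic, so harmonic `p` has wavenumber `p * pi / L`.
#'
#' @param p Integer harmonic index (vectorised; may be negative).
#' @param width_L Channel width in metres, positive.
#' @return Wavenumber(s) in rad/m; odd in `p`.
#' @export
wavenumber <- function(p, width_L) {
  stopifnot(is.numeric(width_L), width_L > 0)
  p * pi / width_L
}

#' One Fourier coefficient of the boundary potential
#'
#' The coefficient `a[p, n]` weights the contribution of electrode `n`'s
#' voltage to harmonic `p` of the piecewise-linear boundary potential
#' (constant on electrodes, linear across gaps, even across the lateral
#' walls). With `gamma_p = p * pi / (2N - 1)`:
#' * `p = 0`: `1.5 / (2N - 1)` for the first and last electrodes,
#'   `2 / (2N - 1)` for middle electrodes;
#' * `p != 0`: `(2N - 1) / (p^2 pi^2)` times a combination of cosines of
#'   multiples of `gamma_p` (first/middle/last electrode forms differ; the
#'   last carries an extra `(-1)^p`).
#'
#' Coefficients are real, even in `p`, and each harmonic row sums over
#' electrodes to `1` for `p = 0` and `0` otherwise (so a uniform voltage
#' reproduces a constant boundary exactly).
#'
#' @param p Integer harmonic index.
#' @param n 0-based electrode index.
#' @param n_electrodes Electrode count `N >= 2`.
#' @return Dimensionless coefficient.
#' @export
fourier_coefficient <- function(p, n, n_electrodes) {
  N <- .check_count(n_electrodes, "n_electrodes")
  if (N < 2L) stop("n_electrodes must be >= 2", call. = FALSE)
  n <- .check_count(n, "n")
  if (n < 0L || n > N - 1L)
    stop("electrode index out of range [0, ", N - 1L, "]", call. = FALSE)
  p <- .check_count(p, "p")
  if (p == 0L) {
    if (n == 0L || n == N - 1L) 1.5 / (2 * N - 1) else 2 / (2 * N - 1)
  } else {
    g <- p * pi / (2 * N - 1)
    s <- (2 * N - 1) / (p^2 * pi^2)
    if (n == 0L) {
      s * (cos(g) - cos(2 * g))
    } else if (n == N - 1L) {
      (-1)^p * s * (cos(g) - cos(2 * g))
    } else {
      s * (-cos((2 * n - 1) * g) + cos(2 * n * g) +
             cos((2 * n + 1) * g) - cos((2 * n + 2) * g))
    }
  }
}

#' Geometry coefficient matrix of one electrode array
#'
#' Stacks [fourier_coefficient()] into the `(2P + 1) x N` matrix `A` with
#' rows ordered `p = -P, ..., P` (row names `"p=-P"` ... `"p=P"`). `A` is a
#' pure function of `(N, P)`; results are cached so each geometry is built
#' once per session.
#'
#' @param n_electrodes Electrode count `N >= 2`.
#' @param truncation_P Number of positive harmonics retained, `P >= 1`.
#' @return Numeric matrix of shape `(2P + 1) x N`.
#' @export
coefficient_matrix <- function(n_electrodes, truncation_P) {
  N <- .check_count(n_electrodes, "n_electrodes")
  P <- .check_count(truncation_P, "truncation_P")
  if (N < 2L) stop("n_electrodes must be >= 2", call. = FALSE)
  if (P < 1L) stop("truncation_P must be >= 1", call. = FALSE)
  key <- paste0(N, ":", P)
  hit <- .coeff_cache[[key]]
  if (!is.null(hit)) return(hit)
  ps <- seq.int(-P, P)
  g0 <- pi / (2 * N - 1)              # gamma_p = p * g0
  A <- matrix(0, nrow = 2L * P + 1L, ncol = N,
              dimnames = list(paste0("p=", ps), NULL))
  # p = 0 row
  A[P + 1L, ] <- c(1.5, rep(2, N - 2L), 1.5) / (2 * N - 1)
  # p != 0 rows, vectorised over p
  pnz <- ps[ps != 0L]
  scale <- (2 * N - 1) / (pnz^2 * pi^2)
  edge <- scale * (cos(pnz * g0) - cos(2 * pnz * g0))
  rows <- match(pnz, ps)
  A[rows, 1L] <- edge
  A[rows, N] <- (-1)^pnz * edge
  if (N > 2L) {
    for (n in 1L:(N - 2L)) {
      A[rows, n + 1L] <- scale *
        (-cos((2 * n - 1) * pnz * g0) + cos(2 * n * pnz * g0) +
           cos((2 * n + 1) * pnz * g0) - cos((2 * n + 2) * pnz * g0))
    }
  }
  .coeff_cache[[key]] <- A
  A
}

#' Piecewise-linear boundary potential at the electrode plane
#'
#' The approximate Dirichlet data the Fourier series represents: voltage
#' `u[n]` on electrode `n`'s span, linear interpolation between neighbouring
#' electrode voltages across each gap, extended evenly across `y = 0` and
#' `y = L` (the lateral mirror symmetry), hence defined for all `y`.
#'
#' @param y Positions in metres (vectorised; any real value, folded by the
#'   2L-periodic even extension).
#' @param u Numeric vector of electrode voltages for the chosen array.
#' @param geometry A [channel_geometry()].
#' @param which_array `"bottom"` or `"top"`.
#' @return Potential in volts at each `y`.
#' @export
boundary_potential <- function(y, u, geometry, which_array = c("bottom", "top")) {
  stopifnot(inherits(geometry, "channel_geometry"), is.numeric(y))
  which_array <- match.arg(which_array)
  N <- if (which_array == "bottom") geometry$n_bottom else geometry$n_top
  if (length(u) != N)
    stop("voltage vector length ", length(u), " does not match N = ", N,
         call. = FALSE)
  L <- geometry$width_L
  # even 2L-periodic fold into [0, L]
  yf <- y %% (2 * L)
  yf <- ifelse(yf > L, 2 * L - yf, yf)
  lam <- L / (2 * N - 1)
  t <- pmin(pmax(yf / lam, 0), 2 * N - 1)   # position in pitch units
  k <- pmin(floor(t), 2 * N - 2)            # segment index 0 .. 2N-2
  on_electrode <- (k %% 2) == 0
  n_el <- pmin(k %/% 2, N - 1)
  phi <- u[n_el + 1L]
  # gaps: segment k = 2n+1 runs from electrode n to electrode n+1
  gap <- !on_electrode
  if (any(gap)) {
    n_gap <- (k[gap] - 1) %/% 2
    frac <- t[gap] - (2 * n_gap + 1)
    phi[gap] <- u[n_gap + 1L] + (u[n_gap + 2L] - u[n_gap + 1L]) * frac
  }
  phi
}

#' Vertical decay profile of one harmonic
#'
#' In the single-array frame, harmonic `p` of the boundary potential decays
#' with height as `Z_0(z) = (h - z)/h` for `p = 0` and
#' `Z_p(z) = sinh(|omega_p| (h - z)) / sinh(|omega_p| h)` for `p != 0`
#' (the overflow-safe rewriting of the exponential ratio in the separable
#' solution). Every profile satisfies `Z(0) = 1`, `Z(h) = 0`; profiles are
#' even in `p`.
#'
#' @param p Integer harmonic index.
#' @param z Height(s) above the array plane, in `[0, h]` (vectorised).
#' @param geometry A [channel_geometry()] supplying both the width (which
#'   sets `omega_p = p pi / L`) and the height `h`.
#' @return Dimensionless profile value(s).
#' @export
z_profile <- function(p, z, geometry) {
  stopifnot(inherits(geometry, "channel_geometry"), is.numeric(z))
  p <- .check_count(p, "p")
  h <- geometry$height_h
  if (any(z < 0 | z > h))
    stop("z outside [0, h]", call. = FALSE)
  m <- abs(wavenumber(p, geometry$width_L))
  drop(.zprofile(z, m, h)$z)
}

# Vertical profile Z_p and derivatives in the single-array frame:
#   Z_0(zeta)   = (h - zeta) / h                       (linear harmonic)
#   Z_p(zeta)   = sinh(m (h - zeta)) / sinh(m h),  m = |omega_p|
# computed in the overflow-safe form
#   Z_p = exp(-m zeta) (1 - exp(-2 m (h - zeta))) / (1 - exp(-2 m h)),
# identical to the exponential-ratio form of the separable solution but
# stable for large m h. Returns list(z, dz, ddz): value, d/dzeta, d2/dzeta2
# as n_points x n_harmonics matrices. `m` is the vector of |omega_p|.
.zprofile <- function(zeta, m, h) {
  np <- length(zeta)
  nh <- length(m)
  M <- matrix(m, np, nh, byrow = TRUE)
  ZT <- matrix(zeta, np, nh)
  z <- dz <- ddz <- matrix(0, np, nh)
  zero <- m == 0
  if (any(zero)) {
    z[, zero] <- (h - zeta) / h
    dz[, zero] <- -1 / h
    # ddz stays 0
  }
  if (any(!zero)) {
    i <- which(!zero)
    Mi <- M[, i, drop = FALSE]
    Zi <- ZT[, i, drop = FALSE]
    e1 <- exp(-Mi * Zi)
    e2 <- exp(-2 * Mi * (h - Zi))
    den <- 1 - exp(-2 * Mi * h)
    z[, i] <- e1 * (1 - e2) / den
    dz[, i] <- -Mi * e1 * (1 + e2) / den
    ddz[, i] <- Mi^2 * z[, i, drop = FALSE]
  }
  list(z = z, dz = dz, ddz = ddz)
}

# Basis block for one array: harmonic p contributes cos(omega_p y) Z_|p|(zeta)
# where zeta is the distance from that array's plane and dzeta/dz = zsign in
# the evaluation frame. Returns n_points x (2P+1) matrices for the value and
# its y/z derivatives up to order 2. Harmonic p = 0 is the linear profile;
# for p != 0 the y and z second derivatives cancel termwise (each basis
# function is harmonic).
.basis_block <- function(y, zeta, zsign, omega, h, order = 2L) {
  np <- length(y)
  nh <- length(omega)
  OM <- matrix(omega, np, nh, byrow = TRUE)
  ARG <- matrix(y, np, nh) * OM
  CY <- cos(ARG)
  zp <- .zprofile(zeta, abs(omega), h)
  out <- list(b = CY * zp$z)
  if (order >= 1L) {
    SY <- sin(ARG)
    out$by <- -OM * SY * zp$z
    out$bz <- zsign * CY * zp$dz
    if (order >= 2L) {
      out$byy <- -OM^2 * CY * zp$z
      out$byz <- -zsign * OM * SY * zp$dz
      out$bzz <- CY * zp$ddz    # zsign^2 = 1
    }
  }
  out
}

#' Fourier field model of one or two electrode arrays
#'
#' Precomputes everything that depends on the geometry alone: the wavenumbers
#' `omega_p = p pi / L` and the coefficient matrices `A` (bottom array and,
#' in the dual frame, top array). Evaluating the potential at a point is then
#' a basis-times-matrix-times-voltage product.
#'
#' In the `"dual"` frame (the default; two facing arrays at `z = +/- h/2`)
#' the potential is the superposition of a single-array solution anchored at
#' each wall and grounded at the opposite wall. In the `"single"` frame one
#' array sits at `z = 0` and the plane `z = h` is grounded.
#'
#' @param geometry A [channel_geometry()].
#' @param truncation_P Number of positive harmonics `P`; default `2 N`
#'   (with `N` the larger electrode count), past which the force-orientation
#'   accuracy no longer improves.
#' @param frame `"dual"` or `"single"`.
#' @return Object of class `fourier_model`.
#' @examples
#' geo <- channel_geometry(150e-6, 80e-6, 8)
#' mod <- fourier_model(geo)           # dual arrays, P = 16
#' @export
fourier_model <- function(geometry, truncation_P = NULL,
                          frame = c("dual", "single")) {
  stopifnot(inherits(geometry, "channel_geometry"))
  frame <- match.arg(frame)
  if (is.null(truncation_P))
    truncation_P <- 2L * max(geometry$n_top, geometry$n_bottom)
  P <- .check_count(truncation_P, "truncation_P")
  if (P < 1L) stop("truncation_P must be >= 1", call. = FALSE)
  ps <- seq.int(-P, P)
  structure(list(
    geometry = geometry,
    truncation_P = P,
    frame = frame,
    harmonics = ps,
    omega = wavenumber(ps, geometry$width_L),
    coeff_bottom = coefficient_matrix(geometry$n_bottom, P),
    coeff_top = if (frame == "dual") coefficient_matrix(geometry$n_top, P)
  ), class = "fourier_model")
}

#' @export
print.fourier_model <- function(x, ...) {
  cat(sprintf("<fourier_model> frame = %s, P = %d (%d harmonics)\n",
              x$frame, x$truncation_P, length(x$harmonics)))
  print(x$geometry)
  invisible(x)
}

# coefficient-times-voltage vectors; validates pattern against the model
.coeff_times_u <- function(model, voltages) {
  stopifnot(inherits(model, "fourier_model"),
            inherits(voltages, "voltage_pattern"))
  geo <- model$geometry
  if (length(voltages$u_bottom) != geo$n_bottom)
    stop("u_bottom length does not match geometry", call. = FALSE)
  cb <- drop(model$coeff_bottom %*% voltages$u_bottom)
  if (model$frame == "dual") {
    if (is.null(voltages$u_top))
      stop("dual-frame model needs u_top voltages", call. = FALSE)
    if (length(voltages$u_top) != geo$n_top)
      stop("u_top length does not match geometry", call. = FALSE)
    ct <- drop(model$coeff_top %*% voltages$u_top)
  } else {
    ct <- NULL
  }
  list(bottom = cb, top = ct)
}

# frame domain check
.check_domain <- function(model, y, z) {
  h <- model$geometry$height_h
  if (model$frame == "single") {
    if (any(z < 0 | z > h))
      stop("z outside [0, h] for the single-array frame", call. = FALSE)
  } else {
    if (any(z < -h / 2 | z > h / 2))
      stop("z outside [-h/2, h/2] for the dual-array frame", call. = FALSE)
  }
  invisible(TRUE)
}

# distance(s) from each array plane plus dzeta/dz sign, per frame
.zeta_blocks <- function(model, z) {
  h <- model$geometry$height_h
  if (model$frame == "single") {
    list(bottom = list(zeta = z, zsign = 1))
  } else {
    list(bottom = list(zeta = h / 2 + z, zsign = 1),
         top = list(zeta = h / 2 - z, zsign = -1))
  }
}

#' Electric potential at given positions
#'
#' Evaluates `phi(y, z) = te(y, z) . A . U`. Positions `y` outside `[0, L]`
#' are handled automatically by the even 2L-periodic structure of the cosine
#' basis (the lateral mirror symmetry).
#'
#' @param model A [fourier_model()].
#' @param voltages A [voltage_pattern()] matching the model's geometry.
#' @param y,z Positions in metres (vectors of equal length, or one scalar
#'   recycled). `z` must lie in the model frame's domain.
#' @return Potential in volts, one value per position.
#' @export
field_potential <- function(model, voltages, y, z) {
  n <- max(length(y), length(z))
  y <- rep_len(y, n); z <- rep_len(z, n)
  .check_domain(model, y, z)
  cu <- .coeff_times_u(model, voltages)
  zb <- .zeta_blocks(model, z)
  h <- model$geometry$height_h
  bb <- .basis_block(y, zb$bottom$zeta, zb$bottom$zsign, model$omega, h,
                     order = 0L)
  phi <- drop(bb$b %*% cu$bottom)
  if (!is.null(cu$top)) {
    bt <- .basis_block(y, zb$top$zeta, zb$top$zsign, model$omega, h,
                       order = 0L)
    phi <- phi + drop(bt$b %*% cu$top)
  }
  phi
}

#' Potential and its spatial derivatives at given positions
#'
#' All derivatives are analytic term-by-term derivatives of the basis, so no
#' finite differencing is involved. The returned first and second derivatives
#' feed the DEP force formula; interior samples satisfy the Laplace equation
#' (`d2phi_dy2 + d2phi_dz2 = 0`) termwise.
#'
#' @inheritParams field_potential
#' @return A data frame of class `field_sample` with columns `y`, `z`, `phi`,
#'   `dphi_dy`, `dphi_dz`, `d2phi_dy2`, `d2phi_dydz`, `d2phi_dz2` (SI units).
#' @export
field_sample <- function(model, voltages, y, z) {
  n <- max(length(y), length(z))
  y <- rep_len(y, n); z <- rep_len(z, n)
  .check_domain(model, y, z)
  cu <- .coeff_times_u(model, voltages)
  zb <- .zeta_blocks(model, z)
  h <- model$geometry$height_h
  acc <- NULL
  for (side in names(zb)) {
    blk <- .basis_block(y, zb[[side]]$zeta, zb[[side]]$zsign, model$omega, h,
                        order = 2L)
    cv <- cu[[side]]
    part <- lapply(blk, function(B) drop(B %*% cv))
    acc <- if (is.null(acc)) part else Map(`+`, acc, part)
  }
  out <- data.frame(y = y, z = z,
                    phi = acc$b,
                    dphi_dy = acc$by, dphi_dz = acc$bz,
                    d2phi_dy2 = acc$byy, d2phi_dydz = acc$byz,
                    d2phi_dz2 = acc$bzz)
  class(out) <- c("field_sample", "data.frame")
  out
}

# Complex-exponential reference evaluation of the potential (sum over
# p = -P..P of a[p,n] exp(i omega_p y) Z_p(z)). Kept as an independent path
# for testing the folded real-cosine basis; not used in production.
.potential_complex <- function(model, voltages, y, z) {
  n <- max(length(y), length(z))
  y <- rep_len(y, n); z <- rep_len(z, n)
  cu <- .coeff_times_u(model, voltages)
  zb <- .zeta_blocks(model, z)
  h <- model$geometry$height_h
  phi <- complex(real = rep(0, n))
  for (side in names(zb)) {
    zp <- .zprofile(zb[[side]]$zeta, abs(model$omega), h)
    E <- exp(1i * outer(y, model$omega))
    phi <- phi + drop((E * zp$z) %*% cu[[side]])
  }
  phi
}
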