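# Independent numerical oracle: finite-difference solution of the EXACT
# boundary-value problem (Dirichlet on electrode strips, zero normal flux on
# gaps and lateral walls), against which the Fourier model -- which uses the
# approximate linear-gap / mirror-wall boundary conditions -- is validated.

#' Assemble and factorize the finite-difference Laplace operator
#'
#' Discretizes the channel cross-section `[0, L] x [0, h]` with a 5-point
#' stencil. The y-grid is aligned to the electrode pitch (spacing
#' `lambda / m` with `m = ceiling(lambda / spacing)`, using the least common
#' multiple of both arrays' strip counts when they differ) so that every
#' electrode edge falls exactly on a node; the z-spacing is `h` divided into
#' equal cells no coarser than `spacing`. Boundary conditions:
#' * electrode strips (both walls in the dual frame; bottom wall only in the
#'   single frame, whose entire top wall is grounded): Dirichlet `u_n`;
#' * gaps between electrodes and the two lateral walls: homogeneous Neumann
#'   (no charge accumulation, zero normal flux), imposed by second-order
#'   ghost-node mirroring.
#'
#' The operator and its sparse LU factorization depend only on the geometry,
#' so one factorization serves any number of voltage patterns; the voltages
#' enter through a precomputed sparse right-hand-side map.
#'
#' @param geometry A [channel_geometry()].
#' @param spacing Target grid spacing in metres (default `0.5e-6`; the actual
#'   spacings, at most this coarse, are returned).
#' @param frame `"dual"` (arrays on both walls) or `"single"` (bottom array,
#'   grounded top wall).
#' @return Object of class `laplace_operator`.
#' @export
laplace_operator <- function(geometry, spacing = 0.5e-6,
                             frame = c("dual", "single")) {
  stopifnot(inherits(geometry, "channel_geometry"),
            is.numeric(spacing), spacing > 0)
  frame <- match.arg(frame)
  L <- geometry$width_L; h <- geometry$height_h
  # y-grid: cells per channel = K, a multiple of each array's strip count
  gcd <- function(a, b) if (b == 0) a else gcd(b, a %% b)
  kb <- 2L * geometry$n_bottom - 1L
  kt <- 2L * geometry$n_top - 1L
  strips <- if (frame == "dual") as.integer(kb * kt / gcd(kb, kt)) else kb
  # tolerance guards against 10/2 -> 5.000000000000001 -> ceiling 6
  K <- strips * as.integer(ceiling(L / strips / spacing - 1e-9))
  sy <- L / K
  nzc <- as.integer(ceiling(h / spacing - 1e-9))
  sz <- h / nzc
  ny <- K + 1L
  nz <- nzc + 1L
  cy <- 1 / sy^2; cz <- 1 / sz^2

  # Dirichlet classification of wall nodes. For a wall with N electrodes the
  # pitch holds mpp = K / (2N - 1) cells; node i (1-based) sits at t =
  # (i-1)/mpp pitch units; strip floor(t) even -> on electrode, and integer
  # t odd is an electrode's trailing edge (still Dirichlet).
  wall_electrode <- function(N) {
    mpp <- K %/% (2L * N - 1L)
    q <- 0:(ny - 1L)
    cidx <- q %/% mpp
    r <- q %% mpp
    idx <- integer(ny)                       # 0 = not on an electrode
    on_even <- (cidx %% 2L) == 0L
    idx[on_even] <- cidx[on_even] %/% 2L + 1L
    edge <- !on_even & r == 0L
    idx[edge] <- (cidx[edge] - 1L) %/% 2L + 1L
    pmin(idx, N)                              # i = ny maps to electrode N
  }
  bot_idx <- wall_electrode(geometry$n_bottom)       # column in u_bottom
  if (frame == "dual") {
    top_idx <- wall_electrode(geometry$n_top)        # column in u_top
  } else {
    top_idx <- rep(-1L, ny)                          # grounded (u = 0)
  }

  # node id = i + (j - 1) * ny, i over y, j over z (bottom row j = 1)
  nid <- function(i, j) i + (j - 1L) * ny
  dir_col <- integer(ny * nz)     # >0: voltage column; -1: grounded; 0: free
  dir_col[nid(1:ny, 1L)] <- ifelse(bot_idx > 0L, bot_idx, 0L)
  dir_col[nid(1:ny, nz)] <- ifelse(top_idx > 0L,
                                   geometry$n_bottom + top_idx, top_idx)
  is_dir <- dir_col != 0L
  unknown <- which(!is_dir)
  nu <- length(unknown)
  row_of <- integer(ny * nz)
  row_of[unknown] <- seq_len(nu)

  ii <- (unknown - 1L) %% ny + 1L
  jj <- (unknown - 1L) %/% ny + 1L
  # mirror neighbours at Neumann boundaries (corners are always Dirichlet)
  nb <- list(
    list(id = nid(ifelse(ii > 1L, ii - 1L, ii + 1L), jj), c = cy),
    list(id = nid(ifelse(ii < ny, ii + 1L, ii - 1L), jj), c = cy),
    list(id = nid(ii, ifelse(jj > 1L, jj - 1L, jj + 1L)), c = cz),
    list(id = nid(ii, ifelse(jj < nz, jj + 1L, jj - 1L)), c = cz)
  )
  ti <- tj <- tx <- vector("list", 5L)
  ri <- rj <- rx <- vector("list", 4L)
  for (d in seq_along(nb)) {
    tgt <- nb[[d]]$id
    free <- !is_dir[tgt]
    ti[[d]] <- which(free)
    tj[[d]] <- row_of[tgt[free]]
    tx[[d]] <- rep(nb[[d]]$c, sum(free))
    driven <- !free & dir_col[tgt] > 0L
    ri[[d]] <- which(driven)
    rj[[d]] <- dir_col[tgt[driven]]
    rx[[d]] <- rep(-nb[[d]]$c, sum(driven))
    # grounded Dirichlet neighbours contribute 0 to the RHS
  }
  ti[[5L]] <- seq_len(nu); tj[[5L]] <- seq_len(nu)
  tx[[5L]] <- rep(-2 * (cy + cz), nu)
  A <- Matrix::sparseMatrix(i = unlist(ti), j = unlist(tj), x = unlist(tx),
                            dims = c(nu, nu))
  nvolt <- geometry$n_bottom +
    if (frame == "dual") geometry$n_top else 0L
  R <- Matrix::sparseMatrix(i = unlist(ri), j = unlist(rj), x = unlist(rx),
                            dims = c(nu, nvolt))
  structure(list(
    geometry = geometry, frame = frame,
    spacing_y = sy, spacing_z = sz, ny = ny, nz = nz,
    ys = seq(0, L, length.out = ny), zs = seq(0, h, length.out = nz),
    unknown = unknown, dir_col = dir_col, diag_scale = 2 * (cy + cz),
    lu = Matrix::lu(A), A = A, rhs_map = R
  ), class = "laplace_operator")
}

#' @export
print.laplace_operator <- function(x, ...) {
  cat(sprintf("<laplace_operator> %s frame, %d x %d grid (%.3g x %.3g um)\n",
              x$frame, x$ny, x$nz, x$spacing_y * 1e6, x$spacing_z * 1e6))
  invisible(x)
}

#' Solve the exact boundary-value problem on a grid
#'
#' Numerical oracle for the analytical field model: solves the Laplace
#' equation with Dirichlet data on the electrode strips and zero normal flux
#' on gaps and lateral walls (the exact conditions, not the linear-gap /
#' mirror approximation behind the Fourier series). Direct sparse solve; the
#' residual is checked against `1e-10 * max |u|`.
#'
#' @param x A [channel_geometry()] or a prebuilt [laplace_operator()] (reuse
#'   the operator when solving many voltage patterns).
#' @param voltages A [voltage_pattern()]; `u_top` is required in the dual
#'   frame and ignored in the single frame.
#' @param spacing,frame Passed to [laplace_operator()] when `x` is a
#'   geometry.
#' @return Object of class `reference_solution`: the gridded potential
#'   (`phi`, an `ny x nz` matrix over `ys` by `zs`), grid metadata, and the
#'   inputs. In the dual frame grid heights `zs` run over `[0, h]`; the dual
#'   frame coordinate is `z = zs - h/2`.
#' @examples
#' geo <- channel_geometry(60e-6, 60e-6, 2)
#' sol <- solve_laplace_fd(geo, voltage_pattern(c(1, 1), c(0, 0), geo),
#'                         spacing = 2e-6)
#' @export
solve_laplace_fd <- function(x, voltages, spacing = 0.5e-6,
                             frame = c("dual", "single")) {
  if (inherits(x, "channel_geometry")) {
    op <- laplace_operator(x, spacing = spacing, frame = match.arg(frame))
  } else if (inherits(x, "laplace_operator")) {
    op <- x
  } else stop("x must be a channel_geometry or laplace_operator",
              call. = FALSE)
  stopifnot(inherits(voltages, "voltage_pattern"))
  geo <- op$geometry
  if (length(voltages$u_bottom) != geo$n_bottom)
    stop("u_bottom length does not match geometry", call. = FALSE)
  if (op$frame == "dual") {
    if (is.null(voltages$u_top) || length(voltages$u_top) != geo$n_top)
      stop("dual frame requires u_top of length n_top", call. = FALSE)
    uvec <- c(voltages$u_bottom, voltages$u_top)
  } else {
    uvec <- voltages$u_bottom
  }
  b <- as.numeric(op$rhs_map %*% uvec)
  xsol <- as.numeric(Matrix::solve(op$lu, b))
  umax <- max(abs(uvec), 1e-300)
  # raw residual has units V / m^2 (stencil scale); normalise to volts
  res <- max(abs(as.numeric(op$A %*% xsol) - b)) / op$diag_scale
  if (res > 1e-10 * umax)
    stop(sprintf("linear solve residual %.3e exceeds tolerance %.3e",
                 res, 1e-10 * umax), call. = FALSE)
  phi <- numeric(op$ny * op$nz)
  phi[op$unknown] <- xsol
  driven <- op$dir_col > 0L
  phi[driven] <- uvec[op$dir_col[driven]]
  # grounded nodes (dir_col == -1) stay 0
  dim(phi) <- c(op$ny, op$nz)
  structure(list(
    phi = phi, ys = op$ys, zs = op$zs,
    spacing_y = op$spacing_y, spacing_z = op$spacing_z,
    geometry = geo, frame = op$frame, voltages = voltages,
    residual = res
  ), class = "reference_solution")
}

#' @export
print.reference_solution <- function(x, ...) {
  cat(sprintf(
    "<reference_solution> %s frame, %d x %d grid, residual %.2e V\n",
    x$frame, length(x$ys), length(x$zs), x$residual))
  invisible(x)
}

# central-difference derivative grids (interior nodes only; border rows and
# columns are left NA and excluded by the interpolation-domain check)
.ref_derivatives <- function(sol) {
  p <- sol$phi; sy <- sol$spacing_y; sz <- sol$spacing_z
  ny <- nrow(p); nz <- ncol(p)
  pad <- function() matrix(NA_real_, ny, nz)
  i <- 2:(ny - 1); j <- 2:(nz - 1)
  dy <- pad(); dz <- pad(); dyy <- pad(); dzz <- pad(); dyz <- pad()
  dy[i, ] <- (p[i + 1, ] - p[i - 1, ]) / (2 * sy)
  dz[, j] <- (p[, j + 1] - p[, j - 1]) / (2 * sz)
  dyy[i, ] <- (p[i + 1, ] - 2 * p[i, ] + p[i - 1, ]) / sy^2
  dzz[, j] <- (p[, j + 1] - 2 * p[, j] + p[, j - 1]) / sz^2
  dyz[i, j] <- (p[i + 1, j + 1] - p[i + 1, j - 1] -
                  p[i - 1, j + 1] + p[i - 1, j - 1]) / (4 * sy * sz)
  list(phi = p, dphi_dy = dy, dphi_dz = dz,
       d2phi_dy2 = dyy, d2phi_dydz = dyz, d2phi_dz2 = dzz)
}

#' Field sample interpolated from a reference solution
#'
#' Derivatives are formed by central differences on the grid and then, like
#' the potential itself, interpolated bilinearly at the query points. Points
#' must lie at least two cells away from every boundary so that the
#' derivative stencils are complete.
#'
#' @param solution A [solve_laplace_fd()] result.
#' @param y,z Query positions in metres, expressed in the solution's frame
#'   (dual: `z` in `[-h/2, h/2]`; single: `z` in `[0, h]`).
#' @return A `field_sample` data frame (same columns as [field_sample()]).
#' @export
reference_field_sample <- function(solution, y, z) {
  stopifnot(inherits(solution, "reference_solution"))
  n <- max(length(y), length(z))
  y <- rep_len(y, n); z <- rep_len(z, n)
  h <- solution$geometry$height_h
  zg <- if (solution$frame == "dual") z + h / 2 else z
  sy <- solution$spacing_y; sz <- solution$spacing_z
  L <- solution$geometry$width_L
  if (any(y < 2 * sy - 1e-15 | y > L - 2 * sy + 1e-15 |
          zg < 2 * sz - 1e-15 | zg > h - 2 * sz + 1e-15))
    stop("query point closer than 2 cells to a boundary ",
         "(derivative stencil incomplete)", call. = FALSE)
  der <- .ref_derivatives(solution)
  ny <- length(solution$ys)
  nz <- length(solution$zs)
  i0 <- pmin(pmax(floor(y / sy) + 1, 2), ny - 2)
  j0 <- pmin(pmax(floor(zg / sz) + 1, 2), nz - 2)
  fx <- y / sy - (i0 - 1)
  fz <- zg / sz - (j0 - 1)
  interp <- function(M) {
    M[cbind(i0, j0)] * (1 - fx) * (1 - fz) +
      M[cbind(i0 + 1, j0)] * fx * (1 - fz) +
      M[cbind(i0, j0 + 1)] * (1 - fx) * fz +
      M[cbind(i0 + 1, j0 + 1)] * fx * fz
  }
  out <- data.frame(y = y, z = z,
                    phi = interp(der$phi),
                    dphi_dy = interp(der$dphi_dy),
                    dphi_dz = interp(der$dphi_dz),
                    d2phi_dy2 = interp(der$d2phi_dy2),
                    d2phi_dydz = interp(der$d2phi_dydz),
                    d2phi_dz2 = interp(der$d2phi_dz2))
  class(out) <- c("field_sample", "data.frame")
  out
}
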