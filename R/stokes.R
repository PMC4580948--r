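#' Flow parameters and physical scales
#'
#' Nondimensionalization scales for the creeping-flow problem: length
#' `L` = 50 um, active-transport velocity `V` = 0.5 um/s, time `tau` =
#' `L/V` = 100 s.  The force-velocity coupling `a_prime` converts the
#' normalized motor-velocity field into a volumetric force density
#' \eqn{f' = a' v'_m}; `a_prime = 45` is the standard calibration for
#' geometry-1 (55 for geometry-2), chosen so mean dimensional flow speeds
#' match measured cytoplasmic streaming.  The Reynolds number bound
#' justifies dropping inertia.
#'
#' @param a_prime Nondimensional force-velocity coupling.
#' @param L Length scale (um).  @param V Velocity scale (um/s).
#' @return A list of class `flow_params` with the scales and derived
#'   quantities (`tau`, pressure/force scales for bookkeeping).
#' @export
flow_params <- function(a_prime = 45, L = 50, V = 0.5) {
  stopifnot(a_prime > 0, L > 0, V > 0)
  structure(list(a_prime = a_prime, L = L, V = V, tau = L / V),
            class = "flow_params")
}

#' Upper bound on the Reynolds number of cytoplasmic streaming
#'
#' \eqn{Re = \rho V L / \mu} with conservative bounds for cytoplasm
#' (viscosity at least that of water, density at most ten times water),
#' giving \eqn{Re \le 2.5\times 10^{-4}} at the default scales.
#'
#' @param rho Density bound (kg/m^3, default 1e4).
#' @param mu Viscosity bound (Pa s, default 1e-3).
#' @param V Velocity scale (m/s, default 0.5e-6).
#' @param L Length scale (m, default 50e-6).
#' @export
reynolds_bound <- function(rho = 1e4, mu = 1e-3, V = 0.5e-6, L = 50e-6) {
  rho * V * L / mu
}

#' Low-level steady Stokes solve on a masked MAC grid
#'
#' Solves \eqn{-\nabla^2 u + \nabla p = f}, \eqn{\nabla\cdot u = 0} with
#' no-slip on the (staircase) boundary of the masked region, by conjugate
#' gradients on the pressure Schur complement with inner CG solves of the
#' vector Laplacian.  Exposed for validation against analytic solutions on
#' simple masks; [solve_stokes()] is the oocyte-level interface.
#'
#' @param mask Logical (or 0/1) 3D array marking interior cells.
#' @param h Cell size.
#' @param fx,fy,fz Force-density arrays on cell centers, same shape.
#' @param tol Relative tolerance on the outer (divergence) residual.
#' @param maxit_outer,maxit_inner Iteration caps.
#' @param tol_inner Relative tolerance of the inner Laplacian solves.
#' @return A list with cell-centered velocity arrays `ux`, `uy`, `uz`,
#'   pressure `p`, `max_div` and iteration counts.
#' @export
stokes_mac_solve <- function(mask, h, fx, fy, fz, tol = 1e-8,
                             maxit_outer = 500, maxit_inner = 20000,
                             tol_inner = 1e-10) {
  dm <- dim(mask)
  stopifnot(length(dm) == 3, identical(dim(fx), dm),
            identical(dim(fy), dm), identical(dim(fz), dm), h > 0)
  cpp_stokes_mac(as.integer(mask), as.integer(dm),
                 as.numeric(fx), as.numeric(fy), as.numeric(fz),
                 h, tol, as.integer(maxit_outer), as.integer(maxit_inner),
                 tol_inner)
}

## erode a logical 3D mask by one cell (6-neighbourhood): TRUE only where
## the cell and all face neighbours are inside
erode_mask <- function(mask) {
  dm <- dim(mask)
  out <- mask
  pad <- function(shift_dim, by) {
    m <- array(FALSE, dm)
    idx_src <- idx_dst <- lapply(dm, seq_len)
    n <- dm[shift_dim]
    if (by == 1) {
      idx_dst[[shift_dim]] <- 1:(n - 1); idx_src[[shift_dim]] <- 2:n
    } else {
      idx_dst[[shift_dim]] <- 2:n; idx_src[[shift_dim]] <- 1:(n - 1)
    }
    m[idx_dst[[1]], idx_dst[[2]], idx_dst[[3]]] <-
      mask[idx_src[[1]], idx_src[[2]], idx_src[[3]]]
    m
  }
  for (d in 1:3) for (b in c(1, -1)) out <- out & pad(d, b)
  out
}

## solver grid over the oocyte bounding box [-1,1]^2 x [0, z0P]
stokes_grid <- function(geom, h) {
  nx <- round(2 / h)
  nz <- round(geom$z0P / h)
  x <- -1 + (seq_len(nx) - 0.5) * h
  z <- (seq_len(nz) - 0.5) * (geom$z0P / nz)
  list(x = x, y = x, z = z, h = h, dim = c(nx, nx, nz))
}

## vectorized trilinear interpolation from a regular grid (cell centers
## x0 + (i-1) dx) to arbitrary points; outside the node hull values clamp to
## the nearest layer unless zero_outside, in which case they vanish
trilinear_interp <- function(xg, yg, zg, arr, pts, zero_outside = FALSE) {
  n <- nrow(pts)
  loc <- function(g, v) {
    dx <- g[2] - g[1]
    t <- (v - g[1]) / dx
    i0 <- floor(t)
    f <- t - i0
    i0 <- pmin(pmax(i0, 0), length(g) - 2)
    f <- pmin(pmax(t - i0, 0), 1)
    list(i = i0 + 1L, f = f)
  }
  lx <- loc(xg, pts[, 1]); ly <- loc(yg, pts[, 2]); lz <- loc(zg, pts[, 3])
  dm <- dim(arr)
  at <- function(i, j, k) arr[cbind(i, j, k)]
  v <- (1 - lx$f) * (1 - ly$f) * (1 - lz$f) * at(lx$i, ly$i, lz$i) +
    lx$f * (1 - ly$f) * (1 - lz$f) * at(lx$i + 1L, ly$i, lz$i) +
    (1 - lx$f) * ly$f * (1 - lz$f) * at(lx$i, ly$i + 1L, lz$i) +
    lx$f * ly$f * (1 - lz$f) * at(lx$i + 1L, ly$i + 1L, lz$i) +
    (1 - lx$f) * (1 - ly$f) * lz$f * at(lx$i, ly$i, lz$i + 1L) +
    lx$f * (1 - ly$f) * lz$f * at(lx$i + 1L, ly$i, lz$i + 1L) +
    (1 - lx$f) * ly$f * lz$f * at(lx$i, ly$i + 1L, lz$i + 1L) +
    lx$f * ly$f * lz$f * at(lx$i + 1L, ly$i + 1L, lz$i + 1L)
  if (zero_outside) {
    out <- pts[, 1] < xg[1] | pts[, 1] > xg[length(xg)] |
      pts[, 2] < yg[1] | pts[, 2] > yg[length(yg)] |
      pts[, 3] < zg[1] | pts[, 3] > zg[length(zg)]
    v[out] <- 0
  }
  v
}

#' Solve the cytoplasmic Stokes flow forced by a motor-velocity field
#'
#' The volumetric force \eqn{f' = a' v'_m} is trilinearly interpolated from
#' the coarse motor grid onto the solver grid (cells outside the oocyte, or
#' outside the motor grid's extent, carry zero force), and the steady
#' incompressible Stokes equations are solved with no-slip walls on the
#' oocyte surface — and, optionally, on a sphere representing the nucleus.
#'
#' @param motor A `motor_field` from [coarse_grain()] (or
#'   [ensemble_average()]).
#' @param a_prime Force-velocity coupling (default 45, the geometry-1
#'   calibration).
#' @param h Solver cell size (default: the motor grid's `dG`).
#' @param nucleus `NULL`, or `list(center = c(x, y, z), r = radius)` for a
#'   spherical excluded volume with its own no-slip boundary.
#' @param tol Outer solver tolerance (relative divergence residual).
#' @param ... Passed to [stokes_mac_solve()].
#' @return An object of class `flow_field`: nondimensional velocity arrays
#'   `ux, uy, uz` on the solver grid, the grid, `max_div`, `a_prime` and
#'   provenance metadata.
#' @export
solve_stokes <- function(motor, a_prime = 45, h = NULL, nucleus = NULL,
                         tol = 1e-8, ...) {
  stopifnot(inherits(motor, "motor_field"), a_prime > 0)
  geom <- motor$grid$geometry
  if (is.null(h)) h <- motor$grid$dG
  sg <- stokes_grid(geom, h)
  centers <- as.matrix(expand.grid(x = sg$x, y = sg$y, z = sg$z))
  mask <- geom_contains(geom, centers)
  if (!is.null(nucleus)) {
    d2 <- (centers[, 1] - nucleus$center[1])^2 +
      (centers[, 2] - nucleus$center[2])^2 +
      (centers[, 3] - nucleus$center[3])^2
    mask <- mask & d2 > nucleus$r^2
  }
  mask <- array(mask, dim = sg$dim)
  g <- motor$grid
  comp <- function(arr) {
    f <- trilinear_interp(g$x, g$y, g$z, arr, centers, zero_outside = TRUE)
    array(f * a_prime * as.numeric(mask), dim = sg$dim)
  }
  sol <- stokes_mac_solve(mask, h, comp(motor$vx), comp(motor$vy),
                          comp(motor$vz), tol = tol, ...)
  structure(list(
    ux = sol$ux, uy = sol$uy, uz = sol$uz, p = sol$p,
    faces = list(x = sol$ufx, y = sol$ufy, z = sol$ufz),
    grid = sg, mask = mask, max_div = sol$max_div,
    outer_iterations = sol$outer_iterations,
    a_prime = a_prime, nucleus = nucleus, geometry = geom),
    class = "flow_field")
}

#' @export
print.flow_field <- function(x, ...) {
  cat(sprintf(
    "<flow_field> %d x %d x %d grid (h = %g), a' = %g, max |div u| = %.2e\n",
    x$grid$dim[1], x$grid$dim[2], x$grid$dim[3], x$grid$h, x$a_prime,
    x$max_div))
  invisible(x)
}

#' Mean flow speeds of a flow field
#'
#' `"3d"` mode averages the velocity magnitude over all interior cells.
#' `"2d"` mode averages the speed of the 3D field sampled on the central
#' cross-section plane `y = 0` (for these flows the two statistics are
#' close, with the cross-section slightly faster, since streaming is
#' strongest around the AP axis).  `"2d_inplane"` additionally projects out
#' the out-of-plane component, emulating what particle image velocimetry
#' sees in a confocal section.
#'
#' @param flow A `flow_field` (or list of them; stats pool all cells).
#' @param mode `"3d"`, `"2d"` or `"2d_inplane"`.
#' @param V Velocity scale in um/s (default 0.5); speeds are returned in
#'   nm/s.
#' @return A list with `mean_nm_s`, `sd_nm_s` and `n_cells`.
#' @export
speed_stats <- function(flow, mode = c("3d", "2d", "2d_inplane"), V = 0.5) {
  mode <- match.arg(mode)
  flows <- if (inherits(flow, "flow_field")) list(flow) else flow
  sp <- unlist(lapply(flows, function(fl) {
    m <- fl$mask
    if (mode == "3d") {
      sqrt(fl$ux[m]^2 + fl$uy[m]^2 + fl$uz[m]^2)
    } else {
      jmid <- which.min(abs(fl$grid$y))
      sel <- m[, jmid, ]
      uy2 <- if (mode == "2d") fl$uy[, jmid, ][sel]^2 else 0
      sqrt(fl$ux[, jmid, ][sel]^2 + uy2 + fl$uz[, jmid, ][sel]^2)
    }
  }))
  list(mean_nm_s = mean(sp) * V * 1000, sd_nm_s = stats::sd(sp) * V * 1000,
       n_cells = length(sp))
}

#' Calibrate the force-velocity coupling to a target mean speed
#'
#' Stokes flow is linear in the forcing, so after one solve at a reference
#' coupling `a0` the calibrated value is
#' \eqn{a' = a_0 \cdot \mathrm{target} / \mathrm{speed}(a_0)}, using the
#' ensemble-mean 3D speed over the supplied motor fields.
#'
#' @param motors A list of `motor_field` objects (>= 1).
#' @param target Target mean 3D speed in nm/s (default 14.5).
#' @param a0 Reference coupling for the probe solves.
#' @param V Velocity scale (um/s).
#' @param ... Passed to [solve_stokes()].
#' @return A list with `a_prime`, `target`, `achieved` (the speed implied
#'   at the calibrated coupling), `a0_speed` and `n_fields`.
#' @export
calibrate_a_prime <- function(motors, target = 14.5, a0 = 45, V = 0.5, ...) {
  if (inherits(motors, "motor_field")) motors <- list(motors)
  stopifnot(length(motors) >= 1, target > 0)
  flows <- lapply(motors, solve_stokes, a_prime = a0, ...)
  s0 <- speed_stats(flows, "3d", V = V)$mean_nm_s
  if (s0 <= 0) stop("zero motor field: cannot calibrate")
  a <- a0 * target / s0
  list(a_prime = a, target = target, achieved = s0 * a / a0,
       a0_speed = s0, n_fields = length(motors))
}

#' Interpolate a flow field onto a coarse grid
#'
#' Trilinear interpolation of the solver-grid velocity onto the cell
#' centers of a [coarse_grid()] (e.g. the transport grid); cells outside
#' the oocyte get zero velocity.
#'
#' @param flow A `flow_field`.
#' @param grid A [coarse_grid()].
#' @return A list of arrays `ux, uy, uz` on the coarse grid.  When the
#'   solver grid coincides cell-for-cell with `grid` (same `h`, aligned
#'   layers), the solver's staggered face velocities are attached as
#'   `faces`; the transport stepper then advects with the exactly
#'   divergence-free field instead of re-averaged cell values.
#' @export
flow_on_grid <- function(flow, grid) {
  stopifnot(inherits(flow, "flow_field"), inherits(grid, "coarse_grid"))
  centers <- as.matrix(expand.grid(x = grid$x, y = grid$y, z = grid$z))
  inside <- as.numeric(grid$inside)
  sg <- flow$grid
  comp <- function(arr)
    array(trilinear_interp(sg$x, sg$y, sg$z, arr, centers) * inside,
          dim = grid$dim)
  out <- list(ux = comp(flow$ux), uy = comp(flow$uy), uz = comp(flow$uz))
  ## aligned grids: carry the divergence-free staggered field along
  k0 <- (grid$z[1] - sg$z[1]) / grid$dG
  if (abs(sg$h - grid$dG) < 1e-12 &&
      abs(sg$x[1] - grid$x[1]) < 1e-9 &&
      abs(k0 - round(k0)) < 1e-6 &&
      sg$dim[3] >= round(k0) + grid$dim[3]) {
    k0 <- round(k0)
    kz <- k0 + seq_len(grid$dim[3])
    out$faces <- list(
      x = flow$faces$x[, , kz, drop = FALSE],
      y = flow$faces$y[, , kz, drop = FALSE],
      z = flow$faces$z[, , k0 + seq_len(grid$dim[3] + 1), drop = FALSE])
  }
  out
}
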