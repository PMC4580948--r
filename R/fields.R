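#' Coarse-grained cubic grid over the oocyte
#'
#' Regular grid of cubic cells with nondimensional side `dG` (default 0.04).
#' Cell centers range over `[-1 + dG/2, 1 - dG/2]` in x and y and
#' `[z0A + dG/2, z0P - dG/2]` along the AP (z) axis.  Cells whose centers
#' fall outside the oocyte are flagged.
#'
#' @param geom An [oocyte_geometry()].
#' @param dG Cell side length (nondimensional).
#' @return An object of class `coarse_grid`: list with center coordinate
#'   vectors `x`, `y`, `z`, `dim`, `dG` and logical array `inside`.
#' @export
coarse_grid <- function(geom, dG = 0.04) {
  stopifnot(inherits(geom, "oocyte_geometry"), dG > 0)
  x <- seq(-1 + dG / 2, 1 - dG / 2 + 1e-12, by = dG)
  z <- seq(geom$z0A + dG / 2, geom$z0P - dG / 2 + 1e-12, by = dG)
  dm <- c(length(x), length(x), length(z))
  centers <- as.matrix(expand.grid(x = x, y = x, z = z))
  inside <- array(geom_contains(geom, centers), dim = dm)
  structure(list(x = x, y = x, z = z, dim = dm, dG = dG,
                 inside = inside, geometry = geom),
            class = "coarse_grid")
}

#' @export
print.coarse_grid <- function(x, ...) {
  cat(sprintf("<coarse_grid> %d x %d x %d cells, dG = %g (%d inside)\n",
              x$dim[1], x$dim[2], x$dim[3], x$dG, sum(x$inside)))
  invisible(x)
}

## linear cell index of points on a coarse grid; NA outside the grid box
grid_cell_index <- function(grid, pts) {
  ix <- round((pts[, 1] - grid$x[1]) / grid$dG) + 1
  iy <- round((pts[, 2] - grid$y[1]) / grid$dG) + 1
  iz <- round((pts[, 3] - grid$z[1]) / grid$dG) + 1
  ok <- ix >= 1 & ix <= grid$dim[1] & iy >= 1 & iy <= grid$dim[2] &
    iz >= 1 & iz <= grid$dim[3]
  out <- rep(NA_integer_, nrow(pts))
  out[ok] <- ix[ok] + grid$dim[1] * ((iy[ok] - 1) +
                                       grid$dim[2] * (iz[ok] - 1))
  out
}

#' Coarse-grain a cytoskeleton realization into a motor-velocity field
#'
#' The orientation unit vectors of all MT segments whose midpoints fall in
#' the same grid cell are vectorially summed; the resulting field is
#' normalized so the mean vector magnitude over occupied cells equals 1.
#' Per-cell segment counts are stored separately as the MT density map.
#'
#' @param realization A `cytoskeleton` from [grow_cytoskeleton()].
#' @param grid A [coarse_grid()]; defaults to the standard `dG = 0.04` grid.
#' @return An object of class `motor_field`: list with normalized component
#'   arrays `vx`, `vy`, `vz`, raw (unnormalized) sums `raw`, segment
#'   `counts`, the `grid` and the `normalization` constant.
#' @export
coarse_grain <- function(realization, grid = NULL) {
  stopifnot(inherits(realization, "cytoskeleton"))
  if (is.null(grid)) grid <- coarse_grid(realization$geometry)
  segs <- realization$segments
  if (nrow(segs) == 0) stop("realization has no segments")
  idx <- grid_cell_index(grid, segs[, 1:3, drop = FALSE])
  keep <- !is.na(idx)
  idx <- idx[keep]
  ntot <- prod(grid$dim)
  raw <- vapply(4:6, function(col) {
    v <- numeric(ntot)
    acc <- rowsum(segs[keep, col], idx)
    v[as.integer(rownames(acc))] <- acc[, 1]
    v
  }, numeric(ntot))
  counts <- numeric(ntot)
  tab <- tabulate(idx, nbins = ntot)
  counts <- tab
  mag <- sqrt(rowSums(raw^2))
  occ <- counts > 0
  norm <- mean(mag[occ])
  v <- raw / norm
  shape <- function(col) array(col, dim = grid$dim)
  structure(list(
    vx = shape(v[, 1]), vy = shape(v[, 2]), vz = shape(v[, 3]),
    raw = list(x = shape(raw[, 1]), y = shape(raw[, 2]),
               z = shape(raw[, 3])),
    counts = array(counts, dim = grid$dim),
    normalization = norm,
    n_segments = sum(keep),
    grid = grid),
    class = "motor_field")
}

#' @export
print.motor_field <- function(x, ...) {
  cat(sprintf("<motor_field> %d x %d x %d grid, %d segments in %d occupied cells\n",
              x$grid$dim[1], x$grid$dim[2], x$grid$dim[3],
              x$n_segments, sum(x$counts > 0)))
  invisible(x)
}

#' Directional bias of MT segments
#'
#' In `"3d"` mode, the percentage of all segments whose orientation has a
#' positive (posterior-pointing) component along the AP axis, versus
#' negative (anterior); segments with exactly zero axial component are split
#' evenly.  In `"slice"` mode the same statistic is restricted to segments
#' with midpoints inside a slab of thickness `dG` whose center plane lies at
#' lateral depth `depth` from the cortex along y (`depth = 1` is the mid
#' plane y = 0).
#'
#' All common conventions are reported: the posterior:anterior percentage
#' pair, the posterior percentage's excess over the unbiased 50% (the
#' convention in which the wild-type cytoskeleton shows "8.5% more"
#' posterior segments), and the full percentage-point difference.
#'
#' @param realization A `cytoskeleton` (or a segment matrix with
#'   orientation columns `ox, oy, oz` and midpoint columns `mx, my, mz`).
#' @param mode `"3d"` or `"slice"`.
#' @param depth Slab-center depth from the lateral cortex (slice mode).
#' @param dG Slab thickness (default 0.04).
#' @return A list with `frac_posterior`, `frac_anterior` (percent),
#'   `excess_pp` (percentage points), `n_segments`.
#' @export
directional_bias <- function(realization, mode = c("3d", "slice"),
                             depth = 1, dG = 0.04) {
  mode <- match.arg(mode)
  segs <- if (inherits(realization, "cytoskeleton"))
    realization$segments else realization
  if (mode == "slice") {
    y0 <- 1 - depth
    segs <- segs[abs(segs[, "my"] - y0) <= dG / 2, , drop = FALSE]
    if (nrow(segs) == 0) stop("empty slab at depth ", depth)
  }
  oz <- segs[, "oz"]
  n <- length(oz)
  pos <- sum(oz > 0) + sum(oz == 0) / 2
  frac_post <- 100 * pos / n
  list(frac_posterior = frac_post,
       frac_anterior = 100 - frac_post,
       excess_over_half = frac_post - 50,
       excess_pp = 2 * frac_post - 100,
       n_segments = n)
}

#' Ensemble average of motor-velocity fields
#'
#' Per-cell vector sums across realizations, taken before each
#' realization's normalization, plus pooled segment counts.  The summed
#' field is then normalized to mean vector magnitude 1 over occupied cells,
#' like a single-realization motor field.
#'
#' @param fields A list of `motor_field` objects on the same grid.
#' @return A `motor_field` containing the ensemble mean orientation field.
#' @export
ensemble_average <- function(fields) {
  stopifnot(length(fields) >= 2,
            all(vapply(fields, inherits, logical(1), "motor_field")))
  dm <- fields[[1]]$grid$dim
  for (f in fields)
    if (!identical(f$grid$dim, dm) || f$grid$dG != fields[[1]]$grid$dG)
      stop("motor fields live on different grids")
  raw <- list(x = 0, y = 0, z = 0)
  counts <- 0
  nseg <- 0
  for (f in fields) {
    raw$x <- raw$x + f$raw$x
    raw$y <- raw$y + f$raw$y
    raw$z <- raw$z + f$raw$z
    counts <- counts + f$counts
    nseg <- nseg + f$n_segments
  }
  mag <- sqrt(raw$x^2 + raw$y^2 + raw$z^2)
  occ <- counts > 0
  norm <- mean(mag[occ])
  structure(list(
    vx = raw$x / norm, vy = raw$y / norm, vz = raw$z / norm,
    raw = raw, counts = counts, normalization = norm,
    n_segments = nseg, grid = fields[[1]]$grid),
    class = "motor_field")
}

#' Unbiased temporal vector autocorrelation of a field sequence
#'
#' For a sequence of vector fields \eqn{u(n)}, \eqn{n = 0, \dots, N-1},
#' sampled on a common grid,
#' \deqn{C(k) = \left\langle \frac{1}{N - k} \sum_i \sum_{n=0}^{N-1-k}
#'   u_i(n + k)\, u_i(n) \right\rangle,}
#' averaged over grid points, then normalized so the peak value is 1.
#'
#' @param fields A list of numeric matrices (grid points x components) or
#'   vectors, all the same shape, ordered in time.
#' @param lags Integer lags to evaluate (default `0:(N-1)`).
#' @return A data frame with `lag` and `C`.
#' @export
field_autocorrelation <- function(fields, lags = NULL) {
  N <- length(fields)
  stopifnot(N >= 2)
  flat <- lapply(fields, function(f) as.numeric(f))
  len <- lengths(flat)
  if (any(len != len[1])) stop("fields differ in shape")
  if (is.null(lags)) lags <- 0:(N - 1)
  if (any(lags >= N)) stop("lag must be smaller than the sequence length")
  C <- vapply(lags, function(k) {
    s <- 0
    for (n in seq_len(N - k))
      s <- s + sum(flat[[n + k]] * flat[[n]])
    s / (N - k) / len[1]
  }, numeric(1))
  data.frame(lag = lags, C = C / max(C))
}

#' Cortical density profile of a realization's segment counts
#'
#' Bins MT segment counts by the arclength coordinate of their nearest
#' cortical point (posterior cap), normalized per bin area, for checks of
#' the AP density gradient.
#'
#' @param field A `motor_field` (its `counts` array is used).
#' @param n_bins Number of arclength bins.
#' @return A data frame with bin center `s_frac` (fraction of s0) and mean
#'   cell `density` among oocyte-interior cells in each bin.
#' @export
cortical_density_profile <- function(field, n_bins = 10) {
  grid <- field$grid
  geom <- grid$geometry
  centers <- as.matrix(expand.grid(x = grid$x, y = grid$y, z = grid$z))
  inside <- as.vector(grid$inside)
  rho <- pmin(sqrt(centers[, 1]^2 + centers[, 2]^2), 1)
  ## distance to the posterior cap surface along z, as a cheap cortical tag
  dz <- geom$z0P * (1 - rho^2) - centers[, 3]
  cortical <- inside & dz >= 0 & dz < 3 * grid$dG
  s <- cap_arclength(geom, "posterior", rho[cortical])
  s0 <- cap_arclength(geom, "posterior", 1)
  bin <- cut(s / s0, seq(0, 1, length.out = n_bins + 1), include.lowest = TRUE)
  dens <- tapply(as.vector(field$counts)[cortical], bin, mean)
  data.frame(s_frac = (seq_len(n_bins) - 0.5) / n_bins,
             density = as.numeric(dens))
}
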