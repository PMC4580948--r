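#' Build a library of motor/flow field pairs
#'
#' Generates `n` independent cytoskeleton realizations, coarse-grains each
#' into a motor-velocity field on `grid`, and (optionally) solves the
#' forced Stokes flow for each — producing the field-pair library that
#' transport simulations cycle through to emulate network turnover.
#'
#' @param n Number of field pairs.
#' @param geom An [oocyte_geometry()].
#' @param seeding A [seeding_params()].
#' @param polymer A [polymer_params()].
#' @param grid The transport [coarse_grid()].
#' @param flow Solve Stokes flows? (`FALSE` stores `u = NULL`.)
#' @param a_prime Force-velocity coupling for the flow solves.
#' @param h Stokes solver cell size (default: `grid$dG`).
#' @param stokes_tol Outer Stokes tolerance.
#' @param cam_patch Optional CAM patch spec passed to [add_cam_patch()].
#' @param seed RNG seed (realization i uses `seed + i`).
#' @param keep_realizations Also return the realizations (memory-heavy).
#' @return A list of pairs `list(vm = <motor arrays>, u = <flow arrays or
#'   NULL>)`, with the motor fields' bias summaries attached as an
#'   attribute.
#' @export
build_field_pairs <- function(n, geom, seeding, polymer, grid,
                              flow = TRUE, a_prime = 45, h = NULL,
                              stokes_tol = 1e-6, cam_patch = NULL,
                              seed = 1, keep_realizations = FALSE) {
  stopifnot(n >= 1)
  pairs <- vector("list", n)
  reals <- if (keep_realizations) vector("list", n) else NULL
  for (i in seq_len(n)) {
    seeds <- sample_seeds(geom, seeding, seed = seed + i)
    if (!is.null(cam_patch))
      seeds <- do.call(add_cam_patch, c(list(seeds), cam_patch))
    real <- grow_cytoskeleton(seeds, polymer)
    mf <- coarse_grain(real, grid)
    u <- NULL
    if (flow) {
      fl <- solve_stokes(mf, a_prime = a_prime, h = h, tol = stokes_tol)
      u <- flow_on_grid(fl, grid)
    }
    pairs[[i]] <- list(vm = list(ux = mf$vx, uy = mf$vy, uz = mf$vz), u = u)
    if (keep_realizations) reals[[i]] <- real
  }
  if (keep_realizations) attr(pairs, "realizations") <- reals
  pairs
}

#' Reduced-scale fixture configuration
#'
#' A deterministic, self-contained configuration small enough that every
#' pipeline stage runs in seconds: few anterior seeds, a coarse grid, short
#' durations.  Used by the test suite and the command line `--fixture`
#' flag.
#'
#' @param N_A Anterior seed count (default 500).
#' @param dG Coarse-grid cell size (default 0.1).
#' @param n_pairs Field pairs in the library (default 3).
#' @param duration_hr Scenario duration (default 0.5).
#' @param seed Base RNG seed.
#' @return A list with `geom`, `seeding`, `polymer`, `grid`, `transport`,
#'   `n_pairs`, `duration_hr`, `seed`.
#' @export
make_fixture <- function(N_A = 500, dG = 0.1, n_pairs = 3,
                         duration_hr = 0.5, seed = 1) {
  geom <- oocyte_geometry("geometry1")
  list(geom = geom,
       seeding = seeding_params("wildtype", N_A = N_A),
       polymer = polymer_params(),
       grid = coarse_grid(geom, dG),
       transport = transport_params(),
       n_pairs = n_pairs, duration_hr = duration_hr, seed = seed)
}

#' Export seed points as CSV
#'
#' Columns `cap, rho, phi, s, x, y, z, nx, ny, nz`, with a JSON metadata
#' sidecar recording geometry and density parameters.
#'
#' @param seeds A `seed_points` data frame.
#' @param file Output CSV path (metadata written to `<file>.meta.json`).
#' @export
export_seeds_csv <- function(seeds, file) {
  stopifnot(inherits(seeds, "seed_points"))
  utils::write.csv(as.data.frame(seeds), file, row.names = FALSE)
  geom <- attr(seeds, "geometry"); par <- attr(seeds, "params")
  meta <- list(geometry = geom[c("z0A", "z0P", "L", "preset")],
               seeding = par[c("h0A", "kA", "h0P", "kP", "N_A", "preset")],
               counts = attr(seeds, "counts"),
               rng_seed = attr(seeds, "seed"))
  jsonlite::write_json(meta, paste0(file, ".meta.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(file)
}

#' Write fields to a legacy ASCII VTK structured-points file
#'
#' Writes one or more scalar or 3-vector fields sampled on a regular grid
#' as `STRUCTURED_POINTS` legacy VTK, readable by ParaView and VisIt.
#'
#' @param file Output path.
#' @param origin,spacing Grid origin and spacing (length 3).
#' @param dims Grid dimensions (length 3).
#' @param fields Named list; each element either a numeric array (scalar
#'   field) or a list of three arrays (vector field), all of shape `dims`.
#' @export
write_vtk_structured <- function(file, origin, spacing, dims, fields) {
  stopifnot(length(origin) == 3, length(spacing) == 3, length(dims) == 3,
            length(fields) >= 1, !is.null(names(fields)))
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               "ooplasm field export", "ASCII",
               "DATASET STRUCTURED_POINTS",
               sprintf("DIMENSIONS %d %d %d", dims[1], dims[2], dims[3]),
               sprintf("ORIGIN %g %g %g", origin[1], origin[2], origin[3]),
               sprintf("SPACING %g %g %g", spacing[1], spacing[2],
                       spacing[3]),
               sprintf("POINT_DATA %d", prod(dims))), con)
  for (nm in names(fields)) {
    f <- fields[[nm]]
    if (is.list(f)) {
      writeLines(sprintf("VECTORS %s double", nm), con)
      m <- cbind(as.numeric(f[[1]]), as.numeric(f[[2]]),
                 as.numeric(f[[3]]))
      writeLines(sprintf("%.9g %.9g %.9g", m[, 1], m[, 2], m[, 3]), con)
    } else {
      writeLines(c(sprintf("SCALARS %s double 1", nm),
                   "LOOKUP_TABLE default"), con)
      writeLines(sprintf("%.9g", as.numeric(f)), con)
    }
  }
  invisible(file)
}

#' Serialize a motor or flow field for external use
#'
#' Writes the field to legacy VTK; following the convention that analysis
#' and visualization happen with the AP axis as x, components and axes are
#' relabelled from the internal z-along-AP frame to x-along-AP at this
#' serialization step (x' = z, y' = x, z' = y, a right-handed relabelling).
#'
#' @param field A `motor_field` or `flow_field`.
#' @param file Output path.
#' @export
export_field_vtk <- function(field, file) {
  if (inherits(field, "motor_field")) {
    g <- field$grid
    v <- list(field$vz, field$vx, field$vy)
    counts <- field$counts
    perm <- function(a) aperm(a, c(3, 1, 2))
    write_vtk_structured(file,
      origin = c(g$z[1], g$x[1], g$y[1]),
      spacing = rep(g$dG, 3), dims = c(g$dim[3], g$dim[1], g$dim[2]),
      fields = list(motor_velocity = lapply(v, perm),
                    segment_count = perm(counts)))
  } else if (inherits(field, "flow_field")) {
    g <- field$grid
    v <- list(field$uz, field$ux, field$uy)
    perm <- function(a) aperm(a, c(3, 1, 2))
    write_vtk_structured(file,
      origin = c(g$z[1], g$x[1], g$y[1]),
      spacing = c(g$h, g$h, g$h), dims = c(g$dim[3], g$dim[1], g$dim[2]),
      fields = list(flow_velocity = lapply(v, perm)))
  } else stop("unsupported field type")
  invisible(file)
}
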