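#' Cargo transport parameters
#'
#' Two-species reaction-advection-diffusion parameters for mRNA cargo.
#' The bound state (concentration `c_b`) is carried by the motor-velocity
#' field; the unbound state (`c_u`) is advected by the cytoplasmic flow and
#' diffuses.  Nondimensional groups are derived from the dimensional rates:
#' mean reaction rate \eqn{K = (k_b + k_u)/2}, Damkoehler number
#' \eqn{Da = L K / V}, Peclet number \eqn{Pe = L V / D}.  Defaults
#' (`k_u = 0.17` 1/s, `k_b = 0.0255` 1/s, `beta = 0.13`, `D = 0.02`
#' um^2/s) give `K = 0.09775`, `Da = 9.775` and `Pe = 1250`.
#'
#' The anchoring variant replaces the bound state by an anchored state that
#' binds only at the extreme posterior (rate constant `10 * k_b`, so
#' `K_anch = 0.1275` and `Da_anch = 12.75`) and never releases
#' (`beta_anch = 1`).
#'
#' @param k_u Unbinding rate constant (1/s).
#' @param k_b Binding rate constant (1/s).
#' @param beta Bound fraction at equilibrium (default 0.13).
#' @param D Diffusion constant of unbound cargo (um^2/s).
#' @param L,V Length (um) and velocity (um/s) scales.
#' @param dt Nondimensional time step (default 0.005).
#' @param steps_per_pair Steps per motor/flow field pair (default 432,
#'   i.e. 3.6 min of simulated time per pair at the default scales).
#' @param anchor_thickness Axial extent of the anchoring region at the
#'   posterior pole (nondimensional, default 0.08 = 4 um).
#' @return An object of class `transport_params` including the derived
#'   `K`, `Da`, `Pe`, `K_anch`, `Da_anch`.
#' @export
transport_params <- function(k_u = 0.17, k_b = 0.0255, beta = 0.13,
                             D = 0.02, L = 50, V = 0.5, dt = 0.005,
                             steps_per_pair = 432, anchor_thickness = 0.08) {
  stopifnot(k_u > 0, k_b > 0, beta > 0, beta < 1, D > 0, dt > 0)
  K <- (k_b + k_u) / 2
  ## anchored state: binding at 10 k_b, no release (k_u = 0)
  K_anch <- 10 * k_b / 2
  structure(list(
    k_u = k_u, k_b = k_b, beta = beta, D = D, L = L, V = V,
    K = K, Da = L * K / V, Pe = L * V / D,
    K_anch = K_anch, Da_anch = L * K_anch / V, beta_anch = 1,
    dt = dt, steps_per_pair = as.integer(steps_per_pair),
    anchor_thickness = anchor_thickness, tau = L / V),
    class = "transport_params")
}

#' @export
print.transport_params <- function(x, ...) {
  cat(sprintf(
    "<transport_params> Da = %g, Pe = %g, beta = %g, dt = %g (%d steps/pair)\n",
    x$Da, x$Pe, x$beta, x$dt, x$steps_per_pair))
  invisible(x)
}

#' Initial cargo distributions
#'
#' Builds a normalized (unit total mass) concentration array on a coarse
#' grid: an isotropic Gaussian cloud (`"gaussian"`, e.g. the central oskar
#' cloud of s.d. 0.15 or an injection bolus of s.d. 0.08), or a thin layer
#' of cells along the anterior surface (`"anterior_layer"`, two cells
#' thick), emulating conditioned bicoid entering from the nurse cells.
#'
#' @param grid A [coarse_grid()].
#' @param kind `"gaussian"` or `"anterior_layer"`.
#' @param center Gaussian center (default: AP-axis midpoint).
#' @param sd Gaussian standard deviation (default 0.15).
#' @return A concentration array (zero outside the oocyte, total mass 1).
#' @export
initial_condition <- function(grid, kind = c("gaussian", "anterior_layer"),
                              center = NULL, sd = 0.15) {
  kind <- match.arg(kind)
  geom <- grid$geometry
  centers <- as.matrix(expand.grid(x = grid$x, y = grid$y, z = grid$z))
  if (kind == "gaussian") {
    ## default center: the volume centroid of the two-cap solid, which for
    ## parabolic caps sits at z = (z0A + z0P)/3 on the axis
    if (is.null(center))
      center <- c(0, 0, (geom$z0A + geom$z0P) / 3)
    d2 <- (centers[, 1] - center[1])^2 + (centers[, 2] - center[2])^2 +
      (centers[, 3] - center[3])^2
    c0 <- exp(-d2 / (2 * sd^2))
  } else {
    ## cells within two cell layers of the anterior cap surface
    rho2 <- centers[, 1]^2 + centers[, 2]^2
    dz <- centers[, 3] - geom$z0A * (1 - rho2)
    c0 <- as.numeric(dz >= 0 & dz < 2 * grid$dG)
  }
  c0 <- c0 * as.numeric(grid$inside)
  if (sum(c0) == 0) stop("empty initial condition")
  array(c0 / sum(c0), dim = grid$dim)
}

#' Mass fraction in a polar slice
#'
#' Fraction of total cargo mass (all species) in cells within axial
#' distance `thickness` (default 0.08, i.e. 4 um) of the chosen pole.
#'
#' @param state A transport state: list with arrays `cb`, `cu` and
#'   optionally `ca` on `grid`.
#' @param grid The [coarse_grid()] the state lives on.
#' @param thickness Axial slice thickness (nondimensional).
#' @param pole `"posterior"` or `"anterior"`.
#' @export
slice_fraction <- function(state, grid, thickness = 0.08,
                           pole = c("posterior", "anterior")) {
  pole <- match.arg(pole)
  geom <- grid$geometry
  tot <- state$cb + state$cu + if (!is.null(state$ca)) state$ca else 0
  zi <- grid$z
  sel <- if (pole == "posterior") zi >= geom$z0P - thickness
  else zi <= geom$z0A + thickness
  sum(tot[, , sel]) / sum(tot)
}

## anchor region: the extreme posterior pole -- interior cells within
## Euclidean distance `extent` of the pole point (0, 0, z0P).  This is
## deliberately smaller than the 4 um readout slab: anchoring acts at the
## very posterior boundary only.
anchor_region <- function(grid, extent = 0.08) {
  geom <- grid$geometry
  centers <- as.matrix(expand.grid(x = grid$x, y = grid$y, z = grid$z))
  d2 <- centers[, 1]^2 + centers[, 2]^2 + (centers[, 3] - geom$z0P)^2
  arr <- array(d2 <= extent^2, dim = grid$dim) & grid$inside
  if (!any(arr)) stop("empty anchor region")
  arr
}

#' One explicit step block of the transport system
#'
#' Advances the state by `nsteps` explicit finite-volume steps under a
#' fixed motor/flow field pair.  Bound cargo is advected by the motor
#' field, unbound cargo by the flow field and diffusion; the species
#' exchange conservatively.  No-flux boundaries: faces touching masked
#' cells carry zero flux.  Errors out if the advective CFL number exceeds
#' one.
#'
#' @param state List with concentration arrays `cb`, `cu` (and `ca`).
#' @param vm Motor velocity component arrays `list(ux, uy, uz)` (or a
#'   `motor_field`, using `vx, vy, vz`).
#' @param u Flow velocity arrays `list(ux, uy, uz)`, or `NULL` for no flow.
#' @param grid The [coarse_grid()].
#' @param params A [transport_params()].
#' @param nsteps Number of time steps (default `params$steps_per_pair`).
#' @param motor_on Advect the bound species? (FALSE for anchor-only or
#'   diffusion-only scenarios.)
#' @param motor_sign +1 for plus-end (Kinesin, oskar) transport, -1 for
#'   minus-end (Dynein, bicoid).
#' @param anchor Logical anchor-region array to enable the anchored state,
#'   or `NULL`.
#' @return The updated state.
#' @export
transport_step <- function(state, vm, u, grid, params,
                           nsteps = NULL, motor_on = TRUE, motor_sign = 1,
                           anchor = NULL) {
  stopifnot(inherits(grid, "coarse_grid"),
            inherits(params, "transport_params"))
  if (is.null(nsteps)) nsteps <- params$steps_per_pair
  if (inherits(vm, "motor_field")) vm <- list(ux = vm$vx, uy = vm$vy,
                                              uz = vm$vz)
  zero <- array(0, dim = grid$dim)
  if (is.null(vm)) vm <- list(ux = zero, uy = zero, uz = zero)
  if (is.null(u)) u <- list(ux = zero, uy = zero, uz = zero)
  if (is.null(state$ca)) state$ca <- zero
  faces <- u$faces
  res <- cpp_transport_steps(
    as.integer(grid$inside), as.integer(grid$dim),
    motor_sign * vm$ux, motor_sign * vm$uy, motor_sign * vm$uz,
    u$ux, u$uy, u$uz,
    state$cb, state$cu, state$ca,
    as.integer(nsteps), params$dt, grid$dG,
    params$Da, params$beta, 1 / params$Pe,
    isTRUE(motor_on),
    if (is.null(anchor)) 0 else params$Da_anch,
    if (is.null(anchor)) integer(0) else as.integer(anchor),
    if (is.null(faces)) numeric(0) else as.numeric(faces$x),
    if (is.null(faces)) numeric(0) else as.numeric(faces$y),
    if (is.null(faces)) numeric(0) else as.numeric(faces$z))
  state$cb <- res$cb; state$cu <- res$cu; state$ca <- res$ca
  state
}

#' Named transport scenarios
#'
#' The scenario catalogue covering the simulated experiments: oskar
#' localisation in wild type with and without flows, the idealized
#' posterior anchor without motor transport, pure diffusion, naive bicoid
#' injections (minus-end transport) at three sites, conditioned bicoid
#' from the anterior surface, the par-1 hypomorph series (via their seeding
#' presets) and the CAM ectopic-nucleation patch.
#'
#' @return A named list of scenario definitions (lists with fields `name`,
#'   `init`, `motor_sign`, `flow_on`, `motor_on`, `anchor_on`,
#'   `seeding_preset`, `cam_patch`, `duration_hr`).
#' @export
scenario_presets <- function() {
  base <- list(motor_sign = 1, flow_on = TRUE, motor_on = TRUE,
               anchor_on = FALSE, seeding_preset = "wildtype",
               cam_patch = NULL, duration_hr = 6)
  make <- function(name, init, ...) {
    sc <- utils::modifyList(base, list(...))
    sc$name <- name; sc$init <- init
    sc
  }
  ## injection sites as fractions of the AP axis (z0A + frac * AP length)
  list(
    `oskar-wt` = make("oskar-wt",
      list(kind = "gaussian", center = NULL, sd = 0.15)),
    `oskar-no-flow` = make("oskar-no-flow",
      list(kind = "gaussian", center = NULL, sd = 0.15), flow_on = FALSE),
    `oskar-anchor-only` = make("oskar-anchor-only",
      list(kind = "gaussian", center = NULL, sd = 0.15),
      motor_on = FALSE, anchor_on = TRUE),
    `diffusion-only` = make("diffusion-only",
      list(kind = "gaussian", center = NULL, sd = 0.15),
      motor_on = FALSE, flow_on = FALSE),
    `bicoid-posterior` = make("bicoid-posterior",
      list(kind = "gaussian", site = "posterior-center", sd = 0.08),
      motor_sign = -1, duration_hr = 1.5),
    `bicoid-anterior-dorsal` = make("bicoid-anterior-dorsal",
      list(kind = "gaussian", site = "anterior-dorsal", sd = 0.08),
      motor_sign = -1, duration_hr = 1.5),
    `bicoid-anterior-middle` = make("bicoid-anterior-middle",
      list(kind = "gaussian", site = "anterior-middle", sd = 0.08),
      motor_sign = -1, duration_hr = 6),
    `bicoid-conditioned` = make("bicoid-conditioned",
      list(kind = "anterior_layer"), motor_sign = -1, duration_hr = 6),
    `par1-strong` = make("par1-strong",
      list(kind = "gaussian", center = NULL, sd = 0.15),
      seeding_preset = "par1-strong"),
    `par1-intermediate` = make("par1-intermediate",
      list(kind = "gaussian", center = NULL, sd = 0.15),
      seeding_preset = "par1-intermediate", duration_hr = 6),
    `par1-shallow` = make("par1-shallow",
      list(kind = "gaussian", center = NULL, sd = 0.15),
      seeding_preset = "par1-shallow"),
    `cam-patch` = make("cam-patch",
      list(kind = "gaussian", center = NULL, sd = 0.15),
      cam_patch = list(rho = 0.45, phi = pi / 2, radius = 0.25,
                       n_add = 2000))
  )
}

## resolve a named injection site to coordinates
injection_site <- function(site, geom) {
  ap <- geom$ap_length
  switch(site,
    "posterior-center" = c(0, 0, geom$z0A + 0.75 * ap),
    "anterior-dorsal"  = c(0, 0.5, geom$z0A + 0.2 * ap),
    "anterior-middle"  = c(0, 0, geom$z0A + 0.2 * ap),
    stop("unknown injection site: ", site))
}

#' Run a transport scenario over a precomputed field-pair library
#'
#' Cycles through the supplied motor/flow field pairs in seed-randomized
#' order, each pair active for `params$steps_per_pair` time steps, until
#' the scenario duration is reached.  Records the polar slice fraction and
#' axial center of mass after each activation.
#'
#' @param scenario One entry of [scenario_presets()] (or a compatible
#'   list).
#' @param pairs List of field pairs: each `list(vm = <motor arrays or
#'   motor_field>, u = <flow arrays or NULL>)`, all on `grid`.
#' @param grid The transport [coarse_grid()].
#' @param params A [transport_params()].
#' @param duration_hr Simulated duration in hours (default: scenario's).
#' @param seed RNG seed for the pair ordering.
#' @return A list with the final `state`, a data frame `series` (time in
#'   hours, posterior and anterior slice fractions, axial center of mass),
#'   and the scenario.
#' @export
run_scenario <- function(scenario, pairs, grid, params = transport_params(),
                         duration_hr = NULL, seed = NULL) {
  stopifnot(length(pairs) >= 1, inherits(grid, "coarse_grid"))
  if (!is.null(seed)) set.seed(seed)
  if (is.null(duration_hr)) duration_hr <- scenario$duration_hr
  geom <- grid$geometry
  init <- scenario$init
  center <- if (!is.null(init$site)) injection_site(init$site, geom)
  else init$center
  c0 <- if (init$kind == "anterior_layer")
    initial_condition(grid, "anterior_layer")
  else initial_condition(grid, "gaussian", center = center, sd = init$sd)
  ## start at reaction equilibrium between bound and unbound
  has_bound <- isTRUE(scenario$motor_on)
  state <- list(cb = if (has_bound) params$beta * c0 else c0 * 0,
                cu = if (has_bound) (1 - params$beta) * c0 else c0,
                ca = c0 * 0)
  anchor <- if (isTRUE(scenario$anchor_on))
    anchor_region(grid, params$anchor_thickness) else NULL

  pair_time_hr <- params$steps_per_pair * params$dt * params$tau / 3600
  n_act <- max(1L, round(duration_hr / pair_time_hr))
  order_idx <- integer(0)
  while (length(order_idx) < n_act)
    order_idx <- c(order_idx, sample.int(length(pairs)))
  order_idx <- order_idx[seq_len(n_act)]

  zc <- grid$z
  series <- data.frame(time_hr = numeric(n_act), posterior = numeric(n_act),
                       anterior = numeric(n_act), com_z = numeric(n_act),
                       mass = numeric(n_act))
  for (a in seq_len(n_act)) {
    pr <- pairs[[order_idx[a]]]
    u <- if (isTRUE(scenario$flow_on)) pr$u else NULL
    state <- transport_step(state, pr$vm, u, grid, params,
                            motor_on = isTRUE(scenario$motor_on),
                            motor_sign = scenario$motor_sign,
                            anchor = anchor)
    tot <- state$cb + state$cu + state$ca
    mz <- apply(tot, 3, sum)
    series$time_hr[a] <- a * pair_time_hr
    series$posterior[a] <- slice_fraction(state, grid,
                                          params$anchor_thickness,
                                          "posterior")
    series$anterior[a] <- slice_fraction(state, grid,
                                         params$anchor_thickness, "anterior")
    series$com_z[a] <- sum(mz * zc) / sum(mz)
    series$mass[a] <- sum(tot)
  }
  list(state = state, series = series, scenario = scenario,
       pair_order = order_idx)
}

#' Add an ectopic cortical nucleation patch (CAM phenotype)
#'
#' Adds `n_add` extra seed points, uniform by area, inside a surface patch
#' of Euclidean radius `radius` around the point at `(rho, phi)` on the
#' posterior cap — emulating follicle-cell clones that induce MT nucleation
#' adjacent to (dorsal of) the posterior pole.
#'
#' @param seeds A `seed_points` data frame.
#' @param rho,phi Patch center surface coordinates on the posterior cap.
#' @param radius Patch radius (Euclidean, nondimensional).
#' @param n_add Number of seeds to add.
#' @param seed Optional RNG seed.
#' @return The augmented `seed_points` data frame.
#' @export
add_cam_patch <- function(seeds, rho = 0.45, phi = pi / 2, radius = 0.25,
                          n_add = 2000, seed = NULL) {
  stopifnot(inherits(seeds, "seed_points"), n_add >= 1)
  if (!is.null(seed)) set.seed(seed)
  geom <- attr(seeds, "geometry")
  ctr <- surface_point(geom, "posterior", rho, phi)[1, ]
  acc <- NULL
  while (is.null(acc) || nrow(acc) < n_add) {
    m <- 4L * n_add
    r <- alt_uniform_inverse(geom$z0P, stats::runif(m))
    ph <- stats::runif(m, 0, 2 * pi)
    pos <- surface_point(geom, "posterior", r, ph)
    keep <- (pos[, 1] - ctr[1])^2 + (pos[, 2] - ctr[2])^2 +
      (pos[, 3] - ctr[3])^2 < radius^2
    if (any(keep))
      acc <- rbind(acc, data.frame(rho = r[keep], phi = ph[keep]))
  }
  acc <- acc[seq_len(n_add), ]
  pos <- surface_point(geom, "posterior", acc$rho, acc$phi)
  nrm <- inward_normal(geom, "posterior", acc$rho, acc$phi)
  extra <- data.frame(cap = "posterior", rho = acc$rho, phi = acc$phi,
                      s = cap_arclength(geom, "posterior", acc$rho),
                      x = pos[, 1], y = pos[, 2], z = pos[, 3],
                      nx = nrm[, 1], ny = nrm[, 2], nz = nrm[, 3])
  out <- rbind(as.data.frame(seeds), extra)
  counts <- attr(seeds, "counts")
  counts$N_P <- counts$N_P + n_add
  counts$N <- counts$N + n_add
  attr(out, "counts") <- counts
  attr(out, "params") <- attr(seeds, "params")
  attr(out, "geometry") <- geom
  attr(out, "seed") <- attr(seeds, "seed")
  class(out) <- c("seed_points", "data.frame")
  out
}
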