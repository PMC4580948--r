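#' Straight-rod continuum model parameters
#'
#' In the continuum limit MTs are straight rods nucleated continuously on
#' the cortex with the same arclength density as the polymer model, oriented
#' uniformly into the inward half space, with lengths from the gamma3 law.
#' The joint density for a rod from surface point \eqn{\sigma} to reach an
#' interior point \eqn{x} at distance \eqn{r} is
#' \deqn{p(x, \sigma) = p_\Sigma(s \mid h_0, k)\; \frac{N_\Gamma}{2\pi r^2}
#'   \left[1 - \Phi_\Gamma(r \mid 3, \Lambda)\right],
#'   \qquad N_\Gamma = 1/(2\Lambda).}
#' Because straight rods reach further than curved polymers of the same
#' contour length, the standard rod preset uses a reduced mean length
#' `epsilon = 0.28` (versus 0.5 in the polymer model).
#'
#' @param seeding A [seeding_params()] (the `N_A` field is not used by the
#'   continuum model).
#' @param epsilon Mean rod length as fraction of the AP-axis length
#'   (default 0.28).
#' @return An object of class `rod_params`.
#' @export
rod_params <- function(seeding = seeding_params("wildtype"),
                       epsilon = 0.28) {
  stopifnot(inherits(seeding, "seeding_params"), epsilon > 0)
  structure(list(seeding = seeding, epsilon = epsilon), class = "rod_params")
}

## quadrature nodes in rho, graded toward the cap tip to resolve the
## near-pole peak of the r^-2 kernel; Gauss-Legendre on geometric panels
rod_rho_nodes <- function(n_panel = 16L, n_gl = 12L, rho_min = 1e-3) {
  gl <- pracma_gauss_legendre(n_gl)
  breaks <- c(0, rho_min * (1 / rho_min)^(seq_len(n_panel) / n_panel))
  nodes <- weights <- numeric(0)
  for (i in seq_len(n_panel)) {
    a <- breaks[i]; b <- breaks[i + 1]
    nodes <- c(nodes, (a + b) / 2 + (b - a) / 2 * gl$x)
    weights <- c(weights, (b - a) / 2 * gl$w)
  }
  list(nodes = nodes, weights = weights)
}

## Gauss-Legendre nodes/weights on [-1, 1] via the Golub-Welsch eigenvalue
## method (symmetric tridiagonal Jacobi matrix)
pracma_gauss_legendre <- function(n) {
  if (n == 1) return(list(x = 0, w = 2))
  i <- seq_len(n - 1)
  b <- i / sqrt(4 * i^2 - 1)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1)] <- b
  J[cbind(i + 1, i)] <- b
  e <- eigen(J, symmetric = TRUE)
  x <- rev(e$values)
  w <- 2 * rev(e$vectors[1, ]^2)
  list(x = x, w = w)
}

## per-cap contribution to the uncorrected axial net orientation
## o_x(z) pV(z) and to pV(z), for axis observation points z (vectorized)
rod_axis_cap <- function(z_obs, geom, cap, h0, k, Lambda, quad) {
  z0 <- cap_z0(geom, cap)
  rho <- quad$nodes
  s <- cap_arclength(geom, cap, rho)
  s0 <- cap_arclength(geom, cap, 1)
  p_s <- seeding_density(s, s0, h0, k)
  dS <- 2 * pi * rho * sqrt(1 + (2 * z0 * rho)^2) * quad$weights
  z_surf <- z0 * (1 - rho^2)
  ## distances from each axis point to each surface node
  dzm <- outer(z_obs, z_surf, "-")            # n_z x n_rho
  r2 <- sweep(dzm^2, 2, rho^2, "+")
  r <- sqrt(r2)
  surv <- 1 - gamma3_length_cdf(r, Lambda)
  kern <- surv / (2 * pi * r2) / (2 * Lambda)
  ## rods launch only into the inward half space of their seed point:
  ## the observation point must satisfy n . (x - sigma) > 0
  sgn <- if (cap == "posterior") -1 else 1
  hs <- sgn * (outer(z_obs, z0 * (1 + rho^2), "-")) > 0
  kern <- kern * hs
  w_ps <- dS * p_s
  list(opv = (dzm / r * kern) %*% w_ps,       # axial component e_xs . e_z
       pv = kern %*% w_ps)
}

#' Uncorrected net orientation profile along the AP axis
#'
#' Evaluates \eqn{o_x(x)\,p_V(x)} (the axial component of the
#' surface-integrated weighted rod orientations, not divided by the rod
#' density) at `n_points` uniformly spaced axis positions strictly inside
#' the domain, the last one offset `pole_offset` from the posterior pole.
#' Sign changes of this profile determine the fixed-point structure of the
#' mean cytoskeleton.
#'
#' @param params A [rod_params()].
#' @param geom An [oocyte_geometry()].
#' @param n_points Number of axis points (default 200).
#' @param pole_offset Interior offset from either pole (default 0.005).
#' @param quad Optional quadrature node list from `rod_rho_nodes()`.
#' @return A data frame with axis position `z`, `opv` (\eqn{o_x p_V}) and
#'   `pv`.
#' @export
rod_axis_profile <- function(params, geom, n_points = 200,
                             pole_offset = 0.005, quad = NULL) {
  stopifnot(inherits(params, "rod_params"),
            inherits(geom, "oocyte_geometry"), n_points >= 3)
  if (is.null(quad)) quad <- rod_rho_nodes()
  sd <- params$seeding
  Lambda <- params$epsilon * geom$ap_length / 2
  z <- seq(geom$z0A + pole_offset, geom$z0P - pole_offset,
           length.out = n_points)
  ant <- rod_axis_cap(z, geom, "anterior", sd$h0A, sd$kA, Lambda, quad)
  pos <- rod_axis_cap(z, geom, "posterior", sd$h0P, sd$kP, Lambda, quad)
  data.frame(z = z, opv = as.numeric(ant$opv + pos$opv),
             pv = as.numeric(ant$pv + pos$pv))
}

#' Net rod orientation at an arbitrary interior point
#'
#' Full surface quadrature of
#' \eqn{o(x) = p_V(x)^{-1} \int d\Sigma\, \hat e_{x\sigma}\, p(x, \sigma)}
#' and the rod density \eqn{p_V(x) = \int d\Sigma\, p(x, \sigma)}.
#' Quadrature nodes within `exclude` of `x` are skipped (integrable
#' \eqn{r^{-2}} singularity).
#'
#' @param x Interior point (length-3 vector).
#' @param params A [rod_params()].
#' @param geom An [oocyte_geometry()].
#' @param n_phi Azimuthal trapezoid nodes (default 256).
#' @param exclude Exclusion radius around `x` (default 1e-3).
#' @param quad Optional radial quadrature nodes.
#' @return A list with the orientation vector `o` and density `pv`.
#' @export
rod_net_orientation <- function(x, params, geom, n_phi = 256,
                                exclude = 1e-3, quad = NULL) {
  stopifnot(length(x) == 3, inherits(params, "rod_params"))
  if (!geom_contains(geom, x)) stop("`x` lies outside the oocyte")
  if (is.null(quad)) quad <- rod_rho_nodes()
  sd <- params$seeding
  Lambda <- params$epsilon * geom$ap_length / 2
  phi <- (seq_len(n_phi) - 0.5) * 2 * pi / n_phi
  o <- c(0, 0, 0); pv <- 0
  for (cap in c("anterior", "posterior")) {
    z0 <- cap_z0(geom, cap)
    h0 <- if (cap == "anterior") sd$h0A else sd$h0P
    k <- if (cap == "anterior") sd$kA else sd$kP
    rho <- quad$nodes
    s <- cap_arclength(geom, cap, rho)
    s0 <- cap_arclength(geom, cap, 1)
    p_s <- seeding_density(s, s0, h0, k)
    wrho <- rho * sqrt(1 + (2 * z0 * rho)^2) * quad$weights * p_s
    for (ip in seq_len(n_phi)) {
      sx <- rho * cos(phi[ip]); sy <- rho * sin(phi[ip])
      sz <- z0 * (1 - rho^2)
      dx <- x[1] - sx; dy <- x[2] - sy; dz <- x[3] - sz
      r2 <- dx^2 + dy^2 + dz^2
      r <- sqrt(r2)
      sgn <- if (cap == "posterior") -1 else 1
      hs <- sgn * (2 * z0 * rho * (cos(phi[ip]) * dx + sin(phi[ip]) * dy) +
                     dz) > 0
      ok <- r > exclude & hs
      kern <- numeric(length(r))
      kern[ok] <- (1 - gamma3_length_cdf(r[ok], Lambda)) /
        (2 * pi * r2[ok]) / (2 * Lambda)
      wk <- wrho * kern * (2 * pi / n_phi)
      pv <- pv + sum(wk)
      o <- o + c(sum(dx / r * wk, na.rm = TRUE),
                 sum(dy / r * wk, na.rm = TRUE),
                 sum(dz / r * wk, na.rm = TRUE))
    }
  }
  list(o = o / pv, pv = pv)
}

#' Classify the cytoskeletal topology from an axis profile
#'
#' Three regimes, determined by the sign pattern of \eqn{o_x p_V} along the
#' axis: `"wildtype"` if positive (posterior-pointing) everywhere — the
#' posterior pole attracts the whole volume; `"split"` if negative somewhere
#' while still positive at the grid point closest to the posterior pole — a
#' stable/saddle fixed-point pair partitions the volume; and
#' `"strong_hypomorph"` if negative at the posterior-most point — only the
#' central stable point remains.  Zero crossings are located by linear
#' interpolation; crossings from positive to negative (with increasing z)
#' are stable fixed points, the reverse are unstable.
#'
#' @param profile A data frame from [rod_axis_profile()].
#' @return A list with `label` and a data frame `fixed_points` (`z`,
#'   `stability`).
#' @export
classify_topology <- function(profile) {
  v <- profile$opv
  z <- profile$z
  if (all(v == 0)) stop("degenerate all-zero axis profile")
  n <- length(v)
  label <- if (all(v > 0)) "wildtype"
  else if (v[n] > 0) "split"
  else "strong_hypomorph"
  cross <- which(v[-n] * v[-1] < 0)
  fp <- data.frame(z = numeric(0), stability = character(0))
  for (i in cross) {
    zc <- z[i] + (z[i + 1] - z[i]) * v[i] / (v[i] - v[i + 1])
    fp <- rbind(fp, data.frame(
      z = zc, stability = if (v[i] > 0) "stable" else "unstable"))
  }
  list(label = label, fixed_points = fp)
}

#' Topology phase diagram over mean rod length and posterior gradient width
#'
#' Classifies the rod-model topology on a grid of `(epsilon, kP)` values at
#' fixed posterior pole density `h0P` (anterior parameters held at the
#' wild-type values).  Radial quadrature and axis discretization are shared
#' across the grid.
#'
#' @param geom An [oocyte_geometry()].
#' @param epsilon Vector of mean-length fractions (default 40 values in
#'   `[0.05, 0.6]`).
#' @param kP Vector of posterior width parameters (default 40
#'   logarithmically spaced values in `[0.02, 3]`).
#' @param h0P Posterior pole density (default 0).
#' @param h0A,kA Anterior density parameters.
#' @param n_points Axis points per classification (default 200).
#' @return A data frame with `epsilon`, `kP`, `h0P`, `label` and the
#'   fixed-point positions (NA when absent).
#' @export
phase_diagram <- function(geom, epsilon = seq(0.05, 0.6, length.out = 40),
                          kP = exp(seq(log(0.02), log(3), length.out = 40)),
                          h0P = 0, h0A = 0.8, kA = 20, n_points = 200) {
  stopifnot(inherits(geom, "oocyte_geometry"))
  quad <- rod_rho_nodes()
  out <- expand.grid(epsilon = epsilon, kP = kP)
  out$h0P <- h0P
  out$label <- NA_character_
  out$z_stable <- NA_real_
  out$z_unstable <- NA_real_
  for (i in seq_len(nrow(out))) {
    sp <- seeding_params(h0A = h0A, kA = kA, h0P = h0P, kP = out$kP[i])
    pr <- rod_axis_profile(rod_params(sp, out$epsilon[i]), geom,
                           n_points = n_points, quad = quad)
    cl <- classify_topology(pr)
    out$label[i] <- cl$label
    if (nrow(cl$fixed_points)) {
      st <- cl$fixed_points$z[cl$fixed_points$stability == "stable"]
      un <- cl$fixed_points$z[cl$fixed_points$stability == "unstable"]
      if (length(st)) out$z_stable[i] <- st[1]
      if (length(un)) out$z_unstable[i] <- un[length(un)]
    }
  }
  out
}

#' Saddle-node bifurcation normal form
#'
#' The two-dimensional normal form \eqn{(v_x, v_y) = (x^2 + \lambda, -y)}:
#' for \eqn{\lambda < 0} a stable and an unstable fixed point sit at
#' \eqn{x = \mp\sqrt{-\lambda}}, merging at the critical point
#' \eqn{\lambda = 0} and annihilating for \eqn{\lambda > 0}.
#'
#' @param lambda_bif Bifurcation parameter.
#' @param x,y Coordinate vectors at which to evaluate the field.
#' @return A list with matrices `vx`, `vy` on the `(x, y)` grid and a data
#'   frame `fixed_points`.
#' @export
normal_form_field <- function(lambda_bif, x = seq(-2, 2, length.out = 41),
                              y = seq(-1, 1, length.out = 21)) {
  vx <- outer(x^2 + lambda_bif, rep(1, length(y)))
  vy <- outer(rep(1, length(x)), -y)
  fp <- if (lambda_bif < 0) {
    data.frame(x = c(-sqrt(-lambda_bif), sqrt(-lambda_bif)), y = 0,
               stability = c("stable", "unstable"))
  } else if (lambda_bif == 0) {
    data.frame(x = 0, y = 0, stability = "degenerate")
  } else {
    data.frame(x = numeric(0), y = numeric(0), stability = character(0))
  }
  list(vx = vx, vy = vy, x = x, y = y, fixed_points = fp)
}
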