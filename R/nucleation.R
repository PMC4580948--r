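#' Cortical seeding-density parameters
#'
#' Microtubule (MT) seeding points are drawn along each cap's arclength
#' \eqn{s} from the unnormalized density
#' \deqn{\tilde p_\Sigma(s \mid h_0, k) = h_0 + (1 - h_0)
#'   \left[1 + (k/s_0)^2\right] \frac{s^2}{k^2 + s^2},}
#' which satisfies \eqn{\tilde p_\Sigma(s_0) = 1} at the corner ring.
#' `h0` in `[0, 1]` sets the density at the cap tip (pole); `k > 0` sets the
#' lateral width of the low-nucleation region (nondimensional; dimensional
#' width is `k * L` micrometres).  For `k >> s0` the density approaches the
#' parabola \eqn{h_0 + (1 - h_0)(s/s_0)^2}; for `k << s0` it approaches a
#' Hill function with coefficient 2.
#'
#' Presets (anterior always `h0A = 0.8, kA = 20`):
#' \describe{
#'   \item{`wildtype`}{`h0P = 0, kP = 3` (150 um / L): steep posterior gradient.}
#'   \item{`par1-intermediate`}{`h0P = 0, kP = 0.35` (17.5 um): gradient pulled
#'     laterally toward the posterior pole.}
#'   \item{`par1-strong`}{`h0P = 0, kP = 0.02` (1 um): near-uniform posterior
#'     seeding, the strong par-1 hypomorph.}
#'   \item{`par1-shallow`}{`h0P = 0.7, kP = 0.8` (40 um): slightly reduced
#'     density at the posterior pole.}
#' }
#'
#' @param preset Preset name (see Details), or `NULL` to use the explicit
#'   parameters.
#' @param h0A,kA Anterior depth and width parameters.
#' @param h0P,kP Posterior depth and width parameters.
#' @param N_A Number of anterior seeding points (default 25000).
#' @return An object of class `seeding_params`.
#' @examples
#' p <- seeding_params("wildtype")
#' seed_counts(oocyte_geometry("geometry1"), p)$N   # 55764
#' @export
seeding_params <- function(preset = NULL, h0A = 0.8, kA = 20,
                           h0P = 0, kP = 3, N_A = 25000) {
  if (!is.null(preset)) {
    preset <- match.arg(preset, c("wildtype", "par1-intermediate",
                                  "par1-strong", "par1-shallow"))
    post <- switch(preset,
      "wildtype"          = c(h0P = 0,   kP = 3),
      "par1-intermediate" = c(h0P = 0,   kP = 0.35),
      "par1-strong"       = c(h0P = 0,   kP = 0.02),
      "par1-shallow"      = c(h0P = 0.7, kP = 0.8))
    h0P <- unname(post["h0P"]); kP <- unname(post["kP"])
  } else preset <- "custom"
  stopifnot(h0A >= 0, h0A <= 1, h0P >= 0, h0P <= 1, kA > 0, kP > 0,
            N_A >= 1, N_A == round(N_A))
  structure(list(h0A = h0A, kA = kA, h0P = h0P, kP = kP,
                 N_A = as.integer(N_A), preset = preset),
            class = "seeding_params")
}

#' @export
print.seeding_params <- function(x, ...) {
  cat(sprintf(
    "<seeding_params %s> anterior h0 = %g, k = %g; posterior h0 = %g, k = %g; N_A = %d\n",
    x$preset, x$h0A, x$kA, x$h0P, x$kP, x$N_A))
  invisible(x)
}

#' Unnormalized seeding density along arclength
#'
#' @param s Arclength value(s), `0 <= s <= s0`.
#' @param s0 Maximum arclength of the cap (tip to corner ring).
#' @param h0,k Density shape parameters (see [seeding_params()]).
#' @return \eqn{\tilde p_\Sigma(s)}, with \eqn{\tilde p_\Sigma(s_0) = 1}.
#' @export
seeding_density <- function(s, s0, h0, k) {
  if (k <= 0) stop("`k` must be positive")
  stopifnot(h0 >= 0, h0 <= 1, all(s >= 0), all(s <= s0 + 1e-12))
  h0 + (1 - h0) * (1 + (k / s0)^2) * s^2 / (k^2 + s^2)
}

## integral of the unnormalized density over one cap,
## A(h0, k) = int dSigma ptilde(s(rho)), by adaptive quadrature in rho
cap_density_integral <- function(geom, cap, h0, k) {
  z0 <- cap_z0(geom, cap)
  s0 <- cap_arclength(geom, cap, 1)
  integrand <- function(r) {
    s <- cap_arclength(geom, cap, r)
    2 * pi * r * sqrt(1 + (2 * z0 * r)^2) * seeding_density(s, s0, h0, k)
  }
  stats::integrate(integrand, 0, 1, rel.tol = 1e-12)$value
}

#' Anterior/posterior seed counts from density matching
#'
#' With the per-cap densities normalized individually, requiring equal point
#' densities on the two sides of the corner ring fixes the posterior count
#' \deqn{N_P = N_A \frac{A(h_{0P}, k_P)}{A(h_{0A}, k_A)},}
#' where \eqn{A(h_0, k) = \int d\Sigma\, \tilde p_\Sigma} is the integrated
#' unnormalized density over one cap; this is equivalent to drawing from the
#' globally normalized density.  `N_P` is rounded to the nearest integer.
#'
#' @param geom An [oocyte_geometry()].
#' @param params A [seeding_params()].
#' @return A list with `N_A`, `N_P`, `N`, and the cap integrals `A_A`, `A_P`.
#' @export
seed_counts <- function(geom, params) {
  stopifnot(inherits(geom, "oocyte_geometry"),
            inherits(params, "seeding_params"))
  A_A <- cap_density_integral(geom, "anterior",  params$h0A, params$kA)
  A_P <- cap_density_integral(geom, "posterior", params$h0P, params$kP)
  N_P <- as.integer(round(params$N_A * A_P / A_A))
  list(N_A = params$N_A, N_P = N_P, N = params$N_A + N_P,
       A_A = A_A, A_P = A_P)
}

## Tabulated per-cap CDF C(rho) and its monotone-interpolated inverse.
## Nodes are Chebyshev-spaced in rho to resolve both the tip and the corner.
cap_cdf_inverse <- function(geom, cap, h0, k, n_nodes = 4096L) {
  z0 <- cap_z0(geom, cap)
  s0 <- cap_arclength(geom, cap, 1)
  rho <- (1 - cos(pi * seq(0, n_nodes - 1L) / (n_nodes - 1L))) / 2
  s <- cap_arclength(geom, cap, rho)
  w <- 2 * pi * rho * sqrt(1 + (2 * z0 * rho)^2) *
    seeding_density(s, s0, h0, k)
  ## cumulative trapezoid
  C <- c(0, cumsum((w[-1] + w[-n_nodes]) / 2 * diff(rho)))
  C <- C / C[n_nodes]
  ## strictly increasing except possibly flat start (h0 = 0 at the tip)
  keep <- c(TRUE, diff(C) > 0)
  stats::splinefun(C[keep], rho[keep], method = "hyman")
}

#' Draw cortical seeding points by inverse-transform sampling
#'
#' Samples `N_A` anterior and `N_P` posterior points (counts from
#' [seed_counts()]) with radial coordinates obtained by numerically inverting
#' the per-cap cumulative distribution of the seeding density, and azimuths
#' uniform on `[0, 2*pi)`.  Reproducible given the R RNG state; pass `seed`
#' to fix it explicitly.
#'
#' @inheritParams seed_counts
#' @param seed Optional integer RNG seed.
#' @return A data frame of class `seed_points` with columns `cap`, `rho`,
#'   `phi`, `s` (arclength), `x`, `y`, `z` and inward normal `nx`, `ny`,
#'   `nz`; counts and parameters are attached as attributes.
#' @export
sample_seeds <- function(geom, params, seed = NULL) {
  stopifnot(inherits(geom, "oocyte_geometry"),
            inherits(params, "seeding_params"))
  if (!is.null(seed)) set.seed(seed)
  counts <- seed_counts(geom, params)
  one_cap <- function(cap, h0, k, n) {
    inv <- cap_cdf_inverse(geom, cap, h0, k)
    rho <- pmin(pmax(inv(stats::runif(n)), 0), 1)
    phi <- stats::runif(n, 0, 2 * pi)
    pos <- surface_point(geom, cap, rho, phi)
    nrm <- inward_normal(geom, cap, rho, phi)
    data.frame(cap = cap, rho = rho, phi = phi,
               s = cap_arclength(geom, cap, rho),
               x = pos[, 1], y = pos[, 2], z = pos[, 3],
               nx = nrm[, 1], ny = nrm[, 2], nz = nrm[, 3])
  }
  out <- rbind(
    one_cap("anterior",  params$h0A, params$kA, counts$N_A),
    one_cap("posterior", params$h0P, params$kP, counts$N_P))
  attr(out, "counts") <- counts[c("N_A", "N_P", "N")]
  attr(out, "params") <- params
  attr(out, "geometry") <- geom
  attr(out, "seed") <- seed
  class(out) <- c("seed_points", "data.frame")
  out
}

#' Kolmogorov-Smirnov check of sampled seeds against the target density
#'
#' Compares the empirical distribution of sampled arclengths on one cap with
#' the analytic area-weighted target CDF of the seeding density.
#'
#' @param seeds A `seed_points` data frame from [sample_seeds()].
#' @param cap Which cap to check.
#' @return A list with the KS `statistic` and the sample size `n`.
#' @export
empirical_density_check <- function(seeds, cap = "posterior") {
  stopifnot(inherits(seeds, "seed_points"))
  cap <- match.arg(cap, c("anterior", "posterior"))
  geom <- attr(seeds, "geometry"); params <- attr(seeds, "params")
  h0 <- if (cap == "anterior") params$h0A else params$h0P
  k  <- if (cap == "anterior") params$kA  else params$kP
  rho <- seeds$rho[seeds$cap == cap]
  if (length(rho) < 1e4)
    warning("fewer than 1e4 seeds on this cap; KS distance will be noisy")
  inv <- cap_cdf_inverse(geom, cap, h0, k)
  ## target CDF by dense tabulation + interpolation of the inverse map
  u <- seq(0, 1, length.out = 4096L)
  cdf <- stats::approxfun(inv(u), u, yleft = 0, yright = 1, ties = "ordered")
  emp <- stats::ecdf(rho)
  grid <- sort(rho)
  list(statistic = max(abs(emp(grid) - cdf(grid))), n = length(rho))
}

#' Analytically invertible alternative seeding densities
#'
#' Two tractable alternatives to the standard density, both with closed-form
#' inverse CDFs: a power-law gradient along the cap,
#' \eqn{p_n \propto \rho^{n-1} / \sqrt{1 + (2 z_{0i} \rho)^2}} with inverse
#' \eqn{\rho = u^{1/(n+1)}}, and an area-uniform density \eqn{p_u = 1/\Sigma_i}
#' whose CDF on a parabolic cap is
#' \eqn{C_u(\rho) = \{[1 + (2 z_{0i}\rho)^2]^{3/2} - 1\} / \{[1 + (2 z_{0i})^2]^{3/2} - 1\}}
#' (flat disc: \eqn{C_u = \rho^2}, inverse \eqn{\sqrt u}).
#'
#' @param geom An [oocyte_geometry()].
#' @param cap `"anterior"` or `"posterior"`.
#' @param n_draw Number of points to draw.
#' @param kind `"gradient"` (power law, exponent `n`) or `"uniform"`.
#' @param n Gradient exponent (`n >= 1`), default 2 (parabolic).
#' @param seed Optional RNG seed.
#' @return A data frame with columns `rho`, `phi`.
#' @export
alt_density_sample <- function(geom, cap, n_draw,
                               kind = c("gradient", "uniform"),
                               n = 2, seed = NULL) {
  stopifnot(inherits(geom, "oocyte_geometry"), n_draw >= 1)
  kind <- match.arg(kind)
  if (!is.null(seed)) set.seed(seed)
  u <- stats::runif(n_draw)
  rho <- if (kind == "gradient") {
    stopifnot(n >= 1)
    u^(1 / (n + 1))
  } else {
    alt_uniform_inverse(cap_z0(geom, cap), u)
  }
  data.frame(rho = rho, phi = stats::runif(n_draw, 0, 2 * pi))
}

## closed-form inverse CDF of the area-uniform density on a parabolic cap
alt_uniform_inverse <- function(z0, u) {
  if (z0 == 0) return(sqrt(u))
  g <- (1 + (2 * z0)^2)^(3 / 2) - 1
  sqrt(pmax((u * g + 1)^(2 / 3) - 1, 0)) / (2 * z0)
}

## forward CDF, for round-trip checks
alt_uniform_cdf <- function(z0, rho) {
  if (z0 == 0) return(rho^2)
  ((1 + (2 * z0 * rho)^2)^(3 / 2) - 1) / ((1 + (2 * z0)^2)^(3 / 2) - 1)
}

#' Posterior count matching for the alternative densities
#'
#' For an area-uniform anterior density and a gradient posterior density of
#' exponent `n`, equating point densities at the corner ring gives
#' \deqn{N_P = \frac{3 (2 z_{0A})^2 N_A}{n + 1}
#'   \frac{\sqrt{1 + (2 z_{0P})^2}}{[1 + (2 z_{0A})^2]^{3/2} - 1}}
#' for two parabolic caps, and
#' \eqn{N_P = \frac{2 N_A}{n+1} \sqrt{1 + (2 z_{0P})^2}} for a flat anterior
#' disc.
#'
#' @inheritParams alt_density_sample
#' @param N_A Anterior seed count.
#' @export
alt_seed_counts <- function(geom, N_A, n = 2) {
  stopifnot(inherits(geom, "oocyte_geometry"), N_A >= 1, n >= 1)
  z0A <- geom$z0A; z0P <- geom$z0P
  N_P <- if (z0A == 0) {
    2 * N_A / (n + 1) * sqrt(1 + (2 * z0P)^2)
  } else {
    3 * (2 * z0A)^2 * N_A / (n + 1) *
      sqrt(1 + (2 * z0P)^2) / ((1 + (2 * z0A)^2)^(3 / 2) - 1)
  }
  list(N_A = N_A, N_P = as.integer(round(N_P)),
       N = N_A + as.integer(round(N_P)))
}
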