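#' Persistent-random-walk polymer parameters
#'
#' MTs are chains of straight segments of nondimensional length `lambda`
#' (default 0.015, i.e. 0.75 um at the default scale L = 50 um).  Each
#' segment orientation is drawn from a von Mises-Fisher distribution with
#' concentration `kappa` around the previous segment; `kappa = 18` gives an
#' effective persistence length of about 13.5 um.  Each MT grows until it
#' hits the boundary, reaches a random target length, or attains `Ns_max`
#' segments.
#'
#' Target lengths follow the growing-ensemble length law derived from
#' three-step Gamma-distributed catastrophe (`length_law = "gamma3"`), with
#' mean \eqn{2\Lambda} set to fraction `epsilon` of the AP-axis length, so
#' \eqn{\Lambda = \epsilon (z_{0P} - z_{0A}) / 2}.  The one-parameter
#' exponential law (`"exponential"`, mean \eqn{\Lambda = \epsilon (z_{0P} -
#' z_{0A})}) is available as an alternative.
#'
#' @param lambda Segment length (nondimensional, default 0.015).
#' @param kappa von Mises-Fisher concentration (default 18; 0 = flexible
#'   random walk, large = stiff rod).
#' @param Ns_max Maximum number of segments per polymer (default 200).
#' @param epsilon Mean target length as a fraction of the AP-axis length
#'   (default 0.5).
#' @param length_law `"gamma3"` or `"exponential"`.
#' @return An object of class `polymer_params`.
#' @export
polymer_params <- function(lambda = 0.015, kappa = 18, Ns_max = 200,
                           epsilon = 0.5, length_law = c("gamma3",
                                                         "exponential")) {
  length_law <- match.arg(length_law)
  stopifnot(lambda > 0, kappa >= 0, Ns_max >= 1, epsilon > 0)
  structure(list(lambda = lambda, kappa = kappa, Ns_max = as.integer(Ns_max),
                 epsilon = epsilon, length_law = length_law),
            class = "polymer_params")
}

#' @export
print.polymer_params <- function(x, ...) {
  cat(sprintf(
    "<polymer_params> lambda = %g, kappa = %g, Ns_max = %d, epsilon = %g, law = %s\n",
    x$lambda, x$kappa, x$Ns_max, x$epsilon, x$length_law))
  invisible(x)
}

## mean-length parameter Lambda of the length law
length_scale_Lambda <- function(params, geom) {
  ap <- geom$z0P - geom$z0A
  if (params$length_law == "gamma3") params$epsilon * ap / 2
  else params$epsilon * ap
}

#' Cumulative distribution of the gamma3 target-length law
#'
#' \deqn{\Phi_\Gamma(l \mid 3, \Lambda) = 1 - e^{-l/\Lambda}
#'   \frac{6\Lambda^2 + 4 l \Lambda + l^2}{6 \Lambda^2},}
#' the length distribution of a growing MT ensemble whose catastrophe
#' lengths are Gamma(3) distributed; its mean is \eqn{2\Lambda}.
#'
#' @param l Length value(s), `l >= 0`.
#' @param Lambda Step-length parameter, `Lambda > 0`.
#' @export
gamma3_length_cdf <- function(l, Lambda) {
  stopifnot(Lambda > 0, all(l >= 0))
  1 - exp(-l / Lambda) * (6 * Lambda^2 + 4 * l * Lambda + l^2) /
    (6 * Lambda^2)
}

#' Draw target lengths from the configured length law
#'
#' The gamma3 law is sampled by inverse-transform sampling of
#' [gamma3_length_cdf()] (numerically inverted by monotone interpolation on
#' a dense table); the exponential law is sampled directly.
#'
#' @param n Number of draws.
#' @param params A [polymer_params()].
#' @param geom An [oocyte_geometry()] (sets the AP length, hence `Lambda`).
#' @param seed Optional RNG seed.
#' @export
sample_target_length <- function(n, params, geom, seed = NULL) {
  stopifnot(inherits(params, "polymer_params"),
            inherits(geom, "oocyte_geometry"))
  if (!is.null(seed)) set.seed(seed)
  Lambda <- length_scale_Lambda(params, geom)
  if (params$length_law == "exponential")
    return(stats::rexp(n, rate = 1 / Lambda))
  lgrid <- seq(0, 40 * Lambda, length.out = 8192L)
  cdf <- gamma3_length_cdf(lgrid, Lambda)
  keep <- c(TRUE, diff(cdf) > 0)
  inv <- stats::splinefun(cdf[keep], lgrid[keep], method = "hyman")
  u <- stats::runif(n)
  pmax(inv(pmin(u, max(cdf))), 0)
}

#' Draw unit vectors from a von Mises-Fisher distribution
#'
#' Samples from \eqn{f(\hat\mu \mid \hat\mu_0, \kappa) \propto
#' e^{\kappa \hat\mu \cdot \hat\mu_0}} on the unit sphere; `kappa = 0` is
#' the uniform distribution.
#'
#' @param n Number of draws.
#' @param mu Mean direction (any nonzero 3-vector; normalized internally).
#' @param kappa Concentration parameter, `kappa >= 0`.
#' @param seed Optional RNG seed.
#' @return An `n x 3` matrix of unit vectors.
#' @export
sample_vmf <- function(n, mu, kappa, seed = NULL) {
  stopifnot(length(mu) == 3, kappa >= 0, n >= 1)
  if (!is.null(seed)) set.seed(seed)
  cpp_sample_vmf(as.integer(n), as.numeric(mu), kappa)
}

#' Grow a full cytoskeleton realization
#'
#' Grows one persistent-random-walk MT from every seed point: the first
#' segment is uniform on the inward hemisphere, subsequent segments are von
#' Mises-Fisher about the previous one, and growth stops at the boundary
#' (the exiting segment is dropped), at the sampled target length, or at
#' `Ns_max` segments.
#'
#' @param seeds A `seed_points` data frame from [sample_seeds()].
#' @param params A [polymer_params()].
#' @param seed Optional RNG seed (fixes target lengths and growth draws).
#' @return An object of class `cytoskeleton`: list with `segments` (matrix
#'   columns `mx, my, mz` midpoints and `ox, oy, oz` orientations),
#'   `offsets` (0-based segment offsets per polymer), `terminated`
#'   (`"target_length"`, `"boundary"` or `"Ns_max"` per polymer),
#'   `target_lengths`, plus the seed table and parameters.
#' @export
grow_cytoskeleton <- function(seeds, params, seed = NULL) {
  stopifnot(inherits(seeds, "seed_points"),
            inherits(params, "polymer_params"))
  if (!is.null(seed)) set.seed(seed)
  geom <- attr(seeds, "geometry")
  n <- nrow(seeds)
  target <- sample_target_length(n, params, geom)
  res <- cpp_grow_polymers(
    as.matrix(seeds[, c("x", "y", "z")]),
    as.matrix(seeds[, c("nx", "ny", "nz")]),
    target, params$lambda, params$kappa, params$Ns_max,
    geom$z0A, geom$z0P)
  segs <- cbind(res$mid, res$ori)
  colnames(segs) <- c("mx", "my", "mz", "ox", "oy", "oz")
  structure(list(
    segments = segs,
    offsets = res$offsets,
    terminated = c("target_length", "boundary", "Ns_max")[res$terminated],
    target_lengths = target,
    seeds = seeds,
    params = params,
    geometry = geom,
    rng_seed = seed),
    class = "cytoskeleton")
}

#' @export
print.cytoskeleton <- function(x, ...) {
  cat(sprintf("<cytoskeleton> %d polymers, %d segments (%s, kappa = %g, epsilon = %g)\n",
              length(x$terminated), nrow(x$segments),
              x$geometry$preset, x$params$kappa, x$params$epsilon))
  invisible(x)
}

#' Closed-form persistence statistics of the polymer walk
#'
#' `sigma_of_kappa()` gives the mean resultant
#' \eqn{\sigma = \coth\kappa - 1/\kappa} of the von Mises-Fisher step;
#' `mean_end_to_end()` the expected end-to-end distance
#' \eqn{\lambda (1 - \sigma^{N_s}) / (1 - \sigma)} of an `Ns`-segment chain;
#' `persistence_length()` the tangent-correlation decay length
#' \eqn{P = -\lambda / \ln\sigma}, with the limiting approximations
#' \eqn{P \approx \lambda / \ln(3/\kappa)} (small \eqn{\kappa}) and
#' \eqn{P \approx \lambda\kappa} (large \eqn{\kappa}).
#'
#' @param kappa Concentration parameter (`kappa >= 0`).
#' @export
sigma_of_kappa <- function(kappa) {
  stopifnot(all(kappa >= 0))
  out <- ifelse(kappa < 1e-8, kappa / 3, 1 / tanh(kappa) - 1 / kappa)
  pmin(out, 1)
}

#' @rdname sigma_of_kappa
#' @param Ns Number of segments.
#' @param lambda Segment length.
#' @export
mean_end_to_end <- function(Ns, kappa, lambda) {
  stopifnot(Ns >= 1)
  s <- sigma_of_kappa(kappa)
  ifelse(s >= 1, lambda * Ns, lambda * (1 - s^Ns) / (1 - s))
}

#' @rdname sigma_of_kappa
#' @param approx `"exact"` for \eqn{-\lambda/\ln\sigma}, `"large_kappa"` for
#'   \eqn{\lambda\kappa}, `"small_kappa"` for \eqn{\lambda/\ln(3/\kappa)}.
#' @param L Length scale to convert to dimensional units (default 1 keeps
#'   the nondimensional value).
#' @export
persistence_length <- function(kappa, lambda, L = 1,
                               approx = c("exact", "large_kappa",
                                          "small_kappa")) {
  approx <- match.arg(approx)
  P <- switch(approx,
    exact = -lambda / log(sigma_of_kappa(kappa)),
    large_kappa = lambda * kappa,
    small_kappa = lambda / log(3 / kappa))
  P * L
}

#' Empirical tangent-tangent correlation of free chains
#'
#' Simulates unconstrained persistent random walks and measures
#' \eqn{\langle \hat\mu_{1+k} \cdot \hat\mu_1 \rangle} as a function of
#' contour separation, for comparison against the analytic decay
#' \eqn{\sigma^k = e^{-k\lambda/P}}.
#'
#' @param kappa Concentration parameter.
#' @param n_chain Number of chains.
#' @param ns Segments per chain.
#' @param seed Optional RNG seed.
#' @return A data frame with `lag` (segments) and mean `correlation`.
#' @export
tangent_correlation <- function(kappa, n_chain = 2000, ns = 40, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ori <- cpp_free_chains(as.integer(n_chain), as.integer(ns), kappa)
  first <- ori[seq(1, by = ns, length.out = n_chain), , drop = FALSE]
  corr <- vapply(seq_len(ns) - 1L, function(k) {
    rows <- seq(1 + k, by = ns, length.out = n_chain)
    mean(rowSums(ori[rows, , drop = FALSE] * first))
  }, numeric(1))
  data.frame(lag = seq_len(ns) - 1L, correlation = corr)
}
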