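#' Oocyte geometry from two rotationally symmetric parabolic caps
#'
#' The stage 9 oocyte is modelled as the closed solid bounded by an anterior
#' and a posterior parabolic cap, both rotationally symmetric about the
#' anteroposterior (AP) axis.  In cylindrical coordinates
#' \eqn{(\rho, \phi)} with \eqn{\rho \in [0, 1]} the cap surfaces are
#' \deqn{\sigma_i(\rho, \phi) = \rho\,\hat e_\rho + z_{0i}(1 - \rho^2)\,\hat e_z,}
#' where \eqn{i \in \{A, P\}} and \eqn{z_{0A} < z_{0P}} are the nondimensional
#' cap heights.  All computations are nondimensional with length scale
#' \code{L} (micrometres); the AP axis is the internal \eqn{z} axis.
#'
#' Two presets are provided.  \code{"geometry1"} (the standard shape) uses
#' \eqn{z_{0A} = 0.2} (anterior cap curved into the volume) and
#' \eqn{z_{0P} = 1.48}, giving an AP-axis length of 1.28 and an aspect ratio
#' (width over length) of 1.5625.  \code{"geometry2"} uses a flat anterior
#' disc \eqn{z_{0A} = 0} and \eqn{z_{0P} = 1}.
#'
#' @param preset `"geometry1"` or `"geometry2"`; ignored when both `z0A` and
#'   `z0P` are supplied.
#' @param z0A,z0P Nondimensional cap heights, `0 <= z0A < z0P`.
#' @param L Length scale in micrometres (default 50).
#' @return An object of class `oocyte_geometry`: a list with fields `z0A`,
#'   `z0P`, `L`, `ap_length` and `preset`.
#' @examples
#' g <- oocyte_geometry("geometry1")
#' g$ap_length              # 1.28
#' total_volume(g)          # pi * 1.28 / 2
#' @export
oocyte_geometry <- function(preset = c("geometry1", "geometry2"),
                            z0A = NULL, z0P = NULL, L = 50) {
  if (is.null(z0A) != is.null(z0P))
    stop("supply both `z0A` and `z0P`, or neither")
  if (is.null(z0A)) {
    preset <- match.arg(preset)
    if (preset == "geometry1") {
      z0A <- 0.2; z0P <- 1.48
    } else {
      z0A <- 0; z0P <- 1
    }
  } else {
    preset <- "custom"
  }
  stopifnot(is.numeric(z0A), is.numeric(z0P), length(z0A) == 1L,
            length(z0P) == 1L, z0A >= 0, z0P > z0A, L > 0)
  structure(
    list(z0A = z0A, z0P = z0P, L = L, ap_length = z0P - z0A, preset = preset),
    class = "oocyte_geometry"
  )
}

#' @export
print.oocyte_geometry <- function(x, ...) {
  cat(sprintf(
    "<oocyte_geometry %s> z0A = %g, z0P = %g, AP length = %g, L = %g um\n",
    x$preset, x$z0A, x$z0P, x$ap_length, x$L))
  invisible(x)
}

cap_z0 <- function(geom, cap) {
  cap <- match.arg(cap, c("anterior", "posterior"))
  if (cap == "anterior") geom$z0A else geom$z0P
}

#' Point on a cap surface
#'
#' Evaluates the surface parameterization
#' \eqn{\sigma_i(\rho,\phi) = \rho\hat e_\rho + z_{0i}(1-\rho^2)\hat e_z}.
#'
#' @param geom An [oocyte_geometry()].
#' @param cap `"anterior"` or `"posterior"`.
#' @param rho Radial coordinate(s) in `[0, 1]`.
#' @param phi Azimuthal angle(s) in `[0, 2*pi)`.
#' @return A numeric matrix with one `(x, y, z)` row per input point.
#' @export
surface_point <- function(geom, cap, rho, phi) {
  stopifnot(inherits(geom, "oocyte_geometry"))
  if (any(rho < 0 | rho > 1)) stop("`rho` must lie in [0, 1]")
  if (any(phi < 0 | phi >= 2 * pi)) stop("`phi` must lie in [0, 2*pi)")
  z0 <- cap_z0(geom, cap)
  n <- max(length(rho), length(phi))
  rho <- rep_len(rho, n); phi <- rep_len(phi, n)
  cbind(x = rho * cos(phi), y = rho * sin(phi), z = z0 * (1 - rho^2))
}

#' Arclength along a cap from the pole tip
#'
#' Closed form
#' \deqn{s_i(\rho) = \tfrac{\rho}{2}\sqrt{1 + (2 z_{0i} \rho)^2}
#'   + \tfrac{1}{4 z_{0i}} \sinh^{-1}(2 z_{0i} \rho),}
#' with the flat-disc limit \eqn{s(\rho) = \rho} for \eqn{z_{0i} = 0}.
#' `s = 0` is the cap tip on the AP axis; `s = s0 = cap_arclength(geom, cap, 1)`
#' is the corner ring where the two caps meet.
#'
#' @inheritParams surface_point
#' @return Arclength value(s), same length as `rho`.
#' @export
cap_arclength <- function(geom, cap, rho) {
  stopifnot(inherits(geom, "oocyte_geometry"))
  if (any(rho < 0 | rho > 1)) stop("`rho` must lie in [0, 1]")
  z0 <- cap_z0(geom, cap)
  if (z0 == 0) return(rho)
  rho / 2 * sqrt(1 + (2 * z0 * rho)^2) + asinh(2 * z0 * rho) / (4 * z0)
}

#' Total surface area of one cap
#'
#' \deqn{\Sigma_i = \frac{\pi}{6 z_{0i}^2}\left([1 + (2 z_{0i})^2]^{3/2} - 1\right),}
#' reducing to \eqn{\Sigma = \pi} for a flat disc.
#'
#' @inheritParams surface_point
#' @export
cap_surface_area <- function(geom, cap) {
  stopifnot(inherits(geom, "oocyte_geometry"))
  z0 <- cap_z0(geom, cap)
  if (z0 == 0) return(pi)
  pi / (6 * z0^2) * ((1 + (2 * z0)^2)^(3 / 2) - 1)
}

#' Inward-pointing unit normal of a cap surface
#'
#' The caps bound the volume from opposite sides, so the inward normals are
#' \deqn{\hat n_P = -\frac{2 z_{0P} \rho\, \hat e_\rho + \hat e_z}
#'   {\sqrt{1 + (2 z_{0P}\rho)^2}}, \qquad
#'   \hat n_A = +\frac{2 z_{0A} \rho\, \hat e_\rho + \hat e_z}
#'   {\sqrt{1 + (2 z_{0A}\rho)^2}}:}
#' at the posterior pole the inward direction is \eqn{-\hat e_z} (toward the
#' anterior), at the anterior cap tip it is \eqn{+\hat e_z}; for a flat
#' anterior disc \eqn{\hat n_A = \hat e_z} everywhere.
#'
#' @inheritParams surface_point
#' @return A matrix of unit vectors, one row per point.
#' @export
inward_normal <- function(geom, cap, rho, phi) {
  stopifnot(inherits(geom, "oocyte_geometry"))
  if (any(rho < 0 | rho > 1)) stop("`rho` must lie in [0, 1]")
  cap <- match.arg(cap, c("anterior", "posterior"))
  z0 <- cap_z0(geom, cap)
  n <- max(length(rho), length(phi))
  rho <- rep_len(rho, n); phi <- rep_len(phi, n)
  sgn <- if (cap == "posterior") -1 else 1
  denom <- sqrt(1 + (2 * z0 * rho)^2)
  cbind(x = sgn * 2 * z0 * rho * cos(phi) / denom,
        y = sgn * 2 * z0 * rho * sin(phi) / denom,
        z = sgn / denom)
}

#' Point membership test for the oocyte volume
#'
#' A point `(x, y, z)` lies inside the closed domain iff
#' \eqn{\rho = \sqrt{x^2 + y^2} \le 1} and
#' \eqn{z_{0A}(1 - \rho^2) \le z \le z_{0P}(1 - \rho^2)}.
#' Membership is boundary-inclusive with tolerance `tol`, so points returned
#' by [surface_point()] always test `TRUE`.
#'
#' @param geom An [oocyte_geometry()].
#' @param points A numeric matrix with columns `(x, y, z)` (or a length-3
#'   vector for a single point).
#' @param tol Boundary tolerance (default `1e-12`).
#' @return A logical vector, one entry per point.
#' @export
geom_contains <- function(geom, points, tol = 1e-12) {
  stopifnot(inherits(geom, "oocyte_geometry"))
  if (is.null(dim(points))) points <- matrix(points, ncol = 3L)
  rho2 <- points[, 1]^2 + points[, 2]^2
  z <- points[, 3]
  rho2 <= 1 + tol &
    z >= geom$z0A * (1 - rho2) - tol &
    z <= geom$z0P * (1 - rho2) + tol
}

#' Cap and total volumes
#'
#' The solid of revolution under one parabolic cap has nondimensional volume
#' \eqn{V_i = \pi z_{0i} / 2}.  With the anterior cap curved into the volume
#' (geometry-1) the total oocyte volume is the difference
#' \eqn{V = \pi (z_{0P} - z_{0A}) / 2}; this also covers the flat-disc
#' anterior of geometry-2 where \eqn{z_{0A} = 0}.
#'
#' @inheritParams surface_point
#' @export
cap_volume <- function(geom, cap) {
  stopifnot(inherits(geom, "oocyte_geometry"))
  pi * cap_z0(geom, cap) / 2
}

#' @rdname cap_volume
#' @export
total_volume <- function(geom) {
  stopifnot(inherits(geom, "oocyte_geometry"))
  pi * (geom$z0P - geom$z0A) / 2
}

#' Volume of a solid of revolution from a sampled planar boundary curve
#'
#' Given a planar curve `(x(t), y(t))` sampled monotonically in `t`, the
#' volume of the solid obtained by revolving it about the x axis is
#' \deqn{V = \pi \int y(t)^2 \frac{dx}{dt}\, dt,}
#' evaluated here by trapezoidal quadrature on the samples.  Used to measure
#' oocyte volumes from extracted, symmetrized boundary outlines.
#'
#' @param x,y Numeric vectors sampling the curve.
#' @return The (signed) volume of revolution.
#' @export
revolve_volume <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2L)
  dx <- diff(x)
  if (any(dx > 0) && any(dx < 0))
    warning("boundary curve is not monotone in x; volume may be ill-defined")
  y2 <- y^2
  pi * sum((y2[-length(y2)] + y2[-1]) / 2 * dx)
}

#' Nucleus-to-oocyte volume ratio
#'
#' The nucleus is approximated as a sphere of radius `r` (nondimensional,
#' scale `L`); its volume fraction of the oocyte is
#' \eqn{\frac{4}{3}\pi r^3 / V_{oocyte}}.
#'
#' @param r Sphere radius (nondimensional).
#' @param geom An [oocyte_geometry()].
#' @export
nucleus_ratio <- function(r, geom) {
  stopifnot(r > 0)
  (4 / 3) * pi * r^3 / total_volume(geom)
}
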