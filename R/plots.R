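#' Plot a topology phase diagram
#'
#' Renders the `(epsilon, kP)` classification grid from [phase_diagram()]
#' as a colour image (base graphics): wild type red, split blue, strong
#' hypomorph green.
#'
#' @param pd A data frame from [phase_diagram()].
#' @param ... Passed to [graphics::image()].
#' @export
plot_phase_diagram <- function(pd, ...) {
  eps <- sort(unique(pd$epsilon))
  kps <- sort(unique(pd$kP))
  lev <- c("wildtype", "split", "strong_hypomorph")
  z <- matrix(match(pd$label, lev),
              nrow = length(eps))[order(unique(pd$epsilon)),
                                  order(unique(pd$kP))]
  graphics::image(log(kps), eps, t(z), zlim = c(1, 3),
                  col = c("#c23b22", "#4f6db8", "#3f9b55"),
                  xlab = "log posterior gradient width kP",
                  ylab = "mean MT length fraction epsilon", ...)
  graphics::legend("topleft", fill = c("#c23b22", "#4f6db8", "#3f9b55"),
                   legend = c("wild type", "split", "strong hypomorph"),
                   bg = "white", cex = 0.8)
  invisible(z)
}

#' Quiver plot of a motor or flow field cross-section
#'
#' Draws the in-plane vectors of the central `y = 0` cross-section with
#' the AP axis horizontal, as a quick diagnostic of the field topology.
#'
#' @param field A `motor_field` or `flow_field`.
#' @param scale Arrow length multiplier (default auto).
#' @param every Subsampling stride for arrows (default 2).
#' @param ... Passed to [graphics::plot()].
#' @export
plot_field_section <- function(field, scale = NULL, every = 2, ...) {
  if (inherits(field, "motor_field")) {
    g <- field$grid
    xs <- g$x; zs <- g$z
    jmid <- which.min(abs(g$y))
    vx <- field$vx[, jmid, ]; vz <- field$vz[, jmid, ]
    msk <- g$inside[, jmid, ]
  } else if (inherits(field, "flow_field")) {
    g <- field$grid
    xs <- g$x; zs <- g$z
    jmid <- which.min(abs(g$y))
    vx <- field$ux[, jmid, ]; vz <- field$uz[, jmid, ]
    msk <- field$mask[, jmid, ]
  } else stop("unsupported field type")
  ii <- seq(1, length(xs), by = every)
  kk <- seq(1, length(zs), by = every)
  pts <- expand.grid(i = ii, k = kk)
  keep <- msk[cbind(pts$i, pts$k)]
  pts <- pts[keep, ]
  u <- vz[cbind(pts$i, pts$k)]   # AP component drawn horizontally
  v <- vx[cbind(pts$i, pts$k)]
  nz <- u^2 + v^2 > 0
  pts <- pts[nz, ]; u <- u[nz]; v <- v[nz]
  if (is.null(scale)) {
    m <- stats::quantile(sqrt(u^2 + v^2), 0.9)
    scale <- if (m > 0) (zs[2] - zs[1]) * every / m else 1
  }
  graphics::plot(NA, xlim = range(zs), ylim = range(xs), asp = 1,
                 xlab = "AP axis", ylab = "lateral", ...)
  graphics::arrows(zs[pts$k], xs[pts$i],
                   zs[pts$k] + scale * u, xs[pts$i] + scale * v,
                   length = 0.02, col = "grey25")
  invisible(NULL)
}
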