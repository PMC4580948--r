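## small helper: spherical mask + forces on a cube grid
sphere_setup <- function(h = 0.06, R = 1) {
  n <- round(2.2 / h)
  x <- -1.1 + (seq_len(n) - 0.5) * h
  pts <- as.matrix(expand.grid(x = x, y = x, z = x))
  r2 <- rowSums(pts^2)
  list(n = n, x = x, pts = pts, r2 = r2,
       mask = array(r2 < R^2, dim = c(n, n, n)))
}

test_that("zero force and conservative (uniform) force give zero flow", {
  s <- sphere_setup(0.1)
  z <- array(0, dim = dim(s$mask))
  sol0 <- stokes_mac_solve(s$mask, 0.1, z, z, z)
  expect_equal(max(abs(sol0$ux)), 0)
  ## a uniform force is a discrete pressure gradient: no flow results
  fz <- array(1, dim = dim(s$mask)); fz[!s$mask] <- 0
  solu <- stokes_mac_solve(s$mask, 0.1, z, z, fz, tol = 1e-10)
  expect_lt(max(abs(solu$uz)), 1e-10)
  expect_lt(solu$max_div, 1e-10)
})

test_that("rotational forcing in a sphere matches the analytic Stokes solution", {
  ## f = z_hat x r  =>  u = (1 - r^2)(z_hat x r) / 10, p = const
  s <- sphere_setup(0.05)
  dm <- dim(s$mask)
  fx <- array(-s$pts[, 2], dm); fy <- array(s$pts[, 1], dm)
  fx[!s$mask] <- 0; fy[!s$mask] <- 0
  sol <- stokes_mac_solve(s$mask, 0.05, fx, fy, array(0, dm), tol = 1e-8)
  uex <- (1 - s$r2) * (-s$pts[, 2]) / 10
  vex <- (1 - s$r2) * s$pts[, 1] / 10
  sel <- s$r2 < 0.8^2
  err <- sqrt(sum((sol$ux[sel] - uex[sel])^2 + (sol$uy[sel] - vex[sel])^2 +
                    sol$uz[sel]^2) / sum(uex[sel]^2 + vex[sel]^2))
  expect_lt(err, 0.02)
  ## discrete incompressibility at the solver tolerance
  expect_lt(sol$max_div, 1e-8 * max(abs(sol$ux)) / 1e-2)
})

test_that("the solution refines consistently (reference-mesh oracle)", {
  ## same rotational problem at two resolutions; coarse interpolates to fine
  coarse <- sphere_setup(0.1); fine <- sphere_setup(0.06)
  mk <- function(s) {
    dm <- dim(s$mask)
    fx <- array(-s$pts[, 2], dm); fy <- array(s$pts[, 1], dm)
    fx[!s$mask] <- 0; fy[!s$mask] <- 0
    stokes_mac_solve(s$mask, s$x[2] - s$x[1], fx, fy, array(0, dm),
                     tol = 1e-7)
  }
  sc <- mk(coarse); sf <- mk(fine)
  ## compare on interior fine points against trilinear-interpolated coarse
  sel <- fine$r2 < 0.7^2
  ui <- ooplasm:::trilinear_interp(coarse$x, coarse$x, coarse$x,
                                   array(sc$ux, dim(coarse$mask)),
                                   fine$pts[sel, , drop = FALSE])
  relerr <- sqrt(sum((ui - sf$ux[sel])^2) / sum(sf$ux[sel]^2))
  expect_lt(relerr, 0.05)
})

test_that("Stokes response is linear in the coupling and calibration is a fixed point", {
  grid <- coarse_grid(geom1, 0.08)
  mf <- coarse_grain(small_realization, grid)
  fl1 <- solve_stokes(mf, a_prime = 45, h = 0.08, tol = 1e-8)
  fl2 <- solve_stokes(mf, a_prime = 90, h = 0.08, tol = 1e-8)
  expect_equal(2 * fl1$ux, fl2$ux, tolerance = 1e-5)
  expect_equal(2 * speed_stats(fl1, "3d")$mean_nm_s,
               speed_stats(fl2, "3d")$mean_nm_s, tolerance = 1e-5)
  cal <- calibrate_a_prime(mf, target = 14.5, a0 = 45, h = 0.08, tol = 1e-8)
  fl3 <- solve_stokes(mf, a_prime = cal$a_prime, h = 0.08, tol = 1e-8)
  expect_equal(speed_stats(fl3, "3d")$mean_nm_s, 14.5, tolerance = 1e-4)
  expect_error(calibrate_a_prime(list()), "1")
})

test_that("wild-type flows are anterior-dominant with no-slip walls", {
  grid <- coarse_grid(geom1, 0.08)
  mf <- coarse_grain(small_realization, grid)
  fl <- solve_stokes(mf, a_prime = 45, h = 0.053, tol = 1e-6)
  sp <- sqrt(fl$ux^2 + fl$uy^2 + fl$uz^2)
  zarr <- array(rep(fl$grid$z, each = prod(fl$grid$dim[1:2])),
                dim = fl$grid$dim)
  zmid <- (geom1$z0A + geom1$z0P) / 2
  expect_gt(mean(sp[fl$mask & zarr < zmid]),
            mean(sp[fl$mask & zarr >= zmid]))
  ## no-slip: boundary-adjacent speeds are small compared to the bulk
  shell <- fl$mask & !ooplasm:::erode_mask(fl$mask)
  expect_lt(mean(sp[shell]), mean(sp[fl$mask & !shell]))
})

test_that("a nucleus-sized excluded volume only disturbs the flow locally", {
  grid <- coarse_grid(geom1, 0.08)
  mf <- coarse_grain(small_realization, grid)
  nuc <- list(center = c(0.5, 0, 0.45), r = 0.21)  # ~2% of oocyte volume
  fl0 <- solve_stokes(mf, a_prime = 45, h = 0.053, tol = 1e-6)
  fl1 <- solve_stokes(mf, a_prime = 45, h = 0.053, tol = 1e-6,
                      nucleus = nuc)
  ## a cross-section on the far side of the oocyte, away from the nucleus
  imid <- which.min(abs(fl0$grid$x + 0.5))
  m <- fl0$mask[imid, , ] & fl1$mask[imid, , ]
  du <- sqrt((fl1$ux[imid, , ][m] - fl0$ux[imid, , ][m])^2 +
               (fl1$uy[imid, , ][m] - fl0$uy[imid, , ][m])^2 +
               (fl1$uz[imid, , ][m] - fl0$uz[imid, , ][m])^2)
  u0 <- sqrt(fl0$ux[imid, , ][m]^2 + fl0$uy[imid, , ][m]^2 +
               fl0$uz[imid, , ][m]^2)
  expect_lt(mean(du) / mean(u0), 0.10)
})
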