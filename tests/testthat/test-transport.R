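## tiny shared grid and zero-velocity fields
tgrid <- coarse_grid(geom1, 0.08)
zero3 <- local({
  z <- array(0, dim = tgrid$dim)
  list(ux = z, uy = z, uz = z)
})
tp <- transport_params()

test_that("derived transport parameters reproduce the printed constants", {
  expect_equal(tp$k_b, 0.0255)
  expect_equal(tp$K, 0.09775)
  expect_equal(round(tp$K, 4), 0.0978)
  expect_equal(tp$Da, 9.775)
  expect_equal(tp$Pe, 1250)
  expect_equal(tp$beta, 0.13)
  ## anchoring variant: rate constant 10 k_b, no release (k_u = 0)
  expect_equal(tp$K_anch, 10 * 0.0255 / 2)
  expect_equal(tp$K_anch, 0.1275)
  expect_equal(tp$Da_anch, 12.75)
  expect_equal(tp$beta_anch, 1)
  ## 432 steps of dt = 0.005 at tau = 100 s is 3.6 min per field pair
  expect_equal(tp$steps_per_pair * tp$dt * tp$tau / 60, 3.6)
  ## creeping-flow bound
  expect_equal(reynolds_bound(), 2.5e-4)
})

test_that("reaction equilibrium is stationary and mass is conserved exactly", {
  c0 <- array(as.numeric(tgrid$inside), dim = tgrid$dim)
  state <- list(cb = tp$beta * c0, cu = (1 - tp$beta) * c0)
  ## bound:unbound at beta : (1 - beta), i.e. cb/cu = 0.13/0.87 ~ 0.1494
  expect_equal(tp$beta / (1 - tp$beta), 0.1494, tolerance = 1e-3)
  out <- transport_step(state, zero3, zero3, tgrid, tp, nsteps = 100)
  expect_equal(out$cb, state$cb, tolerance = 1e-12)
  expect_equal(out$cu, state$cu, tolerance = 1e-12)
  ## arbitrary start: relaxes toward the beta-partition cell-wise, and
  ## total mass is conserved to round-off
  st2 <- list(cb = c0, cu = 0.3 * c0)
  out2 <- transport_step(st2, zero3, zero3, tgrid, tp, nsteps = 2000)
  tot0 <- sum(st2$cb + st2$cu)
  expect_equal(sum(out2$cb + out2$cu), tot0, tolerance = 1e-10)
  ratio <- out2$cb[tgrid$inside] / out2$cu[tgrid$inside]
  expect_equal(max(abs(ratio - tp$beta / (1 - tp$beta))), 0,
               tolerance = 1e-3)
})

test_that("upwind advection matches a 1D reference and stays positive", {
  ## straight channel of cells along z, constant motor velocity
  chan <- tgrid
  chan$inside <- array(FALSE, tgrid$dim)
  chan$inside[12, 12, ] <- TRUE
  nz <- tgrid$dim[3]
  v <- zero3; v$uz <- array(0.5, tgrid$dim)
  cb <- array(0, tgrid$dim)
  cb[12, 12, 3:5] <- 1                       # box profile
  state <- list(cb = cb, cu = array(0, tgrid$dim))
  nsteps <- 60
  ## suppress the reactions to isolate advection (beta = 0 keeps all mass
  ## bound is not allowed; instead use Da ~ 0)
  tp0 <- transport_params()
  tp0$Da <- 1e-12
  out <- transport_step(state, v, zero3, chan, tp0, nsteps = nsteps)
  ## 1D first-order upwind oracle with closed ends
  c1 <- cb[12, 12, ]
  lam <- 0.5 * tp0$dt / tgrid$dG
  for (s in seq_len(nsteps)) {
    flux <- 0.5 * c1[1:(nz - 1)]             # v > 0: upwind = left cell
    c1 <- c1 + tp0$dt / tgrid$dG * (c(0, flux) - c(flux, 0))
  }
  expect_equal(out$cb[12, 12, ], c1, tolerance = 1e-12)
  ## no new extrema, positivity, translated centre of mass
  expect_true(all(out$cb >= 0))
  expect_lte(max(out$cb), max(cb))
  com0 <- sum(tgrid$z * cb[12, 12, ]) / sum(cb[12, 12, ])
  com1 <- sum(tgrid$z * out$cb[12, 12, ]) / sum(out$cb[12, 12, ])
  expect_equal(com1 - com0, 0.5 * nsteps * tp0$dt, tolerance = 1e-6)
  ## CFL guard trips on too-fast faces
  vbad <- zero3; vbad$uz <- array(20, tgrid$dim)
  expect_error(transport_step(state, vbad, zero3, chan, tp0, nsteps = 1),
               "CFL")
})

test_that("slice fractions: uniform value, monotonicity, and saturation", {
  c0 <- array(as.numeric(tgrid$inside), dim = tgrid$dim)
  state <- list(cb = c0, cu = 0 * c0)
  fr <- slice_fraction(state, tgrid, 0.08, "posterior")
  ## analytic volume fraction of the 4 um polar slab is ~0.34%; the
  ## staircase grid overestimates the tip volume at dG = 0.08
  slab <- pi * (0.08 - (1.48^2 - 1.40^2) / (2 * 1.48)) / total_volume(geom1)
  expect_equal(fr, slab, tolerance = 1)
  expect_lt(fr, 0.05)
  expect_gt(slice_fraction(state, tgrid, 0.16), fr)
  ## all mass inside the slice
  cs <- 0 * c0
  cs[, , tgrid$z >= geom1$z0P - 0.08] <- c0[, , tgrid$z >= geom1$z0P - 0.08]
  expect_equal(slice_fraction(list(cb = cs, cu = 0 * cs), tgrid), 1)
})

test_that("the posterior anchor is a perfect sink with non-decreasing anchored mass", {
  anchor <- ooplasm:::anchor_region(tgrid, tp$anchor_thickness)
  c0 <- initial_condition(tgrid, "gaussian", center = c(0, 0, 1.1),
                          sd = 0.2)
  state <- list(cb = 0 * c0, cu = c0, ca = 0 * c0)
  prev <- 0
  for (i in 1:5) {
    state <- transport_step(state, NULL, NULL, tgrid, tp, nsteps = 200,
                            motor_on = FALSE, anchor = anchor)
    expect_gte(sum(state$ca), prev)
    prev <- sum(state$ca)
    tot <- sum(state$cb + state$cu + state$ca)
    expect_equal(tot, 1, tolerance = 1e-10)
  }
  expect_gt(prev, 0)
  ## anchored cargo never unbinds: cu near the pole stays depleted
  expect_lt(max(state$cu[anchor]), max(state$cu))
})

test_that("scenario presets cover the experiment catalogue and run on the fixture", {
  sc <- scenario_presets()
  expect_true(all(c("oskar-wt", "oskar-no-flow", "oskar-anchor-only",
                    "diffusion-only", "bicoid-posterior",
                    "bicoid-anterior-dorsal", "bicoid-anterior-middle",
                    "bicoid-conditioned", "par1-strong",
                    "par1-intermediate", "par1-shallow", "cam-patch") %in%
                    names(sc)))
  expect_equal(sc[["bicoid-posterior"]]$motor_sign, -1)
  expect_false(sc[["oskar-no-flow"]]$flow_on)
  expect_false(sc[["diffusion-only"]]$motor_on)
  ## a fixture-scale oskar run drifts posteriorly and conserves mass
  fx <- make_fixture(N_A = 400, dG = 0.1, n_pairs = 2, seed = 3)
  pairs <- build_field_pairs(fx$n_pairs, fx$geom, fx$seeding, fx$polymer,
                             fx$grid, flow = FALSE, seed = fx$seed)
  run <- run_scenario(sc[["oskar-wt"]], pairs, fx$grid, fx$transport,
                      duration_hr = 1, seed = 4)
  expect_equal(max(abs(run$series$mass - 1)), 0, tolerance = 1e-9)
  expect_gt(tail(run$series$com_z, 1), run$series$com_z[1])
  ## deterministic given the seed
  run2 <- run_scenario(sc[["oskar-wt"]], pairs, fx$grid, fx$transport,
                       duration_hr = 1, seed = 4)
  expect_identical(run$state$cb, run2$state$cb)
})

test_that("CAM patches add area-uniform seeds inside the patch", {
  seeds <- sample_seeds(geom1, seeding_params("wildtype", N_A = 500),
                        seed = 12)
  n0 <- nrow(seeds)
  aug <- add_cam_patch(seeds, rho = 0.45, phi = pi / 2, radius = 0.25,
                       n_add = 300, seed = 13)
  expect_equal(nrow(aug), n0 + 300)
  extra <- aug[(n0 + 1):nrow(aug), ]
  ctr <- surface_point(geom1, "posterior", 0.45, pi / 2)[1, ]
  d <- sqrt((extra$x - ctr[1])^2 + (extra$y - ctr[2])^2 +
              (extra$z - ctr[3])^2)
  expect_true(all(d < 0.25))
  expect_true(all(extra$cap == "posterior"))
  expect_true(all(geom_contains(geom1, as.matrix(extra[, c("x", "y", "z")]))))
  expect_equal(attr(aug, "counts")$N, attr(seeds, "counts")$N + 300)
})
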