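test_that("the rod kernel is a normalized length-weighted half-space density", {
  ## integrating N_Gamma (2 pi r^2)^-1 [1 - Phi_Gamma(r)] over an open half
  ## space reduces to N_Gamma * E[l] = 1
  Lam <- 0.1792
  val <- integrate(function(r) (1 - gamma3_length_cdf(r, Lam)) / (2 * Lam),
                   0, Inf, rel.tol = 1e-10)$value
  expect_equal(val, 1, tolerance = 1e-8)
})

test_that("net orientation on the axis is axial and posterior-pointing for wild type", {
  rp <- rod_params(seeding_params("wildtype"), epsilon = 0.28)
  mid <- c(0, 0, (0.2 + 1.48) / 2)
  res <- rod_net_orientation(mid, rp, geom1, n_phi = 64)
  ## rotational symmetry: transverse components vanish
  expect_lt(max(abs(res$o[1:2])), 1e-10)
  expect_gt(res$o[3], 0)
  expect_gt(res$pv, 0)
  expect_error(rod_net_orientation(c(0, 0, 1.6), rp, geom1), "outside")
})

test_that("axis profile agrees with a Monte-Carlo rod-sampling oracle", {
  ## brute force: sample rods (seed from the cortical density, direction
  ## uniform on the inward hemisphere, length from the gamma3 law), count
  ## length-weighted passages through a ball around axis points
  sp <- seeding_params("wildtype", N_A = 200000)
  rp <- rod_params(sp, epsilon = 0.28)
  seeds <- sample_seeds(geom1, sp, seed = 31)
  set.seed(32)
  n <- nrow(seeds)
  ## uniform inward hemisphere by flipping uniform-sphere draws
  w <- runif(n, -1, 1); ph <- runif(n, 0, 2 * pi)
  d <- cbind(sqrt(1 - w^2) * cos(ph), sqrt(1 - w^2) * sin(ph), w)
  nrm <- as.matrix(seeds[, c("nx", "ny", "nz")])
  flip <- rowSums(d * nrm) < 0
  d[flip, ] <- -d[flip, ]
  len <- sample_target_length(n, polymer_params(epsilon = 0.28), geom1)
  org <- as.matrix(seeds[, c("x", "y", "z")])
  Lam <- 0.28 * geom1$ap_length / 2
  ## route 1: sampled seeds as surface quadrature nodes with the exact
  ## direction/length weights (tight: only the cortical sampling is random)
  for (zx in c(0.6, 1.0)) {
    x <- c(0, 0, zx)
    dx <- -sweep(org, 2, x)
    r <- sqrt(rowSums(dx^2))
    hs <- rowSums(dx * nrm) > 0
    kern <- (1 - gamma3_length_cdf(r, Lam)) / r^2 * hs
    o_surf <- sum(dx[, 3] / r * kern) / sum(kern)
    qd <- rod_net_orientation(x, rp, geom1, n_phi = 64)
    expect_equal(o_surf, qd$o[3], tolerance = 0.02)
  }
  ## route 2: fully generative rods, length-weighted passages through a
  ## ball (noisy: only ~1e3 rods reach the interior neighbourhood)
  x <- c(0, 0, 0.4); delta <- 0.1
  t0 <- (x[1] - org[, 1]) * d[, 1] + (x[2] - org[, 2]) * d[, 2] +
    (x[3] - org[, 3]) * d[, 3]
  hc2 <- delta^2 - (rowSums(sweep(org, 2, x)^2) - t0^2)
  sel <- hc2 > 0
  hc <- sqrt(hc2[sel])
  chord <- pmax(0, pmin(len[sel], t0[sel] + hc) - pmax(0, t0[sel] - hc))
  mc_o <- sum(chord * d[sel, 3]) / sum(chord)
  qd <- rod_net_orientation(x, rp, geom1, n_phi = 64)
  expect_equal(mc_o, qd$o[3], tolerance = 0.05)
})

test_that("topology classification follows the axis sign pattern", {
  z <- seq(0.205, 1.475, length.out = 100)
  ## strictly positive: wild type, no fixed points
  cl <- classify_topology(data.frame(z = z, opv = 1 + 0 * z))
  expect_equal(cl$label, "wildtype")
  expect_equal(nrow(cl$fixed_points), 0)
  ## (+, -, +): split with one stable and one unstable point
  v <- cos((z - 0.205) / (1.475 - 0.205) * 2 * pi)
  cl2 <- classify_topology(data.frame(z = z, opv = v))
  expect_equal(cl2$label, "split")
  expect_equal(cl2$fixed_points$stability, c("stable", "unstable"))
  ## negative at the posterior-most point: strong hypomorph
  cl3 <- classify_topology(data.frame(z = z, opv = 0.5 - (z - 0.2)))
  expect_equal(cl3$label, "strong_hypomorph")
  expect_error(classify_topology(data.frame(z = z, opv = 0 * z)),
               "degenerate")
})

test_that("wild-type and par-1 presets land in the expected topology regimes", {
  prof_wt <- rod_axis_profile(rod_params(seeding_params("wildtype"), 0.28),
                              geom1)
  expect_equal(classify_topology(prof_wt)$label, "wildtype")
  ## near-uniform posterior seeding with a pole deficit: stable point present
  prof_sh <- rod_axis_profile(
    rod_params(seeding_params("par1-shallow"), 0.28), geom1)
  expect_equal(classify_topology(prof_sh)$label, "strong_hypomorph")
  prof_im <- rod_axis_profile(
    rod_params(seeding_params("par1-intermediate"), 0.28), geom1)
  cl <- classify_topology(prof_im)
  expect_equal(cl$label, "split")
  ## profile responds continuously to parameters
  p1 <- rod_axis_profile(rod_params(seeding_params(kP = 3), 0.28), geom1)
  p2 <- rod_axis_profile(rod_params(seeding_params(kP = 3.03), 0.28), geom1)
  expect_lt(max(abs(p1$opv - p2$opv)) / max(abs(p1$opv)), 0.05)
  ## classification is stable under doubling the quadrature resolution
  q2 <- ooplasm:::rod_rho_nodes(n_panel = 32, n_gl = 24)
  prof_wt2 <- rod_axis_profile(rod_params(seeding_params("wildtype"), 0.28),
                               geom1, quad = q2)
  expect_equal(classify_topology(prof_wt2)$label, "wildtype")
  expect_equal(prof_wt2$opv, prof_wt$opv, tolerance = 5e-3)
})

test_that("phase diagrams show the three regimes with the published adjacency", {
  eps <- seq(0.05, 0.6, length.out = 10)
  kps <- exp(seq(log(0.02), log(3), length.out = 10))
  pd0 <- phase_diagram(geom1, eps, kps, h0P = 0, n_points = 120)
  expect_setequal(unique(pd0$label),
                  c("wildtype", "split", "strong_hypomorph"))
  ## wild type at long rods and steep gradients; split at short rods
  expect_equal(pd0$label[pd0$epsilon == eps[10] & pd0$kP == kps[10]],
               "wildtype")
  expect_equal(pd0$label[pd0$epsilon == eps[1] & pd0$kP == kps[5]], "split")
  ## the wildtype region is connected along its boundary row
  wt <- with(pd0, tapply(label == "wildtype", epsilon, sum))
  expect_true(all(diff(wt) >= 0))  # grows monotonically with rod length
  ## posterior pole nucleation expands the strong-hypomorph region
  pd1 <- phase_diagram(geom1, eps, kps, h0P = 0.1, n_points = 120)
  expect_gt(sum(pd1$label == "strong_hypomorph"),
            sum(pd0$label == "strong_hypomorph"))
  ## triple point at h0P = 0.1: some 2x2 block of cells holds all three
  labm <- matrix(pd1$label, length(eps), length(kps))
  has_triple <- FALSE
  for (i in seq_len(nrow(labm) - 1))
    for (j in seq_len(ncol(labm) - 1))
      if (length(unique(c(labm[i:(i + 1), j:(j + 1)]))) == 3)
        has_triple <- TRUE
  expect_true(has_triple)
})

test_that("fixed-point separation scales as the square root near the saddle-node", {
  ## vary kP toward the split/wildtype boundary at fixed epsilon
  eps <- 0.28
  sep <- function(kp) {
    pr <- rod_axis_profile(rod_params(seeding_params(kP = kp), eps), geom1,
                           n_points = 400)
    fp <- classify_topology(pr)$fixed_points
    if (nrow(fp) < 2) return(NA_real_)
    max(fp$z) - min(fp$z)
  }
  ## bracket the boundary kP* where the pair annihilates
  lo <- 0.4; hi <- 1.2
  for (i in 1:25) {
    mid <- (lo + hi) / 2
    if (is.na(sep(mid))) hi <- mid else lo <- mid
  }
  kstar <- (lo + hi) / 2
  dk <- kstar * c(0.02, 0.08, 0.32)
  s <- vapply(kstar - dk, sep, numeric(1))
  fit <- lm(log(s) ~ log(dk))
  expect_equal(unname(coef(fit)[2]), 0.5, tolerance = 0.1)
})

test_that("saddle-node normal form has the textbook fixed-point structure", {
  nf <- normal_form_field(-1)
  expect_equal(nf$fixed_points$x, c(-1, 1))
  expect_equal(nf$fixed_points$stability, c("stable", "unstable"))
  expect_equal(normal_form_field(0)$fixed_points$stability, "degenerate")
  expect_equal(nrow(normal_form_field(1)$fixed_points), 0)
  ## the field itself: vx = x^2 + lambda, vy = -y
  expect_equal(nf$vx[, 1], nf$x^2 - 1)
  expect_equal(nf$vy[1, ], -nf$y)
})
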