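test_that("von Mises-Fisher sampler moments match the closed-form mean resultant", {
  ## kappa = 0: uniform sphere, resultant vanishes
  v0 <- sample_vmf(2e5, c(0, 0, 1), 0, seed = 1)
  expect_lt(sqrt(sum(colMeans(v0)^2)), 0.005)
  ## kappa = 18: <mu . mu_prev> = coth(18) - 1/18
  v18 <- sample_vmf(1e6, c(0, 0, 1), 18, seed = 2)
  expect_equal(mean(v18[, 3]), sigma_of_kappa(18), tolerance = 1e-3)
  expect_equal(sigma_of_kappa(18), 1 / tanh(18) - 1 / 18)
  ## moderate kappa along an arbitrary axis
  mu <- c(1, -2, 0.5) / sqrt(5.25)
  v5 <- sample_vmf(5e5, mu, 5, seed = 3)
  expect_equal(mean(v5 %*% mu), sigma_of_kappa(5), tolerance = 2e-3)
  ## kappa -> infinity: delta at the mean direction
  vb <- sample_vmf(100, mu, 1e8, seed = 4)
  expect_lt(max(abs(sweep(vb, 2, mu))), 1e-3)
  ## draws are unit vectors
  expect_equal(unname(rowSums(vb^2)), rep(1, 100), tolerance = 1e-12)
})

test_that("gamma3 target-length law: CDF limits, mean 2 Lambda, KS against the density", {
  Lam <- 0.32
  expect_equal(gamma3_length_cdf(0, Lam), 0)
  expect_equal(gamma3_length_cdf(1e3, Lam), 1)
  expect_true(all(diff(gamma3_length_cdf(seq(0, 3, 0.01), Lam)) > 0))
  pp <- polymer_params(epsilon = 0.5)  # Lambda = 0.5 * 1.28 / 2 = 0.32
  l <- sample_target_length(1e6, pp, geom1, seed = 5)
  expect_equal(mean(l), 2 * 0.32, tolerance = 0.01)
  ## independent oracle: CDF via numerical integration of the incomplete-
  ## Gamma ensemble density
  dens <- function(x) exp(-x / Lam) * (2 * Lam^2 + 2 * x * Lam + x^2) /
    (6 * Lam^3)
  cdf_num <- Vectorize(function(q) integrate(dens, 0, q)$value)
  qs <- quantile(l, c(0.1, 0.25, 0.5, 0.75, 0.9))
  expect_equal(unname(cdf_num(qs)), c(0.1, 0.25, 0.5, 0.75, 0.9),
               tolerance = 2e-3)
  ## exponential alternative has mean epsilon * AP
  pe <- polymer_params(epsilon = 0.5, length_law = "exponential")
  le <- sample_target_length(1e6, pe, geom1, seed = 6)
  expect_equal(mean(le), 0.5 * 1.28, tolerance = 0.01)
})

test_that("end-to-end and persistence-length closed forms reproduce printed values", {
  ## kappa -> 0: chains curl up to a single segment
  expect_equal(mean_end_to_end(200, 0, 0.015), 0.015, tolerance = 1e-6)
  ## kappa -> infinity: straight rods
  expect_equal(mean_end_to_end(25, 1e9, 0.015), 25 * 0.015)
  ## kappa = 18, Ns = 25: 54% of full extension (0.5475)
  frac <- mean_end_to_end(25, 18, 0.015) / (25 * 0.015)
  expect_equal(frac, 0.5475, tolerance = 1e-4)
  expect_true(frac > 0.54 && frac < 0.55)
  ## persistence length: exact and the large-kappa approximation (13.5 um)
  expect_equal(persistence_length(18, 0.015, L = 50, approx = "large_kappa"),
               13.5)
  expect_equal(persistence_length(18, 0.015, L = 50), -0.75 / log(sigma_of_kappa(18)))
  ## small-kappa approximation agrees with the exact form as kappa -> 0
  expect_equal(persistence_length(0.01, 0.015, approx = "small_kappa"),
               persistence_length(0.01, 0.015), tolerance = 1e-3)
})

test_that("simulated tangent correlations decay with the analytic persistence length", {
  for (kappa in c(5, 18, 50)) {
    tc <- tangent_correlation(kappa, n_chain = 4000, ns = 30, seed = kappa)
    keep <- tc$correlation > 0.2 & tc$lag > 0
    fit <- lm(log(correlation) ~ lag, data = tc[keep, ])
    expect_equal(unname(-coef(fit)[2]), -log(sigma_of_kappa(kappa)),
                 tolerance = 0.05)
  }
})

test_that("polymer growth respects geometry, target lengths and the stiff limit", {
  ## stiff limit: seed at the posterior pole grows a straight ray along -z
  seeds <- sample_seeds(geom1, seeding_params(N_A = 5), seed = 11)
  pole <- seeds[1, ]
  pole$cap <- "posterior"; pole$rho <- 0; pole$phi <- 0
  pole$x <- 0; pole$y <- 0; pole$z <- 1.48
  pole$nx <- 0; pole$ny <- 0; pole$nz <- -1
  attr(pole, "geometry") <- geom1
  class(pole) <- class(seeds)
  stiff <- grow_cytoskeleton(pole, polymer_params(kappa = 1e9), seed = 12)
  ori <- stiff$segments[, c("ox", "oy", "oz")]
  expect_true(nrow(ori) >= 1)
  ## first orientation is random on the hemisphere, but with infinite
  ## stiffness all subsequent ones equal it
  expect_lt(max(abs(sweep(ori, 2, ori[1, ]))), 1e-3)
  expect_true(all(geom_contains(geom1, stiff$segments[, 1:3])))

  ## a target length below lambda gives exactly one segment
  one <- grow_cytoskeleton(pole, polymer_params(epsilon = 1e-4), seed = 13)
  expect_true(all(diff(one$offsets) <= 1))

  ## realization-level invariants on the shared small fixture
  real <- small_realization
  expect_equal(length(real$terminated), nrow(real$seeds))
  expect_true(all(geom_contains(geom1, real$segments[, 1:3])))
  ## chain lengths never exceed target + lambda nor Ns_max segments
  nseg <- diff(real$offsets)
  expect_true(all(nseg <= 200))
  lam <- real$params$lambda
  expect_true(all(nseg * lam <= pmin(real$target_lengths + lam, 200 * lam)))
  ## few polymers hit the segment cap under wild-type parameters
  expect_lt(mean(real$terminated == "Ns_max"), 0.05)
  ## reproducibility from the seed chain
  seeds2 <- sample_seeds(geom1, seeding_params("wildtype", N_A = 2000),
                         seed = 7)
  real2 <- grow_cytoskeleton(seeds2, polymer_params(), seed = 8)
  expect_identical(real$segments, real2$segments)
})
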