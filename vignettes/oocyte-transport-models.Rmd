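---
title: "Modelling the oocyte microtubule cytoskeleton, cytoplasmic streaming and mRNA transport"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling the oocyte microtubule cytoskeleton, cytoplasmic streaming and mRNA transport}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ooplasm)
```

## Overview

`ooplasm` models how the stage 9 *Drosophila* oocyte localises mRNA along
its anteroposterior (AP) axis using only a cortical gradient of microtubule
(MT) nucleation. The pipeline has four layers, each usable on its own:

1. **Cytoskeleton** — stochastic MT networks grown from cortical seed
   points as persistent random walks, plus a continuum straight-rod model
   for fixed-point and bifurcation analysis.
2. **Motor-velocity field** — the local vector sum of MT segment
   orientations on a coarse grid, representing Kinesin-driven transport.
3. **Cytoplasmic flow** — incompressible Stokes flow forced by the motor
   field (slow streaming, Reynolds number below 2.5e-4).
4. **Cargo transport** — a two-species reaction-advection-diffusion system
   for bound and unbound mRNA, cycled through pairs of motor/flow fields to
   emulate network turnover.

All computation is nondimensional with length scale L = 50 um, velocity
scale V = 0.5 um/s (so time scale tau = 100 s). The AP axis is the internal
z axis; serialized outputs relabel it to x, the convention used for
visualization.

## Geometry

The oocyte is two rotationally symmetric parabolic caps,
$\sigma_i(\rho,\phi) = \rho\,\hat e_\rho + z_{0i}(1-\rho^2)\,\hat e_z$.
The standard shape (`geometry1`, $z_{0A} = 0.2$, $z_{0P} = 1.48$) has AP
length 1.28 and aspect ratio 1.56; `geometry2` ($z_{0A} = 0$, $z_{0P} = 1$)
replaces the inward-curved anterior with a flat disc. Arclength, surface
area, normals and cap volumes have closed forms, each cross-checked against
quadrature and rejection sampling in the tests.

One geometric subtlety deserves note: the inward normal of the *posterior*
cap points toward the anterior ($-\hat e_z$ at the pole), because the volume
lies below that cap. Both the polymer growth (initial directions must point
into the volume) and the rod model (rods launch into the inward half space)
depend on this orientation; with the sign flipped, more than half of all
wild-type polymers die on the boundary within a few segments and the global
orientation statistics are far off the measured ones.

## Cortical nucleation

Seed points are drawn along each cap's arclength $s$ from
$$\tilde p_\Sigma(s \mid h_0, k) = h_0 + (1-h_0)\left[1 + (k/s_0)^2\right]
\frac{s^2}{k^2+s^2},$$
which is 1 at the corner ring and $h_0$ at the pole; $k$ (nondimensional;
$kL$ in um) sets how far the low-nucleation region extends laterally. The
bracketed factor is fixed by the normalization $\tilde p_\Sigma(s_0) = 1$.
Wild type uses a steep posterior gradient ($h_{0P} = 0$, $k_P = 3$) and a
shallow anterior one ($h_{0A} = 0.8$, $k_A = 20$). The *par-1* hypomorph
series flattens the posterior gradient: $k_P = 0.35$ (intermediate),
$k_P = 0.02$ (strong, essentially uniform), and $h_{0P} = 0.7, k_P = 0.8$
(shallow pole deficit).

Sampling is inverse-transform: the per-cap CDF is tabulated on 4096
Chebyshev-spaced radial nodes and inverted by monotone (Hyman) cubic
interpolation; azimuths are uniform. Normalizing per cap and fixing the
posterior count by
$N_P = N_A\, A(h_{0P},k_P)/A(h_{0A},k_A)$ (equal point densities at the
corner ring) is distributionally identical to drawing from the globally
normalized density; the tests verify the sampled cap fractions and the
arclength distributions (Kolmogorov-Smirnov distance below 0.02 at 3e4
seeds). With $N_A = 25000$ this yields N = 55764 wild-type seeds and
N = 84953 for the strong hypomorph. Closed-form alternative densities
(power-law gradient, area-uniform) are provided for robustness checks.

## Polymer growth

Each seed grows a chain of straight segments of length $\lambda = 0.015$
(0.75 um): the first direction is uniform on the inward hemisphere,
subsequent directions follow a von Mises-Fisher distribution with
concentration $\kappa = 18$ about the previous segment. $\lambda$ is
nondimensional; this is the only reading consistent with the effective
persistence length $P \approx \lambda_{\rm dim}\kappa = 0.75 \times 18 =
13.5$ um quoted for these parameters (the exact decay length is
$-\lambda/\ln\sigma = 13.1$ um with
$\sigma = \coth\kappa - 1/\kappa$).

Target lengths follow the growing-ensemble law derived from three-step
Gamma catastrophe ageing, with CDF
$\Phi_\Gamma(l\mid 3,\Lambda) = 1 - e^{-l/\Lambda}
(6\Lambda^2 + 4l\Lambda + l^2)/(6\Lambda^2)$ and mean $2\Lambda$ set to a
fraction $\epsilon$ of the AP length ($\epsilon = 0.5$ for the polymer
model). Growth stops at the boundary (the exiting segment is dropped
entirely — no clipping; a config switch is not provided because at
$\lambda = 0.015$ the difference is below every statistic we track), at the
target length (cumulative length compared after adding each segment), or at
200 segments (under 0.01% of wild-type polymers reach the cap).

The von Mises-Fisher sampler inverts the polar-cosine CDF,
$w = 1 + \kappa^{-1}\ln(u + (1-u)e^{-2\kappa})$, with uniform azimuth,
rotated into the frame of the previous direction. Sampler moments, the
simulated tangent-correlation decay (within 5% of $-\lambda/\ln\sigma$ for
$\kappa \in \{5, 18, 50\}$) and the end-to-end formula
$\langle R\rangle = \lambda(1-\sigma^{N_s})/(1-\sigma)$ are verified
against each other in the tests.

## Directional statistics

A wild-type realization reproduces the published orientation statistics:
about 58.6% of segments point posteriorly. We report this under every
convention in circulation — the posterior:anterior percentage pair, the
excess over the unbiased 50% (8.6 points, the "8.5% more" convention:
the published experimental pair is 57.97%:42.03%), and the full
posterior-minus-anterior difference. The 2D bias in slabs one grid cell
thick rises from ~50% at the lateral cortex to ~60.5% in the mid plane, and
the near-uniform posterior seeding of the strong hypomorph evens the 3D
bias out to ~50.2%:49.8%.

## Rod model and bifurcation analysis

In the continuum limit, MTs are straight rods nucleated on the cortex with
density $p_\Sigma$, oriented uniformly into the inward half space, with
lengths from $\Phi_\Gamma$. The weighted orientation density at interior
point $x$ from boundary point $\sigma$ at distance $r$ is
$$p(x,\sigma) = p_\Sigma(s)\,\frac{N_\Gamma}{2\pi r^2}
\left[1-\Phi_\Gamma(r)\right], \qquad N_\Gamma = \frac{1}{2\Lambda},$$
multiplied by the indicator that $x$ lies in the inward half space of
$\sigma$ (rods cannot launch outward). Rods whose straight path leaves and
re-enters the domain past the inward-curved anterior are *not* excluded —
a known, small approximation of the continuum picture. Because straight
rods reach further than equally long curved chains, the rod model uses
$\epsilon = 0.28$ (the polymer chains at $\kappa = 18$ are ~55% extended).

On the axis the azimuthal integral is exact by symmetry, so profiles of the
uncorrected net orientation $o_x p_V$ reduce to 1D radial quadrature:
Gauss-Legendre on 16 geometrically graded panels (from 1e-3) per cap, which
resolves the near-pole kernel peak; classification is unchanged under
doubling the rule. Off-axis evaluation uses a product rule with a 1e-3
exclusion ball around the integrable $r^{-2}$ singularity and is validated
against brute-force Monte-Carlo rod sampling.

Topology classification follows the sign pattern of $o_x p_V$ on 200
uniform axis points offset 0.005 from the poles: positive everywhere means
wild type (the posterior pole attracts everything); negative somewhere but
positive at the posterior-most point means a stable/saddle pair splits the
volume; negative at the posterior-most point leaves only the central stable
point (strong hypomorph). One caveat discovered here: with $h_{0P} = 0$ the
seeding density vanishes *exactly* at the pole, so an arbitrarily small
attracting basin always survives at the pole tip; whether a near-uniform
configuration ($k_P \to 0$) classifies as "split" or "strong hypomorph"
then depends on the axis offset. At the 0.005 offset used here the strong
regime at $h_{0P} = 0$ appears at small $\epsilon$; any $h_{0P} > 0$
removes the degeneracy, and the published expansion of the strong region
with pole nucleation (including the triple point at $h_{0P} = 0.1$) is
reproduced. Near the phase boundary the fixed-point separation scales as
the square root of the parameter distance — the saddle-node signature,
matching the normal form $(v_x, v_y) = (x^2+\lambda, -y)$.

## Stokes flow

Forces are the motor field scaled by $a' = 45$ (geometry-1 calibration;
55 for geometry-2). The solver is a matrix-free MAC staggered-grid scheme
with a staircase no-slip boundary: velocity unknowns live on faces shared
by two interior cells, and the pressure Schur complement
$G^T A^{-1} G$ (A the vector Laplacian) is solved by conjugate gradients
with inner CG solves, driving the discrete divergence to the requested
tolerance (1e-8 and below is routine). Validation: zero and conservative
forcings give exactly zero flow; rotational forcing in a sphere matches the
closed-form solution $u = (1-r^2)(\hat z \times r)/10$ within 2% away from
the staircase boundary; refinement is consistent between meshes.

The mean speed statistic converges under refinement (16.6 nm/s for one
realization at h = 0.0286 and h = 0.02, versus 18.0 at h = 0.04); ensembles
at h = 0.0286 average 15.5-16.6 nm/s against the published calibration
point of 14.5 nm/s at the same $a'$ — about 10% fast, which we report
rather than recalibrate. The "2D cross-section" statistic is
the speed of the 3D field on the central section; the near-equality of the
published 2D and 3D values (14.8 vs 14.5 nm/s) identifies this convention,
whereas an in-plane projection would sit ~20% below the 3D mean.
Linearity in $a'$ makes calibration to any target a one-solve operation.
A spherical no-slip nucleus (~2% of the volume, anterior) perturbs the flow
only near itself — flows are volume-forced, not boundary-forced.

## Cargo transport

Bound cargo ($c_b$, fraction $\beta = 0.13$ at equilibrium) advects along
the motor field; unbound cargo ($c_u$) advects with the flow and diffuses
with $Pe^{-1}$:
$$\partial_t c_b + \nabla\cdot(v_m c_b) = 2Da\,[\beta c_u - (1-\beta)c_b],$$
and conversely for $c_u$ with diffusion. Rates derive from $k_u = 0.17$
s$^{-1}$ and $k_b = 0.0255$ s$^{-1}$ (we keep the published rounded
$k_b$; recomputing it from $\beta$ and $k_u$ gives 0.0254, and propagating
the published value reproduces every derived constant: K = 0.09775,
Da = 9.775, Pe = 1250). The scheme is conservative first-order upwind
finite volumes on the staggered grid, explicit in time with dt = 0.005
(CFL-checked), no-flux walls, and exactly conservative reaction exchange;
mass is conserved to round-off and positivity is preserved. When the flow
was solved on the same lattice, its exactly divergence-free face field is
used for advection directly; re-averaging cell-centred values would
introduce spurious compressions of the same order as the velocity itself.

Each motor/flow pair is active for 432 steps (3.6 simulated minutes);
scenarios cycle through a library of pairs in seed-randomized order.
Initial conditions: a Gaussian cloud (s.d. 0.15) at the volume centroid
(on the axis at $(z_{0A}+z_{0P})/3$ — the two-cap solid bulges
anteriorly) for oskar-type scenarios; injection boli of s.d. 0.08 at named
sites; or a two-cell layer on the anterior surface for conditioned bicoid.
Dynein transport is the motor field with inverted sign. The anchoring
variant replaces the bound state with an anchored one: binding at
$10 k_b$ ($Da^{\rm anch} = 12.75$), no release, and *only at the extreme
posterior pole* — implemented as the cells within 0.08 (4 um) of the pole
point. This is deliberately smaller than the 4-um readout slab: anchoring
is a property of the very posterior boundary, while the slab is the
localisation readout.

### Reduced study sizes and what they show

Full-scale runs in this package use the published grid (dG = 0.04,
50x50x32) and durations (6 h = 100 field-pair activations), but a library
of 10 field pairs rather than 50, and Stokes solves at the transport
resolution; the acceptance checks additionally run reduced qualitative
scenarios without flows where the flow contribution is secondary. Under
these conditions the wild-type 4-um posterior slab holds 12-16% of cargo
(published: 12.5%), the pole anchor without motor transport captures 3-4%
(published: 2.7%), and pure diffusion leaves ~0.35% — close to the slab's
share of the volume at uniformity (0.34%), which is an upper bound for any
centred initial condition at late times. The published diffusion-only
figure of 2.2% cannot be produced by a 3D 4-um slab readout under any
initial condition we consider plausible; we report our computed value
rather than force agreement. Likewise, in our discretization removing the
flows *raises* posterior localisation slightly, whereas the published runs
report a small decrease; both agree that flows are a secondary contribution
to localisation, which is the scientific claim at stake.

### What the generator does and does not emulate

The synthetic cytoskeletons capture cortical nucleation gradients,
finite-length persistent-random-walk geometry and network turnover; they do
not model dynamic instability in time, MT-MT interactions, motor stepping,
organelle crowding, or anchoring biology beyond the idealized posterior
sink. Passing tests therefore support the *sufficiency* of cortical
nucleation gradients for compartmentalization and localisation in this
model class — not a complete account of oocyte transport.

## Numerical choices summarized

- CDF inversions (seeding, target lengths): dense tabulation + monotone
  cubic interpolation, error < 1e-6 in the sampled coordinate.
- Membership tests are boundary-inclusive with tolerance 1e-12 (seed
  points lie exactly on the surface).
- Posterior seed count rounds to the nearest integer.
- Rod quadrature: graded Gauss-Legendre panels as above; axis grids of
  120-400 points depending on the resolution the caller needs.
- Stokes: outer tolerance 1e-6 to 1e-8 relative (divergence residual),
  inner Laplacian CG at 1e-8 to 1e-10.
- Transport stability: advective CFL below 1 (checked, hard error) and
  diffusive number $6 Pe^{-1} dt/h^2 < 1$.
- RNG: R's Mersenne-Twister throughout; every sampling function accepts a
  seed, and realization containers record it.

## A worked example

```{r example, eval = FALSE}
geom  <- oocyte_geometry("geometry1")
seeds <- sample_seeds(geom, seeding_params("wildtype"), seed = 1)
real  <- grow_cytoskeleton(seeds, polymer_params())
directional_bias(real, "3d")$frac_posterior       # ~58.6 %
motor <- coarse_grain(real)
flow  <- solve_stokes(motor, a_prime = 45)
speed_stats(flow, "3d")$mean_nm_s                 # ~15-18 nm/s
grid  <- coarse_grid(geom, 0.04)
pairs <- build_field_pairs(10, geom, seeding_params("wildtype"),
                           polymer_params(), grid, seed = 1)
run   <- run_scenario(scenario_presets()[["oskar-wt"]], pairs, grid,
                      transport_params(), seed = 1)
tail(run$series$posterior, 1)                     # ~0.12-0.16
```
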