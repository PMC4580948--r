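#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// von Mises-Fisher draw on the unit sphere around direction mu.
// Polar cosine by inverse CDF: w = 1 + log(u + (1-u) exp(-2 kappa)) / kappa;
// azimuth uniform; result rotated into the frame of mu.
static inline void vmf_draw(const double* mu, double kappa, double* out) {
  double w;
  if (kappa < 1e-12) {
    w = 2.0 * unif_rand() - 1.0;
  } else {
    double u = unif_rand();
    w = 1.0 + std::log(u + (1.0 - u) * std::exp(-2.0 * kappa)) / kappa;
    if (w < -1.0) w = -1.0;
    if (w > 1.0) w = 1.0;
  }
  double phi = 2.0 * M_PI * unif_rand();
  double st = std::sqrt(std::max(0.0, 1.0 - w * w));
  double vx = st * std::cos(phi), vy = st * std::sin(phi);
  // orthonormal basis completing mu
  double e1[3];
  if (std::fabs(mu[0]) < 0.6) {
    e1[0] = 0.0; e1[1] = -mu[2]; e1[2] = mu[1];
  } else {
    e1[0] = -mu[2]; e1[1] = 0.0; e1[2] = mu[0];
  }
  double n1 = std::sqrt(e1[0]*e1[0] + e1[1]*e1[1] + e1[2]*e1[2]);
  e1[0] /= n1; e1[1] /= n1; e1[2] /= n1;
  double e2[3] = {mu[1]*e1[2] - mu[2]*e1[1],
                  mu[2]*e1[0] - mu[0]*e1[2],
                  mu[0]*e1[1] - mu[1]*e1[0]};
  for (int d = 0; d < 3; ++d)
    out[d] = vx * e1[d] + vy * e2[d] + w * mu[d];
}

static inline void uniform_sphere(double* out) {
  double w = 2.0 * unif_rand() - 1.0;
  double phi = 2.0 * M_PI * unif_rand();
  double st = std::sqrt(std::max(0.0, 1.0 - w * w));
  out[0] = st * std::cos(phi);
  out[1] = st * std::sin(phi);
  out[2] = w;
}

// [[Rcpp::export]]
NumericMatrix cpp_sample_vmf(int n, NumericVector mu, double kappa) {
  NumericMatrix out(n, 3);
  double m[3] = {mu[0], mu[1], mu[2]};
  double nm = std::sqrt(m[0]*m[0] + m[1]*m[1] + m[2]*m[2]);
  if (nm <= 0) stop("`mu` must be a nonzero vector");
  for (int d = 0; d < 3; ++d) m[d] /= nm;
  double v[3];
  for (int i = 0; i < n; ++i) {
    vmf_draw(m, kappa, v);
    out(i, 0) = v[0]; out(i, 1) = v[1]; out(i, 2) = v[2];
  }
  return out;
}

static inline bool inside_oocyte(double x, double y, double z,
                                 double z0A, double z0P) {
  const double tol = 1e-12;
  double rho2 = x * x + y * y;
  if (rho2 > 1.0 + tol) return false;
  return z >= z0A * (1.0 - rho2) - tol && z <= z0P * (1.0 - rho2) + tol;
}

// Grow persistent-random-walk polymers from cortical seed points.
// First segment orientation: uniform on the inward hemisphere (rejection on
// n . mu < 0); subsequent orientations von Mises-Fisher around the previous
// segment.  Growth stops at the first segment whose endpoint leaves the
// geometry (segment dropped), when cumulative length reaches the target, or
// at ns_max segments.
// Returns per-segment midpoints and orientations plus per-polymer offsets
// (0-based, length n+1) and termination codes (1 target, 2 boundary,
// 3 ns_max).
// [[Rcpp::export]]
List cpp_grow_polymers(NumericMatrix seed_pos, NumericMatrix seed_nrm,
                       NumericVector target_len, double lambda, double kappa,
                       int ns_max, double z0A, double z0P) {
  int n = seed_pos.nrow();
  if (seed_nrm.nrow() != n || target_len.size() != n)
    stop("seed inputs have inconsistent lengths");
  std::vector<double> mid, ori;
  mid.reserve(3 * n * 8); ori.reserve(3 * n * 8);
  IntegerVector offsets(n + 1), term(n);
  long nseg_total = 0;

  for (int s = 0; s < n; ++s) {
    double pos[3] = {seed_pos(s, 0), seed_pos(s, 1), seed_pos(s, 2)};
    double nrm[3] = {seed_nrm(s, 0), seed_nrm(s, 1), seed_nrm(s, 2)};
    double dir[3];
    double target = target_len[s];
    double len = 0.0;
    int code = 3;
    for (int i = 0; i < ns_max; ++i) {
      if (i == 0) {
        do {
          uniform_sphere(dir);
        } while (dir[0]*nrm[0] + dir[1]*nrm[1] + dir[2]*nrm[2] < 0.0);
      } else {
        double prev[3] = {dir[0], dir[1], dir[2]};
        vmf_draw(prev, kappa, dir);
      }
      double nxt[3] = {pos[0] + lambda * dir[0],
                       pos[1] + lambda * dir[1],
                       pos[2] + lambda * dir[2]};
      if (!inside_oocyte(nxt[0], nxt[1], nxt[2], z0A, z0P)) {
        code = 2;
        break;
      }
      for (int d = 0; d < 3; ++d) {
        mid.push_back(pos[d] + 0.5 * lambda * dir[d]);
        ori.push_back(dir[d]);
      }
      ++nseg_total;
      pos[0] = nxt[0]; pos[1] = nxt[1]; pos[2] = nxt[2];
      len += lambda;
      if (len >= target) { code = 1; break; }
    }
    term[s] = code;
    offsets[s + 1] = (int) nseg_total;
  }

  int m = (int) nseg_total;
  NumericMatrix midM(m, 3), oriM(m, 3);
  for (int i = 0; i < m; ++i)
    for (int d = 0; d < 3; ++d) {
      midM(i, d) = mid[3 * (size_t)i + d];
      oriM(i, d) = ori[3 * (size_t)i + d];
    }
  return List::create(_["mid"] = midM, _["ori"] = oriM,
                      _["offsets"] = offsets, _["terminated"] = term);
}

// Free persistent random walks (no geometry), returning segment orientations
// for tangent-correlation analysis: n_chain chains of ns segments each,
// initial orientation uniform on the sphere.
// [[Rcpp::export]]
NumericMatrix cpp_free_chains(int n_chain, int ns, double kappa) {
  NumericMatrix out(n_chain * ns, 3);
  double dir[3];
  for (int c = 0; c < n_chain; ++c) {
    uniform_sphere(dir);
    for (int i = 0; i < ns; ++i) {
      if (i > 0) {
        double prev[3] = {dir[0], dir[1], dir[2]};
        vmf_draw(prev, kappa, dir);
      }
      int r = c * ns + i;
      out(r, 0) = dir[0]; out(r, 1) = dir[1]; out(r, 2) = dir[2];
    }
  }
  return out;
}
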