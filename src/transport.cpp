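#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Explicit finite-volume update of the two-species reaction-advection-
// diffusion system on a masked regular grid with staggered face fluxes:
//
//   dt cb + div(vm cb) =  2 Da (beta cu - (1-beta) cb)
//   dt cu + div(u  cu) = -2 Da (beta cu - (1-beta) cb) + Pe^-1 lap(cu)
//
// First-order upwind advection, no-flux walls (masked faces carry zero
// flux), conservative reaction exchange.  The optional anchored species ca
// replaces the bound state: inside the anchor region cargo binds at rate
// 2 Da_anch (beta_anch = 1, no release) and is never advected.
//
// Face velocities are averages of the two adjacent cell-centre values;
// faces touching a masked cell are closed.

namespace {
inline int id3(int i, int j, int k, int nx, int ny) {
  return i + nx * (j + ny * k);
}
}

// [[Rcpp::export]]
List cpp_transport_steps(IntegerVector mask, IntegerVector dims,
                         NumericVector vmx, NumericVector vmy,
                         NumericVector vmz,
                         NumericVector ux, NumericVector uy, NumericVector uz,
                         NumericVector cb0, NumericVector cu0,
                         NumericVector ca0,
                         int nsteps, double dt, double h,
                         double Da, double beta, double invPe,
                         bool motor_on, double Da_anch,
                         IntegerVector anchor_mask,
                         NumericVector ufx = NumericVector(0),
                         NumericVector ufy = NumericVector(0),
                         NumericVector ufz = NumericVector(0)) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  int ntot = nx * ny * nz;
  if (mask.size() != ntot) stop("mask/dims disagree");
  bool anchor_on = Da_anch > 0;
  if (anchor_on && anchor_mask.size() != ntot)
    stop("anchor_mask/dims disagree");

  // face flow velocities: either the supplied staggered (divergence-free)
  // field, or averages of the cell-centred values
  bool have_faces = ufx.size() > 0;
  if (have_faces &&
      (ufx.size() != (nx + 1) * ny * nz || ufy.size() != nx * (ny + 1) * nz ||
       ufz.size() != nx * ny * (nz + 1)))
    stop("face-velocity arrays have wrong dimensions");

  std::vector<int> cL, cR;
  std::vector<double> fvm, fu;
  {
    const NumericVector* vv[3] = {&vmx, &vmy, &vmz};
    const NumericVector* uu[3] = {&ux, &uy, &uz};
    int di[3] = {1, 0, 0}, dj[3] = {0, 1, 0}, dk[3] = {0, 0, 1};
    for (int d = 0; d < 3; ++d)
      for (int k = 0; k < nz; ++k)
        for (int j = 0; j < ny; ++j)
          for (int i = 0; i < nx; ++i) {
            int ii = i + di[d], jj = j + dj[d], kk = k + dk[d];
            if (ii >= nx || jj >= ny || kk >= nz) continue;
            int a = id3(i, j, k, nx, ny), b = id3(ii, jj, kk, nx, ny);
            if (!mask[a] || !mask[b]) continue;
            cL.push_back(a);
            cR.push_back(b);
            fvm.push_back(0.5 * ((*vv[d])[a] + (*vv[d])[b]));
            double uface;
            if (have_faces) {
              if (d == 0) uface = ufx[(i + 1) + (nx + 1) * (j + ny * k)];
              else if (d == 1) uface = ufy[i + nx * ((j + 1) + (ny + 1) * k)];
              else uface = ufz[i + nx * (j + ny * (k + 1))];
            } else {
              uface = 0.5 * ((*uu[d])[a] + (*uu[d])[b]);
            }
            fu.push_back(uface);
          }
  }
  size_t nf = cL.size();

  // stability checks
  double cmax = 0;
  int worst = -1;
  for (size_t f = 0; f < nf; ++f) {
    double c = std::max(std::fabs(fvm[f]), std::fabs(fu[f])) * dt / h;
    if (c > cmax) { cmax = c; worst = cL[f]; }
  }
  if (cmax > 1.0)
    stop("advective CFL violated (%.3f) at cell %d", cmax, worst + 1);
  if (6.0 * invPe * dt / (h * h) > 1.0)
    stop("diffusive stability limit violated");

  std::vector<double> cb(cb0.begin(), cb0.end());
  std::vector<double> cu(cu0.begin(), cu0.end());
  std::vector<double> ca(ca0.begin(), ca0.end());
  std::vector<double> dcb(ntot), dcu(ntot);

  double inv_h = 1.0 / h;
  for (int stp = 0; stp < nsteps; ++stp) {
    std::fill(dcb.begin(), dcb.end(), 0.0);
    std::fill(dcu.begin(), dcu.end(), 0.0);
    for (size_t f = 0; f < nf; ++f) {
      int a = cL[f], b = cR[f];
      if (motor_on) {
        double v = fvm[f];
        double flx = v > 0 ? v * cb[a] : v * cb[b];
        dcb[a] -= flx * inv_h;
        dcb[b] += flx * inv_h;
      }
      double vu = fu[f];
      double flx = (vu > 0 ? vu * cu[a] : vu * cu[b]) -
        invPe * (cu[b] - cu[a]) * inv_h;
      dcu[a] -= flx * inv_h;
      dcu[b] += flx * inv_h;
    }
    if (anchor_on) {
      for (int c = 0; c < ntot; ++c) {
        if (!mask[c]) continue;
        if (anchor_mask[c]) {
          double rate = 2.0 * Da_anch * cu[c];
          ca[c] += dt * rate;
          dcu[c] -= rate;
        }
        cu[c] += dt * dcu[c];
      }
    } else if (motor_on) {
      for (int c = 0; c < ntot; ++c) {
        if (!mask[c]) continue;
        double R = 2.0 * Da * (beta * cu[c] - (1.0 - beta) * cb[c]);
        cb[c] += dt * (dcb[c] + R);
        cu[c] += dt * (dcu[c] - R);
      }
    } else {
      // no motor transport and no anchor: binding is off (k_b = 0)
      for (int c = 0; c < ntot; ++c)
        if (mask[c]) cu[c] += dt * dcu[c];
    }
  }

  NumericVector cbO(cb.begin(), cb.end());
  NumericVector cuO(cu.begin(), cu.end());
  NumericVector caO(ca.begin(), ca.end());
  cbO.attr("dim") = dims; cuO.attr("dim") = dims; caO.attr("dim") = dims;
  return List::create(_["cb"] = cbO, _["cu"] = cuO, _["ca"] = caO,
                      _["cfl"] = cmax);
}
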