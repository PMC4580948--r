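#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Steady incompressible Stokes solver on a MAC staggered grid with an
// immersed (staircase) no-slip boundary given by a cell mask.
//
//   -laplace(u) + grad p = f,   div u = 0
//
// Velocity unknowns live on faces shared by two interior cells; all other
// faces are held at zero (no slip, first order).  The pressure Schur
// complement G^T A^{-1} G (A = vector Laplacian, SPD) is solved by outer
// conjugate gradients with inner CG solves for A; constants are projected
// out of the pressure.

namespace {

struct FaceSet {
  std::vector<int> cellL, cellR;   // interior cell ids either side
  std::vector<int> nbr;            // 6 * nact neighbour face ids (-1 = wall)
  std::vector<int> gpos;           // face-grid linear position per active face
  int nact = 0;
};

inline int idx3(int i, int j, int k, int d0, int d1) {
  return i + d0 * (j + d1 * k);
}

// Build active faces for one velocity component.
// dir: 0=x,1=y,2=z. Face-grid dims: cell dims with +1 in `dir`.
FaceSet build_faces(const std::vector<int>& cid, int nx, int ny, int nz,
                    int dir) {
  FaceSet F;
  int fdx = nx + (dir == 0), fdy = ny + (dir == 1), fdz = nz + (dir == 2);
  std::vector<int> fid((size_t)fdx * fdy * fdz, -1);
  for (int k = 0; k < fdz; ++k)
    for (int j = 0; j < fdy; ++j)
      for (int i = 0; i < fdx; ++i) {
        int iL = i - (dir == 0), jL = j - (dir == 1), kL = k - (dir == 2);
        if (iL < 0 || jL < 0 || kL < 0) continue;
        if (i >= nx || j >= ny || k >= nz) continue;
        int cL = cid[idx3(iL, jL, kL, nx, ny)];
        int cR = cid[idx3(i, j, k, nx, ny)];
        if (cL < 0 || cR < 0) continue;
        int p = idx3(i, j, k, fdx, fdy);
        fid[p] = F.nact++;
        F.cellL.push_back(cL);
        F.cellR.push_back(cR);
        F.gpos.push_back(p);
      }
  F.nbr.assign((size_t)6 * F.nact, -1);
  for (int a = 0; a < F.nact; ++a) {
    int p = F.gpos[a];
    int i = p % fdx, j = (p / fdx) % fdy, k = p / (fdx * fdy);
    int di[6] = {-1, 1, 0, 0, 0, 0};
    int dj[6] = {0, 0, -1, 1, 0, 0};
    int dk[6] = {0, 0, 0, 0, -1, 1};
    for (int q = 0; q < 6; ++q) {
      int ii = i + di[q], jj = j + dj[q], kk = k + dk[q];
      if (ii < 0 || jj < 0 || kk < 0 || ii >= fdx || jj >= fdy || kk >= fdz)
        continue;
      F.nbr[(size_t)6 * a + q] = fid[idx3(ii, jj, kk, fdx, fdy)];
    }
  }
  return F;
}

// A x = (6x - sum(neighbours)) / h^2 on active faces (Dirichlet 0 outside)
void applyA(const FaceSet& F, const std::vector<double>& x,
            std::vector<double>& out, double inv_h2) {
  for (int a = 0; a < F.nact; ++a) {
    double s = 6.0 * x[a];
    const int* nb = &F.nbr[(size_t)6 * a];
    for (int q = 0; q < 6; ++q)
      if (nb[q] >= 0) s -= x[nb[q]];
    out[a] = s * inv_h2;
  }
}

// CG solve A x = b; x used as initial guess; returns iterations
int cgA(const FaceSet& F, const std::vector<double>& b, std::vector<double>& x,
        double inv_h2, double tol, int maxit) {
  int n = F.nact;
  std::vector<double> r(n), p(n), Ap(n);
  applyA(F, x, Ap, inv_h2);
  double rr = 0, bb = 0;
  for (int i = 0; i < n; ++i) {
    r[i] = b[i] - Ap[i];
    p[i] = r[i];
    rr += r[i] * r[i];
    bb += b[i] * b[i];
  }
  if (bb == 0) { std::fill(x.begin(), x.end(), 0.0); return 0; }
  double tol2 = tol * tol * bb;
  int it = 0;
  while (rr > tol2 && it < maxit) {
    applyA(F, p, Ap, inv_h2);
    double pAp = 0;
    for (int i = 0; i < n; ++i) pAp += p[i] * Ap[i];
    double alpha = rr / pAp;
    double rr_new = 0;
    for (int i = 0; i < n; ++i) {
      x[i] += alpha * p[i];
      r[i] -= alpha * Ap[i];
      rr_new += r[i] * r[i];
    }
    double beta = rr_new / rr;
    rr = rr_new;
    for (int i = 0; i < n; ++i) p[i] = r[i] + beta * p[i];
    ++it;
  }
  return it;
}

} // namespace

// [[Rcpp::export]]
List cpp_stokes_mac(IntegerVector mask, IntegerVector dims,
                    NumericVector fx, NumericVector fy, NumericVector fz,
                    double h, double tol = 1e-8, int maxit_outer = 500,
                    int maxit_inner = 20000, double tol_inner = 1e-10) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  int ntot = nx * ny * nz;
  if (mask.size() != ntot || fx.size() != ntot)
    stop("mask/force dimensions disagree");
  std::vector<int> cid(ntot, -1);
  int ncell = 0;
  for (int p = 0; p < ntot; ++p)
    if (mask[p]) cid[p] = ncell++;
  if (ncell == 0) stop("empty mask");

  FaceSet F[3] = {build_faces(cid, nx, ny, nz, 0),
                  build_faces(cid, nx, ny, nz, 1),
                  build_faces(cid, nx, ny, nz, 2)};
  double inv_h2 = 1.0 / (h * h), inv_h = 1.0 / h;

  // force at faces: average of adjacent cell-centre values
  std::vector<double> fface[3], w[3], y[3], g[3], u[3];
  const NumericVector* fcomp[3] = {&fx, &fy, &fz};
  std::vector<double> fcell[3];
  for (int d = 0; d < 3; ++d) {
    fcell[d].assign(ncell, 0.0);
    for (int p = 0; p < ntot; ++p)
      if (cid[p] >= 0) fcell[d][cid[p]] = (*fcomp[d])[p];
    int n = F[d].nact;
    fface[d].assign(n, 0.0);
    for (int a = 0; a < n; ++a)
      fface[d][a] = 0.5 * (fcell[d][F[d].cellL[a]] + fcell[d][F[d].cellR[a]]);
    w[d].assign(n, 0.0);
    y[d].assign(n, 0.0);
    g[d].assign(n, 0.0);
    u[d].assign(n, 0.0);
  }

  // w = A^{-1} f ; b = -div(w)
  long inner_total = 0;
  for (int d = 0; d < 3; ++d)
    inner_total += cgA(F[d], fface[d], w[d], inv_h2, tol_inner, maxit_inner);
  std::vector<double> b(ncell, 0.0);
  for (int d = 0; d < 3; ++d)
    for (int a = 0; a < F[d].nact; ++a) {
      b[F[d].cellL[a]] -= w[d][a] * inv_h;
      b[F[d].cellR[a]] += w[d][a] * inv_h;
    }
  // project out mean
  auto project = [&](std::vector<double>& v) {
    double m = 0;
    for (int c = 0; c < ncell; ++c) m += v[c];
    m /= ncell;
    for (int c = 0; c < ncell; ++c) v[c] -= m;
  };
  project(b);

  // outer CG on S p = b, S = G^T A^{-1} G  (applied as -div(A^{-1} G p))
  std::vector<double> pvec(ncell, 0.0), r(b), pdir(b), Sp(ncell);
  double rr = 0, bb = 0;
  for (int c = 0; c < ncell; ++c) { rr += r[c] * r[c]; bb += b[c] * b[c]; }
  double tol2 = tol * tol * bb;
  int it_outer = 0;
  while (bb > 0 && rr > tol2 && it_outer < maxit_outer) {
    // Sp = -div(A^{-1} G pdir)
    for (int d = 0; d < 3; ++d) {
      for (int a = 0; a < F[d].nact; ++a)
        g[d][a] = (pdir[F[d].cellR[a]] - pdir[F[d].cellL[a]]) * inv_h;
      std::fill(y[d].begin(), y[d].end(), 0.0);
      inner_total += cgA(F[d], g[d], y[d], inv_h2, tol_inner, maxit_inner);
    }
    std::fill(Sp.begin(), Sp.end(), 0.0);
    for (int d = 0; d < 3; ++d)
      for (int a = 0; a < F[d].nact; ++a) {
        Sp[F[d].cellL[a]] -= y[d][a] * inv_h;
        Sp[F[d].cellR[a]] += y[d][a] * inv_h;
      }
    project(Sp);
    double pSp = 0;
    for (int c = 0; c < ncell; ++c) pSp += pdir[c] * Sp[c];
    if (pSp <= 0) break; // nullspace direction; converged in range
    double alpha = rr / pSp;
    double rr_new = 0;
    for (int c = 0; c < ncell; ++c) {
      pvec[c] += alpha * pdir[c];
      r[c] -= alpha * Sp[c];
      rr_new += r[c] * r[c];
    }
    double beta = rr_new / rr;
    rr = rr_new;
    for (int c = 0; c < ncell; ++c) pdir[c] = r[c] + beta * pdir[c];
    ++it_outer;
  }

  // u = A^{-1} (f - G p)
  for (int d = 0; d < 3; ++d) {
    for (int a = 0; a < F[d].nact; ++a)
      g[d][a] = fface[d][a] -
        (pvec[F[d].cellR[a]] - pvec[F[d].cellL[a]]) * inv_h;
    u[d] = w[d]; // warm start
    inner_total += cgA(F[d], g[d], u[d], inv_h2, tol_inner, maxit_inner);
  }

  // diagnostics: max |div u|
  std::vector<double> div(ncell, 0.0);
  for (int d = 0; d < 3; ++d)
    for (int a = 0; a < F[d].nact; ++a) {
      div[F[d].cellL[a]] += u[d][a] * inv_h;
      div[F[d].cellR[a]] -= u[d][a] * inv_h;
    }
  double max_div = 0;
  for (int c = 0; c < ncell; ++c)
    max_div = std::max(max_div, std::fabs(div[c]));

  // face velocities on the full face grids (inactive faces zero), for
  // consumers needing the exactly divergence-free staggered field
  NumericVector ufx((nx + 1) * ny * nz), ufy(nx * (ny + 1) * nz),
    ufz(nx * ny * (nz + 1));
  NumericVector* uf[3] = {&ufx, &ufy, &ufz};
  for (int d = 0; d < 3; ++d)
    for (int a = 0; a < F[d].nact; ++a)
      (*uf[d])[F[d].gpos[a]] = u[d][a];
  ufx.attr("dim") = IntegerVector::create(nx + 1, ny, nz);
  ufy.attr("dim") = IntegerVector::create(nx, ny + 1, nz);
  ufz.attr("dim") = IntegerVector::create(nx, ny, nz + 1);

  // cell-centred velocity: average of the two faces of each cell (absent
  // faces are no-slip zero)
  NumericVector ux(ntot), uy(ntot), uz(ntot), pr(ntot);
  std::vector<std::vector<double>> ucc(3, std::vector<double>(ncell, 0.0));
  for (int d = 0; d < 3; ++d) {
    std::vector<double> acc(ncell, 0.0);
    for (int a = 0; a < F[d].nact; ++a) {
      acc[F[d].cellL[a]] += 0.5 * u[d][a];
      acc[F[d].cellR[a]] += 0.5 * u[d][a];
    }
    ucc[d] = acc;
  }
  for (int p = 0; p < ntot; ++p) {
    int c = cid[p];
    if (c >= 0) {
      ux[p] = ucc[0][c]; uy[p] = ucc[1][c]; uz[p] = ucc[2][c];
      pr[p] = pvec[c];
    }
  }
  ux.attr("dim") = dims; uy.attr("dim") = dims; uz.attr("dim") = dims;
  pr.attr("dim") = dims;

  return List::create(_["ux"] = ux, _["uy"] = uy, _["uz"] = uz,
                      _["ufx"] = ufx, _["ufy"] = ufy, _["ufz"] = ufz,
                      _["p"] = pr, _["max_div"] = max_div,
                      _["outer_iterations"] = it_outer,
                      _["inner_iterations"] = (double) inner_total,
                      _["n_cells"] = ncell);
}
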