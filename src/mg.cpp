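#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Geometric multigrid preconditioner for the 27-band voxel FEM operator.
// Band m (0-based) holds A[n, n + shift(m)] at position n, with the offset
// decomposition m = (dx+1) + 3(dy+1) + 9(dz+1), dx fastest.
//
// Coarsening: vertex-centered 2:1 (coarse node I at fine node 2I), trilinear
// interpolation, Galerkin coarse operators (P^T A P), which stay within the
// 27-band structure. Smoother: one symmetric Gauss-Seidel sweep, so the
// V-cycle is a symmetric positive-definite preconditioner for CG.
//
// The whole hierarchy is stored and applied in single precision — the
// V-cycle only preconditions; CG's own residuals and matrix-vector products
// stay in double precision on the input operator. A deflation-style coarse
// correction over high-conductivity (metal) component indicator vectors is
// added to the preconditioner to remove the near-rigid cluster modes that
// neither the smoother nor the trilinear coarse space can represent.

struct Level {
  int nn[3];
  R_xlen_t N;
  std::vector<float> B;    // 27 * N, column-major by band
  std::vector<long long> shift;
  std::vector<float> diag;
  std::vector<float> r, z, tmp, t2, resid;   // work vectors
};

static inline R_xlen_t idx3(int ix, int iy, int iz, const int* nn) {
  return (R_xlen_t)ix + (R_xlen_t)nn[0] * ((R_xlen_t)iy + (R_xlen_t)nn[1] * iz);
}

static void level_shifts(Level& L) {
  L.shift.resize(27);
  for (int m = 0; m < 27; ++m) {
    int dx = m % 3 - 1, dy = (m / 3) % 3 - 1, dz = m / 9 - 1;
    L.shift[m] = (long long)dx + (long long)L.nn[0] * ((long long)dy + (long long)L.nn[1] * dz);
  }
  L.diag.resize(L.N);
  const float* D = L.B.data() + (R_xlen_t)13 * L.N;  // m = 13 is shift 0
  for (R_xlen_t n = 0; n < L.N; ++n) L.diag[n] = D[n];
}

// double-precision banded matvec on the input operator (for CG itself)
static void mv_dbl(const double* B, const long long* sh, R_xlen_t N,
                   const double* x, double* y) {
  for (R_xlen_t n = 0; n < N; ++n) y[n] = 0.0;
  for (int m = 0; m < 27; ++m) {
    const double* col = B + (R_xlen_t)m * N;
    const long long s = sh[m];
    R_xlen_t lo = s < 0 ? (R_xlen_t)(-s) : 0;
    R_xlen_t hi = s > 0 ? N - (R_xlen_t)s : N;
    for (R_xlen_t n = lo; n < hi; ++n) y[n] += col[n] * x[n + s];
  }
}

static void mv(const Level& L, const float* x, float* y) {
  const R_xlen_t N = L.N;
  for (R_xlen_t n = 0; n < N; ++n) y[n] = 0.0f;
  for (int m = 0; m < 27; ++m) {
    const float* col = L.B.data() + (R_xlen_t)m * N;
    const long long s = L.shift[m];
    R_xlen_t lo = s < 0 ? (R_xlen_t)(-s) : 0;
    R_xlen_t hi = s > 0 ? N - (R_xlen_t)s : N;
    for (R_xlen_t n = lo; n < hi; ++n) y[n] += col[n] * x[n + s];
  }
}

// z = M^{-1} r with M = (D+L)D^{-1}(D+U): one symmetric GS sweep.
// The bulk loops carry no index guards; only thin slabs near n = 0 and
// n = N need them.
static void sgs(const Level& L, const float* r, float* z, float* t) {
  const R_xlen_t N = L.N;
  R_xlen_t guard = 0;
  for (int m = 0; m < 13; ++m)
    if (-L.shift[m] > guard) guard = (R_xlen_t)(-L.shift[m]);
  if (guard > N) guard = N;
  for (R_xlen_t n = 0; n < guard; ++n) {
    float acc = r[n];
    for (int m = 0; m < 13; ++m) {
      R_xlen_t j = n + L.shift[m];
      if (j >= 0) acc -= L.B[(R_xlen_t)m * N + n] * t[j];
    }
    t[n] = acc / L.diag[n];
  }
  for (R_xlen_t n = guard; n < N; ++n) {
    float acc = r[n];
    for (int m = 0; m < 13; ++m)
      acc -= L.B[(R_xlen_t)m * N + n] * t[n + L.shift[m]];
    t[n] = acc / L.diag[n];
  }
  const R_xlen_t hi = N - guard;
  for (R_xlen_t n = N; n-- > hi; ) {
    float acc = L.diag[n] * t[n];
    for (int m = 14; m < 27; ++m) {
      R_xlen_t j = n + L.shift[m];
      if (j < N) acc -= L.B[(R_xlen_t)m * N + n] * z[j];
    }
    z[n] = acc / L.diag[n];
  }
  for (R_xlen_t n = hi; n-- > 0; ) {
    float acc = L.diag[n] * t[n];
    for (int m = 14; m < 27; ++m)
      acc -= L.B[(R_xlen_t)m * N + n] * z[n + L.shift[m]];
    z[n] = acc / L.diag[n];
  }
}

// parents of fine index i along one dimension: up to two (coarse index,
// weight) pairs
static inline int parents1d(int i, int nc, int* Ip, double* wp) {
  if (i % 2 == 0) {
    int I = i / 2;
    if (I >= nc) I = nc - 1;
    Ip[0] = I; wp[0] = 1.0;
    return 1;
  }
  int cnt = 0;
  int I0 = (i - 1) / 2, I1 = (i + 1) / 2;
  if (I0 >= 0 && I0 < nc) { Ip[cnt] = I0; wp[cnt] = 0.5; ++cnt; }
  if (I1 >= 0 && I1 < nc) { Ip[cnt] = I1; wp[cnt] = 0.5; ++cnt; }
  return cnt;
}

static void build_coarse(const Level& F, Level& C) {
  for (int d = 0; d < 3; ++d) C.nn[d] = (F.nn[d] - 1) / 2 + 1;
  C.N = (R_xlen_t)C.nn[0] * C.nn[1] * C.nn[2];
  // accumulate the Galerkin product in double, store in float
  std::vector<double> acc_B((R_xlen_t)27 * C.N, 0.0);
  int Ipx[2], Ipy[2], Ipz[2], Jpx[2], Jpy[2], Jpz[2];
  double wpx[2], wpy[2], wpz[2], vpx[2], vpy[2], vpz[2];
  for (int iz = 0; iz < F.nn[2]; ++iz) {
    int npz = parents1d(iz, C.nn[2], Ipz, wpz);
    for (int iy = 0; iy < F.nn[1]; ++iy) {
      int npy = parents1d(iy, C.nn[1], Ipy, wpy);
      for (int ix = 0; ix < F.nn[0]; ++ix) {
        int npx = parents1d(ix, C.nn[0], Ipx, wpx);
        R_xlen_t n = idx3(ix, iy, iz, F.nn);
        for (int m = 0; m < 27; ++m) {
          double a = F.B[(R_xlen_t)m * F.N + n];
          if (a == 0.0) continue;
          int dx = m % 3 - 1, dy = (m / 3) % 3 - 1, dz = m / 9 - 1;
          int jx = ix + dx, jy = iy + dy, jz = iz + dz;
          if (jx < 0 || jy < 0 || jz < 0 ||
              jx >= F.nn[0] || jy >= F.nn[1] || jz >= F.nn[2]) continue;
          int nqx = parents1d(jx, C.nn[0], Jpx, vpx);
          int nqy = parents1d(jy, C.nn[1], Jpy, vpy);
          int nqz = parents1d(jz, C.nn[2], Jpz, vpz);
          for (int az = 0; az < npz; ++az)
          for (int ay = 0; ay < npy; ++ay)
          for (int ax = 0; ax < npx; ++ax) {
            double wi = wpx[ax] * wpy[ay] * wpz[az];
            for (int bz = 0; bz < nqz; ++bz)
            for (int by = 0; by < nqy; ++by)
            for (int bx = 0; bx < nqx; ++bx) {
              double wj = vpx[bx] * vpy[by] * vpz[bz];
              int Dx = Jpx[bx] - Ipx[ax], Dy = Jpy[by] - Ipy[ay],
                  Dz = Jpz[bz] - Ipz[az];
              if (Dx < -1 || Dx > 1 || Dy < -1 || Dy > 1 || Dz < -1 || Dz > 1)
                continue;
              int mc = (Dx + 1) + 3 * (Dy + 1) + 9 * (Dz + 1);
              R_xlen_t I = idx3(Ipx[ax], Ipy[ay], Ipz[az], C.nn);
              acc_B[(R_xlen_t)mc * C.N + I] += wi * wj * a;
            }
          }
        }
      }
    }
  }
  C.B.resize((R_xlen_t)27 * C.N);
  for (R_xlen_t q = 0; q < (R_xlen_t)27 * C.N; ++q) C.B[q] = (float)acc_B[q];
  level_shifts(C);
  // guard against zero/negative coarse diagonals (fully interior to
  // identity-row regions); make them identity rows
  for (R_xlen_t n = 0; n < C.N; ++n) {
    if (C.diag[n] <= 0.0f) {
      for (int m = 0; m < 27; ++m) C.B[(R_xlen_t)m * C.N + n] = 0.0f;
      C.B[(R_xlen_t)13 * C.N + n] = 1.0f;
      C.diag[n] = 1.0f;
    }
  }
  C.r.resize(C.N); C.z.resize(C.N); C.tmp.resize(C.N); C.t2.resize(C.N);
  C.resid.resize(C.N);
}

static void restrict_to(const Level& F, const Level& C, const float* rf,
                        float* rc) {
  for (R_xlen_t n = 0; n < C.N; ++n) rc[n] = 0.0f;
  int Ipx[2], Ipy[2], Ipz[2];
  double wpx[2], wpy[2], wpz[2];
  for (int iz = 0; iz < F.nn[2]; ++iz) {
    int npz = parents1d(iz, C.nn[2], Ipz, wpz);
    for (int iy = 0; iy < F.nn[1]; ++iy) {
      int npy = parents1d(iy, C.nn[1], Ipy, wpy);
      for (int ix = 0; ix < F.nn[0]; ++ix) {
        int npx = parents1d(ix, C.nn[0], Ipx, wpx);
        float v = rf[idx3(ix, iy, iz, F.nn)];
        if (v == 0.0f) continue;
        for (int az = 0; az < npz; ++az)
        for (int ay = 0; ay < npy; ++ay)
        for (int ax = 0; ax < npx; ++ax)
          rc[idx3(Ipx[ax], Ipy[ay], Ipz[az], C.nn)] +=
            (float)(wpx[ax] * wpy[ay] * wpz[az]) * v;
      }
    }
  }
}

static void prolong_add(const Level& F, const Level& C, const float* zc,
                        float* zf) {
  int Ipx[2], Ipy[2], Ipz[2];
  double wpx[2], wpy[2], wpz[2];
  for (int iz = 0; iz < F.nn[2]; ++iz) {
    int npz = parents1d(iz, C.nn[2], Ipz, wpz);
    for (int iy = 0; iy < F.nn[1]; ++iy) {
      int npy = parents1d(iy, C.nn[1], Ipy, wpy);
      for (int ix = 0; ix < F.nn[0]; ++ix) {
        int npx = parents1d(ix, C.nn[0], Ipx, wpx);
        float acc = 0.0f;
        for (int az = 0; az < npz; ++az)
        for (int ay = 0; ay < npy; ++ay)
        for (int ax = 0; ax < npx; ++ax)
          acc += (float)(wpx[ax] * wpy[ay] * wpz[az]) *
            zc[idx3(Ipx[ax], Ipy[ay], Ipz[az], C.nn)];
        zf[idx3(ix, iy, iz, F.nn)] += acc;
      }
    }
  }
}

static void vcycle(std::vector<Level>& levels, size_t l, const float* r,
                   float* z) {
  Level& L = levels[l];
  if (l == levels.size() - 1) {
    // coarsest: a fixed number of symmetric GS iterations
    for (R_xlen_t n = 0; n < L.N; ++n) z[n] = 0.0f;
    for (int it = 0; it < 60; ++it) {
      mv(L, z, L.resid.data());
      for (R_xlen_t n = 0; n < L.N; ++n) L.resid[n] = r[n] - L.resid[n];
      sgs(L, L.resid.data(), L.tmp.data(), L.t2.data());
      for (R_xlen_t n = 0; n < L.N; ++n) z[n] += L.tmp[n];
    }
    return;
  }
  // pre-smooth from zero initial guess
  sgs(L, r, z, L.tmp.data());
  // residual and restriction
  mv(L, z, L.resid.data());
  for (R_xlen_t n = 0; n < L.N; ++n) L.resid[n] = r[n] - L.resid[n];
  Level& C = levels[l + 1];
  restrict_to(L, C, L.resid.data(), C.r.data());
  vcycle(levels, l + 1, C.r.data(), C.z.data());
  prolong_add(L, C, C.z.data(), z);
  // post-smooth
  mv(L, z, L.resid.data());
  for (R_xlen_t n = 0; n < L.N; ++n) L.resid[n] = r[n] - L.resid[n];
  sgs(L, L.resid.data(), L.tmp.data(), L.t2.data());
  for (R_xlen_t n = 0; n < L.N; ++n) z[n] += L.tmp[n];
}

// [[Rcpp::export]]
List pcg_mg(NumericMatrix B, IntegerVector nn, NumericVector b,
            NumericVector x0, double rtol, int maxit, List deflate) {
  const R_xlen_t N = B.nrow();
  if ((R_xlen_t)nn[0] * nn[1] * nn[2] != N)
    stop("node count does not match lattice dimensions");
  const double* Bp = REAL(B);
  std::vector<Level> levels;
  levels.reserve(16);   // emplace_back must not reallocate (live references)
  levels.emplace_back();
  Level& fine = levels[0];
  fine.nn[0] = nn[0]; fine.nn[1] = nn[1]; fine.nn[2] = nn[2];
  fine.N = N;
  fine.B.resize((R_xlen_t)27 * N);
  for (R_xlen_t q = 0; q < (R_xlen_t)27 * N; ++q) fine.B[q] = (float)Bp[q];
  level_shifts(fine);
  fine.r.resize(N); fine.z.resize(N); fine.tmp.resize(N); fine.t2.resize(N);
  fine.resid.resize(N);
  const long long* sh = fine.shift.data();
  for (R_xlen_t n = 0; n < N; ++n)
    if (Bp[(R_xlen_t)13 * N + n] <= 0.0)
      stop("non-positive diagonal entry at node %d", (int)(n + 1));
  while (levels.back().N > 2000 &&
         levels.back().nn[0] > 3 && levels.back().nn[1] > 3 &&
         levels.back().nn[2] > 3) {
    levels.emplace_back();
    build_coarse(levels[levels.size() - 2], levels.back());
  }

  // deflation over metal-component indicator vectors (exact, double)
  int K = deflate.size();
  std::vector<std::vector<R_xlen_t> > wsets(K);
  std::vector<double> Emat;
  std::vector<int> piv;
  if (K > 0) {
    std::vector<double> wk(N), Awk(N);
    std::vector<std::vector<double> > Aw(K);
    for (int k = 0; k < K; ++k) {
      IntegerVector idx = deflate[k];
      wsets[k].reserve(idx.size());
      for (int q = 0; q < idx.size(); ++q) wsets[k].push_back(idx[q] - 1);
      std::fill(wk.begin(), wk.end(), 0.0);
      for (size_t q = 0; q < wsets[k].size(); ++q) wk[wsets[k][q]] = 1.0;
      mv_dbl(Bp, sh, N, wk.data(), Awk.data());
      Aw[k] = Awk;
    }
    Emat.assign((size_t)K * K, 0.0);
    for (int k = 0; k < K; ++k)
      for (int l = 0; l < K; ++l) {
        double acc = 0.0;
        for (size_t q = 0; q < wsets[l].size(); ++q)
          acc += Aw[k][wsets[l][q]];
        Emat[(size_t)k * K + l] = acc;
      }
    // LU with partial pivoting of the small K x K system
    piv.resize(K);
    for (int k = 0; k < K; ++k) piv[k] = k;
    for (int c = 0; c < K; ++c) {
      int best = c;
      for (int rr = c + 1; rr < K; ++rr)
        if (std::fabs(Emat[(size_t)rr * K + c]) >
            std::fabs(Emat[(size_t)best * K + c])) best = rr;
      if (best != c) {
        for (int cc = 0; cc < K; ++cc)
          std::swap(Emat[(size_t)c * K + cc], Emat[(size_t)best * K + cc]);
        std::swap(piv[c], piv[best]);
      }
      if (Emat[(size_t)c * K + c] == 0.0) stop("singular deflation matrix");
      for (int rr = c + 1; rr < K; ++rr) {
        double f = Emat[(size_t)rr * K + c] / Emat[(size_t)c * K + c];
        Emat[(size_t)rr * K + c] = f;
        for (int cc = c + 1; cc < K; ++cc)
          Emat[(size_t)rr * K + cc] -= f * Emat[(size_t)c * K + cc];
      }
    }
  }
  std::vector<double> svec(K), cvec(K);
  auto deflate_add = [&](const double* rr, double* zz) {
    if (K == 0) return;
    for (int k = 0; k < K; ++k) {
      double acc = 0.0;
      for (size_t q = 0; q < wsets[k].size(); ++q) acc += rr[wsets[k][q]];
      svec[k] = acc;
    }
    for (int k = 0; k < K; ++k) cvec[k] = svec[piv[k]];
    for (int c = 0; c < K; ++c)
      for (int rr2 = c + 1; rr2 < K; ++rr2)
        cvec[rr2] -= Emat[(size_t)rr2 * K + c] * cvec[c];
    for (int c = K - 1; c >= 0; --c) {
      for (int cc = c + 1; cc < K; ++cc)
        cvec[c] -= Emat[(size_t)c * K + cc] * cvec[cc];
      cvec[c] /= Emat[(size_t)c * K + c];
    }
    for (int k = 0; k < K; ++k)
      for (size_t q = 0; q < wsets[k].size(); ++q) zz[wsets[k][q]] += cvec[k];
  };

  auto apply_precond = [&](const double* rr, double* zz) {
    for (R_xlen_t n = 0; n < N; ++n) fine.r[n] = (float)rr[n];
    vcycle(levels, 0, fine.r.data(), fine.z.data());
    for (R_xlen_t n = 0; n < N; ++n) zz[n] = (double)fine.z[n];
    deflate_add(rr, zz);
  };

  NumericVector x = clone(x0);
  std::vector<double> r(N), z(N), p(N), Ap(N);
  mv_dbl(Bp, sh, N, REAL(x), Ap.data());
  double bnorm = 0.0;
  for (R_xlen_t n = 0; n < N; ++n) {
    r[n] = b[n] - Ap[n];
    bnorm += b[n] * b[n];
  }
  bnorm = std::sqrt(bnorm);
  if (bnorm == 0.0) {
    std::fill(REAL(x), REAL(x) + N, 0.0);
    return List::create(_["x"] = x, _["iters"] = 0, _["relres"] = 0.0,
                        _["converged"] = true, _["levels"] = (int)levels.size());
  }
  // scale the residual fed to the float V-cycle to avoid underflow when the
  // right-hand side is tiny (currents in amperes)
  double rscale = 0.0;
  for (R_xlen_t n = 0; n < N; ++n) rscale = std::max(rscale, std::fabs(r[n]));
  if (rscale == 0.0) rscale = 1.0;
  std::vector<double> rs(N);
  auto precond_scaled = [&](const std::vector<double>& rr, std::vector<double>& zz) {
    double mx = 0.0;
    for (R_xlen_t n = 0; n < N; ++n) mx = std::max(mx, std::fabs(rr[n]));
    if (mx == 0.0) mx = 1.0;
    for (R_xlen_t n = 0; n < N; ++n) rs[n] = rr[n] / mx;
    apply_precond(rs.data(), zz.data());
    for (R_xlen_t n = 0; n < N; ++n) zz[n] *= mx;
  };
  precond_scaled(r, z);
  double rz = 0.0, rnorm = 0.0;
  for (R_xlen_t n = 0; n < N; ++n) { rz += r[n] * z[n]; rnorm += r[n] * r[n]; }
  rnorm = std::sqrt(rnorm);
  std::copy(z.begin(), z.end(), p.begin());
  int it = 0;
  double relres = rnorm / bnorm;
  while (relres > rtol && it < maxit) {
    mv_dbl(Bp, sh, N, p.data(), Ap.data());
    double pAp = 0.0;
    for (R_xlen_t n = 0; n < N; ++n) pAp += p[n] * Ap[n];
    if (pAp <= 0.0) stop("system is not positive definite (p'Ap <= 0)");
    double alpha = rz / pAp;
    double rn2 = 0.0;
    double* xp = REAL(x);
    for (R_xlen_t n = 0; n < N; ++n) {
      xp[n] += alpha * p[n];
      r[n] -= alpha * Ap[n];
      rn2 += r[n] * r[n];
    }
    rnorm = std::sqrt(rn2);
    relres = rnorm / bnorm;
    ++it;
    if (relres <= rtol) break;
    precond_scaled(r, z);
    double rz_new = 0.0;
    for (R_xlen_t n = 0; n < N; ++n) rz_new += r[n] * z[n];
    double beta = rz_new / rz;
    rz = rz_new;
    for (R_xlen_t n = 0; n < N; ++n) p[n] = z[n] + beta * p[n];
    if (it % 20 == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(_["x"] = x, _["iters"] = it, _["relres"] = relres,
                      _["converged"] = (relres <= rtol),
                      _["levels"] = (int)levels.size());
}
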