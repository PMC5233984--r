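#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Banded symmetric matrix: value of A[n, n + shift[m]] is stored at B(n, m).
// Out-of-range neighbors are structurally zero (assembly never writes them),
// but index guards are kept for safety.

static inline void banded_mv(const double* B, const int* sh, int nb, R_xlen_t N,
                             const double* x, double* y) {
  for (R_xlen_t n = 0; n < N; ++n) y[n] = 0.0;
  for (int m = 0; m < nb; ++m) {
    const double* col = B + (R_xlen_t)m * N;
    const R_xlen_t s = sh[m];
    R_xlen_t lo = s < 0 ? -s : 0;
    R_xlen_t hi = s > 0 ? N - s : N;
    for (R_xlen_t n = lo; n < hi; ++n) y[n] += col[n] * x[n + s];
  }
}

// [[Rcpp::export]]
NumericVector banded_matvec(NumericMatrix B, IntegerVector shifts,
                            NumericVector x) {
  R_xlen_t N = B.nrow();
  int nb = B.ncol();
  NumericVector y(N);
  banded_mv(REAL(B), INTEGER(shifts), nb, N, REAL(x), REAL(y));
  return y;
}

// Symmetric Gauss-Seidel (SSOR omega = 1) preconditioner application:
// solve (D + L) t = r; z = (D + U)^{-1} (D t), with U = L^T.
static void ssor_apply(const double* B, const int* sh, int nb, R_xlen_t N,
                       const std::vector<int>& lower, const std::vector<int>& upper,
                       int mdiag, const double* r, double* z, double* t) {
  const double* D = B + (R_xlen_t)mdiag * N;
  for (R_xlen_t n = 0; n < N; ++n) {
    double acc = r[n];
    for (size_t q = 0; q < lower.size(); ++q) {
      int m = lower[q];
      R_xlen_t nb_idx = n + sh[m];
      if (nb_idx >= 0) acc -= B[(R_xlen_t)m * N + n] * t[nb_idx];
    }
    t[n] = acc / D[n];
  }
  for (R_xlen_t n = N - 1; n >= 0; --n) {
    double acc = D[n] * t[n];
    for (size_t q = 0; q < upper.size(); ++q) {
      int m = upper[q];
      R_xlen_t nb_idx = n + sh[m];
      if (nb_idx < N) acc -= B[(R_xlen_t)m * N + n] * z[nb_idx];
    }
    z[n] = acc / D[n];
    if (n == 0) break;
  }
}

// Preconditioned conjugate gradients on the banded system.
// precond: 0 = Jacobi, 1 = SSOR(1).
// [[Rcpp::export]]
List pcg_banded(NumericMatrix B, IntegerVector shifts, NumericVector b,
                NumericVector x0, double rtol, int maxit, int precond) {
  R_xlen_t N = B.nrow();
  int nb = B.ncol();
  const double* Bp = REAL(B);
  const int* sh = INTEGER(shifts);
  int mdiag = -1;
  std::vector<int> lower, upper;
  for (int m = 0; m < nb; ++m) {
    if (sh[m] == 0) mdiag = m;
    else if (sh[m] < 0) lower.push_back(m);
    else upper.push_back(m);
  }
  if (mdiag < 0) stop("no diagonal band (shift 0) present");
  const double* D = Bp + (R_xlen_t)mdiag * N;
  for (R_xlen_t n = 0; n < N; ++n)
    if (D[n] <= 0.0) stop("non-positive diagonal entry at node %d", (int)(n + 1));

  NumericVector x = clone(x0);
  std::vector<double> r(N), z(N), p(N), Ap(N), tmp(N);
  banded_mv(Bp, sh, nb, N, REAL(x), Ap.data());
  double bnorm = 0.0;
  for (R_xlen_t n = 0; n < N; ++n) {
    r[n] = b[n] - Ap[n];
    bnorm += b[n] * b[n];
  }
  bnorm = std::sqrt(bnorm);
  if (bnorm == 0.0) {
    std::fill(REAL(x), REAL(x) + N, 0.0);
    return List::create(_["x"] = x, _["iters"] = 0, _["relres"] = 0.0,
                        _["converged"] = true);
  }
  auto apply_M = [&](const double* rr, double* zz) {
    if (precond == 1) ssor_apply(Bp, sh, nb, N, lower, upper, mdiag, rr, zz, tmp.data());
    else for (R_xlen_t n = 0; n < N; ++n) zz[n] = rr[n] / D[n];
  };
  apply_M(r.data(), z.data());
  double rz = 0.0, rnorm = 0.0;
  for (R_xlen_t n = 0; n < N; ++n) { rz += r[n] * z[n]; rnorm += r[n] * r[n]; }
  rnorm = std::sqrt(rnorm);
  std::copy(z.begin(), z.end(), p.begin());
  int it = 0;
  double relres = rnorm / bnorm;
  while (relres > rtol && it < maxit) {
    banded_mv(Bp, sh, nb, N, p.data(), Ap.data());
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
    apply_M(r.data(), z.data());
    double rz_new = 0.0;
    for (R_xlen_t n = 0; n < N; ++n) rz_new += r[n] * z[n];
    double beta = rz_new / rz;
    rz = rz_new;
    for (R_xlen_t n = 0; n < N; ++n) p[n] = z[n] + beta * p[n];
    if (it % 200 == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(_["x"] = x, _["iters"] = it, _["relres"] = relres,
                      _["converged"] = (relres <= rtol));
}
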