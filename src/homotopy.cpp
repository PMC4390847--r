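// Total-degree polynomial homotopy continuation path tracker.
//
// Solves square polynomial systems f(z) = 0 (complex, n unknowns) by
// deforming the decoupled start system g_i(z) = z_i^{d_i} - 1 (d_i = total
// degree of equation i) into f along H(z,t) = (1-t) gamma g(z) + t f(z),
// tracking every one of the prod(d_i) start roots with an adaptive
// Euler-predictor / Newton-corrector scheme, then polishing end points
// against f itself. The random complex gamma makes path crossings a
// measure-zero event (the "gamma trick").
//
// Systems here are tiny (n <= 4, degrees <= 3), so dense partial-pivot LU
// on std::complex is all the linear algebra required.

#include <Rcpp.h>
#include <complex>
#include <vector>
#include <cmath>
using namespace Rcpp;
typedef std::complex<double> cd;

static inline cd ipow(cd z, int e) {
  cd r(1.0, 0.0);
  for (int i = 0; i < e; ++i) r *= z;
  return r;
}

struct Eq {
  std::vector<int> E;      // m x n exponents, row-major
  std::vector<double> c;   // m coefficients
  int m;
};

struct PolySys {
  std::vector<Eq> eqs;
  int n;
  std::vector<int> deg;

  cd evalEq(int i, const std::vector<cd>& z) const {
    const Eq& q = eqs[i];
    cd s(0.0, 0.0);
    for (int k = 0; k < q.m; ++k) {
      cd t(q.c[k], 0.0);
      for (int j = 0; j < n; ++j) {
        int e = q.E[k * n + j];
        if (e) t *= ipow(z[j], e);
      }
      s += t;
    }
    return s;
  }

  // sum of term magnitudes, for relative residuals
  double evalAbsEq(int i, const std::vector<cd>& z) const {
    const Eq& q = eqs[i];
    double s = 0.0;
    for (int k = 0; k < q.m; ++k) {
      double t = std::fabs(q.c[k]);
      for (int j = 0; j < n; ++j) {
        int e = q.E[k * n + j];
        if (e) t *= std::pow(std::abs(z[j]), e);
      }
      s += t;
    }
    return s;
  }

  cd evalDer(int i, int j, const std::vector<cd>& z) const {
    const Eq& q = eqs[i];
    cd s(0.0, 0.0);
    for (int k = 0; k < q.m; ++k) {
      int ej = q.E[k * n + j];
      if (!ej) continue;
      cd t(q.c[k] * ej, 0.0);
      t *= ipow(z[j], ej - 1);
      for (int l = 0; l < n; ++l) {
        if (l == j) continue;
        int e = q.E[k * n + l];
        if (e) t *= ipow(z[l], e);
      }
      s += t;
    }
    return s;
  }
};

// Solve A x = b in place (x returned in b); false if numerically singular.
static bool lusolve(std::vector<cd>& A, std::vector<cd>& b, int n) {
  for (int col = 0; col < n; ++col) {
    int piv = col;
    double best = std::abs(A[col * n + col]);
    for (int r = col + 1; r < n; ++r) {
      double v = std::abs(A[r * n + col]);
      if (v > best) { best = v; piv = r; }
    }
    if (best < 1e-300) return false;
    if (piv != col) {
      for (int j = col; j < n; ++j) std::swap(A[col * n + j], A[piv * n + j]);
      std::swap(b[col], b[piv]);
    }
    cd d = A[col * n + col];
    for (int r = col + 1; r < n; ++r) {
      cd f = A[r * n + col] / d;
      if (f == cd(0.0, 0.0)) continue;
      A[r * n + col] = cd(0.0, 0.0);
      for (int j = col + 1; j < n; ++j) A[r * n + j] -= f * A[col * n + j];
      b[r] -= f * b[col];
    }
  }
  for (int r = n - 1; r >= 0; --r) {
    cd s = b[r];
    for (int j = r + 1; j < n; ++j) s -= A[r * n + j] * b[j];
    b[r] = s / A[r * n + r];
  }
  return true;
}

static inline double normInf(const std::vector<cd>& z) {
  double m = 0.0;
  for (size_t i = 0; i < z.size(); ++i) m = std::max(m, std::abs(z[i]));
  return m;
}

// H(z,t) = (1-t) gamma g(z) + t f(z),  g_i = z_i^{d_i} - 1
static void evalH(const PolySys& S, const std::vector<cd>& z, double t,
                  cd gamma, std::vector<cd>& H) {
  for (int i = 0; i < S.n; ++i) {
    cd g = ipow(z[i], S.deg[i]) - cd(1.0, 0.0);
    H[i] = (1.0 - t) * gamma * g + t * S.evalEq(i, z);
  }
}

static void evalJH(const PolySys& S, const std::vector<cd>& z, double t,
                   cd gamma, std::vector<cd>& J) {
  int n = S.n;
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j) {
      cd v = t * S.evalDer(i, j, z);
      if (i == j)
        v += (1.0 - t) * gamma * cd((double)S.deg[i], 0.0) *
             ipow(z[i], S.deg[i] - 1);
      J[i * n + j] = v;
    }
}

// Newton on H(., t); returns true on convergence
static bool correct(const PolySys& S, std::vector<cd>& z, double t, cd gamma,
                    int maxit, double tol) {
  int n = S.n;
  std::vector<cd> H(n), J(n * n);
  for (int it = 0; it < maxit; ++it) {
    evalH(S, z, t, gamma, H);
    evalJH(S, z, t, gamma, J);
    for (int i = 0; i < n; ++i) H[i] = -H[i];
    if (!lusolve(J, H, n)) return false;
    double step = 0.0;
    for (int i = 0; i < n; ++i) { z[i] += H[i]; step = std::max(step, std::abs(H[i])); }
    if (step < tol * (1.0 + normInf(z))) return true;
  }
  return false;
}

// Newton polish directly on f; fills relative residual
static bool polish(const PolySys& S, std::vector<cd>& z, int maxit,
                   double tol, double& relres) {
  int n = S.n;
  std::vector<cd> F(n), J(n * n);
  bool conv = false;
  for (int it = 0; it < maxit; ++it) {
    for (int i = 0; i < n; ++i) F[i] = -S.evalEq(i, z);
    evalJH(S, z, 1.0, cd(0.0, 0.0), J);
    if (!lusolve(J, F, n)) break;
    double step = 0.0;
    for (int i = 0; i < n; ++i) { z[i] += F[i]; step = std::max(step, std::abs(F[i])); }
    if (normInf(z) > 1e12) { relres = 1e30; return false; }
    if (step < tol * (1.0 + normInf(z))) { conv = true; break; }
  }
  relres = 0.0;
  for (int i = 0; i < n; ++i) {
    double sc = S.evalAbsEq(i, z);
    double r = std::abs(S.evalEq(i, z)) / (sc > 1e-300 ? sc : 1.0);
    relres = std::max(relres, r);
  }
  return conv && relres < 1e-8;
}

// status: 0 converged, 1 diverged (point at infinity), 2 tracking failure
static int trackPath(const PolySys& S, std::vector<cd>& z, cd gamma,
                     double& relres) {
  int n = S.n;
  double t = 0.0, dt = 0.05;
  int steps = 0;
  const int maxsteps = 5000;
  std::vector<cd> rhs(n), J(n * n), znew(n);
  while (t < 1.0) {
    if (++steps > maxsteps) return 2;
    double dtc = std::min(dt, 1.0 - t);
    // predictor: J_H dz/dt = -(f - gamma g)
    for (int i = 0; i < n; ++i) {
      cd g = ipow(z[i], S.deg[i]) - cd(1.0, 0.0);
      rhs[i] = -(S.evalEq(i, z) - gamma * g);
    }
    evalJH(S, z, t, gamma, J);
    bool haveTan = lusolve(J, rhs, n);
    for (int i = 0; i < n; ++i)
      znew[i] = z[i] + (haveTan ? rhs[i] * dtc : cd(0.0, 0.0));
    if (correct(S, znew, t + dtc, gamma, 3, 1e-10)) {
      t += dtc;
      z = znew;
      dt = std::min(dt * 2.0, 0.1);
      if (normInf(z) > 1e6) return 1;  // heading to infinity
    } else {
      dt /= 3.0;
      if (dt < 1e-11) {
        // Stalled path. Paths stall either near a singular (multiple) root
        // of the target system -- typically on the Sum(s) = C_eps plane
        // where the osmotic volume diverges -- or while drifting to
        // infinity. Newton polish decides: a small relative residual is
        // accepted as a (possibly multiple) root, large-magnitude
        // endpoints are points at infinity (variables are pre-scaled to
        // O(1), so genuine finite roots stay small).
        polish(S, z, 100, 1e-14, relres);
        if (relres < 1e-6 && normInf(z) < 1e4) return 0;
        return normInf(z) > 50.0 ? 1 : 2;
      }
    }
  }
  polish(S, z, 100, 1e-14, relres);
  if (relres < 1e-6 && normInf(z) < 1e4) return 0;
  return normInf(z) > 50.0 ? 1 : 2;
}

// [[Rcpp::export]]
List hc_track(List Elist, List clist, double gamma_re, double gamma_im) {
  int neq = Elist.size();
  PolySys S;
  S.n = neq;
  S.eqs.resize(neq);
  S.deg.resize(neq);
  for (int i = 0; i < neq; ++i) {
    IntegerMatrix E = Elist[i];
    NumericVector c = clist[i];
    if (E.ncol() != neq) stop("exponent matrix must have n columns");
    if (E.nrow() != c.size()) stop("coefficient length mismatch");
    Eq q;
    q.m = E.nrow();
    q.E.resize(q.m * neq);
    q.c.resize(q.m);
    int d = 1;
    for (int k = 0; k < q.m; ++k) {
      int rowdeg = 0;
      for (int j = 0; j < neq; ++j) {
        q.E[k * neq + j] = E(k, j);
        rowdeg += E(k, j);
      }
      q.c[k] = c[k];
      d = std::max(d, rowdeg);
    }
    S.eqs[i] = q;
    S.deg[i] = d;
  }
  long npaths = 1;
  for (int i = 0; i < neq; ++i) npaths *= S.deg[i];
  if (npaths > 200000) stop("Bezout count too large: ", npaths);

  cd gamma(gamma_re, gamma_im);
  ComplexMatrix roots((int)npaths, neq);
  IntegerVector status((int)npaths);
  NumericVector res((int)npaths);

  std::vector<int> idx(neq, 0);
  for (long p = 0; p < npaths; ++p) {
    std::vector<cd> z(neq);
    for (int i = 0; i < neq; ++i) {
      double ang = 2.0 * M_PI * idx[i] / S.deg[i];
      z[i] = cd(std::cos(ang), std::sin(ang));
    }
    double rr = NA_REAL;
    int st = trackPath(S, z, gamma, rr);
    status[(int)p] = st;
    res[(int)p] = rr;
    for (int i = 0; i < neq; ++i) {
      Rcomplex rc;
      rc.r = z[i].real();
      rc.i = z[i].imag();
      roots((int)p, i) = rc;
    }
    // next multi-index
    for (int i = 0; i < neq; ++i) {
      if (++idx[i] < S.deg[i]) break;
      idx[i] = 0;
    }
  }
  return List::create(_["roots"] = roots, _["status"] = status,
                      _["residual"] = res);
}
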