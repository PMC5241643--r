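// Precision-generic revised primal simplex core with sparse LU,
// Bartels-Golub updates, EXPAND anti-degeneracy, and compensated
// double-quad ("qd") arithmetic for certification and residuals.
//
// The same templated engine runs in IEEE double and in __float128
// (GCC quadmath).  All certification quantities (Pinf, Dinf, residuals,
// objective values) are evaluated in qd arithmetic (~68 decimal digits)
// built from error-free transformations on __float128.

#include <Rcpp.h>
#include <quadmath.h>
#include <cfloat>
#include <cmath>
#include <cstring>
#include <vector>
#include <algorithm>
#include <limits>

using namespace Rcpp;

typedef __float128 quad;

// ---------------------------------------------------------------------------
// qd: compensated pair of __float128 (roughly 226-bit significand)
// ---------------------------------------------------------------------------

struct qd { quad hi, lo; };

static inline qd q_two_sum(quad a, quad b) {
  quad s = a + b;
  quad bb = s - a;
  quad err = (a - (s - bb)) + (b - bb);
  qd r; r.hi = s; r.lo = err; return r;
}
static inline qd q_quick_two_sum(quad a, quad b) {
  quad s = a + b;
  quad err = b - (s - a);
  qd r; r.hi = s; r.lo = err; return r;
}
static inline qd q_two_prod(quad a, quad b) {
  quad p = a * b;
  quad e = fmaq(a, b, -p);
  qd r; r.hi = p; r.lo = e; return r;
}
static inline qd qd_from(quad x) { qd r; r.hi = x; r.lo = 0.0Q; return r; }
static inline qd qd_from2(double hi, double lo) {
  return q_quick_two_sum((quad)hi, (quad)lo);
}
static inline qd qd_add(qd a, qd b) {
  qd s = q_two_sum(a.hi, b.hi);
  qd t = q_two_sum(a.lo, b.lo);
  s.lo += t.hi;
  s = q_quick_two_sum(s.hi, s.lo);
  s.lo += t.lo;
  return q_quick_two_sum(s.hi, s.lo);
}
static inline qd qd_neg(qd a) { qd r; r.hi = -a.hi; r.lo = -a.lo; return r; }
static inline qd qd_sub(qd a, qd b) { return qd_add(a, qd_neg(b)); }
static inline qd qd_mul(qd a, qd b) {
  qd p = q_two_prod(a.hi, b.hi);
  p.lo += a.hi * b.lo + a.lo * b.hi;
  return q_quick_two_sum(p.hi, p.lo);
}
static inline qd qd_div(qd a, qd b) {
  quad q1 = b.hi == 0.0Q ? a.hi / b.hi : a.hi / b.hi;
  qd r = qd_sub(a, qd_mul(qd_from(q1), b));
  quad q2 = r.hi / b.hi;
  r = qd_sub(r, qd_mul(qd_from(q2), b));
  quad q3 = r.hi / b.hi;
  qd s = q_quick_two_sum(q1, q2);
  s.lo += q3;
  return q_quick_two_sum(s.hi, s.lo);
}
static inline qd qd_abs(qd a) { return (a.hi < 0.0Q) ? qd_neg(a) : a; }
static inline bool qd_lt(qd a, qd b) {
  return a.hi < b.hi || (a.hi == b.hi && a.lo < b.lo);
}
static inline double qd_hi_d(qd a) { return (double)a.hi; }
static inline double qd_lo_d(qd a) {
  double h = (double)a.hi;
  return (double)((a.hi - (quad)h) + a.lo);
}
// log10 of a nonnegative qd value; -Inf for exact zero
static inline double qd_log10(qd a) {
  if (a.hi == 0.0Q) return R_NegInf;
  return (double)log10q(fabsq(a.hi));
}

// ---------------------------------------------------------------------------
// Precision traits
// ---------------------------------------------------------------------------

template <class T> struct PT;

template <> struct PT<double> {
  static inline double eps() { return DBL_EPSILON; }
  static inline double abs(double x) { return std::fabs(x); }
  static inline bool finite(double x) { return std::isfinite(x); }
  static inline double inf() { return std::numeric_limits<double>::infinity(); }
  static inline double from2(double hi, double lo) { (void)lo; return hi; }
  static inline double hi_d(double x) { return x; }
  static inline double lo_d(double x) { (void)x; return 0.0; }
  static inline qd to_qd(double x) { return qd_from((quad)x); }
  static inline double from_qd(qd x) { return qd_hi_d(x); }
};

template <> struct PT<quad> {
  static inline quad eps() { return FLT128_EPSILON; }
  static inline quad abs(quad x) { return fabsq(x); }
  static inline bool finite(quad x) { return !isinfq(x) && !isnanq(x); }
  static inline quad inf() { return HUGE_VALQ; }
  static inline quad from2(double hi, double lo) { return (quad)hi + (quad)lo; }
  static inline double hi_d(quad x) { return (double)x; }
  static inline double lo_d(quad x) {
    double h = (double)x;
    return (double)(x - (quad)h);
  }
  static inline qd to_qd(quad x) { return qd_from(x); }
  static inline quad from_qd(qd x) { return x.hi + x.lo; }
};

// ---------------------------------------------------------------------------
// Sparse problem container (computational standard form: A x = 0 where A
// includes one -1 slack column per row; all constraint info in the bounds)
// ---------------------------------------------------------------------------

template <class T> struct Prob {
  int m, N, nstruct;
  std::vector<int> ap, ai;   // CSC column pointers / row indices (0-based)
  std::vector<T> ax;
  std::vector<T> c, l, u;
};

template <class T>
static void load_prob(Prob<T> &P, int m, int ntot, int nstruct,
                      const IntegerVector &ap, const IntegerVector &ai,
                      const NumericVector &ax, const NumericVector &axlo,
                      const NumericVector &cc, const NumericVector &lb,
                      const NumericVector &lblo, const NumericVector &ub,
                      const NumericVector &ublo) {
  P.m = m; P.N = ntot; P.nstruct = nstruct;
  P.ap.assign(ap.begin(), ap.end());
  P.ai.assign(ai.begin(), ai.end());
  int nnz = ax.size();
  P.ax.resize(nnz);
  for (int k = 0; k < nnz; k++) P.ax[k] = PT<T>::from2(ax[k], axlo[k]);
  P.c.resize(ntot); P.l.resize(ntot); P.u.resize(ntot);
  for (int j = 0; j < ntot; j++) {
    P.c[j] = PT<T>::from2(cc[j], 0.0);
    P.l[j] = std::isfinite(lb[j]) ? PT<T>::from2(lb[j], lblo[j]) : (lb[j] > 0 ? PT<T>::inf() : -PT<T>::inf());
    P.u[j] = std::isfinite(ub[j]) ? PT<T>::from2(ub[j], ublo[j]) : (ub[j] > 0 ? PT<T>::inf() : -PT<T>::inf());
  }
}

// ---------------------------------------------------------------------------
// LU factors of the basis: dense working storage, row ops recorded as an
// operator sequence (elimination + interchanges), Bartels-Golub column
// updates with threshold interchanges.
// ---------------------------------------------------------------------------

template <class T> struct LUF {
  int m;
  std::vector<T> U;          // m*m column-major, upper triangular after factor
  std::vector<int> colpos;   // physical U column k holds basis position colpos[k]
  struct Op { int8_t t; int r, i; T mult; }; // t=0 swap(r,i), t=1 row_i -= mult*row_r
  std::vector<Op> ops;
  std::vector<int> orig_row; // physical row -> original row index
  int nupd;
  T umax0;

  inline T &at(int i, int k) { return U[(size_t)k * m + i]; }

  void apply_ops(std::vector<T> &b) const {
    for (size_t t = 0; t < ops.size(); t++) {
      const Op &o = ops[t];
      if (o.t == 0) std::swap(b[o.r], b[o.i]);
      else b[o.i] -= o.mult * b[o.r];
    }
  }
  void apply_ops_rev_transpose(std::vector<T> &b) const {
    for (size_t t = ops.size(); t-- > 0;) {
      const Op &o = ops[t];
      if (o.t == 0) std::swap(b[o.r], b[o.i]);
      else b[o.r] -= o.mult * b[o.i];
    }
  }
  // Solve B x = rhs (rhs in original row indexing, x indexed by basis position)
  void solve(std::vector<T> b, std::vector<T> &xpos) {
    apply_ops(b);
    int n = m;
    std::vector<T> z(n);
    for (int k = n - 1; k >= 0; k--) {
      T s = b[k];
      for (int j = k + 1; j < n; j++) s -= at(k, j) * z[j];
      z[k] = s / at(k, k);
    }
    xpos.assign(n, T(0));
    for (int k = 0; k < n; k++) xpos[colpos[k]] = z[k];
  }
  // Solve B^T y = cpos (cpos indexed by basis position, y in original rows)
  void solve_t(const std::vector<T> &cpos, std::vector<T> &y) {
    int n = m;
    std::vector<T> w(n);
    for (int k = 0; k < n; k++) {
      T s = cpos[colpos[k]];
      for (int j = 0; j < k; j++) s -= at(j, k) * w[j];
      w[k] = s / at(k, k);
    }
    apply_ops_rev_transpose(w);
    y = w;
  }
};

// Scatter basis column (variable j) of A into dense vector
template <class T>
static void scatter_col(const Prob<T> &P, int j, std::vector<T> &col) {
  std::fill(col.begin(), col.end(), T(0));
  for (int k = P.ap[j]; k < P.ap[j + 1]; k++) col[P.ai[k]] += P.ax[k];
}

// Factorize basis given variable list `basic` (positions 0..m-1).
// Returns dependent positions (pos, orig_row) if near-singular columns found.
template <class T>
static std::vector<std::pair<int,int> >
lu_factorize(LUF<T> &F, const Prob<T> &P, const std::vector<int> &basic,
             double factor_tol, double sing_rel) {
  int m = P.m;
  F.m = m;
  F.U.assign((size_t)m * m, T(0));
  F.ops.clear();
  F.nupd = 0;
  F.colpos.resize(m);
  F.orig_row.resize(m);
  for (int i = 0; i < m; i++) F.orig_row[i] = i;
  std::vector<std::pair<int,int> > deps;
  std::vector<T> colnorm0(m, T(0));
  {
    std::vector<T> col(m);
    for (int k = 0; k < m; k++) {
      scatter_col(P, basic[k], col);
      T mx = T(0);
      for (int i = 0; i < m; i++) {
        F.at(i, k) = col[i];
        T a = PT<T>::abs(col[i]);
        if (a > mx) mx = a;
      }
      colnorm0[k] = mx;
      F.colpos[k] = k;
    }
  }
  T umax = T(0);
  T tinyv = PT<T>::eps();
  for (int k = 0; k < m; k++) {
    // pivot among physical rows >= k
    T colmax = T(0);
    for (int i = k; i < m; i++) {
      T a = PT<T>::abs(F.at(i, k));
      if (a > colmax) colmax = a;
    }
    T thresh = T(sing_rel) * (colnorm0[k] > tinyv ? colnorm0[k] : T(1));
    if (colmax <= thresh) {
      // dependent column: record and substitute unit pivot to continue
      deps.push_back(std::make_pair(k, F.orig_row[k]));
      for (int i = k; i < m; i++) F.at(i, k) = T(0);
      F.at(k, k) = T(1);
      continue;
    }
    T admis = colmax / T(factor_tol);
    int best = -1, bestcnt = INT_MAX;
    T bestval = T(0);
    for (int i = k; i < m; i++) {
      T a = PT<T>::abs(F.at(i, k));
      if (a >= admis && a > T(0)) {
        int cnt = 0;
        for (int j = k; j < m; j++) if (F.at(i, j) != T(0)) cnt++;
        if (cnt < bestcnt || (cnt == bestcnt && a > bestval)) {
          best = i; bestcnt = cnt; bestval = a;
        }
      }
    }
    if (best < 0) { // fall back to max magnitude
      for (int i = k; i < m; i++) {
        T a = PT<T>::abs(F.at(i, k));
        if (a > bestval) { bestval = a; best = i; }
      }
    }
    if (best != k) {
      typename LUF<T>::Op o; o.t = 0; o.r = k; o.i = best; o.mult = T(0);
      F.ops.push_back(o);
      for (int j = 0; j < m; j++) std::swap(F.at(k, j), F.at(best, j));
      std::swap(F.orig_row[k], F.orig_row[best]);
    }
    T piv = F.at(k, k);
    for (int i = k + 1; i < m; i++) {
      T v = F.at(i, k);
      if (v != T(0)) {
        T mult = v / piv;
        typename LUF<T>::Op o; o.t = 1; o.r = k; o.i = i; o.mult = mult;
        F.ops.push_back(o);
        F.at(i, k) = T(0);
        for (int j = k + 1; j < m; j++) F.at(i, j) -= mult * F.at(k, j);
      }
    }
    for (int j = k; j < m; j++) {
      T a = PT<T>::abs(F.at(k, j));
      if (a > umax) umax = a;
    }
  }
  F.umax0 = umax;
  return deps;
}

// Bartels-Golub column replacement at basis position p.
// Returns 0 ok, 1 refactorize-needed, 2 singular.
template <class T>
static int lu_update(LUF<T> &F, const Prob<T> &P, int p, int jvar,
                     double update_tol, int max_updates, double sing_rel) {
  int m = F.m;
  std::vector<T> s(m);
  scatter_col(P, jvar, s);
  F.apply_ops(s);
  int kstar = -1;
  for (int k = 0; k < m; k++) if (F.colpos[k] == p) { kstar = k; break; }
  if (kstar < 0) return 2;
  T smax = T(0);
  for (int i = 0; i < m; i++) { T a = PT<T>::abs(s[i]); if (a > smax) smax = a; }
  // shift columns left, spike last
  for (int k = kstar; k < m - 1; k++) {
    for (int i = 0; i < m; i++) F.at(i, k) = F.at(i, k + 1);
    F.colpos[k] = F.colpos[k + 1];
  }
  for (int i = 0; i < m; i++) F.at(i, m - 1) = s[i];
  F.colpos[m - 1] = p;
  // eliminate subdiagonals of the Hessenberg part
  for (int k = kstar; k < m - 1; k++) {
    T a = F.at(k, k), b = F.at(k + 1, k);
    if (b == T(0)) continue;
    if (PT<T>::abs(a) * T(update_tol) < PT<T>::abs(b)) {
      typename LUF<T>::Op o; o.t = 0; o.r = k; o.i = k + 1; o.mult = T(0);
      F.ops.push_back(o);
      for (int j = k; j < m; j++) std::swap(F.at(k, j), F.at(k + 1, j));
      std::swap(F.orig_row[k], F.orig_row[k + 1]);
      a = F.at(k, k); b = F.at(k + 1, k);
    }
    if (a == T(0)) return 2;
    T mult = b / a;
    typename LUF<T>::Op o; o.t = 1; o.r = k; o.i = k + 1; o.mult = mult;
    F.ops.push_back(o);
    F.at(k + 1, k) = T(0);
    for (int j = k + 1; j < m; j++) F.at(k + 1, j) -= mult * F.at(k, j);
  }
  T dlast = PT<T>::abs(F.at(m - 1, m - 1));
  if (dlast <= T(sing_rel) * (smax > T(0) ? smax : T(1))) return 2;
  F.nupd++;
  if (F.nupd >= max_updates) return 1;
  return 0;
}

// qd residual of B x = rhs given basis columns: r = rhs - B x
template <class T>
static void basis_residual_qd(const Prob<T> &P, const std::vector<int> &basic,
                              const std::vector<T> &xpos,
                              const std::vector<T> &rhs, std::vector<qd> &r) {
  int m = P.m;
  r.resize(m);
  for (int i = 0; i < m; i++) r[i] = PT<T>::to_qd(rhs[i]);
  for (int k = 0; k < m; k++) {
    int j = basic[k];
    qd xk = PT<T>::to_qd(xpos[k]);
    for (int t = P.ap[j]; t < P.ap[j + 1]; t++) {
      qd prod = qd_mul(PT<T>::to_qd(P.ax[t]), xk);
      r[P.ai[t]] = qd_sub(r[P.ai[t]], prod);
    }
  }
}

template <class T>
static void basis_residual_t_qd(const Prob<T> &P, const std::vector<int> &basic,
                                const std::vector<T> &y,
                                const std::vector<T> &cpos, std::vector<qd> &r) {
  int m = P.m;
  r.resize(m);
  for (int k = 0; k < m; k++) {
    qd s = PT<T>::to_qd(cpos[k]);
    int j = basic[k];
    for (int t = P.ap[j]; t < P.ap[j + 1]; t++)
      s = qd_sub(s, qd_mul(PT<T>::to_qd(P.ax[t]), PT<T>::to_qd(y[P.ai[t]])));
    r[k] = s;
  }
}

// Solve with optional Wilkinson iterative refinement (residual in qd)
template <class T>
static void solve_refined(LUF<T> &F, const Prob<T> &P,
                          const std::vector<int> &basic,
                          const std::vector<T> &rhs, int passes,
                          std::vector<T> &xpos) {
  F.solve(rhs, xpos);
  for (int pass = 0; pass < passes; pass++) {
    std::vector<qd> rq;
    basis_residual_qd(P, basic, xpos, rhs, rq);
    std::vector<T> r(P.m), dx;
    for (int i = 0; i < P.m; i++) r[i] = PT<T>::from_qd(rq[i]);
    F.solve(r, dx);
    for (int k = 0; k < P.m; k++) xpos[k] += dx[k];
  }
}

template <class T>
static void solve_t_refined(LUF<T> &F, const Prob<T> &P,
                            const std::vector<int> &basic,
                            const std::vector<T> &cpos, int passes,
                            std::vector<T> &y) {
  F.solve_t(cpos, y);
  for (int pass = 0; pass < passes; pass++) {
    std::vector<qd> rq;
    basis_residual_t_qd(P, basic, y, cpos, rq);
    std::vector<T> r(P.m), dy;
    for (int i = 0; i < P.m; i++) r[i] = PT<T>::from_qd(rq[i]);
    F.solve_t(r, dy);
    for (int i = 0; i < P.m; i++) y[i] += dy[i];
  }
}

// ---------------------------------------------------------------------------
// Simplex engine
// ---------------------------------------------------------------------------

enum VStat { BASIC = 0, NB_LOWER = 1, NB_UPPER = 2, NB_FREE = 3 };
enum SStat { ST_OPTIMAL = 0, ST_INFEASIBLE = 1, ST_UNBOUNDED = 2,
             ST_ITERLIM = 3, ST_NUMERR = 4 };

struct Opts {
  double feas_tol, opt_tol, lu_factor_tol, lu_update_tol;
  int expand_freq, iter_limit, refactor_freq, refine;
  bool expand_on;
};

template <class T> struct Engine {
  Prob<T> P;
  Opts opt;
  std::vector<int> vstat, basic, posof;
  std::vector<T> x;
  LUF<T> F;
  int iters, degen, nsing, nrepair, phase1_iters;
  int status;
  double sing_rel;

  Engine() : iters(0), degen(0), nsing(0), nrepair(0), phase1_iters(0),
             status(ST_NUMERR) {}

  inline T btol(T bnd, double tol) const {
    T ab = PT<T>::finite(bnd) ? PT<T>::abs(bnd) : T(0);
    return T(tol) * (T(1) + ab);
  }

  bool refactorize() {
    for (int attempt = 0; attempt < P.m + 2; attempt++) {
      std::vector<std::pair<int,int> > deps =
        lu_factorize(F, P, basic, opt.lu_factor_tol, sing_rel);
      if (deps.empty()) return true;
      nsing += (int)deps.size();
      // basis repair: dependent basic columns -> slack unit columns
      std::vector<bool> used(P.m, false);
      bool progress = false;
      for (size_t t = 0; t < deps.size(); t++) {
        int pos = deps[t].first;
        int row = deps[t].second;
        int sl = P.nstruct + row;
        if (posof[sl] < 0 && !used[row]) {
          displace(pos, sl);
          used[row] = true;
          progress = true;
        } else {
          // slack already basic: any other nonbasic slack unit column
          bool done = false;
          for (int r2 = 0; r2 < P.m && !done; r2++) {
            int s2 = P.nstruct + r2;
            if (posof[s2] < 0 && !used[r2]) {
              displace(pos, s2);
              used[r2] = true;
              done = true; progress = true;
            }
          }
          if (!done) return false;
        }
        nrepair++;
      }
      if (!progress) return false;
    }
    return false;
  }

  void displace(int pos, int newvar) {
    int old = basic[pos];
    // displaced variable -> nonbasic at its nearer bound
    T lo = P.l[old], up = P.u[old];
    bool lf = PT<T>::finite(lo), uf = PT<T>::finite(up);
    if (lf && uf) {
      T dl = PT<T>::abs(x[old] - lo), du = PT<T>::abs(up - x[old]);
      if (du < dl) { vstat[old] = NB_UPPER; x[old] = up; }
      else { vstat[old] = NB_LOWER; x[old] = lo; }
    } else if (lf) { vstat[old] = NB_LOWER; x[old] = lo; }
    else if (uf) { vstat[old] = NB_UPPER; x[old] = up; }
    else { vstat[old] = NB_FREE; x[old] = T(0); }
    posof[old] = -1;
    basic[pos] = newvar;
    posof[newvar] = pos;
    vstat[newvar] = BASIC;
  }

  // rhs for B x_B = -N x_N, accumulated in qd then rounded to T
  void nonbasic_rhs(std::vector<T> &rhs) {
    std::vector<qd> acc(P.m, qd_from(0.0Q));
    for (int j = 0; j < P.N; j++) {
      if (vstat[j] == BASIC || x[j] == T(0)) continue;
      qd xj = PT<T>::to_qd(x[j]);
      for (int t = P.ap[j]; t < P.ap[j + 1]; t++)
        acc[P.ai[t]] = qd_add(acc[P.ai[t]], qd_mul(PT<T>::to_qd(P.ax[t]), xj));
    }
    rhs.resize(P.m);
    for (int i = 0; i < P.m; i++) rhs[i] = -PT<T>::from_qd(acc[i]);
  }

  void compute_xB(int refine) {
    std::vector<T> rhs, xpos;
    nonbasic_rhs(rhs);
    solve_refined(F, P, basic, rhs, refine, xpos);
    for (int k = 0; k < P.m; k++) x[basic[k]] = xpos[k];
  }

  // infeasibility classification of basic variables under tolerance `tol`
  // cls: -1 below lower, +1 above upper, 0 feasible
  void classify(double tol, std::vector<int> &cls, T &suminf, int &ninf) {
    cls.assign(P.m, 0);
    suminf = T(0); ninf = 0;
    for (int k = 0; k < P.m; k++) {
      int j = basic[k];
      T lo = P.l[j], up = P.u[j];
      if (PT<T>::finite(lo) && x[j] < lo - btol(lo, tol)) {
        cls[k] = -1; suminf += lo - x[j]; ninf++;
      } else if (PT<T>::finite(up) && x[j] > up + btol(up, tol)) {
        cls[k] = 1; suminf += x[j] - up; ninf++;
      }
    }
  }

  T objective_phase2() {
    qd s = qd_from(0.0Q);
    for (int j = 0; j < P.N; j++)
      if (x[j] != T(0) && P.c[j] != T(0))
        s = qd_add(s, qd_mul(PT<T>::to_qd(P.c[j]), PT<T>::to_qd(x[j])));
    return PT<T>::from_qd(s);
  }

  // main loop; returns status
  int run(bool cold_start) {
    int m = P.m, N = P.N;
    double feas = opt.feas_tol, dopt = opt.opt_tol;
    double tau = (feas - feas / 2.0) / (double)opt.expand_freq;
    double tolk = feas / 2.0;
    if (!opt.expand_on) { tolk = feas; tau = 0.0; }
    int since_reset = 0, since_refac = 0;
    bool need_refac = true;
    int final_rounds = 0;
    int stall = 0;
    std::vector<int> cls;
    std::vector<T> cB(m), y, d, dpos, acol(m);
    T suminf; int ninf;

    (void)cold_start;
    while (true) {
      if (need_refac) {
        if (!refactorize()) return ST_NUMERR;
        compute_xB(opt.refine);
        need_refac = false;
        since_refac = 0;
      }
      classify(tolk, cls, suminf, ninf);
      bool phase1 = ninf > 0;
      if (phase1 && iters > 0) phase1_iters++;
      // duals for current phase
      for (int k = 0; k < m; k++)
        cB[k] = phase1 ? T(cls[k]) : P.c[basic[k]];
      solve_t_refined(F, P, basic, cB, opt.refine, y);
      T ynorm = T(0);
      for (int i = 0; i < m; i++) { T a = PT<T>::abs(y[i]); if (a > ynorm) ynorm = a; }
      T dtol = T(dopt) * (T(1) + ynorm);
      // pricing (Dantzig: most violating reduced cost, lowest index ties)
      int q = -1, dir = 0;
      T best = dtol;
      for (int j = 0; j < N; j++) {
        if (vstat[j] == BASIC) continue;
        T zj = phase1 ? T(0) : P.c[j];
        for (int t = P.ap[j]; t < P.ap[j + 1]; t++)
          zj -= P.ax[t] * y[P.ai[t]];
        T viol = T(0); int dj = 0;
        if (vstat[j] == NB_LOWER) { if (zj < -best) { viol = -zj; dj = 1; } }
        else if (vstat[j] == NB_UPPER) { if (zj > best) { viol = zj; dj = -1; } }
        else { // free
          if (zj < -best) { viol = -zj; dj = 1; }
          else if (zj > best) { viol = zj; dj = -1; }
        }
        if (dj != 0 && viol > best) { best = viol; q = j; dir = dj; }
      }
      if (q < 0) {
        if (phase1) {
          // candidate infeasible: confirm on fresh factors at strict tol
          if (!refactorize()) return ST_NUMERR;
          compute_xB(std::max(opt.refine, 1));
          classify(feas, cls, suminf, ninf);
          if (ninf == 0) {
            // feasible within delta1 though not within the working
            // tolerance: accept the full tolerance and resume phase 2
            need_refac = false; since_refac = 0;
            tolk = feas;
            continue;
          }
          return ST_INFEASIBLE;
        }
        // candidate optimal: final EXPAND reset + certification round
        if (!refactorize()) return ST_NUMERR;
        compute_xB(std::max(opt.refine, 1));
        classify(feas, cls, suminf, ninf);
        if (ninf > 0 && final_rounds < 3) {
          final_rounds++;
          need_refac = false; since_refac = 0;
          tolk = feas / 2.0; since_reset = 0;
          continue;
        }
        return ST_OPTIMAL;
      }
      if (iters >= opt.iter_limit) return ST_ITERLIM;

      // direction: B d = a_q
      scatter_col(P, q, acol);
      solve_refined(F, P, basic, acol, opt.refine, dpos);
      // rate of change of basic k per unit increase of step:  -dir * d_k
      // ratio test
      T INFT = PT<T>::inf();
      T thmax = INFT;
      T thflip = INFT;
      if (PT<T>::finite(P.l[q]) && PT<T>::finite(P.u[q]))
        thflip = P.u[q] - P.l[q];
      double pass1tol = opt.expand_on ? (tolk + tau) : 0.0;
      T ptiny = PT<T>::eps();
      {
        T dmax = T(0);
        for (int k = 0; k < m; k++) { T a = PT<T>::abs(dpos[k]); if (a > dmax) dmax = a; }
        ptiny = PT<T>::eps() * (T(1) + dmax);
      }
      for (int k = 0; k < m; k++) {
        T rate = -T(dir) * dpos[k];
        if (PT<T>::abs(rate) <= ptiny) continue;
        int j = basic[k];
        T lo = P.l[j], up = P.u[j];
        T th = INFT;
        if (cls[k] == 0) {
          if (rate < T(0) && PT<T>::finite(lo))
            th = (x[j] - lo + btol(lo, pass1tol)) / (-rate);
          else if (rate > T(0) && PT<T>::finite(up))
            th = (up + btol(up, pass1tol) - x[j]) / rate;
        } else if (cls[k] < 0) { // below lower, blocked when it reaches lower
          if (rate > T(0)) th = (lo + btol(lo, pass1tol) - x[j]) / rate;
        } else {                 // above upper
          if (rate < T(0)) th = (x[j] - up + btol(up, pass1tol)) / (-rate);
        }
        if (th < thmax) thmax = th;
      }
      if (!PT<T>::finite(thmax) && !PT<T>::finite(thflip)) {
        if (phase1) return ST_NUMERR;
        status = ST_UNBOUNDED;
        // ray is direction of entering variable
        return ST_UNBOUNDED;
      }
      // pass 2: largest pivot among candidates blocking within thmax
      int pleave = -1, leave_at = 0;
      T bestpiv = T(0), th_best = T(0);
      for (int k = 0; k < m; k++) {
        T rate = -T(dir) * dpos[k];
        if (PT<T>::abs(rate) <= ptiny) continue;
        int j = basic[k];
        T lo = P.l[j], up = P.u[j];
        T th = INFT; int at = 0;
        if (cls[k] == 0) {
          if (rate < T(0) && PT<T>::finite(lo)) { th = (x[j] - lo) / (-rate); at = NB_LOWER; }
          else if (rate > T(0) && PT<T>::finite(up)) { th = (up - x[j]) / rate; at = NB_UPPER; }
        } else if (cls[k] < 0) {
          if (rate > T(0)) { th = (lo - x[j]) / rate; at = NB_LOWER; }
        } else {
          if (rate < T(0)) { th = (x[j] - up) / (-rate); at = NB_UPPER; }
        }
        if (at == 0) continue;
        if (th < T(0)) th = T(0);
        if (th <= thmax) {
          bool take;
          if (opt.expand_on) take = PT<T>::abs(rate) > bestpiv;
          else take = (pleave < 0) || th < th_best; // classic: min ratio, lowest index
          if (take) { pleave = k; bestpiv = PT<T>::abs(rate); th_best = th; leave_at = at; }
        }
      }
      T theta;
      bool do_flip = false;
      if (pleave < 0) {
        if (PT<T>::finite(thflip)) { do_flip = true; theta = thflip; }
        else if (phase1) return ST_NUMERR;
        else return ST_UNBOUNDED;
      } else {
        theta = th_best;
        if (opt.expand_on) {
          T minstep = T(tau) * (T(1) + PT<T>::abs(x[q])) / bestpiv;
          if (theta < minstep) theta = minstep;
        }
        if (PT<T>::finite(thflip) && thflip <= theta) { do_flip = true; theta = thflip; }
      }
      // take the step
      T step_thresh = T(tau) * (T(1) + PT<T>::abs(x[q]));
      if (theta <= step_thresh) { degen++; stall++; } else stall = 0;
      if (!opt.expand_on && theta == T(0)) stall++;
      for (int k = 0; k < m; k++) {
        T rate = -T(dir) * dpos[k];
        if (rate != T(0)) x[basic[k]] += rate * theta;
      }
      if (do_flip) {
        if (dir > 0) { x[q] = P.u[q]; vstat[q] = NB_UPPER; }
        else { x[q] = P.l[q]; vstat[q] = NB_LOWER; }
      } else {
        x[q] = x[q] + T(dir) * theta;
        int lv = basic[pleave];
        x[lv] = (leave_at == NB_LOWER) ? P.l[lv] : P.u[lv];
        vstat[lv] = leave_at;
        posof[lv] = -1;
        basic[pleave] = q;
        posof[q] = pleave;
        vstat[q] = BASIC;
        int rc = lu_update(F, P, pleave, q, opt.lu_update_tol,
                           opt.refactor_freq, sing_rel);
        if (rc == 1) need_refac = true;
        else if (rc == 2) { nsing++; need_refac = true; }
      }
      iters++;
      since_reset++; since_refac++;
      if (opt.expand_on) {
        tolk += tau;
        if (since_reset >= opt.expand_freq || tolk >= feas) {
          tolk = feas / 2.0;
          since_reset = 0;
          compute_xB(opt.refine);
        }
      }
      if (since_refac >= opt.refactor_freq) need_refac = true;
    }
  }
};

// qd certification of current point in the *as-solved* (scaled) space
template <class T>
static void engine_cert(Engine<T> &E, double &pinf, double &dinf,
                        double &pinf_l10, double &dinf_l10,
                        std::vector<T> &yout, std::vector<T> &zout) {
  int m = E.P.m, N = E.P.N;
  // refined duals from phase-2 costs
  std::vector<T> cB(m);
  for (int k = 0; k < m; k++) cB[k] = E.P.c[E.basic[k]];
  solve_t_refined(E.F, E.P, E.basic, cB, std::max(E.opt.refine, 2), yout);
  // primal residual of A x = 0 and bound violations, in qd
  std::vector<qd> act(m, qd_from(0.0Q));
  for (int j = 0; j < N; j++) {
    if (E.x[j] == T(0)) continue;
    qd xj = PT<T>::to_qd(E.x[j]);
    for (int t = E.P.ap[j]; t < E.P.ap[j + 1]; t++)
      act[E.P.ai[t]] = qd_add(act[E.P.ai[t]], qd_mul(PT<T>::to_qd(E.P.ax[t]), xj));
  }
  qd pmax = qd_from(0.0Q);
  for (int i = 0; i < m; i++) {
    qd a = qd_abs(act[i]);
    if (qd_lt(pmax, a)) pmax = a;
  }
  for (int j = 0; j < N; j++) {
    if (PT<T>::finite(E.P.l[j]) && E.x[j] < E.P.l[j]) {
      qd v = qd_sub(PT<T>::to_qd(E.P.l[j]), PT<T>::to_qd(E.x[j]));
      if (qd_lt(pmax, v)) pmax = v;
    }
    if (PT<T>::finite(E.P.u[j]) && E.x[j] > E.P.u[j]) {
      qd v = qd_sub(PT<T>::to_qd(E.x[j]), PT<T>::to_qd(E.P.u[j]));
      if (qd_lt(pmax, v)) pmax = v;
    }
  }
  // reduced costs in qd
  zout.resize(N);
  qd dmax = qd_from(0.0Q);
  for (int j = 0; j < N; j++) {
    qd zj = PT<T>::to_qd(E.P.c[j]);
    for (int t = E.P.ap[j]; t < E.P.ap[j + 1]; t++)
      zj = qd_sub(zj, qd_mul(PT<T>::to_qd(E.P.ax[t]), PT<T>::to_qd(yout[E.P.ai[t]])));
    zout[j] = PT<T>::from_qd(zj);
    qd viol = qd_from(0.0Q);
    if (E.vstat[j] == NB_LOWER) { if (zj.hi < 0.0Q) viol = qd_neg(zj); }
    else if (E.vstat[j] == NB_UPPER) { if (zj.hi > 0.0Q) viol = zj; }
    else viol = qd_abs(zj); // basic or free
    if (qd_lt(dmax, viol)) dmax = viol;
  }
  pinf = qd_hi_d(pmax); dinf = qd_hi_d(dmax);
  pinf_l10 = qd_log10(pmax); dinf_l10 = qd_log10(dmax);
}

static Opts opts_from_list(const List &o) {
  Opts v;
  v.feas_tol = as<double>(o["feas_tol"]);
  v.opt_tol = as<double>(o["opt_tol"]);
  v.lu_factor_tol = as<double>(o["lu_factor_tol"]);
  v.lu_update_tol = as<double>(o["lu_update_tol"]);
  v.expand_freq = as<int>(o["expand_frequency"]);
  v.iter_limit = as<int>(o["iteration_limit"]);
  v.refactor_freq = as<int>(o["refactor_frequency"]);
  v.refine = as<int>(o["refine_passes"]);
  v.expand_on = as<bool>(o["expand"]);
  return v;
}

template <class T>
static List run_simplex_T(int m, int ntot, int nstruct,
                          const IntegerVector &ap, const IntegerVector &ai,
                          const NumericVector &ax, const NumericVector &axlo,
                          const NumericVector &cc, const NumericVector &lb,
                          const NumericVector &lblo, const NumericVector &ub,
                          const NumericVector &ublo, const List &opts,
                          Nullable<IntegerVector> warm) {
  Engine<T> E;
  load_prob(E.P, m, ntot, nstruct, ap, ai, ax, axlo, cc, lb, lblo, ub, ublo);
  E.opt = opts_from_list(opts);
  double e = PT<T>::hi_d(PT<T>::eps());
  E.sing_rel = std::pow(e, 2.0 / 3.0);
  E.vstat.assign(ntot, NB_LOWER);
  E.posof.assign(ntot, -1);
  E.basic.assign(m, 0);
  E.x.assign(ntot, T(0));
  bool cold = true;
  if (warm.isNotNull()) {
    IntegerVector w(warm);
    if ((int)w.size() != ntot) stop("warm start status vector has wrong length");
    int nb = 0;
    for (int j = 0; j < ntot; j++) { E.vstat[j] = w[j]; if (w[j] == BASIC) nb++; }
    if (nb != m) stop("warm start must have exactly m basic variables");
    int pos = 0;
    for (int j = 0; j < ntot; j++) if (E.vstat[j] == BASIC) {
      E.basic[pos] = j; E.posof[j] = pos; pos++;
    }
    cold = false;
  } else {
    // cold start: all-slack basis, structurals at the bound nearer their
    // cost direction
    for (int i = 0; i < m; i++) {
      int sl = nstruct + i;
      E.basic[i] = sl; E.posof[sl] = i; E.vstat[sl] = BASIC;
    }
    for (int j = 0; j < nstruct; j++) {
      bool lf = PT<T>::finite(E.P.l[j]), uf = PT<T>::finite(E.P.u[j]);
      if (!lf && !uf) { E.vstat[j] = NB_FREE; continue; }
      if (lf && !uf) { E.vstat[j] = NB_LOWER; continue; }
      if (!lf && uf) { E.vstat[j] = NB_UPPER; continue; }
      if (E.P.c[j] > T(0)) E.vstat[j] = NB_LOWER;
      else if (E.P.c[j] < T(0)) E.vstat[j] = NB_UPPER;
      else E.vstat[j] = (PT<T>::abs(E.P.l[j]) <= PT<T>::abs(E.P.u[j]))
             ? NB_LOWER : NB_UPPER;
    }
  }
  // nonbasic values on their bounds
  for (int j = 0; j < ntot; j++) {
    if (E.vstat[j] == NB_LOWER) E.x[j] = E.P.l[j];
    else if (E.vstat[j] == NB_UPPER) E.x[j] = E.P.u[j];
    else if (E.vstat[j] == NB_FREE) E.x[j] = T(0);
  }
  int st = E.run(cold);
  E.status = st;
  double pinf = NA_REAL, dinf = NA_REAL, pl10 = NA_REAL, dl10 = NA_REAL;
  std::vector<T> yv, zv;
  engine_cert(E, pinf, dinf, pl10, dl10, yv, zv);
  T obj = E.objective_phase2();
  int N = ntot;
  NumericVector xh(N), xl(N), zh(N), zl(N), yh(m), yl(m);
  for (int j = 0; j < N; j++) {
    xh[j] = PT<T>::hi_d(E.x[j]); xl[j] = PT<T>::lo_d(E.x[j]);
    zh[j] = PT<T>::hi_d(zv[j]); zl[j] = PT<T>::lo_d(zv[j]);
  }
  for (int i = 0; i < m; i++) { yh[i] = PT<T>::hi_d(yv[i]); yl[i] = PT<T>::lo_d(yv[i]); }
  IntegerVector vst(N), bas(m);
  for (int j = 0; j < N; j++) vst[j] = E.vstat[j];
  for (int k = 0; k < m; k++) bas[k] = E.basic[k];
  return List::create(
    _["status"] = st,
    _["x"] = xh, _["x_lo"] = xl,
    _["y"] = yh, _["y_lo"] = yl,
    _["z"] = zh, _["z_lo"] = zl,
    _["objective"] = PT<T>::hi_d(obj), _["objective_lo"] = PT<T>::lo_d(obj),
    _["iterations"] = E.iters,
    _["degenerate_iterations"] = E.degen,
    _["phase1_iterations"] = E.phase1_iters,
    _["pinf"] = pinf, _["dinf"] = dinf,
    _["pinf_log10"] = pl10, _["dinf_log10"] = dl10,
    _["vstat"] = vst, _["basic"] = bas,
    _["n_singular"] = E.nsing, _["n_repair"] = E.nrepair);
}

// [[Rcpp::export]]
List cpp_simplex(int m, int ntot, int nstruct, IntegerVector ap,
                 IntegerVector ai, NumericVector ax, NumericVector axlo,
                 NumericVector cc, NumericVector lb, NumericVector lblo,
                 NumericVector ub, NumericVector ublo, List opts,
                 Nullable<IntegerVector> warm, std::string precision) {
  if (precision == "double")
    return run_simplex_T<double>(m, ntot, nstruct, ap, ai, ax, axlo, cc, lb,
                                 lblo, ub, ublo, opts, warm);
  return run_simplex_T<quad>(m, ntot, nstruct, ap, ai, ax, axlo, cc, lb, lblo,
                             ub, ublo, opts, warm);
}

// ---------------------------------------------------------------------------
// Standalone basis linear-algebra entry points (used by the basis_linalg API
// and its tests; square matrix passed as triplets)
// ---------------------------------------------------------------------------

template <class T>
static void load_square(Prob<T> &P, int m, const IntegerVector &bi,
                        const IntegerVector &bj, const NumericVector &bx) {
  // build CSC of an m x m matrix from 0-based triplets
  P.m = m; P.N = m; P.nstruct = 0;
  int nnz = bx.size();
  std::vector<int> cnt(m, 0);
  for (int k = 0; k < nnz; k++) cnt[bj[k]]++;
  P.ap.assign(m + 1, 0);
  for (int j = 0; j < m; j++) P.ap[j + 1] = P.ap[j] + cnt[j];
  P.ai.assign(nnz, 0);
  P.ax.assign(nnz, T(0));
  std::vector<int> w(P.ap.begin(), P.ap.end() - 1);
  for (int k = 0; k < nnz; k++) {
    int p = w[bj[k]]++;
    P.ai[p] = bi[k];
    P.ax[p] = T(bx[k]);
  }
}

template <class T>
static List lu_factor_check_T(int m, const IntegerVector &bi,
                              const IntegerVector &bj, const NumericVector &bx,
                              double factor_tol) {
  Prob<T> P;
  load_square(P, m, bi, bj, bx);
  std::vector<int> basic(m);
  for (int k = 0; k < m; k++) basic[k] = k;
  LUF<T> F;
  double e = PT<T>::hi_d(PT<T>::eps());
  double sing_rel = std::pow(e, 2.0 / 3.0);
  std::vector<std::pair<int,int> > deps =
    lu_factorize(F, P, basic, factor_tol, sing_rel);
  // reconstruct: column colpos[k] of B_rec = inverse ops applied to U(:,k)
  double recon = 0.0, bnorm = 0.0;
  std::vector<std::vector<T> > Brec(m, std::vector<T>(m, T(0)));
  for (int k = 0; k < m; k++) {
    std::vector<T> col(m, T(0));
    for (int i = 0; i <= k; i++) col[i] = F.at(i, k);
    for (size_t t = F.ops.size(); t-- > 0;) {
      const typename LUF<T>::Op &o = F.ops[t];
      if (o.t == 0) std::swap(col[o.r], col[o.i]);
      else col[o.i] += o.mult * col[o.r];
    }
    for (int i = 0; i < m; i++) Brec[i][F.colpos[k]] = col[i];
  }
  std::vector<std::vector<T> > B(m, std::vector<T>(m, T(0)));
  for (int k = 0; k < (int)bx.size(); k++) B[bi[k]][bj[k]] += T(bx[k]);
  for (int i = 0; i < m; i++)
    for (int j = 0; j < m; j++) {
      double diff = PT<T>::hi_d(PT<T>::abs(Brec[i][j] - B[i][j]));
      double a = PT<T>::hi_d(PT<T>::abs(B[i][j]));
      if (diff > recon) recon = diff;
      if (a > bnorm) bnorm = a;
    }
  IntegerVector dpos(deps.size()), drow(deps.size());
  for (size_t t = 0; t < deps.size(); t++) {
    dpos[t] = deps[t].first + 1;
    drow[t] = deps[t].second + 1;
  }
  return List::create(_["dependent_positions"] = dpos,
                      _["dependent_rows"] = drow,
                      _["reconstruction_error"] = recon,
                      _["matrix_norm"] = bnorm);
}

// [[Rcpp::export]]
List cpp_lu_factor_check(int m, IntegerVector bi, IntegerVector bj,
                         NumericVector bx, double factor_tol,
                         std::string precision) {
  if (precision == "double") return lu_factor_check_T<double>(m, bi, bj, bx, factor_tol);
  return lu_factor_check_T<quad>(m, bi, bj, bx, factor_tol);
}

template <class T>
static List basis_solve_T(int m, const IntegerVector &bi, const IntegerVector &bj,
                          const NumericVector &bx, const NumericVector &rhs,
                          bool transpose, int refine, double factor_tol) {
  Prob<T> P;
  load_square(P, m, bi, bj, bx);
  std::vector<int> basic(m);
  for (int k = 0; k < m; k++) basic[k] = k;
  LUF<T> F;
  double e = PT<T>::hi_d(PT<T>::eps());
  std::vector<std::pair<int,int> > deps =
    lu_factorize(F, P, basic, factor_tol, std::pow(e, 2.0 / 3.0));
  if (!deps.empty()) stop("basis matrix is singular (dependent columns)");
  std::vector<T> b(m), xv;
  for (int i = 0; i < m; i++) b[i] = T(rhs[i]);
  if (!transpose) solve_refined(F, P, basic, b, refine, xv);
  else solve_t_refined(F, P, basic, b, refine, xv);
  // residual in qd
  std::vector<qd> rq;
  if (!transpose) basis_residual_qd(P, basic, xv, b, rq);
  else basis_residual_t_qd(P, basic, xv, b, rq);
  qd rmax = qd_from(0.0Q);
  for (int i = 0; i < m; i++) { qd a = qd_abs(rq[i]); if (qd_lt(rmax, a)) rmax = a; }
  NumericVector xh(m), xl(m);
  for (int i = 0; i < m; i++) { xh[i] = PT<T>::hi_d(xv[i]); xl[i] = PT<T>::lo_d(xv[i]); }
  return List::create(_["x"] = xh, _["x_lo"] = xl,
                      _["residual_inf"] = qd_hi_d(rmax),
                      _["residual_log10"] = qd_log10(rmax));
}

// [[Rcpp::export]]
List cpp_basis_solve(int m, IntegerVector bi, IntegerVector bj,
                     NumericVector bx, NumericVector rhs, bool transpose,
                     int refine, double factor_tol, std::string precision) {
  if (precision == "double")
    return basis_solve_T<double>(m, bi, bj, bx, rhs, transpose, refine, factor_tol);
  return basis_solve_T<quad>(m, bi, bj, bx, rhs, transpose, refine, factor_tol);
}

// Update driver: factorize B0, then replace columns one at a time
// (replacements given as positions + dense new columns); after each update,
// solve B x = rhs via updated factors and via a fresh factorization.
template <class T>
static List update_driver_T(int m, const IntegerVector &bi, const IntegerVector &bj,
                            const NumericVector &bx, const IntegerVector &pos,
                            const NumericMatrix &cols, const NumericVector &rhs,
                            double factor_tol, double update_tol) {
  // maintain a dense copy of current B as triplet source for fresh factors
  std::vector<std::vector<double> > B(m, std::vector<double>(m, 0.0));
  for (int k = 0; k < (int)bx.size(); k++) B[bi[k]][bj[k]] += bx[k];
  // problem container whose columns are the current basis columns
  int nrep = pos.size();
  NumericVector sigs(nrep);
  double max_dev = 0.0;
  double e = PT<T>::hi_d(PT<T>::eps());
  double sing_rel = std::pow(e, 2.0 / 3.0);

  // build Prob from dense B
  Prob<T> P;
  P.m = m; P.N = m; P.nstruct = 0;
  std::vector<int> basic(m);
  for (int k = 0; k < m; k++) basic[k] = k;
  LUF<T> F;
  bool have_factors = false;
  for (int r = -1; r < nrep; r++) {
    if (r >= 0) {
      int p = pos[r];
      for (int i = 0; i < m; i++) B[i][p] = cols(i, r);
    }
    // rebuild P from dense B
    P.ap.assign(m + 1, 0);
    P.ai.clear(); P.ax.clear();
    for (int j = 0; j < m; j++) {
      for (int i = 0; i < m; i++)
        if (B[i][j] != 0.0) { P.ai.push_back(i); P.ax.push_back(T(B[i][j])); }
      P.ap[j + 1] = (int)P.ai.size();
    }
    int sig = 0;
    if (r < 0 || !have_factors) {
      std::vector<std::pair<int,int> > deps =
        lu_factorize(F, P, basic, factor_tol, sing_rel);
      have_factors = deps.empty();
      if (!have_factors && r < 0)
        stop("initial basis matrix is singular");
    } else {
      int rc = lu_update(F, P, pos[r], pos[r], update_tol, 10000, sing_rel);
      sig = rc;
      if (rc == 2) { // singular signal: refactorize (and report)
        std::vector<std::pair<int,int> > deps =
          lu_factorize(F, P, basic, factor_tol, sing_rel);
        have_factors = deps.empty();
      }
    }
    if (r >= 0) sigs[r] = sig;
    if (have_factors) {
      std::vector<T> b(m), x1, x2;
      for (int i = 0; i < m; i++) b[i] = T(rhs[i]);
      solve_refined(F, P, basic, b, 0, x1);
      LUF<T> Ff;
      std::vector<std::pair<int,int> > deps =
        lu_factorize(Ff, P, basic, factor_tol, sing_rel);
      if (deps.empty()) {
        solve_refined(Ff, P, basic, b, 0, x2);
        double xn = 0.0, dv = 0.0;
        for (int i = 0; i < m; i++) {
          double a = PT<T>::hi_d(PT<T>::abs(x2[i]));
          double d = PT<T>::hi_d(PT<T>::abs(x1[i] - x2[i]));
          if (a > xn) xn = a;
          if (d > dv) dv = d;
        }
        double rel = dv / (1.0 + xn);
        if (rel > max_dev) max_dev = rel;
      }
    }
  }
  return List::create(_["signals"] = sigs, _["max_solve_deviation"] = max_dev);
}

// [[Rcpp::export]]
List cpp_lu_update_driver(int m, IntegerVector bi, IntegerVector bj,
                          NumericVector bx, IntegerVector pos,
                          NumericMatrix cols, NumericVector rhs,
                          double factor_tol, double update_tol,
                          std::string precision) {
  if (precision == "double")
    return update_driver_T<double>(m, bi, bj, bx, pos, cols, rhs, factor_tol, update_tol);
  return update_driver_T<quad>(m, bi, bj, bx, pos, cols, rhs, factor_tol, update_tol);
}

// ---------------------------------------------------------------------------
// qd evaluation helpers exposed to R
// ---------------------------------------------------------------------------

// Pinf/Dinf of a candidate (v, y) on original problem data, in qd.
// Row activity constraints are intervals [rlo, rhi]; statuses cover
// structural columns then one slack status per row.
// [[Rcpp::export]]
List cpp_infeasibilities(int m, int n, IntegerVector si, IntegerVector sj,
                         NumericVector sx, NumericVector sxlo,
                         NumericVector rlo, NumericVector rlolo,
                         NumericVector rhi, NumericVector rhilo,
                         NumericVector lb, NumericVector ub, NumericVector cc,
                         NumericVector vh, NumericVector vl, NumericVector yh,
                         NumericVector yl, IntegerVector vstat) {
  std::vector<qd> act(m, qd_from(0.0Q));
  std::vector<qd> zty(n, qd_from(0.0Q));
  int nnz = sx.size();
  for (int k = 0; k < nnz; k++) {
    int i = si[k], j = sj[k];
    qd a = qd_from2(sx[k], sxlo[k]);
    act[i] = qd_add(act[i], qd_mul(a, qd_from2(vh[j], vl[j])));
    zty[j] = qd_add(zty[j], qd_mul(a, qd_from2(yh[i], yl[i])));
  }
  qd pmax = qd_from(0.0Q);
  for (int i = 0; i < m; i++) {
    if (std::isfinite(rlo[i])) {
      qd v = qd_sub(qd_from2(rlo[i], rlolo[i]), act[i]);
      if (qd_lt(pmax, v)) pmax = v;
    }
    if (std::isfinite(rhi[i])) {
      qd v = qd_sub(act[i], qd_from2(rhi[i], rhilo[i]));
      if (qd_lt(pmax, v)) pmax = v;
    }
  }
  for (int j = 0; j < n; j++) {
    if (std::isfinite(lb[j])) {
      qd v = qd_sub(qd_from((quad)lb[j]), qd_from2(vh[j], vl[j]));
      if (qd_lt(pmax, v)) pmax = v;
    }
    if (std::isfinite(ub[j])) {
      qd v = qd_sub(qd_from2(vh[j], vl[j]), qd_from((quad)ub[j]));
      if (qd_lt(pmax, v)) pmax = v;
    }
  }
  qd dmax = qd_from(0.0Q);
  NumericVector zout(n + m), zoutlo(n + m);
  for (int j = 0; j < n + m; j++) {
    qd zj;
    if (j < n) zj = qd_sub(qd_from((quad)cc[j]), zty[j]);
    else zj = qd_from2(yh[j - n], yl[j - n]); // slack reduced cost = y_i
    zout[j] = qd_hi_d(zj); zoutlo[j] = qd_lo_d(zj);
    qd viol = qd_from(0.0Q);
    int st = vstat[j];
    if (st == NB_LOWER) { if (zj.hi < 0.0Q) viol = qd_neg(zj); }
    else if (st == NB_UPPER) { if (zj.hi > 0.0Q) viol = zj; }
    else viol = qd_abs(zj);
    if (qd_lt(dmax, viol)) dmax = viol;
  }
  // objective c'v in qd
  qd obj = qd_from(0.0Q);
  for (int j = 0; j < n; j++)
    if (cc[j] != 0.0)
      obj = qd_add(obj, qd_mul(qd_from((quad)cc[j]), qd_from2(vh[j], vl[j])));
  return List::create(_["pinf"] = qd_hi_d(pmax), _["dinf"] = qd_hi_d(dmax),
                      _["pinf_log10"] = qd_log10(pmax),
                      _["dinf_log10"] = qd_log10(dmax),
                      _["objective"] = qd_hi_d(obj),
                      _["objective_lo"] = qd_lo_d(obj),
                      _["z"] = zout, _["z_lo"] = zoutlo);
}

// Residuals r = b - A x, d = c - A'y in qd (general rectangular A as triplets)
// [[Rcpp::export]]
List cpp_residuals_qd(int m, int n, IntegerVector ai, IntegerVector aj,
                      NumericVector ax, NumericVector axlo, NumericVector bh,
                      NumericVector bl, NumericVector cc, NumericVector xh,
                      NumericVector xl, NumericVector yh, NumericVector yl) {
  std::vector<qd> r(m), d(n);
  for (int i = 0; i < m; i++) r[i] = qd_from2(bh[i], bl[i]);
  for (int j = 0; j < n; j++) d[j] = qd_from((quad)cc[j]);
  int nnz = ax.size();
  for (int k = 0; k < nnz; k++) {
    int i = ai[k], j = aj[k];
    qd a = qd_from2(ax[k], axlo[k]);
    r[i] = qd_sub(r[i], qd_mul(a, qd_from2(xh[j], xl[j])));
    d[j] = qd_sub(d[j], qd_mul(a, qd_from2(yh[i], yl[i])));
  }
  NumericVector rh(m), rl(m), dh(n), dl(n);
  for (int i = 0; i < m; i++) { rh[i] = qd_hi_d(r[i]); rl[i] = qd_lo_d(r[i]); }
  for (int j = 0; j < n; j++) { dh[j] = qd_hi_d(d[j]); dl[j] = qd_lo_d(d[j]); }
  return List::create(_["r"] = rh, _["r_lo"] = rl, _["d"] = dh, _["d_lo"] = dl);
}

// Exact-ish sparse mat-vec in qd: (A v) returned as hi/lo pairs
// [[Rcpp::export]]
List cpp_matvec_qd(int m, IntegerVector ai, IntegerVector aj, NumericVector ax,
                   NumericVector vh, NumericVector vl) {
  std::vector<qd> r(m, qd_from(0.0Q));
  int nnz = ax.size();
  for (int k = 0; k < nnz; k++)
    r[ai[k]] = qd_add(r[ai[k]], qd_mul(qd_from((quad)ax[k]),
                                       qd_from2(vh[aj[k]], vl[aj[k]])));
  NumericVector rh(m), rl(m);
  for (int i = 0; i < m; i++) { rh[i] = qd_hi_d(r[i]); rl[i] = qd_lo_d(r[i]); }
  return List::create(_["hi"] = rh, _["lo"] = rl);
}

// x + s * dx in qd, hi/lo in and out (s a double scalar)
// [[Rcpp::export]]
List cpp_axpy_qd(NumericVector xh, NumericVector xl, NumericVector dxh,
                 NumericVector dxl, double s) {
  int n = xh.size();
  NumericVector oh(n), ol(n);
  qd sq = qd_from((quad)s);
  for (int j = 0; j < n; j++) {
    qd v = qd_add(qd_from2(xh[j], xl[j]),
                  qd_mul(sq, qd_from2(dxh[j], dxl[j])));
    oh[j] = qd_hi_d(v); ol[j] = qd_lo_d(v);
  }
  return List::create(_["hi"] = oh, _["lo"] = ol);
}

// elementwise (a - b) in qd with hi/lo inputs; returns hi/lo
// [[Rcpp::export]]
List cpp_sub_qd(NumericVector ah, NumericVector al, NumericVector bh,
                NumericVector bl) {
  int n = ah.size();
  NumericVector oh(n), ol(n);
  for (int j = 0; j < n; j++) {
    qd v = qd_sub(qd_from2(ah[j], al[j]), qd_from2(bh[j], bl[j]));
    oh[j] = qd_hi_d(v); ol[j] = qd_lo_d(v);
  }
  return List::create(_["hi"] = oh, _["lo"] = ol);
}

// difference between an hi/lo value and the exact rational num/den,
// evaluated in qd and returned as a double (tiny values representable)
// [[Rcpp::export]]
double cpp_qd_diff_rational(double ah, double al, double num, double den) {
  qd a = qd_from2(ah, al);
  qd r = qd_div(qd_from((quad)num), qd_from((quad)den));
  qd d = qd_sub(a, r);
  return qd_hi_d(d);
}

// dense linear solve in qd (Gaussian elimination, partial pivoting);
// independent high-precision oracle for small systems
// [[Rcpp::export]]
List cpp_dense_solve_qd(NumericMatrix A, NumericVector b) {
  int n = A.nrow();
  std::vector<std::vector<qd> > W(n, std::vector<qd>(n));
  std::vector<qd> rhs(n);
  for (int i = 0; i < n; i++) {
    for (int j = 0; j < n; j++) W[i][j] = qd_from((quad)A(i, j));
    rhs[i] = qd_from((quad)b[i]);
  }
  for (int k = 0; k < n; k++) {
    int p = k;
    for (int i = k + 1; i < n; i++)
      if (qd_lt(qd_abs(W[p][k]), qd_abs(W[i][k]))) p = i;
    if (W[p][k].hi == 0.0Q) stop("singular matrix in qd solve");
    std::swap(W[p], W[k]); std::swap(rhs[p], rhs[k]);
    for (int i = k + 1; i < n; i++) {
      if (W[i][k].hi == 0.0Q && W[i][k].lo == 0.0Q) continue;
      qd mult = qd_div(W[i][k], W[k][k]);
      for (int j = k; j < n; j++)
        W[i][j] = qd_sub(W[i][j], qd_mul(mult, W[k][j]));
      rhs[i] = qd_sub(rhs[i], qd_mul(mult, rhs[k]));
    }
  }
  std::vector<qd> x(n);
  for (int k = n - 1; k >= 0; k--) {
    qd s = rhs[k];
    for (int j = k + 1; j < n; j++) s = qd_sub(s, qd_mul(W[k][j], x[j]));
    x[k] = qd_div(s, W[k][k]);
  }
  NumericVector xh(n), xl(n);
  for (int i = 0; i < n; i++) { xh[i] = qd_hi_d(x[i]); xl[i] = qd_lo_d(x[i]); }
  return List::create(_["x"] = xh, _["x_lo"] = xl);
}

// parse decimal strings into quad precision, returned as hi/lo double pairs
// [[Rcpp::export]]
List cpp_parse_quad(CharacterVector s) {
  int n = s.size();
  NumericVector hi(n), lo(n);
  for (int i = 0; i < n; i++) {
    quad v = strtoflt128(CHAR(STRING_ELT(s, i)), NULL);
    hi[i] = (double)v;
    lo[i] = (double)(v - (quad)hi[i]);
  }
  return List::create(_["hi"] = hi, _["lo"] = lo);
}

// format hi/lo pairs as 34-significant-digit decimal strings
// [[Rcpp::export]]
CharacterVector cpp_format_quad(NumericVector hi, NumericVector lo) {
  int n = hi.size();
  CharacterVector out(n);
  char buf[64];
  for (int i = 0; i < n; i++) {
    quad v = (quad)hi[i] + (quad)lo[i];
    quadmath_snprintf(buf, sizeof buf, "%.33Qe", v);
    out[i] = buf;
  }
  return out;
}
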