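// Bounded-variable primal simplex for the small dense LPs arising in
// flux balance / flux variability analysis of toy- to mid-scale models.
//
//   maximize c'x  s.t.  A x = b,  lb <= x <= ub
//
// All lower bounds must be finite (the package encodes "unbounded below"
// with a large negative sentinel before calling); upper bounds may be +Inf.
// Two phases with explicit artificial variables; dense tableau updates;
// Dantzig pricing with a Bland's-rule fallback against cycling.

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <limits>

using namespace Rcpp;

static const double INF = std::numeric_limits<double>::infinity();

enum VStat { NB_LB = 0, NB_UB = 1, BASIC = 2 };

// [[Rcpp::export(name = ".simplex_solve")]]
List simplex_solve(NumericMatrix A, NumericVector b,
                   NumericVector cobj, NumericVector lb, NumericVector ub,
                   double tol = 1e-9, int max_iter = 20000) {
  const int m = A.nrow();
  const int n = A.ncol();
  const int N = n + m;  // structural + artificial

  // Tableau: m x N, starts as [A | signed I]; xB holds basic values.
  std::vector<std::vector<double> > T(m, std::vector<double>(N, 0.0));
  std::vector<double> xB(m);
  std::vector<int> basis(m);
  std::vector<int> stat(N, NB_LB);
  std::vector<double> LB(N), UB(N);

  for (int j = 0; j < n; ++j) { LB[j] = lb[j]; UB[j] = ub[j]; }
  for (int j = n; j < N; ++j) { LB[j] = 0.0; UB[j] = INF; }

  // nonbasic structural variables start at the bound nearer zero
  std::vector<double> xN(N, 0.0);
  for (int j = 0; j < n; ++j) {
    if (std::isfinite(UB[j]) && std::fabs(UB[j]) < std::fabs(LB[j])) {
      stat[j] = NB_UB; xN[j] = UB[j];
    } else {
      stat[j] = NB_LB; xN[j] = LB[j];
    }
  }

  // residual r = b - A xN fixes the sign of each artificial column
  for (int i = 0; i < m; ++i) {
    double r = b[i];
    for (int j = 0; j < n; ++j) {
      T[i][j] = A(i, j);
      r -= A(i, j) * xN[j];
    }
    double sgn = (r < 0.0) ? -1.0 : 1.0;
    T[i][n + i] = sgn;
    basis[i] = n + i;
    stat[n + i] = BASIC;
    xB[i] = std::fabs(r);
    if (sgn < 0.0) {
      // keep the tableau in terms of B^{-1}A with B the signed identity
      for (int j = 0; j < N; ++j) T[i][j] = -T[i][j];
      T[i][n + i] = 1.0;
    }
  }

  std::vector<double> cost(N, 0.0);

  int phase = 1;
  for (int j = n; j < N; ++j) cost[j] = -1.0;  // maximize -sum(artificials)

  int iter = 0;
  bool unbounded = false;
  std::vector<double> zrow(N);

  while (true) {
    if (iter++ > max_iter) {
      return List::create(_["status"] = 3, _["x"] = R_NilValue,
                          _["objective"] = NA_REAL, _["iterations"] = iter);
    }
    bool bland = (iter > 4 * (m + n + 10));

    // reduced costs z_j = c_j - c_B' T[, j]
    for (int j = 0; j < N; ++j) zrow[j] = cost[j];
    for (int i = 0; i < m; ++i) {
      double cb = cost[basis[i]];
      if (cb != 0.0) {
        const std::vector<double>& Ti = T[i];
        for (int j = 0; j < N; ++j) zrow[j] -= cb * Ti[j];
      }
    }

    // entering variable
    int enter = -1; double best = tol; int dir = +1;
    for (int j = 0; j < N; ++j) {
      if (stat[j] == BASIC) continue;
      if (phase == 2 && j >= n) continue;           // artificials locked out
      if (LB[j] == UB[j]) continue;                 // fixed variable
      double z = zrow[j];
      double gain = 0.0; int d = 0;
      if (stat[j] == NB_LB && z > tol) { gain = z; d = +1; }
      else if (stat[j] == NB_UB && z < -tol) { gain = -z; d = -1; }
      if (d != 0) {
        if (bland) { enter = j; dir = d; break; }
        if (gain > best) { best = gain; enter = j; dir = d; }
      }
    }

    if (enter < 0) {  // optimal for current phase
      if (phase == 1) {
        double art = 0.0;
        for (int i = 0; i < m; ++i) if (basis[i] >= n) art += xB[i];
        if (art > 1e-7) {
          return List::create(_["status"] = 1, _["x"] = R_NilValue,
                              _["objective"] = NA_REAL, _["iterations"] = iter);
        }
        // lock artificials at zero and switch to the true objective
        for (int j = n; j < N; ++j) { UB[j] = 0.0; }
        for (int j = 0; j < N; ++j) cost[j] = (j < n) ? cobj[j] : 0.0;
        phase = 2;
        continue;
      }
      break;  // phase 2 optimal
    }

    // ratio test: entering moves t >= 0 away from its current bound
    double t = INF; int leave = -1; int leave_to = NB_LB;
    double span = UB[enter] - LB[enter];
    bool span_limits = std::isfinite(span) && span < t;
    if (span_limits) t = span;
    for (int i = 0; i < m; ++i) {
      double alpha = dir * T[i][enter];
      if (alpha > tol) {  // basic decreases toward its lower bound
        double lim = (xB[i] - LB[basis[i]]) / alpha;
        if (lim < t - 1e-12 || (bland && leave >= 0 && std::fabs(lim - t) <= 1e-12 &&
                                basis[i] < basis[leave])) {
          t = lim; leave = i; leave_to = NB_LB;
        }
      } else if (alpha < -tol) {  // basic increases toward its upper bound
        double ubi = UB[basis[i]];
        if (std::isfinite(ubi)) {
          double lim = (ubi - xB[i]) / (-alpha);
          if (lim < t - 1e-12 || (bland && leave >= 0 && std::fabs(lim - t) <= 1e-12 &&
                                  basis[i] < basis[leave])) {
            t = lim; leave = i; leave_to = NB_UB;
          }
        }
      }
    }

    if (!std::isfinite(t)) {
      unbounded = true;  // only possible in phase 2
      break;
    }
    if (t < 0.0) t = 0.0;

    if (leave < 0) {
      // entering flips to its opposite bound; basis unchanged
      for (int i = 0; i < m; ++i) xB[i] -= dir * T[i][enter] * t;
      stat[enter] = (stat[enter] == NB_LB) ? NB_UB : NB_LB;
      continue;
    }

    // pivot: entering becomes basic in row `leave`
    double enter_val = (stat[enter] == NB_LB) ? (LB[enter] + t) : (UB[enter] - t);
    for (int i = 0; i < m; ++i) if (i != leave) xB[i] -= dir * T[i][enter] * t;

    int lv = basis[leave];
    stat[lv] = leave_to;
    double piv = T[leave][enter];
    std::vector<double>& Tl = T[leave];
    double inv = 1.0 / piv;
    for (int j = 0; j < N; ++j) Tl[j] *= inv;
    for (int i = 0; i < m; ++i) {
      if (i == leave) continue;
      double f = T[i][enter];
      if (f != 0.0) {
        std::vector<double>& Ti = T[i];
        for (int j = 0; j < N; ++j) Ti[j] -= f * Tl[j];
      }
    }
    basis[leave] = enter;
    stat[enter] = BASIC;
    xB[leave] = enter_val;
  }

  if (unbounded) {
    return List::create(_["status"] = 2, _["x"] = R_NilValue,
                        _["objective"] = R_PosInf, _["iterations"] = iter);
  }

  NumericVector x(n);
  for (int j = 0; j < n; ++j) x[j] = (stat[j] == NB_UB) ? UB[j] : LB[j];
  for (int i = 0; i < m; ++i) if (basis[i] < n) x[basis[i]] = xB[i];
  double obj = 0.0;
  for (int j = 0; j < n; ++j) obj += cobj[j] * x[j];
  return List::create(_["status"] = 0, _["x"] = x,
                      _["objective"] = obj, _["iterations"] = iter);
}
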