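#include <Rcpp.h>
using namespace Rcpp;

// Saul-Jordan upper bound on E[log(1 + e^Z)], Z ~ N(m, v):
//   SJ(m, v, xi) = xi*m + log( exp(-xi*m + xi^2 v/2)
//                            + exp((1-xi)*m + (1-xi)^2 v/2) )
// Derivatives used by the mean-field updates:
//   dSJ/dm = sigmoid(m + (1-2 xi) v / 2)            (call it W)
//   dSJ/dv = (xi^2 (1-W) + (1-xi)^2 W) / 2          (call it SV)
static inline double sj_one(double m, double v, double xi) {
  double A = -xi * m + 0.5 * xi * xi * v;
  double B = (1.0 - xi) * m + 0.5 * (1.0 - xi) * (1.0 - xi) * v;
  double M = A > B ? A : B;
  return xi * m + M + log1p(std::exp(-std::fabs(A - B)));
}

static inline double sigmoid(double e) {
  if (e >= 0) return 1.0 / (1.0 + std::exp(-e));
  double t = std::exp(e);
  return t / (1.0 + t);
}

// One pass over the response matrix: per-cell bound terms y*m - SJ and the
// derivative fields, accumulated into row (person) and column (item) sums.
//' @noRd
// [[Rcpp::export(name = ".sj_eval_cpp")]]
List sj_eval_cpp(NumericMatrix m, NumericMatrix v, NumericMatrix xi,
                 IntegerMatrix Y, bool want_derivs) {
  const int S = m.nrow(), L = m.ncol();
  NumericVector row(S), col(L);
  NumericMatrix W(want_derivs ? S : 0, want_derivs ? L : 0);
  NumericMatrix SV(want_derivs ? S : 0, want_derivs ? L : 0);
  for (int k = 0; k < L; ++k) {
    for (int i = 0; i < S; ++i) {
      double mm = m(i, k), vv = v(i, k), xx = xi(i, k);
      double term = Y(i, k) * mm - sj_one(mm, vv, xx);
      row[i] += term;
      col[k] += term;
      if (want_derivs) {
        double w = sigmoid(mm + 0.5 * (1.0 - 2.0 * xx) * vv);
        W(i, k) = w;
        SV(i, k) = 0.5 * (xx * xx * (1.0 - w) +
                          (1.0 - xx) * (1.0 - xx) * w);
      }
    }
  }
  return List::create(_["row"] = row, _["col"] = col, _["W"] = W,
                      _["SV"] = SV);
}

// Optimal xi solves the stationarity condition xi = sigmoid(m + (1-2 xi) v/2).
// g(xi) = xi - sigmoid(...) is strictly increasing (g' = 1 + v w (1-w) >= 1),
// so Newton from a warm start converges; iterates are clipped into (0, 1).
//' @noRd
// [[Rcpp::export(name = ".sj_xi_solve_cpp")]]
NumericMatrix sj_xi_solve_cpp(NumericMatrix m, NumericMatrix v,
                              NumericMatrix xi0, int maxit, double tol) {
  const int S = m.nrow(), L = m.ncol();
  const double lo = 1e-12, hi = 1.0 - 1e-12;
  NumericMatrix out(S, L);
  for (int k = 0; k < L; ++k) {
    for (int i = 0; i < S; ++i) {
      double mm = m(i, k), vv = v(i, k);
      double x = xi0(i, k);
      if (x <= lo || x >= hi) x = 0.5;
      for (int it = 0; it < maxit; ++it) {
        double w = sigmoid(mm + 0.5 * (1.0 - 2.0 * x) * vv);
        double g = x - w;
        double gp = 1.0 + vv * w * (1.0 - w);
        double xn = x - g / gp;
        if (xn < lo) xn = lo;
        if (xn > hi) xn = hi;
        if (std::fabs(xn - x) < tol) {
          x = xn;
          break;
        }
        x = xn;
      }
      out(i, k) = x;
    }
  }
  return out;
}
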