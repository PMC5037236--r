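#include <Rcpp.h>
using namespace Rcpp;

// Single pass over the response matrix computing every per-block sufficient
// statistic of the Saul-Jordan mean-field objective, without materializing
// any S x L intermediate. Per cell: the (moment-matched) Gaussian logit
// (m, v), the bound term y*m - SJ, and the derivative fields
//   w  = dSJ/dm = sigmoid(m + (1-2 xi) v / 2)
//   sv = dSJ/dv = (xi^2 (1-w) + (1-xi)^2 w)/2
// accumulated into gradient / curvature / variance-target sums for the
// ability (t), difficulty (b) and log-discrimination (z) blocks.
//' @noRd
// [[Rcpp::export(name = ".vb_stats_cpp")]]
List vb_stats_cpp(NumericVector mu_t, NumericVector v_t, NumericVector mu_b,
                  NumericVector v_b, NumericVector mu_z, NumericVector v_z,
                  NumericMatrix xi, IntegerMatrix Y, int model) {
  const int S = Y.nrow(), L = Y.ncol();
  NumericVector row(S), col(L), gt(S), ct(S), stt(S), gb(L), cb(L), sbb(L),
      gz(L), cz(L), gvz(L), hvz(L);
  std::vector<double> alpha(L, 1.0), A2(L, 1.0);
  if (model == 2) {
    for (int k = 0; k < L; ++k) {
      alpha[k] = std::exp(mu_z[k] + 0.5 * v_z[k]);
      A2[k] = std::exp(2.0 * (mu_z[k] + v_z[k]));
    }
  }
  for (int k = 0; k < L; ++k) {
    const double ak = alpha[k], A2k = A2[k], a2 = ak * ak;
    const double mbk = mu_b[k], vbk = v_b[k];
    const int* yk = &Y(0, k);
    const double* xk = &xi(0, k);
    double col_a = 0, gb_a = 0, cb_a = 0, sbb_a = 0, gz_a = 0, cz_a = 0,
           gvz_a = 0, hvz_a = 0;
    for (int i = 0; i < S; ++i) {
      const double d = mu_t[i] - mbk;
      const double Tv = v_t[i] + vbk;
      const double Td = d * d + Tv;
      const double m = ak * d;
      const double v = A2k * Td - a2 * d * d;
      const double x = xk[i];
      const double A = -x * m + 0.5 * x * x * v;
      const double B = (1.0 - x) * m + 0.5 * (1.0 - x) * (1.0 - x) * v;
      double sj, w;
      if (B > A) {
        const double t = std::exp(A - B);
        sj = x * m + B + log1p(t);
        w = 1.0 / (1.0 + t);
      } else {
        const double t = std::exp(B - A);
        sj = x * m + A + log1p(t);
        w = t / (1.0 + t);
      }
      const double sv = 0.5 * (x * x * (1.0 - w) +
                               (1.0 - x) * (1.0 - x) * w);
      const int y = yk[i];
      const double term = y * m - sj;
      row[i] += term;
      col_a += term;
      const double ym = y - w;
      const double wc = w * (1.0 - w);
      const double dv = 2.0 * d * (A2k - a2); // d v / d mu_t (= -d/d mu_b)
      gt[i] += ym * ak - sv * dv;
      ct[i] += wc * a2;
      stt[i] += sv * A2k;
      gb_a += -ym * ak + sv * dv;
      cb_a += wc * a2;
      sbb_a += sv * A2k;
      if (model == 2) {
        gz_a += ym * m - 2.0 * sv * v;
        cz_a += wc * m * m;
        gvz_a += 0.5 * ym * m - sv * (v + A2k * Td);
        hvz_a += 0.25 * wc * m * m + sv * A2k * Td;
      }
    }
    col[k] = col_a;
    gb[k] = gb_a;
    cb[k] = cb_a;
    sbb[k] = sbb_a;
    gz[k] = gz_a;
    cz[k] = cz_a;
    gvz[k] = gvz_a;
    hvz[k] = hvz_a;
  }
  return List::create(_["row"] = row, _["col"] = col, _["gt"] = gt,
                      _["ct"] = ct, _["stt"] = stt, _["gb"] = gb,
                      _["cb"] = cb, _["sbb"] = sbb, _["gz"] = gz,
                      _["cz"] = cz, _["gvz"] = gvz, _["hvz"] = hvz);
}

// Newton solve of the optimal xi per response cell, computing the logit
// moments on the fly from the factor parameters; returns a fresh xi matrix.
//' @noRd
// [[Rcpp::export(name = ".vb_xi_cpp")]]
NumericMatrix vb_xi_cpp(NumericVector mu_t, NumericVector v_t,
                        NumericVector mu_b, NumericVector v_b,
                        NumericVector mu_z, NumericVector v_z,
                        NumericMatrix xi0, int model, int maxit,
                        double tol) {
  const int S = xi0.nrow(), L = xi0.ncol();
  NumericMatrix out(S, L);
  const double lo = 1e-12, hi = 1.0 - 1e-12;
  for (int k = 0; k < L; ++k) {
    double ak = 1.0, A2k = 1.0;
    if (model == 2) {
      ak = std::exp(mu_z[k] + 0.5 * v_z[k]);
      A2k = std::exp(2.0 * (mu_z[k] + v_z[k]));
    }
    const double a2 = ak * ak;
    for (int i = 0; i < S; ++i) {
      const double d = mu_t[i] - mu_b[k];
      const double Td = d * d + v_t[i] + v_b[k];
      const double m = ak * d;
      const double v = A2k * Td - a2 * d * d;
      double x = xi0(i, k);
      if (x <= lo || x >= hi) x = 0.5;
      for (int it = 0; it < maxit; ++it) {
        const double e = m + 0.5 * (1.0 - 2.0 * x) * v;
        double w;
        if (e >= 0) w = 1.0 / (1.0 + std::exp(-e));
        else {
          const double t = std::exp(e);
          w = t / (1.0 + t);
        }
        const double g = x - w;
        const double gp = 1.0 + v * w * (1.0 - w);
        double xn = x - g / gp;
        if (xn < lo) xn = lo;
        if (xn > hi) xn = hi;
        const double dx = std::fabs(xn - x);
        x = xn;
        if (dx < tol) break;
      }
      out(i, k) = x;
    }
  }
  return out;
}
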