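#include <Rcpp.h>
using namespace Rcpp;

// Elementary symmetric functions gamma_r(eps), r = 0..L, by the summation
// recursion. Caller is expected to pass easiness values scaled by their
// geometric mean for numerical balance (gamma_r(c*eps) = c^r * gamma_r(eps)).
static std::vector<double> esf_gamma(const std::vector<double>& eps) {
  const int L = eps.size();
  std::vector<double> g(L + 1, 0.0);
  g[0] = 1.0;
  for (int k = 0; k < L; ++k) {
    for (int r = std::min(k + 1, L); r >= 1; --r) {
      g[r] += eps[k] * g[r - 1];
    }
  }
  return g;
}

// gamma with items in `skip` removed (values < 0 mean no skip)
static std::vector<double> esf_gamma_skip(const std::vector<double>& eps,
                                          int skip1, int skip2) {
  std::vector<double> sub;
  sub.reserve(eps.size());
  for (int k = 0; k < (int)eps.size(); ++k) {
    if (k != skip1 && k != skip2) sub.push_back(eps[k]);
  }
  return esf_gamma(sub);
}

//' @noRd
// [[Rcpp::export(name = ".esf_table_cpp")]]
List esf_table_cpp(NumericVector easiness) {
  const int L = easiness.size();
  std::vector<double> eps(easiness.begin(), easiness.end());
  std::vector<double> g = esf_gamma(eps);
  NumericMatrix g1(L, L); // row k: gamma^{(k)}_r, r = 0..L-1
  for (int k = 0; k < L; ++k) {
    std::vector<double> gk = esf_gamma_skip(eps, k, -1);
    for (int r = 0; r < L; ++r) g1(k, r) = gk[r];
  }
  return List::create(_["gamma"] = NumericVector(g.begin(), g.end()),
                      _["gamma_partial"] = g1);
}

// Conditional log-likelihood of the Rasch model and its derivatives with
// respect to beta = log(easiness) = -difficulty.
//
// score_counts: counts n_r of persons with raw score r, r = 0..L (extreme
//   scores carry no information and should already be zeroed by the caller).
// item_totals: number of correct responses per item among those persons.
//
// loglik = sum_k t_k beta_k - sum_r n_r log gamma_r
// grad_k = t_k - sum_r n_r pi_rk,            pi_rk = eps_k g1_{k,r-1}/gamma_r
// hess_kj = -sum_r n_r (E[x_k x_j | r] - pi_rk pi_rj)
//' @noRd
// [[Rcpp::export(name = ".cml_derivs_cpp")]]
List cml_derivs_cpp(NumericVector beta, NumericVector score_counts,
                    NumericVector item_totals, bool hessian) {
  const int L = beta.size();
  double mb = 0.0;
  for (int k = 0; k < L; ++k) mb += beta[k];
  mb /= L;
  std::vector<double> eps(L);
  for (int k = 0; k < L; ++k) eps[k] = std::exp(beta[k] - mb);

  std::vector<double> g = esf_gamma(eps);
  // pi(r, k)
  NumericMatrix pi(L + 1, L);
  std::vector<std::vector<double> > g1(L);
  for (int k = 0; k < L; ++k) {
    g1[k] = esf_gamma_skip(eps, k, -1);
    for (int r = 1; r <= L; ++r) {
      double num = (r - 1 <= L - 1) ? g1[k][r - 1] : 0.0;
      pi(r, k) = eps[k] * num / g[r];
    }
  }

  double ll = 0.0;
  for (int k = 0; k < L; ++k) ll += item_totals[k] * beta[k];
  for (int r = 0; r <= L; ++r) {
    if (score_counts[r] > 0.0)
      ll -= score_counts[r] * (std::log(g[r]) + r * mb);
  }

  NumericVector grad(L);
  for (int k = 0; k < L; ++k) {
    double s = item_totals[k];
    for (int r = 1; r <= L; ++r) s -= score_counts[r] * pi(r, k);
    grad[k] = s;
  }

  NumericMatrix H(L, L);
  if (hessian) {
    for (int k = 0; k < L; ++k) {
      double hkk = 0.0;
      for (int r = 1; r <= L; ++r)
        hkk -= score_counts[r] * pi(r, k) * (1.0 - pi(r, k));
      H(k, k) = hkk;
    }
    for (int k = 0; k < L; ++k) {
      for (int j = k + 1; j < L; ++j) {
        std::vector<double> gkj = esf_gamma_skip(eps, k, j);
        double hkj = 0.0;
        for (int r = 2; r <= L; ++r) {
          if (score_counts[r] == 0.0) continue;
          double exx = eps[k] * eps[j] * gkj[r - 2] / g[r];
          hkj -= score_counts[r] * (exx - pi(r, k) * pi(r, j));
        }
        H(k, j) = hkj;
        H(j, k) = hkj;
      }
    }
  }

  return List::create(_["loglik"] = ll, _["gradient"] = grad,
                      _["hessian"] = H);
}
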