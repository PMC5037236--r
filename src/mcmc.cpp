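#include <Rcpp.h>
using namespace Rcpp;

// stable log(sigmoid(e))
static inline double logsig(double e) {
  if (e < -33.0) return e;
  return -log1p(std::exp(-e));
}

// cell log-likelihood: y in {0,1}, logit e
static inline double cell_ll(int y, double e) {
  return y ? logsig(e) : logsig(-e);
}

// Conjugate draw for the mean of a normal population:
// m | x ~ N( prec_each*sum(x) / P, 1/P ), P = n*prec_each + 1/prior_var
static double draw_gauss_mean(double sum_vals, int n, double prec_each,
                              double prior_var) {
  double P = n * prec_each + 1.0 / prior_var;
  double mu = prec_each * sum_vals / P;
  return mu + norm_rand() / std::sqrt(P);
}

// Conjugate draw for a normal population precision with Gamma(shape0, rate0)
// prior: u | x, m ~ Gamma(shape0 + n/2, rate0 + ss/2), ss = sum (x_i - m)^2
static double draw_gamma_prec(double ss, int n, double shape0, double rate0) {
  double shape = shape0 + 0.5 * n;
  double rate = rate0 + 0.5 * ss;
  return R::rgamma(shape, 1.0 / rate); // R::rgamma is shape/scale
}

//' @noRd
// [[Rcpp::export(name = ".conj_mean_draws_cpp")]]
NumericVector conj_mean_draws_cpp(NumericVector values, double prec_each,
                                  double prior_var, int ndraws) {
  double s = 0.0;
  for (double v : values) s += v;
  NumericVector out(ndraws);
  for (int t = 0; t < ndraws; ++t)
    out[t] = draw_gauss_mean(s, values.size(), prec_each, prior_var);
  return out;
}

//' @noRd
// [[Rcpp::export(name = ".conj_prec_draws_cpp")]]
NumericVector conj_prec_draws_cpp(NumericVector values, double m,
                                  double shape0, double rate0, int ndraws) {
  double ss = 0.0;
  for (double v : values) ss += (v - m) * (v - m);
  NumericVector out(ndraws);
  for (int t = 0; t < ndraws; ++t)
    out[t] = draw_gamma_prec(ss, values.size(), shape0, rate0);
  return out;
}

struct Adapt {
  std::vector<double> sd;
  std::vector<int> acc;
  std::vector<int> tries;
  void init(int n, double s0) {
    sd.assign(n, s0);
    acc.assign(n, 0);
    tries.assign(n, 0);
  }
  // called every `window` iterations during burn-in; target 0.3-0.5
  void tune() {
    for (size_t j = 0; j < sd.size(); ++j) {
      if (tries[j] == 0) continue;
      double rate = (double)acc[j] / tries[j];
      if (rate < 0.3) sd[j] *= 0.7;
      else if (rate > 0.5) sd[j] *= 1.4;
      if (sd[j] < 0.01) sd[j] = 0.01;
      if (sd[j] > 50.0) sd[j] = 50.0;
      acc[j] = 0;
      tries[j] = 0;
    }
  }
};

// Metropolis-within-Gibbs for the 1PL/2PL logistic IRT model.
// model: 1 or 2. regime: 0 = fixed priors (matched/stdvague), 1 = hierarchical.
// Fixed-prior parameters are (mean, var) for theta, b and log a. Hierarchical
// hyperpriors: m ~ N(0, hyper_var), u ~ Gamma(g_shape, g_rate) on precisions.
// Initial values: all latent parameters 0, hierarchical means 0, SDs 1.
//
// A cache C of per-cell log-likelihood terms is maintained so each block
// update costs one logistic evaluation per cell; the ability block proposes
// all persons jointly (their full conditionals are independent given the
// item parameters), item blocks run column-wise over the cache.
//' @noRd
// [[Rcpp::export(name = ".gibbs_irt_cpp")]]
List gibbs_irt_cpp(IntegerMatrix Y, int model, int regime,
                   double th_mean, double th_var, double b_mean, double b_var,
                   double z_mean, double z_var, double hyper_var,
                   double g_shape, double g_rate, int burnin, int keep,
                   double b_prop_init) {
  const int S = Y.nrow(), L = Y.ncol();
  const int total = burnin + keep;
  const int window = 50;
  const int* y = Y.begin(); // column-major

  std::vector<double> th(S, 0.0), b(L, 0.0), z(L, 0.0), a(L, 1.0);
  double m_th = 0.0, u_th = 1.0, m_b = 0.0, u_b = 1.0, m_a = 0.0, u_a = 1.0;

  Adapt ad_th, ad_b, ad_z;
  ad_th.init(S, 1.0);
  ad_b.init(L, b_prop_init);
  ad_z.init(L, 1.0);

  // cell log-likelihood cache and row sums at the current state
  std::vector<double> C((size_t)S * L), rowll(S, 0.0);
  for (int k = 0; k < L; ++k) {
    const int* yk = y + (size_t)S * k;
    double* ck = &C[(size_t)S * k];
    for (int i = 0; i < S; ++i) {
      ck[i] = cell_ll(yk[i], a[k] * (th[i] - b[k]));
      rowll[i] += ck[i];
    }
  }

  std::vector<double> th_prop(S), prop_row(S), colbuf(S);
  std::vector<double> Ptmp((size_t)S * L); // proposed-row cell cache

  NumericMatrix th_draws(keep, S), b_draws(keep, L);
  NumericMatrix z_draws(model == 2 ? keep : 0, model == 2 ? L : 0);
  NumericMatrix hy_draws(keep, 6);
  double acc_th = 0.0, acc_b = 0.0, acc_z = 0.0;

  for (int t = 0; t < total; ++t) {
    const bool adapting = t < burnin;

    // --- abilities: joint independent proposals, one pass over the cells ---
    for (int i = 0; i < S; ++i) {
      th_prop[i] = th[i] + ad_th.sd[i] * norm_rand();
      prop_row[i] = 0.0;
    }
    for (int k = 0; k < L; ++k) {
      const int* yk = y + (size_t)S * k;
      double* pk = &Ptmp[(size_t)S * k];
      const double ak = a[k], bk = b[k];
      for (int i = 0; i < S; ++i) {
        pk[i] = cell_ll(yk[i], ak * (th_prop[i] - bk));
        prop_row[i] += pk[i];
      }
    }
    {
      std::vector<char> accept(S, 0);
      for (int i = 0; i < S; ++i) {
        double cur = th[i], prop = th_prop[i], dprior;
        if (regime == 1)
          dprior = -0.5 * u_th * ((prop - m_th) * (prop - m_th) -
                                  (cur - m_th) * (cur - m_th));
        else
          dprior = -0.5 / th_var * ((prop - th_mean) * (prop - th_mean) -
                                    (cur - th_mean) * (cur - th_mean));
        ad_th.tries[i]++;
        if (std::log(unif_rand()) < prop_row[i] - rowll[i] + dprior) {
          accept[i] = 1;
          th[i] = prop;
          rowll[i] = prop_row[i];
          ad_th.acc[i]++;
          if (!adapting) acc_th += 1.0;
        }
      }
      // refresh cached cells of accepted rows from the proposal cache
      for (int k = 0; k < L; ++k) {
        const double* pk = &Ptmp[(size_t)S * k];
        double* ck = &C[(size_t)S * k];
        for (int i = 0; i < S; ++i)
          if (accept[i]) ck[i] = pk[i];
      }
    }

    // --- difficulties: column-wise with cached current column sums ---
    for (int k = 0; k < L; ++k) {
      double cur = b[k];
      double prop = cur + ad_b.sd[k] * norm_rand();
      const int* yk = y + (size_t)S * k;
      double* ck = &C[(size_t)S * k];
      double cur_col = 0.0, prop_col = 0.0;
      const double ak = a[k];
      for (int i = 0; i < S; ++i) {
        cur_col += ck[i];
        colbuf[i] = cell_ll(yk[i], ak * (th[i] - prop));
        prop_col += colbuf[i];
      }
      double dprior;
      if (regime == 1)
        dprior = -0.5 * u_b * ((prop - m_b) * (prop - m_b) -
                               (cur - m_b) * (cur - m_b));
      else
        dprior = -0.5 / b_var * ((prop - b_mean) * (prop - b_mean) -
                                 (cur - b_mean) * (cur - b_mean));
      ad_b.tries[k]++;
      if (std::log(unif_rand()) < prop_col - cur_col + dprior) {
        b[k] = prop;
        for (int i = 0; i < S; ++i) {
          rowll[i] += colbuf[i] - ck[i];
          ck[i] = colbuf[i];
        }
        ad_b.acc[k]++;
        if (!adapting) acc_b += 1.0;
      }
    }

    // --- log-discriminations (2PL) ---
    if (model == 2) {
      for (int k = 0; k < L; ++k) {
        double cur = z[k];
        double prop = cur + ad_z.sd[k] * norm_rand();
        double ap = std::exp(prop);
        const int* yk = y + (size_t)S * k;
        double* ck = &C[(size_t)S * k];
        double cur_col = 0.0, prop_col = 0.0;
        const double bk = b[k];
        for (int i = 0; i < S; ++i) {
          cur_col += ck[i];
          colbuf[i] = cell_ll(yk[i], ap * (th[i] - bk));
          prop_col += colbuf[i];
        }
        double dprior;
        if (regime == 1)
          dprior = -0.5 * u_a * ((prop - m_a) * (prop - m_a) -
                                 (cur - m_a) * (cur - m_a));
        else
          dprior = -0.5 / z_var * ((prop - z_mean) * (prop - z_mean) -
                                   (cur - z_mean) * (cur - z_mean));
        ad_z.tries[k]++;
        if (std::log(unif_rand()) < prop_col - cur_col + dprior) {
          z[k] = prop;
          a[k] = ap;
          for (int i = 0; i < S; ++i) {
            rowll[i] += colbuf[i] - ck[i];
            ck[i] = colbuf[i];
          }
          ad_z.acc[k]++;
          if (!adapting) acc_z += 1.0;
        }
      }
    }

    // --- hierarchical hyperparameters (exact conjugate draws) ---
    if (regime == 1) {
      double sum_th = 0.0, ss;
      for (int i = 0; i < S; ++i) sum_th += th[i];
      m_th = draw_gauss_mean(sum_th, S, u_th, hyper_var);
      ss = 0.0;
      for (int i = 0; i < S; ++i) ss += (th[i] - m_th) * (th[i] - m_th);
      u_th = draw_gamma_prec(ss, S, g_shape, g_rate);

      double sum_b = 0.0;
      for (int k = 0; k < L; ++k) sum_b += b[k];
      m_b = draw_gauss_mean(sum_b, L, u_b, hyper_var);
      ss = 0.0;
      for (int k = 0; k < L; ++k) ss += (b[k] - m_b) * (b[k] - m_b);
      u_b = draw_gamma_prec(ss, L, g_shape, g_rate);

      if (model == 2) {
        double sum_z = 0.0;
        for (int k = 0; k < L; ++k) sum_z += z[k];
        m_a = draw_gauss_mean(sum_z, L, u_a, hyper_var);
        ss = 0.0;
        for (int k = 0; k < L; ++k) ss += (z[k] - m_a) * (z[k] - m_a);
        u_a = draw_gamma_prec(ss, L, g_shape, g_rate);
      }
    }

    if (adapting && (t + 1) % window == 0) {
      ad_th.tune();
      ad_b.tune();
      if (model == 2) ad_z.tune();
    }

    if (!adapting) {
      int r = t - burnin;
      for (int i = 0; i < S; ++i) th_draws(r, i) = th[i];
      for (int k = 0; k < L; ++k) b_draws(r, k) = b[k];
      if (model == 2)
        for (int k = 0; k < L; ++k) z_draws(r, k) = z[k];
      hy_draws(r, 0) = m_th;
      hy_draws(r, 1) = u_th;
      hy_draws(r, 2) = m_b;
      hy_draws(r, 3) = u_b;
      hy_draws(r, 4) = m_a;
      hy_draws(r, 5) = u_a;
    }
  }

  double denom_keep = (double)keep;
  return List::create(
      _["theta"] = th_draws, _["b"] = b_draws, _["z"] = z_draws,
      _["hyper"] = hy_draws,
      _["acc_theta"] = acc_th / (denom_keep * S),
      _["acc_b"] = acc_b / (denom_keep * L),
      _["acc_z"] = model == 2 ? acc_z / (denom_keep * L) : NA_REAL);
}
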