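// Reversible-jump MCMC for the Bayesian F-model outlier scan.
//
// Model: B-allele count a_lj of n_lj gene copies in population j at locus l
// follows a beta-binomial with mean p_l (ancestral frequency) and
// concentration theta_lj = exp(-(alpha_l + beta_j)), i.e. the logit of the
// locus-by-population F_ST decomposes into a locus effect (selection) and a
// population effect (drift).  A reversible jump switches alpha_l in and out
// of the model; the posterior inclusion probability yields posterior odds of
// selection per locus.  Proposals for p, alpha and beta are random-walk,
// adapted during burn-in; the jump proposal for alpha is tuned by a pilot
// phase run with all locus effects included.

#include <Rcpp.h>
using namespace Rcpp;

static const double G_CLAMP = 15.0;  // clamp on alpha + beta (logit F scale)
static const double P_EPS = 1e-9;

static inline double clampg(double g) {
  if (g > G_CLAMP) return G_CLAMP;
  if (g < -G_CLAMP) return -G_CLAMP;
  return g;
}

// log beta-binomial likelihood cell, binomial coefficient dropped
static inline double cell_ll(double a, double n, double p, double g) {
  double th = std::exp(-clampg(g));
  double u = th * p, v = th * (1.0 - p);
  return R::lbeta(a + u, n - a + v) - R::lbeta(u, v);
}

static inline double logit(double p) { return std::log(p / (1.0 - p)); }
static inline double expit(double x) { return 1.0 / (1.0 + std::exp(-x)); }

// [[Rcpp::export(name = ".outlier_mcmc")]]
List outlier_mcmc(NumericMatrix a, NumericMatrix n,
                  double prior_odds,
                  int pilot, int burn_in, int n_samples, int thin) {
  const int L = a.nrow(), J = a.ncol();
  const double log_incl_odds = -std::log(prior_odds);

  // state
  std::vector<double> p(L), alpha(L, 0.0), beta(J, -1.0);
  std::vector<int> incl(L, 0);
  for (int l = 0; l < L; ++l) {
    double tot = 0.0, cnt = 0.0;
    for (int j = 0; j < J; ++j) { tot += n(l, j); cnt += a(l, j); }
    double ml = cnt / tot;
    p[l] = std::min(1.0 - 1e-4, std::max(1e-4, ml));
  }

  // cached cell log-likelihoods
  NumericMatrix M(L, J);
  auto g_of = [&](int l, int j) { return alpha[l] * incl[l] + beta[j]; };
  for (int l = 0; l < L; ++l)
    for (int j = 0; j < J; ++j)
      M(l, j) = cell_ll(a(l, j), n(l, j), p[l], g_of(l, j));

  // proposal scales and acceptance bookkeeping
  std::vector<double> sp(L, 0.3), sa(L, 0.4), sb(J, 0.1);
  std::vector<double> acc_p(L, 0), try_p(L, 0), acc_a(L, 0), try_a(L, 0);
  std::vector<double> acc_b(J, 0), try_b(J, 0);

  // pilot statistics for the jump proposal
  std::vector<double> mu(L, 0.0), sdj(L, 1.0);
  std::vector<double> asum(L, 0.0), asum2(L, 0.0);
  int pilot_tail = 0;

  // posterior accumulators
  std::vector<double> inc_cnt(L, 0.0), a_sum(L, 0.0), a_cnt(L, 0.0);
  std::vector<double> fst_sum(L, 0.0), p_sum(L, 0.0), b_sum(J, 0.0);

  std::vector<double> buf(J);

  auto update_p = [&](int l) {
    double x = logit(p[l]) + R::norm_rand() * sp[l];
    double pn = expit(x);
    if (pn < P_EPS || pn > 1.0 - P_EPS) return;
    double d = 0.0;
    for (int j = 0; j < J; ++j) {
      buf[j] = cell_ll(a(l, j), n(l, j), pn, g_of(l, j));
      d += buf[j] - M(l, j);
    }
    // uniform prior on p, random walk on logit scale: Jacobian ratio
    d += std::log(pn * (1.0 - pn)) - std::log(p[l] * (1.0 - p[l]));
    try_p[l] += 1;
    if (std::log(R::unif_rand()) < d) {
      p[l] = pn;
      for (int j = 0; j < J; ++j) M(l, j) = buf[j];
      acc_p[l] += 1;
    }
  };

  auto update_alpha = [&](int l) {
    if (!incl[l]) return;
    double an = alpha[l] + R::norm_rand() * sa[l];
    double d = 0.0;
    for (int j = 0; j < J; ++j) {
      buf[j] = cell_ll(a(l, j), n(l, j), p[l], an + beta[j]);
      d += buf[j] - M(l, j);
    }
    d += R::dnorm(an, 0.0, 1.0, 1) - R::dnorm(alpha[l], 0.0, 1.0, 1);
    try_a[l] += 1;
    if (std::log(R::unif_rand()) < d) {
      alpha[l] = an;
      for (int j = 0; j < J; ++j) M(l, j) = buf[j];
      acc_a[l] += 1;
    }
  };

  auto update_beta = [&](int j) {
    double bn = beta[j] + R::norm_rand() * sb[j];
    double d = 0.0;
    for (int l = 0; l < L; ++l)
      d += cell_ll(a(l, j), n(l, j), p[l], alpha[l] * incl[l] + bn) - M(l, j);
    d += R::dnorm(bn, -1.0, 1.8, 1) - R::dnorm(beta[j], -1.0, 1.8, 1);
    try_b[j] += 1;
    if (std::log(R::unif_rand()) < d) {
      double old = beta[j];
      beta[j] = bn;
      for (int l = 0; l < L; ++l)
        M(l, j) = cell_ll(a(l, j), n(l, j), p[l],
                          alpha[l] * incl[l] + beta[j]);
      (void)old;
      acc_b[j] += 1;
    }
  };

  auto rj_toggle = [&](int l) {
    if (!incl[l]) {  // birth: propose alpha* from the pilot-tuned proposal
      double as = mu[l] + R::norm_rand() * sdj[l];
      double d = 0.0;
      for (int j = 0; j < J; ++j) {
        buf[j] = cell_ll(a(l, j), n(l, j), p[l], as + beta[j]);
        d += buf[j] - M(l, j);
      }
      d += R::dnorm(as, 0.0, 1.0, 1) - R::dnorm(as, mu[l], sdj[l], 1)
           + log_incl_odds;
      if (std::log(R::unif_rand()) < d) {
        incl[l] = 1; alpha[l] = as;
        for (int j = 0; j < J; ++j) M(l, j) = buf[j];
      }
    } else {  // death
      double d = 0.0;
      for (int j = 0; j < J; ++j) {
        buf[j] = cell_ll(a(l, j), n(l, j), p[l], beta[j]);
        d += buf[j] - M(l, j);
      }
      d += -R::dnorm(alpha[l], 0.0, 1.0, 1)
           + R::dnorm(alpha[l], mu[l], sdj[l], 1) - log_incl_odds;
      if (std::log(R::unif_rand()) < d) {
        incl[l] = 0; alpha[l] = 0.0;
        for (int j = 0; j < J; ++j) M(l, j) = buf[j];
      }
    }
  };

  auto adapt = [&](std::vector<double>& s, std::vector<double>& acc,
                   std::vector<double>& tr) {
    for (size_t i = 0; i < s.size(); ++i) {
      if (tr[i] < 10) continue;
      double rate = acc[i] / tr[i];
      s[i] *= std::exp(1.5 * (rate - 0.35));
      s[i] = std::min(5.0, std::max(0.01, s[i]));
      acc[i] = 0; tr[i] = 0;
    }
  };

  // ---- pilot phase: all locus effects included, tune everything ----------
  for (int l = 0; l < L; ++l) { incl[l] = 1; alpha[l] = 0.0; }
  for (int l = 0; l < L; ++l)
    for (int j = 0; j < J; ++j)
      M(l, j) = cell_ll(a(l, j), n(l, j), p[l], g_of(l, j));
  for (int it = 0; it < pilot; ++it) {
    for (int l = 0; l < L; ++l) update_p(l);
    for (int l = 0; l < L; ++l) update_alpha(l);
    for (int j = 0; j < J; ++j) update_beta(j);
    if ((it + 1) % 50 == 0) {
      adapt(sp, acc_p, try_p); adapt(sa, acc_a, try_a); adapt(sb, acc_b, try_b);
    }
    if (it >= pilot / 2) {
      ++pilot_tail;
      for (int l = 0; l < L; ++l) { asum[l] += alpha[l]; asum2[l] += alpha[l] * alpha[l]; }
    }
    if ((it + 1) % 200 == 0) Rcpp::checkUserInterrupt();
  }
  for (int l = 0; l < L; ++l) {
    if (pilot_tail > 1) {
      mu[l] = asum[l] / pilot_tail;
      double v = asum2[l] / pilot_tail - mu[l] * mu[l];
      sdj[l] = std::max(0.25, std::sqrt(std::max(v, 0.0)));
    }
  }

  // ---- reversible-jump phase ---------------------------------------------
  for (int l = 0; l < L; ++l) { incl[l] = 0; alpha[l] = 0.0; }
  for (int l = 0; l < L; ++l)
    for (int j = 0; j < J; ++j)
      M(l, j) = cell_ll(a(l, j), n(l, j), p[l], g_of(l, j));

  const int total = burn_in + n_samples * thin;
  for (int it = 0; it < total; ++it) {
    for (int l = 0; l < L; ++l) update_p(l);
    for (int l = 0; l < L; ++l) update_alpha(l);
    for (int j = 0; j < J; ++j) update_beta(j);
    for (int l = 0; l < L; ++l) rj_toggle(l);
    if (it < burn_in && (it + 1) % 50 == 0) {
      adapt(sp, acc_p, try_p); adapt(sa, acc_a, try_a); adapt(sb, acc_b, try_b);
    }
    if (it >= burn_in && (it - burn_in) % thin == 0) {
      for (int l = 0; l < L; ++l) {
        if (incl[l]) { inc_cnt[l] += 1; a_sum[l] += alpha[l]; a_cnt[l] += 1; }
        p_sum[l] += p[l];
        double f = 0.0;
        for (int j = 0; j < J; ++j) f += expit(clampg(g_of(l, j)));
        fst_sum[l] += f / J;
      }
      for (int j = 0; j < J; ++j) b_sum[j] += beta[j];
    }
    if ((it + 1) % 200 == 0) Rcpp::checkUserInterrupt();
  }

  NumericVector incl_prob(L), alpha_mean(L), fst_mean(L), p_mean(L), beta_mean(J);
  for (int l = 0; l < L; ++l) {
    incl_prob[l] = inc_cnt[l] / n_samples;
    alpha_mean[l] = a_cnt[l] > 0 ? a_sum[l] / a_cnt[l] : 0.0;
    fst_mean[l] = fst_sum[l] / n_samples;
    p_mean[l] = p_sum[l] / n_samples;
  }
  for (int j = 0; j < J; ++j) beta_mean[j] = b_sum[j] / n_samples;

  return List::create(
    _["incl_prob"] = incl_prob,
    _["alpha"] = alpha_mean,
    _["fst"] = fst_mean,
    _["p_anc"] = p_mean,
    _["beta"] = beta_mean,
    _["n_samples"] = n_samples);
}
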