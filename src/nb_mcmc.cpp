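// Adaptive Metropolis-within-Gibbs sampler for the hierarchical
// negative-binomial regression with per-focal random intercepts and a
// log-exposure offset:
//
//   log(lambda_ij) = alpha_j + x_ij' beta + log(gamma_ij)
//   y_ij ~ NB(mean lambda_ij, dispersion r), p = r / (r + lambda)
//   beta_k ~ N(0, precision 0.1); alpha_j ~ N(mu_alpha, precision tau_alpha)
//   mu_alpha ~ N(0, precision 0.1); tau_alpha ~ U(0.001, 100); r ~ U(0, 100)
//
// Componentwise Gaussian random walks on beta, alpha, mu_alpha and on logit
// transforms of the bounded tau_alpha and r (with the Jacobian in the
// target). Proposal scales adapt toward 0.44 acceptance in batches during
// burn-in only, so detailed balance holds for the retained draws.

#include <Rcpp.h>
using namespace Rcpp;

static const double TAU_LO = 0.001, TAU_HI = 100.0;
static const double R_LO = 0.0, R_HI = 100.0;
static const double PRIOR_PREC = 0.1;  // beta and mu_alpha

static inline double sigmoid(double u) { return 1.0 / (1.0 + std::exp(-u)); }

// log(r + exp(loglam)) computed stably
static inline double log_r_plus_lam(double log_r, double loglam) {
  double a = std::max(log_r, loglam);
  return a + std::log(std::exp(log_r - a) + std::exp(loglam - a));
}

struct NbData {
  IntegerVector y;
  NumericVector log_gamma;
  NumericMatrix X;
  IntegerVector focal;            // 0-based focal index per dyad
  int n, p, J;
  std::vector<std::vector<int>> col_rows;   // rows with X(i,k) != 0
  std::vector<std::vector<int>> focal_rows; // rows of each focal
};

// per-dyad NB log pmf given cached lgamma terms (depend on r only)
static inline double dyad_ll(double c_i, double y_i, double r, double log_r,
                             double loglam) {
  double lrl = log_r_plus_lam(log_r, loglam);
  return c_i + r * (log_r - lrl) + y_i * (loglam - lrl);
}

class NbSampler {
public:
  NbData d;
  std::vector<double> beta, alpha;
  double mu_alpha, u_tau, u_r;
  std::vector<double> xb;      // X beta per dyad
  std::vector<double> ll;      // per-dyad log likelihood
  std::vector<double> cterm;   // lgamma(y+r) - lgamma(r) - lgamma(y+1)
  std::vector<double> lg_fact; // lgamma(y+1) per dyad
  std::vector<char> y_used;    // which counts occur in the data
  int max_y = 0;
  double tau, r, log_r;

  void set_tau_from_u() { tau = TAU_LO + (TAU_HI - TAU_LO) * sigmoid(u_tau); }
  void set_r_from_u() {
    r = R_LO + (R_HI - R_LO) * sigmoid(u_r);
    log_r = std::log(r);
  }

  void refresh_cterm() {
    for (int i = 0; i < d.n; ++i)
      cterm[i] = R::lgammafn(d.y[i] + r) - R::lgammafn(r) -
                 R::lgammafn(d.y[i] + 1.0);
  }

  double loglam(int i) const { return d.log_gamma[i] + alpha[d.focal[i]] + xb[i]; }

  void refresh_ll() {
    for (int i = 0; i < d.n; ++i)
      ll[i] = dyad_ll(cterm[i], d.y[i], r, log_r, loglam(i));
  }

  double alpha_prior() const {
    double s = 0.0;
    for (int j = 0; j < d.J; ++j) {
      double z = alpha[j] - mu_alpha;
      s += -0.5 * tau * z * z;
    }
    return s + 0.5 * d.J * std::log(tau);
  }

  static double logit_jacobian(double u) {
    double s = sigmoid(u);
    // d(theta)/d(u) = (hi-lo) s (1-s); the constant (hi-lo) cancels in MH
    return std::log(s) + std::log(1.0 - s);
  }
};

// [[Rcpp::export(name = ".nb_mcmc_chain")]]
List nb_mcmc_chain(IntegerVector y, NumericVector log_gamma, NumericMatrix X,
                   IntegerVector focal, int n_focals, int n_iter, int burn_in,
                   int thin, NumericVector init_beta, NumericVector init_alpha,
                   double init_mu, double init_tau, double init_r) {
  NbSampler s;
  s.d.y = y; s.d.log_gamma = log_gamma; s.d.X = X; s.d.focal = focal;
  s.d.n = y.size(); s.d.p = X.ncol(); s.d.J = n_focals;
  s.d.col_rows.resize(s.d.p);
  for (int k = 0; k < s.d.p; ++k)
    for (int i = 0; i < s.d.n; ++i)
      if (X(i, k) != 0.0) s.d.col_rows[k].push_back(i);
  s.d.focal_rows.resize(s.d.J);
  for (int i = 0; i < s.d.n; ++i) s.d.focal_rows[focal[i]].push_back(i);

  s.beta.assign(init_beta.begin(), init_beta.end());
  s.alpha.assign(init_alpha.begin(), init_alpha.end());
  s.mu_alpha = init_mu;
  double st = (init_tau - TAU_LO) / (TAU_HI - TAU_LO);
  s.u_tau = std::log(st / (1.0 - st));
  double sr = (init_r - R_LO) / (R_HI - R_LO);
  s.u_r = std::log(sr / (1.0 - sr));
  s.set_tau_from_u(); s.set_r_from_u();

  s.xb.assign(s.d.n, 0.0);
  for (int i = 0; i < s.d.n; ++i) {
    double v = 0.0;
    for (int k = 0; k < s.d.p; ++k) v += X(i, k) * s.beta[k];
    s.xb[i] = v;
  }
  s.cterm.assign(s.d.n, 0.0);
  s.ll.assign(s.d.n, 0.0);
  s.lg_fact.assign(s.d.n, 0.0);
  for (int i = 0; i < s.d.n; ++i) {
    s.lg_fact[i] = R::lgammafn(y[i] + 1.0);
    if (y[i] > s.max_y) s.max_y = y[i];
  }
  s.y_used.assign(s.max_y + 1, 0);
  for (int i = 0; i < s.d.n; ++i) s.y_used[y[i]] = 1;
  s.refresh_cterm();
  s.refresh_ll();

  int n_par = s.d.p + s.d.J + 3;          // beta, alpha, mu, tau, r
  std::vector<double> lsd(n_par, std::log(0.5));  // log proposal sd
  std::vector<int> acc(n_par, 0), att(n_par, 0);
  std::vector<long> acc_total(n_par, 0), att_total(n_par, 0);
  const int batch = 50;
  int n_keep = (n_iter - burn_in) / thin;
  NumericMatrix out(n_keep, n_par);
  int kept = 0;

  RNGScope scope;
  for (int it = 0; it < n_iter; ++it) {
    bool adapting = it < burn_in;

    // --- beta components ---
    for (int k = 0; k < s.d.p; ++k) {
      double prop = s.beta[k] + R::norm_rand() * std::exp(lsd[k]);
      double dlp = -0.5 * PRIOR_PREC * (prop * prop - s.beta[k] * s.beta[k]);
      double db = prop - s.beta[k];
      const std::vector<int>& rows = s.d.col_rows[k];
      std::vector<double> newll(rows.size());
      for (size_t q = 0; q < rows.size(); ++q) {
        int i = rows[q];
        double lam = s.loglam(i) + X(i, k) * db;
        newll[q] = dyad_ll(s.cterm[i], y[i], s.r, s.log_r, lam);
        dlp += newll[q] - s.ll[i];
      }
      att[k]++; att_total[k]++;
      if (std::log(R::unif_rand()) < dlp) {
        acc[k]++; acc_total[k]++;
        for (size_t q = 0; q < rows.size(); ++q) {
          int i = rows[q];
          s.xb[i] += X(i, k) * db;
          s.ll[i] = newll[q];
        }
        s.beta[k] = prop;
      }
    }

    // --- alpha components ---
    for (int j = 0; j < s.d.J; ++j) {
      int idx = s.d.p + j;
      double prop = s.alpha[j] + R::norm_rand() * std::exp(lsd[idx]);
      double z0 = s.alpha[j] - s.mu_alpha, z1 = prop - s.mu_alpha;
      double dlp = -0.5 * s.tau * (z1 * z1 - z0 * z0);
      double da = prop - s.alpha[j];
      const std::vector<int>& rows = s.d.focal_rows[j];
      std::vector<double> newll(rows.size());
      for (size_t q = 0; q < rows.size(); ++q) {
        int i = rows[q];
        newll[q] = dyad_ll(s.cterm[i], y[i], s.r, s.log_r, s.loglam(i) + da);
        dlp += newll[q] - s.ll[i];
      }
      att[idx]++; att_total[idx]++;
      if (std::log(R::unif_rand()) < dlp) {
        acc[idx]++; acc_total[idx]++;
        for (size_t q = 0; q < rows.size(); ++q) s.ll[rows[q]] = newll[q];
        s.alpha[j] = prop;
      }
    }

    // --- mu_alpha (conjugate structure ignored; RW keeps the scheme uniform)
    {
      int idx = s.d.p + s.d.J;
      double prop = s.mu_alpha + R::norm_rand() * std::exp(lsd[idx]);
      double dlp = -0.5 * PRIOR_PREC * (prop * prop - s.mu_alpha * s.mu_alpha);
      for (int j = 0; j < s.d.J; ++j) {
        double z0 = s.alpha[j] - s.mu_alpha, z1 = s.alpha[j] - prop;
        dlp += -0.5 * s.tau * (z1 * z1 - z0 * z0);
      }
      att[idx]++; att_total[idx]++;
      if (std::log(R::unif_rand()) < dlp) {
        acc[idx]++; acc_total[idx]++;
        s.mu_alpha = prop;
      }
    }

    // --- tau_alpha on logit scale ---
    {
      int idx = s.d.p + s.d.J + 1;
      double prop_u = s.u_tau + R::norm_rand() * std::exp(lsd[idx]);
      double prop_tau = TAU_LO + (TAU_HI - TAU_LO) * sigmoid(prop_u);
      double lp0 = s.alpha_prior() + NbSampler::logit_jacobian(s.u_tau);
      double tau_old = s.tau;
      s.tau = prop_tau;
      double lp1 = s.alpha_prior() + NbSampler::logit_jacobian(prop_u);
      att[idx]++; att_total[idx]++;
      if (std::log(R::unif_rand()) < lp1 - lp0) {
        acc[idx]++; acc_total[idx]++;
        s.u_tau = prop_u;
      } else {
        s.tau = tau_old;
      }
    }

    // --- r on logit scale (full likelihood, new lgamma cache) ---
    {
      int idx = s.d.p + s.d.J + 2;
      double prop_u = s.u_r + R::norm_rand() * std::exp(lsd[idx]);
      double prop_r = R_LO + (R_HI - R_LO) * sigmoid(prop_u);
      double dlp = NbSampler::logit_jacobian(prop_u) -
                   NbSampler::logit_jacobian(s.u_r);
      double prop_log_r = std::log(prop_r);
      // lgamma(y + r) evaluated once per distinct count, not per dyad
      double lg_r = R::lgammafn(prop_r);
      std::vector<double> lg_tab(s.max_y + 1);
      for (int u = 0; u <= s.max_y; ++u)
        if (s.y_used[u]) lg_tab[u] = R::lgammafn(u + prop_r) - lg_r;
      std::vector<double> newc(s.d.n), newll(s.d.n);
      for (int i = 0; i < s.d.n; ++i) {
        newc[i] = lg_tab[y[i]] - s.lg_fact[i];
        newll[i] = dyad_ll(newc[i], y[i], prop_r, prop_log_r, s.loglam(i));
        dlp += newll[i] - s.ll[i];
      }
      att[idx]++; att_total[idx]++;
      if (std::log(R::unif_rand()) < dlp) {
        acc[idx]++; acc_total[idx]++;
        s.u_r = prop_u;
        s.set_r_from_u();
        s.cterm.swap(newc);
        s.ll.swap(newll);
      }
    }

    // --- batch adaptation during burn-in ---
    if (adapting && (it + 1) % batch == 0) {
      double delta = std::min(0.05, 1.0 / std::sqrt((it + 1.0) / batch));
      for (int k = 0; k < n_par; ++k) {
        double rate = att[k] > 0 ? (double)acc[k] / att[k] : 0.0;
        lsd[k] += (rate > 0.44 ? delta : -delta);
        acc[k] = 0; att[k] = 0;
      }
    }

    if (it >= burn_in && (it - burn_in) % thin == 0 && kept < n_keep) {
      for (int k = 0; k < s.d.p; ++k) out(kept, k) = s.beta[k];
      for (int j = 0; j < s.d.J; ++j) out(kept, s.d.p + j) = s.alpha[j];
      out(kept, s.d.p + s.d.J) = s.mu_alpha;
      out(kept, s.d.p + s.d.J + 1) = s.tau;
      out(kept, s.d.p + s.d.J + 2) = s.r;
      kept++;
    }
  }

  NumericVector acc_rate(n_par);
  for (int k = 0; k < n_par; ++k)
    acc_rate[k] = att_total[k] > 0 ? (double)acc_total[k] / att_total[k] : NA_REAL;

  return List::create(_["samples"] = out, _["acceptance"] = acc_rate);
}
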