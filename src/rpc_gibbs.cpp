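#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Robust profile clustering Gibbs sampler.
//
// State layout (0-based internally; labels are 1-based on the R side):
//   z[i]   in 0..K0-1   global class of person i
//   c[i]   in 0..Ks-1   local class of person i (within subgroup s[i])
//   G[i,j] in {0,1}     1 = item j of person i follows the GLOBAL process
//   theta0 flat index (h*p + j)*d + r
//   theta1 flat index ((s*Ks + l)*p + j)*d + r
//
// All categorical conditionals are normalised in log space; Dirichlet draws
// via normalised gammas; every random number comes from R's RNG so that
// set.seed() on the R side makes the whole chain reproducible.

static inline int sample_cat_log(const std::vector<double> &logw) {
  const int K = (int)logw.size();
  double m = logw[0];
  for (int k = 1; k < K; ++k) if (logw[k] > m) m = logw[k];
  double tot = 0.0;
  std::vector<double> w(K);
  for (int k = 0; k < K; ++k) { w[k] = std::exp(logw[k] - m); tot += w[k]; }
  double u = unif_rand() * tot, acc = 0.0;
  for (int k = 0; k < K; ++k) { acc += w[k]; if (u <= acc) return k; }
  return K - 1;
}

static inline void rdirichlet_into(double *out, const double *shape, int K) {
  double tot = 0.0;
  for (int k = 0; k < K; ++k) { out[k] = R::rgamma(shape[k], 1.0); tot += out[k]; }
  if (tot <= 0.0) {            // all gamma draws underflowed (tiny shapes)
    for (int k = 0; k < K; ++k) out[k] = 1.0 / K;
    return;
  }
  for (int k = 0; k < K; ++k) out[k] /= tot;
}

static inline double logsumexp(const std::vector<double> &x) {
  double m = x[0];
  for (size_t k = 1; k < x.size(); ++k) if (x[k] > m) m = x[k];
  double tot = 0.0;
  for (size_t k = 0; k < x.size(); ++k) tot += std::exp(x[k] - m);
  return m + std::log(tot);
}

// [[Rcpp::export]]
List rpc_gibbs_cpp(const IntegerMatrix y,        // n x p, levels 1..d
                   const IntegerVector s,        // n, subgroups 1..S
                   int K0, int Ks, int d, int S,
                   NumericVector pi0,            // K0
                   NumericVector lam0,           // S*Ks flat (s*Ks + l)
                   NumericVector theta0_0,       // K0*p*d flat
                   NumericVector theta1_0,       // S*Ks*p*d flat
                   NumericVector nu0,            // S*p flat (s*p + j)
                   IntegerVector z0, IntegerVector c0,   // 1-based labels
                   const IntegerMatrix G0,
                   double alpha_pi, double alpha_lam, double alpha_theta,
                   double a_nu, double b_nu,
                   bool update_nu, bool nu_by_item,
                   int n_iter, int burn_in, int thin,
                   bool store_G) {
  const int n = y.nrow(), p = y.ncol();
  const int M = (n_iter - burn_in) / thin;

  std::vector<int> z(n), cl(n), sg(n);
  for (int i = 0; i < n; ++i) { z[i] = z0[i] - 1; cl[i] = c0[i] - 1; sg[i] = s[i] - 1; }
  std::vector<int> G(n * p);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < p; ++j) G[i * p + j] = G0(i, j);

  std::vector<double> pi_(pi0.begin(), pi0.end());
  std::vector<double> lam(lam0.begin(), lam0.end());
  std::vector<double> th0(theta0_0.begin(), theta0_0.end());
  std::vector<double> th1(theta1_0.begin(), theta1_0.end());
  std::vector<double> nu(nu0.begin(), nu0.end());

  std::vector<int> nsub(S, 0);
  for (int i = 0; i < n; ++i) nsub[sg[i]]++;

  // storage
  NumericMatrix pi_draws(M, K0), lam_draws(M, S * Ks);
  NumericMatrix th0_draws(M, K0 * p * d), th1_draws(M, S * Ks * p * d);
  NumericMatrix nu_draws(M, S * p);
  IntegerMatrix z_draws(M, n), c_draws(M, n);
  IntegerMatrix G_draws(store_G ? M : 1, store_G ? n * p : 1);
  NumericVector ll_draws(M);

  std::vector<double> lpi(K0), llam(S * Ks), lth0(th0.size()), lth1(th1.size());
  std::vector<double> logw0(K0), logw1(Ks);
  std::vector<double> cnt0(K0 * p * d), cnt1((size_t)S * Ks * p * d);

  int m = 0;
  for (int iter = 1; iter <= n_iter; ++iter) {
    // cache logs of current weights / profiles
    for (int k = 0; k < K0; ++k) lpi[k] = std::log(pi_[k]);
    for (size_t k = 0; k < lam.size(); ++k) llam[k] = std::log(lam[k]);
    for (size_t k = 0; k < th0.size(); ++k) lth0[k] = std::log(th0[k]);
    for (size_t k = 0; k < th1.size(); ++k) lth1[k] = std::log(th1[k]);

    // (1) z_i | ... ~ Cat( pi_h * prod_{j: G=1} theta0[h,j,y_ij] )
    for (int i = 0; i < n; ++i) {
      for (int h = 0; h < K0; ++h) logw0[h] = lpi[h];
      const int *Gi = &G[i * p];
      for (int j = 0; j < p; ++j) {
        if (!Gi[j]) continue;
        const int r = y(i, j) - 1;
        for (int h = 0; h < K0; ++h) logw0[h] += lth0[(h * p + j) * d + r];
      }
      z[i] = sample_cat_log(logw0);
    }

    // (2) c_i | ... ~ Cat( lam[s_i,l] * prod_{j: G=0} theta1[s_i,l,j,y_ij] )
    for (int i = 0; i < n; ++i) {
      const int si = sg[i];
      for (int l = 0; l < Ks; ++l) logw1[l] = llam[si * Ks + l];
      const int *Gi = &G[i * p];
      for (int j = 0; j < p; ++j) {
        if (Gi[j]) continue;
        const int r = y(i, j) - 1;
        for (int l = 0; l < Ks; ++l) logw1[l] += lth1[((si * Ks + l) * p + j) * d + r];
      }
      cl[i] = sample_cat_log(logw1);
    }

    // (3) G_ij ~ Bernoulli( nu*theta0 / (nu*theta0 + (1-nu)*theta1) )
    for (int i = 0; i < n; ++i) {
      const int si = sg[i];
      for (int j = 0; j < p; ++j) {
        const int r = y(i, j) - 1;
        const double nuj = nu[si * p + j];
        const double pg = nuj * th0[(z[i] * p + j) * d + r];
        const double pl = (1.0 - nuj) * th1[((si * Ks + cl[i]) * p + j) * d + r];
        const double den = pg + pl;
        const double prob = (den > 0.0) ? pg / den : 0.5;
        G[i * p + j] = (unif_rand() < prob) ? 1 : 0;
      }
    }

    // (4) pi ~ Dirichlet(alpha_pi + global class counts)
    {
      std::vector<double> shape(K0, alpha_pi);
      for (int i = 0; i < n; ++i) shape[z[i]] += 1.0;
      rdirichlet_into(pi_.data(), shape.data(), K0);
    }

    // (5) lam[s,] ~ Dirichlet(alpha_lam + local class counts within s)
    {
      std::vector<double> shape((size_t)S * Ks, alpha_lam);
      for (int i = 0; i < n; ++i) shape[sg[i] * Ks + cl[i]] += 1.0;
      for (int si = 0; si < S; ++si)
        rdirichlet_into(&lam[si * Ks], &shape[si * Ks], Ks);
    }

    // (6)-(7) theta rows ~ Dirichlet(alpha_theta + level counts)
    std::fill(cnt0.begin(), cnt0.end(), 0.0);
    std::fill(cnt1.begin(), cnt1.end(), 0.0);
    for (int i = 0; i < n; ++i) {
      const int si = sg[i];
      for (int j = 0; j < p; ++j) {
        const int r = y(i, j) - 1;
        if (G[i * p + j]) cnt0[(z[i] * p + j) * d + r] += 1.0;
        else              cnt1[((size_t)(si * Ks + cl[i]) * p + j) * d + r] += 1.0;
      }
    }
    {
      std::vector<double> shape(d);
      for (int h = 0; h < K0; ++h)
        for (int j = 0; j < p; ++j) {
          const size_t off = (size_t)(h * p + j) * d;
          for (int r = 0; r < d; ++r) shape[r] = alpha_theta + cnt0[off + r];
          rdirichlet_into(&th0[off], shape.data(), d);
        }
      for (int si = 0; si < S; ++si)
        for (int l = 0; l < Ks; ++l)
          for (int j = 0; j < p; ++j) {
            const size_t off = ((size_t)(si * Ks + l) * p + j) * d;
            for (int r = 0; r < d; ++r) shape[r] = alpha_theta + cnt1[off + r];
            rdirichlet_into(&th1[off], shape.data(), d);
          }
    }

    // (8) nu ~ Beta(a + #global, b + #local); either one probability per
    // (subgroup, item) or a single shared probability per item
    if (update_nu) {
      std::vector<int> gcount(S * p, 0);
      for (int i = 0; i < n; ++i) {
        const int si = sg[i];
        for (int j = 0; j < p; ++j) gcount[si * p + j] += G[i * p + j];
      }
      if (nu_by_item) {
        for (int j = 0; j < p; ++j) {
          int g1 = 0;
          for (int si = 0; si < S; ++si) g1 += gcount[si * p + j];
          const double nuj = R::rbeta(a_nu + g1, b_nu + (n - g1));
          for (int si = 0; si < S; ++si) nu[si * p + j] = nuj;
        }
      } else {
        for (int si = 0; si < S; ++si)
          for (int j = 0; j < p; ++j) {
            const int g1 = gcount[si * p + j], g0 = nsub[si] - g1;
            nu[si * p + j] = R::rbeta(a_nu + g1, b_nu + g0);
          }
      }
    }

    // retain
    if (iter > burn_in && (iter - burn_in) % thin == 0 && m < M) {
      for (int k = 0; k < K0; ++k) lpi[k] = std::log(pi_[k]);
      for (size_t k = 0; k < lam.size(); ++k) llam[k] = std::log(lam[k]);
      for (size_t k = 0; k < th0.size(); ++k) lth0[k] = std::log(th0[k]);
      for (size_t k = 0; k < th1.size(); ++k) lth1[k] = std::log(th1[k]);
      // subject-specific log-likelihood given current G:
      // log[ sum_h pi_h prod_{j:G=1} theta0 ] + log[ sum_l lam_l prod_{j:G=0} theta1 ]
      double ll = 0.0;
      for (int i = 0; i < n; ++i) {
        const int si = sg[i];
        for (int h = 0; h < K0; ++h) logw0[h] = lpi[h];
        for (int l = 0; l < Ks; ++l) logw1[l] = llam[si * Ks + l];
        const int *Gi = &G[i * p];
        for (int j = 0; j < p; ++j) {
          const int r = y(i, j) - 1;
          if (Gi[j]) for (int h = 0; h < K0; ++h) logw0[h] += lth0[(h * p + j) * d + r];
          else       for (int l = 0; l < Ks; ++l) logw1[l] += lth1[((si * Ks + l) * p + j) * d + r];
        }
        ll += logsumexp(logw0) + logsumexp(logw1);
      }
      ll_draws[m] = ll;
      for (int k = 0; k < K0; ++k) pi_draws(m, k) = pi_[k];
      for (int k = 0; k < S * Ks; ++k) lam_draws(m, k) = lam[k];
      for (size_t k = 0; k < th0.size(); ++k) th0_draws(m, k) = th0[k];
      for (size_t k = 0; k < th1.size(); ++k) th1_draws(m, k) = th1[k];
      for (int k = 0; k < S * p; ++k) nu_draws(m, k) = nu[k];
      for (int i = 0; i < n; ++i) { z_draws(m, i) = z[i] + 1; c_draws(m, i) = cl[i] + 1; }
      if (store_G) for (int k = 0; k < n * p; ++k) G_draws(m, k) = G[k];
      ++m;
    }
  }

  IntegerMatrix Gfin(n, p);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < p; ++j) Gfin(i, j) = G[i * p + j];
  IntegerVector zfin(n), cfin(n);
  for (int i = 0; i < n; ++i) { zfin[i] = z[i] + 1; cfin[i] = cl[i] + 1; }

  return List::create(
    _["pi"] = pi_draws, _["lam"] = lam_draws,
    _["theta0"] = th0_draws, _["theta1"] = th1_draws,
    _["nu"] = nu_draws, _["z"] = z_draws, _["c"] = c_draws,
    _["G"] = G_draws, _["loglik"] = ll_draws,
    _["final"] = List::create(
      _["pi"] = NumericVector(pi_.begin(), pi_.end()),
      _["lam"] = NumericVector(lam.begin(), lam.end()),
      _["theta0"] = NumericVector(th0.begin(), th0.end()),
      _["theta1"] = NumericVector(th1.begin(), th1.end()),
      _["nu"] = NumericVector(nu.begin(), nu.end()),
      _["z"] = zfin, _["c"] = cfin, _["G"] = Gfin));
}
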