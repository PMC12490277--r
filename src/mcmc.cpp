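#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Metropolis-within-Gibbs sampler for the dynamic spatial one-factor model.
//
// Layers (see the R-level log_posterior for the reference definition):
//   Y_ijk ~ Poisson(E_ijk * exp(loglambda_ijk)), optionally interval-censored
//   loglambda_ijk ~ N(gamma_ik * f_ij, sigma2_k)
//   f_.j ~ ICAR (pairwise-difference form), AR(1) in time through
//          mu_tilde_ij = mu_j + eta (f_i,j-1 - mu_j-1); within-year constant
//          shifts cancel, so the f full conditionals are mu-free and mu_j is
//          recovered by the sum-to-zero centering recursion
//   gamma_.k ~ mean-one ICAR (varying) or gamma_k ~ N(1, tau_g2) (constant)
//   variances ~ inverse-gamma (equivalently Gamma on the precision)
//   eta ~ Uniform(eta_lo, eta_hi)
//
// Update sweep: (a) adaptive RW-MH per loglambda cell (exact Gaussian draw
// for missing cells), (b) site-wise conjugate Gaussian updates of f,
// (c) conjugate Gaussian updates of gamma, (d) conjugate variance updates
// with rank-corrected ICAR exponents, (e) mu by centering, (f) adaptive
// RW-MH for eta.  Adaptation targets 0.44 acceptance and freezes at the end
// of burn-in.

static double pois_interval_lp(double a, double b, double m) {
  if (!R_finite(b)) {
    if (a <= 0.0) return 0.0;
    return R::ppois(a - 1.0, m, 0, 1);
  }
  int ia = (int)a, ib = (int)b;
  double lm = std::log(m);
  double mx = R_NegInf;
  std::vector<double> terms(ib - ia + 1);
  for (int y = ia; y <= ib; ++y) {
    double t = -m + y * lm - R::lgammafn(y + 1.0);
    terms[y - ia] = t;
    if (t > mx) mx = t;
  }
  double s = 0.0;
  for (double t : terms) s += std::exp(t - mx);
  return mx + std::log(s);
}

// [[Rcpp::export]]
List run_chain_cpp(IntegerVector dims,
                   NumericVector counts, IntegerVector status,
                   NumericVector cens_low, NumericVector cens_high,
                   NumericVector offsets, int ref,
                   IntegerVector edge_a, IntegerVector edge_b,
                   IntegerVector adj, IntegerVector adj_start,
                   IntegerVector degrees, int n_components,
                   double prior_a, double prior_s,
                   double eta_lo, double eta_hi,
                   List init,
                   int n_iter, int n_burnin, int thin,
                   bool constant_mode, bool use_likelihood) {
  const int n = dims[0], J = dims[1], K = dims[2];
  const int nJ = n * J, nJK = n * J * K;
  const int n_edges = edge_a.size();
  const int ref0 = ref - 1;
  auto cell = [&](int i, int j, int k) { return i + n * j + nJ * k; };

  // state
  std::vector<double> ll(nJK), f(nJ), gam(constant_mode ? K : n * K);
  std::vector<double> sigma2(K), mu(J);
  double tau_f2, tau_g2, eta;
  {
    NumericVector ll0 = init["loglambda"], f0 = init["f"], g0 = init["gamma"],
      s0 = init["sigma2"];
    for (int c = 0; c < nJK; ++c) ll[c] = ll0[c];
    for (int c = 0; c < nJ; ++c) f[c] = f0[c];
    for (size_t c = 0; c < gam.size(); ++c) gam[c] = g0[c];
    for (int k = 0; k < K; ++k) sigma2[k] = s0[k];
    tau_f2 = as<double>(init["tau_f2"]);
    tau_g2 = as<double>(init["tau_g2"]);
    eta = as<double>(init["eta"]);
  }
  auto gamma_ik = [&](int i, int k) {
    return constant_mode ? gam[k] : gam[i + n * k];
  };

  // adaptation state
  std::vector<double> log_scale(nJK, 0.0);
  std::vector<int> acc_batch(nJK, 0);
  double eta_log_scale = std::log(0.1);
  int eta_acc_batch = 0;
  const int batch_len = 50;
  long long ll_acc_total = 0, ll_prop_total = 0, eta_acc_total = 0,
    eta_prop_total = 0;

  const int n_keep = (n_iter - n_burnin) / thin;
  NumericMatrix keep_f(n_keep, nJ), keep_gamma(n_keep, (int)gam.size()),
    keep_ll(n_keep, nJK), keep_sigma2(n_keep, K), keep_mu(n_keep, J);
  NumericVector keep_tauf(n_keep), keep_taug(n_keep), keep_eta(n_keep);
  int kept = 0;

  for (int it = 0; it < n_iter; ++it) {
    const bool adapting = it < n_burnin;

    // (a) loglambda cells
    for (int k = 0; k < K; ++k) {
      const double sd_k = std::sqrt(sigma2[k]);
      for (int j = 0; j < J; ++j) {
        for (int i = 0; i < n; ++i) {
          const int c = cell(i, j, k);
          const double gf = gamma_ik(i, k) * f[i + n * j];
          if (status[c] == 0 || !use_likelihood) {
            ll[c] = gf + sd_k * norm_rand();
            continue;
          }
          const double cur = ll[c];
          const double prop = cur + std::exp(log_scale[c]) * norm_rand();
          double lr = (R::dnorm(prop, gf, sd_k, 1) - R::dnorm(cur, gf, sd_k, 1));
          const double E = offsets[c];
          if (status[c] == 1) {
            lr += -E * (std::exp(prop) - std::exp(cur)) + counts[c] * (prop - cur);
          } else {
            lr += pois_interval_lp(cens_low[c], cens_high[c], E * std::exp(prop)) -
              pois_interval_lp(cens_low[c], cens_high[c], E * std::exp(cur));
          }
          ++ll_prop_total;
          if (std::log(unif_rand()) < lr) {
            ll[c] = prop;
            ++acc_batch[c];
            ++ll_acc_total;
          }
          if (adapting && ((it + 1) % batch_len == 0)) {
            const double delta = std::min(0.05, 1.0 / std::sqrt((it + 1.0) / batch_len));
            if (acc_batch[c] > 0.44 * batch_len) log_scale[c] += delta;
            else log_scale[c] -= delta;
            acc_batch[c] = 0;
          }
        }
      }
    }

    // (b) f sites: mu-free pairwise-difference conditionals
    for (int j = 0; j < J; ++j) {
      for (int i = 0; i < n; ++i) {
        const double wi = degrees[i];
        double P = wi / tau_f2, b = 0.0;
        // year-j pairwise terms
        for (int p = adj_start[i]; p < adj_start[i + 1]; ++p) {
          const int l = adj[p] - 1;
          double A = f[l + n * j];
          if (j > 0) A += eta * (f[i + n * (j - 1)] - f[l + n * (j - 1)]);
          b += A / tau_f2;
        }
        // year-(j+1) terms: f_ij enters through -eta
        if (j + 1 < J) {
          P += eta * eta * wi / tau_f2;
          for (int p = adj_start[i]; p < adj_start[i + 1]; ++p) {
            const int l = adj[p] - 1;
            const double C = f[i + n * (j + 1)] - f[l + n * (j + 1)] +
              eta * f[l + n * j];
            b += eta * C / tau_f2;
          }
        }
        // error layer
        for (int k = 0; k < K; ++k) {
          const double g = gamma_ik(i, k);
          P += g * g / sigma2[k];
          b += g * ll[cell(i, j, k)] / sigma2[k];
        }
        f[i + n * j] = b / P + norm_rand() / std::sqrt(P);
      }
    }

    // (c) gamma
    if (constant_mode) {
      for (int k = 0; k < K; ++k) {
        if (k == ref0) { gam[k] = 1.0; continue; }
        double P = 1.0 / tau_g2, b = 1.0 / tau_g2;
        for (int j = 0; j < J; ++j) {
          for (int i = 0; i < n; ++i) {
            const double fij = f[i + n * j];
            P += fij * fij / sigma2[k];
            b += fij * ll[cell(i, j, k)] / sigma2[k];
          }
        }
        gam[k] = b / P + norm_rand() / std::sqrt(P);
      }
    } else {
      for (int k = 0; k < K; ++k) {
        if (k == ref0) continue;
        for (int i = 0; i < n; ++i) {
          double P = degrees[i] / tau_g2, b = 0.0;
          for (int p = adj_start[i]; p < adj_start[i + 1]; ++p) {
            b += gam[(adj[p] - 1) + n * k] / tau_g2;
          }
          for (int j = 0; j < J; ++j) {
            const double fij = f[i + n * j];
            P += fij * fij / sigma2[k];
            b += fij * ll[cell(i, j, k)] / sigma2[k];
          }
          gam[i + n * k] = b / P + norm_rand() / std::sqrt(P);
        }
      }
    }

    // (d) variances (Gamma posterior on the precision; prior Gamma(a, rate s))
    for (int k = 0; k < K; ++k) {
      double ss = 0.0;
      for (int j = 0; j < J; ++j) {
        for (int i = 0; i < n; ++i) {
          const double r = ll[cell(i, j, k)] - gamma_ik(i, k) * f[i + n * j];
          ss += r * r;
        }
      }
      sigma2[k] = 1.0 / R::rgamma(prior_a + 0.5 * nJ, 1.0 / (prior_s + 0.5 * ss));
    }
    {
      double ss = 0.0;
      for (int j = 0; j < J; ++j) {
        for (int e = 0; e < n_edges; ++e) {
          const int ia = edge_a[e] - 1, ib = edge_b[e] - 1;
          double d = f[ia + n * j] - f[ib + n * j];
          if (j > 0) d -= eta * (f[ia + n * (j - 1)] - f[ib + n * (j - 1)]);
          ss += d * d;
        }
      }
      const double rank = (double)J * (n - n_components);
      tau_f2 = 1.0 / R::rgamma(prior_a + 0.5 * rank, 1.0 / (prior_s + 0.5 * ss));
    }
    {
      double ss = 0.0, rank;
      if (constant_mode) {
        for (int k = 0; k < K; ++k) {
          if (k == ref0) continue;
          ss += (gam[k] - 1.0) * (gam[k] - 1.0);
        }
        rank = K - 1.0;
      } else {
        for (int k = 0; k < K; ++k) {
          if (k == ref0) continue;
          for (int e = 0; e < n_edges; ++e) {
            const double d = gam[(edge_a[e] - 1) + n * k] - gam[(edge_b[e] - 1) + n * k];
            ss += d * d;
          }
        }
        rank = (double)(K - 1) * (n - n_components);
      }
      tau_g2 = 1.0 / R::rgamma(prior_a + 0.5 * rank, 1.0 / (prior_s + 0.5 * ss));
    }

    // (e) mu_j by the sum-to-zero centering recursion
    {
      std::vector<double> a(J, 0.0);
      for (int j = 0; j < J; ++j) {
        for (int i = 0; i < n; ++i) a[j] += f[i + n * j];
        a[j] /= n;
      }
      mu[0] = a[0];
      for (int j = 1; j < J; ++j) mu[j] = a[j] - eta * (a[j - 1] - mu[j - 1]);
    }

    // (f) eta by RW-MH on (eta_lo, eta_hi)
    {
      auto eta_logtarget = [&](double e) {
        double ss = 0.0;
        for (int j = 1; j < J; ++j) {
          for (int ed = 0; ed < n_edges; ++ed) {
            const int ia = edge_a[ed] - 1, ib = edge_b[ed] - 1;
            const double d = (f[ia + n * j] - f[ib + n * j]) -
              e * (f[ia + n * (j - 1)] - f[ib + n * (j - 1)]);
            ss += d * d;
          }
        }
        return -0.5 * ss / tau_f2;
      };
      const double prop = eta + std::exp(eta_log_scale) * norm_rand();
      ++eta_prop_total;
      if (prop > eta_lo && prop < eta_hi) {
        const double lr = eta_logtarget(prop) - eta_logtarget(eta);
        if (std::log(unif_rand()) < lr) {
          eta = prop;
          ++eta_acc_batch;
          ++eta_acc_total;
        }
      }
      if (adapting && ((it + 1) % batch_len == 0)) {
        const double delta = std::min(0.05, 1.0 / std::sqrt((it + 1.0) / batch_len));
        if (eta_acc_batch > 0.44 * batch_len) eta_log_scale += delta;
        else eta_log_scale -= delta;
        eta_acc_batch = 0;
      }
    }

    // store
    if (it >= n_burnin && ((it - n_burnin + 1) % thin == 0) && kept < n_keep) {
      for (int c = 0; c < nJ; ++c) keep_f(kept, c) = f[c];
      for (size_t c = 0; c < gam.size(); ++c) keep_gamma(kept, (int)c) = gam[c];
      for (int c = 0; c < nJK; ++c) keep_ll(kept, c) = ll[c];
      for (int k = 0; k < K; ++k) keep_sigma2(kept, k) = sigma2[k];
      for (int j = 0; j < J; ++j) keep_mu(kept, j) = mu[j];
      keep_tauf[kept] = tau_f2;
      keep_taug[kept] = tau_g2;
      keep_eta[kept] = eta;
      ++kept;
    }
    if (it % 1024 == 0) Rcpp::checkUserInterrupt();
  }

  return List::create(
    _["f"] = keep_f, _["gamma"] = keep_gamma, _["loglambda"] = keep_ll,
    _["sigma2"] = keep_sigma2, _["mu"] = keep_mu, _["tau_f2"] = keep_tauf,
    _["tau_g2"] = keep_taug, _["eta"] = keep_eta,
    _["accept_loglambda"] = ll_prop_total > 0 ?
      (double)ll_acc_total / ll_prop_total : NA_REAL,
    _["accept_eta"] = eta_prop_total > 0 ?
      (double)eta_acc_total / eta_prop_total : NA_REAL);
}
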