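#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Gibbs sampler for the within-patient indirect-comparison model
//
//   y[r] = mu[i(r)] + delta[r] + eps,  eps ~ N(0, tau^2)
//
// FE: delta[r] = d[dev(r)] - d[base(i(r))]  (deterministic contrast)
// RE: each non-baseline contrast is an independent draw
//     delta[r] ~ N(d[dev(r)] - d[base(i(r))], sigma^2);
//     baseline arms have delta == 0.  Independence across a respondent's
//     contrasts keeps (tau, sigma) identified at single-replicate
//     resolution: the implied contrast covariance is tau^2 between
//     contrasts (shared baseline arm) and 2 tau^2 + sigma^2 on the
//     diagonal.
//
// Priors: d_k ~ N(d_mean, d_sd^2) with d[ref] == 0, mu_i ~ N(mu_mean,
// mu_sd^2), tau ~ U(0, tau_upper), sigma ~ U(0, sigma_upper).  The
// uniform-on-sd priors give truncated inverse-gamma conditionals for the
// variances, so every update is an exact conjugate draw (no tuning).

static double rinvgamma_trunc(double shape, double rate, double upper_sd,
                              double current) {
  // draw v ~ InvGamma(shape, rate) subject to sqrt(v) < upper_sd;
  // rejection is cheap because the bound is far in the tail for real data
  const double floor_v = 1e-8;  // keeps degenerate (zero-residual) data finite
  if (rate <= floor_v) return floor_v;
  for (int attempt = 0; attempt < 100; ++attempt) {
    double g = R::rgamma(shape, 1.0 / rate);  // R::rgamma takes scale
    if (g <= 0) continue;
    double v = 1.0 / g;
    if (v < floor_v) v = floor_v;
    if (std::sqrt(v) < upper_sd) return v;
  }
  return current * current;  // keep current value if the bound binds hard
}

// [[Rcpp::export]]
List gibbs_ic_cpp(NumericVector y, IntegerVector resp, IntegerVector dev,
                  IntegerVector base_dev, int n_resp, int n_dev, int ref,
                  bool random_effects, List priors, List init,
                  int n_iter, int n_burn, int thin) {
  const int n = y.size();
  const double d_mean = priors["d_mean"], d_sd = priors["d_sd"];
  const double mu_mean = priors["mu_mean"], mu_sd = priors["mu_sd"];
  const double tau_upper = priors["tau_upper"];
  const double sigma_upper = priors["sigma_upper"];
  const double d_prec0 = 1.0 / (d_sd * d_sd);
  const double mu_prec0 = 1.0 / (mu_sd * mu_sd);

  std::vector<double> mu = as<std::vector<double> >(init["mu"]);
  std::vector<double> d = as<std::vector<double> >(init["d"]);
  double tau = init["tau"], sigma = init["sigma"];
  d[ref] = 0.0;

  // per-respondent record lists; non-baseline records carry the contrasts
  std::vector<std::vector<int> > rec_of(n_resp);
  for (int r = 0; r < n; ++r) rec_of[resp[r]].push_back(r);
  std::vector<int> contrast_recs;  // all non-baseline records
  for (int r = 0; r < n; ++r)
    if (dev[r] != base_dev[resp[r]]) contrast_recs.push_back(r);
  const int M = (int) contrast_recs.size();

  std::vector<double> delta(n, 0.0);  // per-record contrast (RE latent)

  const int n_keep = (n_iter - n_burn + thin - 1) / thin;
  NumericMatrix d_draws(n_keep, n_dev);
  NumericMatrix mu_draws(n_keep, n_resp);
  NumericVector tau_draws(n_keep), sigma_draws(n_keep), dev_draws(n_keep);
  std::vector<double> delta_bar(n, 0.0);
  int kept = 0;

  std::vector<double> off(n, 0.0);

  for (int it = 0; it < n_iter; ++it) {
    double tau2 = tau * tau;
    double sigma2 = sigma * sigma;

    // ---- RE: update latent contrasts delta | mu, d, tau, sigma ----
    if (random_effects) {
      double prec = 1.0 / sigma2 + 1.0 / tau2;
      double sdp = 1.0 / std::sqrt(prec);
      for (int c = 0; c < M; ++c) {
        int r = contrast_recs[c];
        double prior_mean = d[dev[r]] - d[base_dev[resp[r]]];
        double mean = (prior_mean / sigma2 + (y[r] - mu[resp[r]]) / tau2)
          / prec;
        delta[r] = mean + R::norm_rand() * sdp;
      }
      for (int r = 0; r < n; ++r) off[r] = delta[r];
    } else {
      for (int r = 0; r < n; ++r)
        off[r] = d[dev[r]] - d[base_dev[resp[r]]];
    }

    // ---- mu_i | rest (normal conjugate) ----
    for (int i = 0; i < n_resp; ++i) {
      const std::vector<int>& rr = rec_of[i];
      double s = 0.0;
      for (size_t j = 0; j < rr.size(); ++j) s += y[rr[j]] - off[rr[j]];
      double prec = rr.size() / tau2 + mu_prec0;
      double mean = (s / tau2 + mu_mean * mu_prec0) / prec;
      mu[i] = mean + R::norm_rand() / std::sqrt(prec);
    }

    // ---- d_k | rest ----
    if (!random_effects) {
      for (int k = 0; k < n_dev; ++k) {
        if (k == ref) continue;
        double S1 = 0.0, S2 = 0.0;
        for (int r = 0; r < n; ++r) {
          int c = (dev[r] == k) - (base_dev[resp[r]] == k);
          if (c == 0) continue;
          double partial = y[r] - mu[resp[r]]
            - (d[dev[r]] - d[base_dev[resp[r]]]) + c * d[k];
          S1 += 1.0;  // c^2 == 1
          S2 += c * partial;
        }
        double prec = S1 / tau2 + d_prec0;
        double mean = (S2 / tau2 + d_mean * d_prec0) / prec;
        d[k] = mean + R::norm_rand() / std::sqrt(prec);
        for (int r = 0; r < n; ++r)
          off[r] = d[dev[r]] - d[base_dev[resp[r]]];
      }
    } else {
      // d enters only through the prior means of the latent contrasts:
      // each contrast is one pseudo-observation of d[dev] - d[base]
      for (int k = 0; k < n_dev; ++k) {
        if (k == ref) continue;
        double P = d_prec0, num = d_mean * d_prec0;
        for (int c = 0; c < M; ++c) {
          int r = contrast_recs[c];
          int kk = dev[r], bb = base_dev[resp[r]];
          if (kk == k) {            // delta ~ N(d_k - d_bb, sigma^2)
            P += 1.0 / sigma2;
            num += (delta[r] + d[bb]) / sigma2;
          } else if (bb == k) {     // delta ~ N(d_kk - d_k, sigma^2)
            P += 1.0 / sigma2;
            num += (d[kk] - delta[r]) / sigma2;
          }
        }
        d[k] = num / P + R::norm_rand() / std::sqrt(P);
      }

      // ---- sigma^2 | delta, d (truncated inverse gamma) ----
      if (M >= 2) {
        double Q = 0.0;
        for (int c = 0; c < M; ++c) {
          int r = contrast_recs[c];
          double v = delta[r] - (d[dev[r]] - d[base_dev[resp[r]]]);
          Q += v * v;
        }
        double s2 = rinvgamma_trunc((M - 1.0) / 2.0, Q / 2.0, sigma_upper,
                                    sigma);
        sigma = std::sqrt(s2);
      }
    }

    // ---- tau^2 | rest ----
    double SS = 0.0;
    for (int r = 0; r < n; ++r) {
      double e = y[r] - mu[resp[r]] - off[r];
      SS += e * e;
    }
    double t2 = rinvgamma_trunc((n - 1.0) / 2.0, SS / 2.0, tau_upper, tau);
    tau = std::sqrt(t2);

    // ---- RE: collapsed Metropolis refresh of (tau, sigma) ----
    // The variance pair mixes slowly through the latent contrasts, so a
    // random-walk move on (log tau, log sigma) targets their conditional
    // with delta integrated out (valid because delta is redrawn from its
    // full conditional at the top of the next iteration).
    if (random_effects) {
      double t2c = tau * tau, s2c = sigma * sigma;
      double loglik_c = 0.0;
      std::vector<double> rr(n);
      for (int r = 0; r < n; ++r) {
        bool is_base = (dev[r] == base_dev[resp[r]]);
        rr[r] = y[r] - mu[resp[r]]
          - (is_base ? 0.0 : (d[dev[r]] - d[base_dev[resp[r]]]));
        double v = is_base ? t2c : (t2c + s2c);
        loglik_c += -0.5 * (std::log(v) + rr[r] * rr[r] / v);
      }
      for (int step = 0; step < 2; ++step) {
        double lt = std::log(tau) + 0.25 * R::norm_rand();
        double ls = std::log(sigma) + 0.25 * R::norm_rand();
        double tp = std::exp(lt), sp = std::exp(ls);
        if (tp >= tau_upper || sp >= sigma_upper) continue;
        double t2p = tp * tp, s2p = sp * sp;
        double loglik_p = 0.0;
        for (int r = 0; r < n; ++r) {
          bool is_base = (dev[r] == base_dev[resp[r]]);
          double v = is_base ? t2p : (t2p + s2p);
          loglik_p += -0.5 * (std::log(v) + rr[r] * rr[r] / v);
        }
        // log-scale proposal: Jacobian tau*sigma enters the ratio
        double log_acc = loglik_p - loglik_c
          + std::log(tp) + std::log(sp) - std::log(tau) - std::log(sigma);
        if (std::log(R::unif_rand()) < log_acc) {
          tau = tp; sigma = sp; loglik_c = loglik_p;
        }
      }
      t2 = tau * tau;
    }

    // deviance of the current state.  For model comparison the RE
    // deviance is marginal over the latent contrasts (closed form under
    // independence): baseline arms have variance tau^2, contrast arms
    // tau^2 + sigma^2.  Conditional deviances are not comparable across
    // FE and RE because the contrasts chase the noise.
    double dev_now;
    if (!random_effects) {
      dev_now = n * std::log(2.0 * M_PI * t2) + SS / t2;
    } else {
      double s2m = sigma * sigma;
      dev_now = 0.0;
      for (int r = 0; r < n; ++r) {
        bool is_base = (dev[r] == base_dev[resp[r]]);
        double v = is_base ? t2 : (t2 + s2m);
        double e = y[r] - mu[resp[r]]
          - (is_base ? 0.0 : (d[dev[r]] - d[base_dev[resp[r]]]));
        dev_now += std::log(2.0 * M_PI * v) + e * e / v;
      }
    }

    if (it >= n_burn && (it - n_burn) % thin == 0) {
      for (int k = 0; k < n_dev; ++k) d_draws(kept, k) = d[k];
      for (int i = 0; i < n_resp; ++i) mu_draws(kept, i) = mu[i];
      tau_draws[kept] = tau;
      sigma_draws[kept] = sigma;
      dev_draws[kept] = dev_now;
      for (int r = 0; r < n; ++r) delta_bar[r] += delta[r];
      ++kept;
    }
  }

  if (kept > 0)
    for (int r = 0; r < n; ++r) delta_bar[r] /= kept;

  return List::create(
    _["d"] = d_draws, _["mu"] = mu_draws, _["tau"] = tau_draws,
    _["sigma"] = sigma_draws, _["deviance"] = dev_draws,
    _["delta_bar"] = NumericVector(delta_bar.begin(), delta_bar.end()),
    _["n_kept"] = kept);
}
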