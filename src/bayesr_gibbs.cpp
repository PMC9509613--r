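// Single-site Gibbs sampler for the BayesR mixture-prior model
//   y = 1 mu + (line effects) + X beta + e
// with a K-component normal mixture prior on each variant effect,
// component variances gamma_k * sigma_g^2, the first component a point
// mass at zero. sigma_g^2 is re-anchored every iteration from the
// empirical variance of the current genetic values X beta (or, behind a
// flag, from sum((xx_j/n) beta_j^2)).
//
// Uses R's RNG throughout so that chains are reproducible via set.seed().

#include <Rcpp.h>
using namespace Rcpp;

// [[Rcpp::export]]
List bayesr_gibbs_cpp(NumericMatrix Xc, NumericVector y, IntegerVector line,
                      int n_lines, int n_iter, int burn_in, int thin,
                      NumericVector gamma, NumericVector alpha,
                      double vg_init, double vg_floor, int sumvar_rule) {
  const int n = Xc.nrow();
  const int m = Xc.ncol();
  const int K = gamma.size();

  // single-precision copy of the centred dosages: the sampler is memory
  // bandwidth bound and float traffic halves the per-sweep cost; all
  // accumulations remain in double
  std::vector<float> Xf(static_cast<size_t>(n) * m);
  std::vector<double> xx(m);
  for (int j = 0; j < m; ++j) {
    const double* xj = &Xc(0, j);
    float* fj = &Xf[static_cast<size_t>(j) * n];
    double s = 0.0;
    for (int i = 0; i < n; ++i) {
      fj[i] = static_cast<float>(xj[i]);
      s += xj[i] * xj[i];
    }
    xx[j] = s;
  }

  std::vector<double> beta(m, 0.0);
  std::vector<int> comp(m, 0);
  std::vector<double> pi(K, 1.0 / K);
  std::vector<double> lineff(n_lines, 0.0);
  std::vector<int> line_n(n_lines, 0);
  for (int i = 0; i < n; ++i) line_n[line[i]]++;

  double mu = mean(y);
  std::vector<double> e(n);
  std::vector<float> ef(n);  // float mirror of e for the bandwidth-bound dot
  for (int i = 0; i < n; ++i) { e[i] = y[i] - mu; ef[i] = (float)e[i]; }
  double ve = 0.0;
  for (int i = 0; i < n; ++i) ve += e[i] * e[i];
  ve = std::max(ve / n, 1e-12);
  double vg_used = vg_init;
  double vg = 0.0;

  // initial mixture proportions: one Dirichlet(alpha + all-null counts)
  // draw, i.e. the chain starts at the empty (all effects zero) model
  {
    double s = 0.0;
    std::vector<double> g(K);
    for (int k = 0; k < K; ++k) {
      double a = alpha[k] + (k == 0 ? m : 0);
      g[k] = R::rgamma(a, 1.0);
      s += g[k];
    }
    for (int k = 0; k < K; ++k) pi[k] = g[k] / s;
  }

  const int n_kept = (n_iter > burn_in) ? (n_iter - burn_in + thin - 1) / thin : 0;
  NumericVector beta_mean(m);
  NumericMatrix comp_prob(m, K);
  NumericVector pi_mean(K);
  double mu_sum = 0.0, vg_sum = 0.0, ve_sum = 0.0;
  std::vector<double> lineff_sum(n_lines, 0.0);
  NumericMatrix trace(n_kept, K + 2);
  int kept = 0;

  std::vector<double> logp(K), pk(K);
  std::vector<int> counts(K);

  for (int iter = 0; iter < n_iter; ++iter) {
    // (1)+(2) component indicators and effects, single site
    std::fill(counts.begin(), counts.end(), 0);
    for (int j = 0; j < m; ++j) {
      if (xx[j] < 1e-12) { beta[j] = 0.0; comp[j] = 0; counts[0]++; continue; }
      const float* xj = &Xf[static_cast<size_t>(j) * n];
      double r = 0.0;
      for (int i = 0; i < n; ++i) r += xj[i] * ef[i];
      r += xx[j] * beta[j];

      logp[0] = std::log(pi[0] + 1e-300);
      double mx = logp[0];
      for (int k = 1; k < K; ++k) {
        const double vk = gamma[k] * vg_used;
        const double den = ve + xx[j] * vk;
        logp[k] = std::log(pi[k] + 1e-300) - 0.5 * std::log(den / ve)
                  + 0.5 * r * r * vk / (ve * den);
        if (logp[k] > mx) mx = logp[k];
      }
      double tot = 0.0;
      for (int k = 0; k < K; ++k) { pk[k] = std::exp(logp[k] - mx); tot += pk[k]; }
      double u = unif_rand() * tot;
      int knew = K - 1;
      double acc = 0.0;
      for (int k = 0; k < K; ++k) { acc += pk[k]; if (u <= acc) { knew = k; break; } }

      double bnew = 0.0;
      if (knew > 0) {
        const double vk = gamma[knew] * vg_used;
        const double den = ve + xx[j] * vk;
        const double vpost = vk * ve / den;
        const double mpost = vpost * r / ve;
        bnew = R::rnorm(mpost, std::sqrt(vpost));
      }
      const double diff = bnew - beta[j];
      if (diff != 0.0) {
        for (int i = 0; i < n; ++i) {
          e[i] -= xj[i] * diff;
          ef[i] = (float)e[i];
        }
      }
      beta[j] = bnew;
      comp[j] = knew;
      counts[knew]++;
    }

    // (3) mixture proportions ~ Dirichlet(alpha + counts)
    {
      double s = 0.0;
      for (int k = 0; k < K; ++k) { pk[k] = R::rgamma(alpha[k] + counts[k], 1.0); s += pk[k]; }
      for (int k = 0; k < K; ++k) pi[k] = pk[k] / s;
    }

    // (4) residual variance, scaled inverse chi-square with flat prior
    {
      double ess = 0.0;
      for (int i = 0; i < n; ++i) ess += e[i] * e[i];
      const double df = std::max(n - 2, 1);
      ve = std::max(ess / R::rchisq(df), 1e-12);
    }

    // (5) genetic variance re-anchored from the current genetic values
    if (sumvar_rule) {
      vg = 0.0;
      for (int j = 0; j < m; ++j) vg += (xx[j] / n) * beta[j] * beta[j];
    } else {
      double gs = 0.0, gss = 0.0;
      for (int i = 0; i < n; ++i) {
        const double gi = y[i] - mu - lineff[line[i]] - e[i];
        gs += gi; gss += gi * gi;
      }
      gs /= n;
      vg = gss / n - gs * gs;
    }
    vg_used = std::max(vg, vg_floor);

    // (6) intercept and line effects, flat priors
    {
      double s = 0.0;
      for (int i = 0; i < n; ++i) s += e[i];
      const double mu_new = mu + s / n + norm_rand() * std::sqrt(ve / n);
      const double d = mu_new - mu;
      for (int i = 0; i < n; ++i) e[i] += -d;
      mu = mu_new;
    }
    for (int l = 1; l < n_lines; ++l) {
      double s = 0.0;
      for (int i = 0; i < n; ++i) if (line[i] == l) s += e[i];
      const double eff_new = lineff[l] + s / line_n[l]
                             + norm_rand() * std::sqrt(ve / line_n[l]);
      const double d = eff_new - lineff[l];
      for (int i = 0; i < n; ++i) if (line[i] == l) e[i] -= d;
      lineff[l] = eff_new;
    }
    for (int i = 0; i < n; ++i) ef[i] = (float)e[i];

    // accumulate posterior summaries
    if (iter >= burn_in && ((iter - burn_in) % thin) == 0) {
      for (int j = 0; j < m; ++j) {
        beta_mean[j] += beta[j];
        comp_prob(j, comp[j]) += 1.0;
      }
      for (int k = 0; k < K; ++k) pi_mean[k] += pi[k];
      mu_sum += mu; vg_sum += vg; ve_sum += ve;
      for (int l = 0; l < n_lines; ++l) lineff_sum[l] += lineff[l];
      trace(kept, 0) = vg;
      trace(kept, 1) = ve;
      for (int k = 0; k < K; ++k) trace(kept, 2 + k) = pi[k];
      kept++;
    }
  }

  for (int j = 0; j < m; ++j) {
    beta_mean[j] /= kept;
    for (int k = 0; k < K; ++k) comp_prob(j, k) /= kept;
  }
  for (int k = 0; k < K; ++k) pi_mean[k] /= kept;
  NumericVector le(n_lines);
  for (int l = 0; l < n_lines; ++l) le[l] = lineff_sum[l] / kept;

  return List::create(
    _["effect_means"] = beta_mean,
    _["comp_probs"] = comp_prob,
    _["mu"] = mu_sum / kept,
    _["line_effects"] = le,
    _["sigma_g2"] = vg_sum / kept,
    _["sigma_e2"] = ve_sum / kept,
    _["mixture_proportions"] = pi_mean,
    _["samples_kept"] = kept,
    _["trace"] = trace
  );
}
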