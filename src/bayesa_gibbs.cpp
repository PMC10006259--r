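#include <Rcpp.h>
using namespace Rcpp;

// Single-site Gibbs sampler for BayesA whole-genome regression:
//   y = u 1_n + K v + e,  v_j ~ N(0, s2v_j),  e ~ N(0, s2e I)
// with scaled-inverse-chi-squared priors on every variance. A draw from
// scaled-inv-chisq(nu, S) is taken as S' / rchisq(nu) with S' the updated
// scale (the "sum-of-squares" convention: the prior scale S enters the full
// conditional additively, S + v_j^2, not multiplied by nu).
//
// The residual vector e is maintained incrementally; the genomic value of
// sample i is recovered as g_i = y_i - u - e_i, which makes the
// per-iteration heritability Var(g) / (Var(g) + s2e) an O(n) byproduct.
//
// When update_scale is true the common marker-prior scale S_v is itself
// given a Gamma(shape0, rate0) prior (rate0 set so the prior mode is the
// initial S_v) and sampled from its Gamma full conditional each iteration,
// which lets the overall shrinkage adapt to how many markers carry signal.
//
// Uses R's RNG so chains are reproducible via set.seed() on the R side.

static double sample_var(const std::vector<double> &x) {
  int n = x.size();
  double mean = 0.0;
  for (int i = 0; i < n; ++i) mean += x[i];
  mean /= n;
  double ss = 0.0;
  for (int i = 0; i < n; ++i) ss += (x[i] - mean) * (x[i] - mean);
  return ss / (n - 1);
}

// [[Rcpp::export(name = ".bayesa_gibbs")]]
List bayesa_gibbs(NumericVector y, NumericMatrix K,
                  int n_iter, int burn_in, int thin,
                  double df_marker, double df_residual,
                  double S_v, double S_e,
                  double fixed_marker_variance,
                  bool update_scale, double shape0) {
  const int n = y.size();
  const int m = K.ncol();
  if (K.nrow() != n) stop("dimension mismatch between y and K");

  const bool fixed_s2v = !ISNA(fixed_marker_variance);

  std::vector<double> xtx(m);
  for (int j = 0; j < m; ++j) {
    double s = 0.0;
    for (int i = 0; i < n; ++i) s += K(i, j) * K(i, j);
    xtx[j] = s;
  }

  double u = 0.0;
  for (int i = 0; i < n; ++i) u += y[i];
  u /= n;

  std::vector<double> v(m, 0.0);
  std::vector<double> s2v(m, fixed_s2v ? fixed_marker_variance
                                       : S_v / (df_marker + 2.0));
  std::vector<double> e(n), g(n);
  for (int i = 0; i < n; ++i) e[i] = y[i] - u;
  double s2e = S_e / (df_residual + 2.0);
  if (s2e <= 0) s2e = sample_var(std::vector<double>(y.begin(), y.end()));

  const double rate0 = (shape0 - 1.0) / S_v;  // prior mode at the initial S_v
  double S_v_cur = S_v;

  const int n_keep = (n_iter - burn_in) / thin;
  NumericVector h2_samples(n_keep), s2e_samples(n_keep), u_samples(n_keep);
  std::vector<double> v_sum(m, 0.0);
  double u_sum = 0.0;
  int kept = 0;

  for (int t = 1; t <= n_iter; ++t) {
    // intercept: flat prior, normal full conditional
    double me = 0.0;
    for (int i = 0; i < n; ++i) me += e[i];
    me /= n;
    double u_new = u + me + norm_rand() * std::sqrt(s2e / n);
    double du = u_new - u;
    for (int i = 0; i < n; ++i) e[i] -= du;
    u = u_new;

    // marker effects, one at a time
    for (int j = 0; j < m; ++j) {
      double vj = v[j];
      double kte = 0.0;
      for (int i = 0; i < n; ++i) kte += K(i, j) * e[i];
      double C = xtx[j] / s2e + 1.0 / s2v[j];
      double mean = (kte + xtx[j] * vj) / s2e / C;
      double vj_new = mean + norm_rand() / std::sqrt(C);
      double dv = vj_new - vj;
      if (dv != 0.0) {
        for (int i = 0; i < n; ++i) e[i] -= K(i, j) * dv;
      }
      v[j] = vj_new;
      if (!fixed_s2v) {
        s2v[j] = (S_v_cur + vj_new * vj_new) / R::rchisq(df_marker + 1.0);
      }
    }

    // common marker-prior scale: Gamma full conditional
    if (!fixed_s2v && update_scale) {
      double inv_sum = 0.0;
      for (int j = 0; j < m; ++j) inv_sum += 1.0 / s2v[j];
      S_v_cur = R::rgamma(shape0 + 0.5 * m * df_marker,
                          1.0 / (rate0 + 0.5 * inv_sum));
    }

    // residual variance
    double ete = 0.0;
    for (int i = 0; i < n; ++i) ete += e[i] * e[i];
    s2e = (S_e + ete) / R::rchisq(df_residual + n);

    if (t > burn_in && (t - burn_in) % thin == 0) {
      for (int i = 0; i < n; ++i) g[i] = y[i] - u - e[i];
      double var_g = sample_var(g);
      h2_samples[kept] = var_g / (var_g + s2e);
      s2e_samples[kept] = s2e;
      u_samples[kept] = u;
      u_sum += u;
      for (int j = 0; j < m; ++j) v_sum[j] += v[j];
      ++kept;
    }
  }

  NumericVector v_mean(m);
  for (int j = 0; j < m; ++j) v_mean[j] = v_sum[j] / kept;

  return List::create(
      _["u_mean"] = u_sum / kept,
      _["v_mean"] = v_mean,
      _["h2_samples"] = h2_samples,
      _["sigma2_e_samples"] = s2e_samples,
      _["u_samples"] = u_samples,
      _["state"] = List::create(
          _["u"] = u,
          _["v"] = NumericVector(v.begin(), v.end()),
          _["sigma2_v"] = NumericVector(s2v.begin(), s2v.end()),
          _["sigma2_e"] = s2e,
          _["e"] = NumericVector(e.begin(), e.end())));
}
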