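// Gibbs samplers for single- and multi-trait BayesC-pi whole-genome
// regression.  Marker effects have a point-mass-at-zero + normal mixture
// prior with exclusion probability pi (per trait in the multi-trait
// sampler, where a locus may affect any combination of traits).  The
// samplers run on the centered genotype matrix and use R's RNG, so
// set.seed() on the R side makes chains exactly reproducible.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// four-accumulator dot product / axpy on raw column pointers; the split
// accumulators let the compiler vectorize despite the reduction
static inline double dot_raw(const double* x, const double* y, int n) {
  double s0 = 0.0, s1 = 0.0, s2 = 0.0, s3 = 0.0;
  int i = 0;
  for (; i + 4 <= n; i += 4) {
    s0 += x[i] * y[i];
    s1 += x[i + 1] * y[i + 1];
    s2 += x[i + 2] * y[i + 2];
    s3 += x[i + 3] * y[i + 3];
  }
  for (; i < n; ++i) s0 += x[i] * y[i];
  return s0 + s1 + s2 + s3;
}

static inline void axpy_raw(const double* x, double a, double* y, int n) {
  for (int i = 0; i < n; ++i) y[i] += a * x[i];
}

static inline double dot_col(const NumericMatrix& M, int j,
                             const NumericVector& v) {
  return dot_raw(&M(0, j), &v[0], M.nrow());
}

static inline void axpy_col(const NumericMatrix& M, int j, double a,
                            NumericVector& v) {
  axpy_raw(&M(0, j), a, &v[0], M.nrow());
}

static inline double dot_col_mat(const NumericMatrix& M, int j,
                                 const NumericMatrix& Y, int k) {
  return dot_raw(&M(0, j), &Y(0, k), M.nrow());
}

static inline void axpy_col_mat(const NumericMatrix& M, int j, double a,
                                NumericMatrix& Y, int k) {
  axpy_raw(&M(0, j), a, &Y(0, k), M.nrow());
}

// scaled inverse chi-square draw: (nu * s + ss) / chisq(nu + n)
static inline double rsichisq(double nu, double scale_sum, double df_extra) {
  return scale_sum / R::rchisq(nu + df_extra);
}

// [[Rcpp::export]]
List st_bayescpi_cpp(NumericMatrix M, NumericVector y,
                     int n_iter, int burn_in, int thin,
                     double pi_init, bool pi_fixed,
                     double nu_a, double s_a, double nu_e, double s_e) {
  const int n = M.nrow(), m = M.ncol();
  NumericVector xtx(m);
  int m_active = 0;
  for (int j = 0; j < m; ++j) {
    double s = 0.0;
    for (int i = 0; i < n; ++i) s += M(i, j) * M(i, j);
    xtx[j] = s;
    if (s > 0) ++m_active;
  }
  double mu = mean(y), s2a = s_a, s2e = s_e, pi = pi_init;
  NumericVector alpha(m, 0.0);
  IntegerVector delta(m, 0);
  NumericVector ycorr = clone(y);
  for (int i = 0; i < n; ++i) ycorr[i] -= mu;

  const int n_saved = (n_iter - burn_in) / thin;
  NumericVector a_sum(m, 0.0), a2_sum(m, 0.0), incl_sum(m, 0.0);
  NumericVector s2a_chain(n_saved), s2e_chain(n_saved), pi_chain(n_saved);
  double mu_sum = 0.0;
  int saved = 0;

  for (int it = 1; it <= n_iter; ++it) {
    // overall mean
    double s = 0.0;
    for (int i = 0; i < n; ++i) s += ycorr[i];
    double mu_new = mu + s / n + R::norm_rand() * std::sqrt(s2e / n);
    double dmu = mu_new - mu;
    for (int i = 0; i < n; ++i) ycorr[i] -= dmu;
    mu = mu_new;

    // marker effects with inclusion indicators
    int m1 = 0;
    double sum_a2 = 0.0;
    for (int j = 0; j < m; ++j) {
      if (xtx[j] <= 0) { alpha[j] = 0.0; delta[j] = 0; continue; }
      double r = dot_col(M, j, ycorr) + xtx[j] * alpha[j];
      double p1;
      if (pi >= 1.0) p1 = 0.0;
      else if (pi <= 0.0) p1 = 1.0;
      else {
        double var0 = xtx[j] * s2e;
        double var1 = xtx[j] * xtx[j] * s2a + var0;
        double log_lr = 0.5 * (std::log(var0) - std::log(var1)) +
          0.5 * r * r * (1.0 / var0 - 1.0 / var1);
        double log_odds = std::log((1.0 - pi) / pi) + log_lr;
        p1 = 1.0 / (1.0 + std::exp(-log_odds));
      }
      double a_new = 0.0;
      int d_new = 0;
      if (R::unif_rand() < p1) {
        double C = xtx[j] + s2e / s2a;
        a_new = r / C + R::norm_rand() * std::sqrt(s2e / C);
        d_new = 1;
      }
      if (a_new != alpha[j]) axpy_col(M, j, alpha[j] - a_new, ycorr);
      alpha[j] = a_new;
      delta[j] = d_new;
      if (d_new) { ++m1; sum_a2 += a_new * a_new; }
    }

    // variances and pi
    s2a = rsichisq(nu_a, nu_a * s_a + sum_a2, m1);
    double sse = 0.0;
    for (int i = 0; i < n; ++i) sse += ycorr[i] * ycorr[i];
    s2e = rsichisq(nu_e, nu_e * s_e + sse, n);
    if (!pi_fixed) pi = R::rbeta(m_active - m1 + 1.0, m1 + 1.0);
    if (!std::isfinite(s2a) || !std::isfinite(s2e))
      stop("divergent variance draw at iteration %d", it);

    if (it > burn_in && (it - burn_in) % thin == 0) {
      for (int j = 0; j < m; ++j) {
        a_sum[j] += alpha[j];
        a2_sum[j] += alpha[j] * alpha[j];
        incl_sum[j] += delta[j];
      }
      s2a_chain[saved] = s2a;
      s2e_chain[saved] = s2e;
      pi_chain[saved] = pi;
      mu_sum += mu;
      ++saved;
    }
  }

  NumericVector a_mean(m), a_sd(m), incl(m);
  for (int j = 0; j < m; ++j) {
    a_mean[j] = a_sum[j] / saved;
    double v = a2_sum[j] / saved - a_mean[j] * a_mean[j];
    a_sd[j] = std::sqrt(v > 0 ? v : 0);
    incl[j] = incl_sum[j] / saved;
  }
  double pi_mean = 0.0;
  for (int t = 0; t < saved; ++t) pi_mean += pi_chain[t];
  pi_mean /= saved;
  return List::create(_["alpha_mean"] = a_mean, _["alpha_sd"] = a_sd,
                      _["incl_freq"] = incl, _["pi_mean"] = pi_mean,
                      _["mu_mean"] = mu_sum / saved,
                      _["s2a_chain"] = s2a_chain, _["s2e_chain"] = s2e_chain,
                      _["pi_chain"] = pi_chain, _["n_saved"] = saved);
}

// 2x2 symmetric inverse; returns determinant
static inline double inv2(const double a[4], double out[4]) {
  double det = a[0] * a[3] - a[1] * a[2];
  out[0] = a[3] / det; out[3] = a[0] / det;
  out[1] = -a[1] / det; out[2] = -a[2] / det;
  return det;
}

// Wishart(df, scale) draw for 2x2 via Bartlett decomposition
static void rwish2(double df, const double scale[4], double out[4]) {
  // chol of scale (lower)
  double l11 = std::sqrt(scale[0]);
  double l21 = scale[1] / l11;
  double l22 = std::sqrt(scale[3] - l21 * l21);
  double a11 = std::sqrt(R::rchisq(df));
  double a21 = R::norm_rand();
  double a22 = std::sqrt(R::rchisq(df - 1.0));
  // T = L * A (lower)
  double t11 = l11 * a11;
  double t21 = l21 * a11 + l22 * a21;
  double t22 = l22 * a22;
  out[0] = t11 * t11;
  out[1] = out[2] = t11 * t21;
  out[3] = t21 * t21 + t22 * t22;
}

// inverse-Wishart(df, S) draw for 2x2: W ~ Wishart(df, S^-1), return W^-1
static void riwish2(double df, const double S[4], double out[4]) {
  double Sinv[4], W[4];
  inv2(S, Sinv);
  rwish2(df, Sinv, W);
  inv2(W, out);
}

// [[Rcpp::export]]
List mt_bayescpi_cpp(NumericMatrix M, NumericMatrix y, IntegerVector obs_trait,
                     int n_iter, int burn_in, int thin,
                     NumericVector pi_init, bool pi_fixed,
                     double v_g, NumericMatrix S_g,
                     double v_e, NumericMatrix S_e) {
  const int n = M.nrow(), m = M.ncol();
  NumericVector xtx(m);
  int m_active = 0;
  for (int j = 0; j < m; ++j) {
    double s = 0.0;
    for (int i = 0; i < n; ++i) s += M(i, j) * M(i, j);
    xtx[j] = s;
    if (s > 0) ++m_active;
  }
  double mu[2], pi[2];
  double Sig[4] = { S_g(0, 0), S_g(0, 1), S_g(1, 0), S_g(1, 1) };
  double Rres[4] = { S_e(0, 0), S_e(0, 1), S_e(1, 0), S_e(1, 1) };
  pi[0] = pi_init[0]; pi[1] = pi_init[1];
  // initialize means from observed records per trait
  for (int k = 0; k < 2; ++k) {
    double s = 0.0; int c = 0;
    for (int i = 0; i < n; ++i)
      if (obs_trait[i] == k + 1) { s += y(i, k); ++c; }
    mu[k] = c > 0 ? s / c : 0.0;
  }
  NumericMatrix alpha(m, 2);
  IntegerMatrix delta(m, 2);
  // ycorr = y - mu - M alpha; missing entries start at 0 residual
  NumericMatrix ycorr(n, 2);
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < 2; ++k)
      ycorr(i, k) = (obs_trait[i] == k + 1) ? y(i, k) - mu[k] : 0.0;

  const int n_saved = (n_iter - burn_in) / thin;
  NumericMatrix a_sum(m, 2), a2_sum(m, 2), incl_sum(m, 2);
  NumericVector rg_chain(n_saved), pi1_chain(n_saved), pi2_chain(n_saved);
  NumericVector sig_sum(4), r_sum(4);
  double mu_sum[2] = {0.0, 0.0};
  int saved = 0, n_jitter = 0;

  for (int it = 1; it <= n_iter; ++it) {
    // --- impute the unobserved trait's residual per individual ---
    double Rinv[4];
    inv2(Rres, Rinv);
    for (int i = 0; i < n; ++i) {
      int o = obs_trait[i] - 1, ms = 1 - o;
      double cond_m = Rres[1] / Rres[3 * o] * ycorr(i, o);
      double cond_v = Rres[3 * ms] - Rres[1] * Rres[1] / Rres[3 * o];
      if (cond_v < 1e-12) cond_v = 1e-12;
      ycorr(i, ms) = cond_m + R::norm_rand() * std::sqrt(cond_v);
    }

    // --- intercepts (joint bivariate update) ---
    double sbar[2] = {0.0, 0.0};
    for (int i = 0; i < n; ++i) { sbar[0] += ycorr(i, 0); sbar[1] += ycorr(i, 1); }
    sbar[0] /= n; sbar[1] /= n;
    // chol of R/n (lower)
    double c11 = std::sqrt(Rres[0] / n);
    double c21 = (Rres[1] / n) / c11;
    double c22 = std::sqrt(Rres[3] / n - c21 * c21);
    double z1 = R::norm_rand(), z2 = R::norm_rand();
    double d0 = sbar[0] + c11 * z1;
    double d1 = sbar[1] + c21 * z1 + c22 * z2;
    mu[0] += d0; mu[1] += d1;
    for (int i = 0; i < n; ++i) { ycorr(i, 0) -= d0; ycorr(i, 1) -= d1; }

    // --- marker effects: inclusion pattern over the 4 combinations ---
    double Siginv[4];
    double detSig = inv2(Sig, Siginv);
    int m1[2] = {0, 0}, n_both = 0;
    double Sb[4] = {0.0, 0.0, 0.0, 0.0};   // both-included scatter
    double Ssingle[2] = {0.0, 0.0};        // per-trait scatter, any inclusion
    int n_any[2] = {0, 0};
    for (int j = 0; j < m; ++j) {
      if (xtx[j] <= 0) continue;
      double q0 = dot_col_mat(M, j, ycorr, 0) + xtx[j] * alpha(j, 0);
      double q1 = dot_col_mat(M, j, ycorr, 1) + xtx[j] * alpha(j, 1);
      double b0 = Rinv[0] * q0 + Rinv[1] * q1;
      double b1 = Rinv[1] * q0 + Rinv[3] * q1;
      double lp[4];
      // combo 0: none
      lp[0] = std::log(pi[0]) + std::log(pi[1]);
      // combo 1: trait 1 only
      double P0 = xtx[j] * Rinv[0] + 1.0 / Sig[0];
      lp[1] = std::log(1.0 - pi[0]) + std::log(pi[1]) +
        0.5 * (b0 * b0 / P0 - std::log(P0) - std::log(Sig[0]));
      // combo 2: trait 2 only
      double P1 = xtx[j] * Rinv[3] + 1.0 / Sig[3];
      lp[2] = std::log(pi[0]) + std::log(1.0 - pi[1]) +
        0.5 * (b1 * b1 / P1 - std::log(P1) - std::log(Sig[3]));
      // combo 3: both
      double P2[4] = { xtx[j] * Rinv[0] + Siginv[0], xtx[j] * Rinv[1] + Siginv[1],
                       xtx[j] * Rinv[2] + Siginv[2], xtx[j] * Rinv[3] + Siginv[3] };
      double P2inv[4];
      double detP2 = inv2(P2, P2inv);
      double quad = b0 * (P2inv[0] * b0 + P2inv[1] * b1) +
                    b1 * (P2inv[2] * b0 + P2inv[3] * b1);
      lp[3] = std::log(1.0 - pi[0]) + std::log(1.0 - pi[1]) +
        0.5 * (quad - std::log(detP2) - std::log(detSig));
      // guard degenerate pi
      if (pi[0] >= 1.0) { lp[1] = lp[3] = -1e300; }
      if (pi[1] >= 1.0) { lp[2] = lp[3] = -1e300; }
      double mx = lp[0];
      for (int c = 1; c < 4; ++c) if (lp[c] > mx) mx = lp[c];
      double w[4], tot = 0.0;
      for (int c = 0; c < 4; ++c) { w[c] = std::exp(lp[c] - mx); tot += w[c]; }
      double u = R::unif_rand() * tot, acc = 0.0;
      int combo = 3;
      for (int c = 0; c < 4; ++c) { acc += w[c]; if (u <= acc) { combo = c; break; } }
      double a0 = 0.0, a1 = 0.0;
      if (combo == 1) {
        a0 = b0 / P0 + R::norm_rand() / std::sqrt(P0);
      } else if (combo == 2) {
        a1 = b1 / P1 + R::norm_rand() / std::sqrt(P1);
      } else if (combo == 3) {
        // draw from N(P2inv b, P2inv): chol of P2inv (lower)
        double me0 = P2inv[0] * b0 + P2inv[1] * b1;
        double me1 = P2inv[2] * b0 + P2inv[3] * b1;
        double l11 = std::sqrt(P2inv[0]);
        double l21 = P2inv[1] / l11;
        double l22 = std::sqrt(P2inv[3] - l21 * l21);
        double g1 = R::norm_rand(), g2 = R::norm_rand();
        a0 = me0 + l11 * g1;
        a1 = me1 + l21 * g1 + l22 * g2;
      }
      if (a0 != alpha(j, 0)) axpy_col_mat(M, j, alpha(j, 0) - a0, ycorr, 0);
      if (a1 != alpha(j, 1)) axpy_col_mat(M, j, alpha(j, 1) - a1, ycorr, 1);
      alpha(j, 0) = a0; alpha(j, 1) = a1;
      delta(j, 0) = combo == 1 || combo == 3;
      delta(j, 1) = combo == 2 || combo == 3;
      if (delta(j, 0)) { ++m1[0]; Ssingle[0] += a0 * a0; ++n_any[0]; }
      if (delta(j, 1)) { ++m1[1]; Ssingle[1] += a1 * a1; ++n_any[1]; }
      if (delta(j, 0) && delta(j, 1)) {
        ++n_both;
        Sb[0] += a0 * a0; Sb[1] += a0 * a1; Sb[3] += a1 * a1;
      }
    }
    Sb[2] = Sb[1];

    // --- effect covariance ---
    // correlation from the both-included loci (inverse-Wishart step),
    // variances refreshed from every locus carrying that trait (the
    // single-included loci inform the variance only)
    double S_iw[4] = { S_g(0, 0) + Sb[0], S_g(0, 1) + Sb[1],
                       S_g(1, 0) + Sb[2], S_g(1, 1) + Sb[3] };
    double Sig_new[4];
    riwish2(v_g + n_both, S_iw, Sig_new);
    int tries = 0;
    while ((Sig_new[0] <= 0 || Sig_new[3] <= 0 ||
            Sig_new[0] * Sig_new[3] - Sig_new[1] * Sig_new[1] <= 0) &&
           tries < 10) {
      S_iw[0] += 1e-8; S_iw[3] += 1e-8;
      riwish2(v_g + n_both, S_iw, Sig_new);
      ++tries; ++n_jitter;
    }
    double rho = Sig_new[1] / std::sqrt(Sig_new[0] * Sig_new[3]);
    double v1 = rsichisq(v_g, S_g(0, 0) + Ssingle[0], n_any[0]);
    double v2 = rsichisq(v_g, S_g(1, 1) + Ssingle[1], n_any[1]);
    Sig[0] = v1; Sig[3] = v2;
    Sig[1] = Sig[2] = rho * std::sqrt(v1 * v2);

    // --- residual covariance: inverse-Wishart on completed residuals ---
    double Se_post[4] = { S_e(0, 0), S_e(0, 1), S_e(1, 0), S_e(1, 1) };
    for (int i = 0; i < n; ++i) {
      Se_post[0] += ycorr(i, 0) * ycorr(i, 0);
      Se_post[1] += ycorr(i, 0) * ycorr(i, 1);
      Se_post[3] += ycorr(i, 1) * ycorr(i, 1);
    }
    Se_post[2] = Se_post[1];
    riwish2(v_e + n, Se_post, Rres);

    // --- pi per trait ---
    if (!pi_fixed) {
      pi[0] = R::rbeta(m_active - m1[0] + 1.0, m1[0] + 1.0);
      pi[1] = R::rbeta(m_active - m1[1] + 1.0, m1[1] + 1.0);
    }
    if (!std::isfinite(Sig[0]) || !std::isfinite(Rres[0]))
      stop("divergent covariance draw at iteration %d", it);

    if (it > burn_in && (it - burn_in) % thin == 0) {
      for (int j = 0; j < m; ++j)
        for (int k = 0; k < 2; ++k) {
          a_sum(j, k) += alpha(j, k);
          a2_sum(j, k) += alpha(j, k) * alpha(j, k);
          incl_sum(j, k) += delta(j, k);
        }
      rg_chain[saved] = Sig[1] / std::sqrt(Sig[0] * Sig[3]);
      pi1_chain[saved] = pi[0]; pi2_chain[saved] = pi[1];
      for (int c = 0; c < 4; ++c) { sig_sum[c] += Sig[c]; r_sum[c] += Rres[c]; }
      mu_sum[0] += mu[0]; mu_sum[1] += mu[1];
      ++saved;
    }
  }

  NumericMatrix a_mean(m, 2), a_sd(m, 2), incl(m, 2);
  for (int j = 0; j < m; ++j)
    for (int k = 0; k < 2; ++k) {
      a_mean(j, k) = a_sum(j, k) / saved;
      double v = a2_sum(j, k) / saved - a_mean(j, k) * a_mean(j, k);
      a_sd(j, k) = std::sqrt(v > 0 ? v : 0);
      incl(j, k) = incl_sum(j, k) / saved;
    }
  NumericVector sig_mean(4), r_mean(4);
  for (int c = 0; c < 4; ++c) {
    sig_mean[c] = sig_sum[c] / saved;
    r_mean[c] = r_sum[c] / saved;
  }
  double pm1 = 0.0, pm2 = 0.0;
  for (int t = 0; t < saved; ++t) { pm1 += pi1_chain[t]; pm2 += pi2_chain[t]; }
  pm1 /= saved; pm2 /= saved;
  return List::create(_["alpha_mean"] = a_mean, _["alpha_sd"] = a_sd,
                      _["incl_freq"] = incl,
                      _["pi_mean"] = NumericVector::create(pm1, pm2),
                      _["mu_mean"] = NumericVector::create(mu_sum[0] / saved,
                                                           mu_sum[1] / saved),
                      _["sigma_mean"] = sig_mean, _["r_mean"] = r_mean,
                      _["rg_chain"] = rg_chain,
                      _["pi1_chain"] = pi1_chain, _["pi2_chain"] = pi2_chain,
                      _["n_jitter"] = n_jitter, _["n_saved"] = saved);
}
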