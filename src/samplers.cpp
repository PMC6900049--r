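// Single-site Gibbs samplers for whole-genome regression marker models:
// BayesA, BayesB, BayesCpi and BayesR. The model is
//   y = X b + Z alpha + e,  e ~ N(0, I sigma_e2),
// with flat priors on b, a flat (df = -2, scale = 0) scaled-inverse-chi-square
// prior on sigma_e2, and the marker-effect priors that define each model.
// Indicator updates for BayesB/Cpi/R integrate the marker effect out of the
// conditional (GenSel-style), which leaves the stationary distribution
// unchanged and avoids a Metropolis step. Marker update order is fixed
// ascending for reproducibility; R's RNG is used throughout so runs are
// reproducible from set.seed().

#include <Rcpp.h>
using namespace Rcpp;

static inline double rscinvchisq(double df, double sum_sq) {
  // draw from scaled-inv-chi2 with df and df*scale = sum_sq
  return sum_sq / R::rchisq(df);
}

// [[Rcpp::export(name = ".gibbs_wgr")]]
List gibbs_wgr(const NumericVector& y, const NumericMatrix& X,
               const NumericMatrix& Z, const int model,
               const int n_iter, const int burn_in, const int thin,
               const double pi_init, const bool pi_update,
               const double v_df, const double Sa2,
               NumericVector comp_var, const bool update_vg,
               const double sigma_e2_init,
               const bool fix_se2, const bool fix_marker_var,
               const bool adapt_scale, const double vc_prior,
               const double sum2pq) {
  const int n = y.size(), p = X.ncol(), m = Z.ncol();
  if (burn_in >= n_iter) stop("burn_in must be < n_iter");

  // precompute column sums of squares
  std::vector<double> zz(m), xx(p);
  for (int j = 0; j < m; ++j) {
    double s = 0; const double* z = &Z(0, j);
    for (int i = 0; i < n; ++i) s += z[i] * z[i];
    zz[j] = s;
  }
  for (int l = 0; l < p; ++l) {
    double s = 0; const double* x = &X(0, l);
    for (int i = 0; i < n; ++i) s += x[i] * x[i];
    if (s <= 0) stop("fixed-effect column %d has zero sum of squares", l + 1);
    xx[l] = s;
  }

  std::vector<double> alpha(m, 0.0), b(p, 0.0), e(y.begin(), y.end());
  std::vector<double> sj2(m, Sa2 > 0 ? Sa2 : 1e-4);  // per-marker variances (A/B)
  std::vector<int> comp(m, 0);                       // BayesR component labels
  double sigma_e2 = sigma_e2_init, pi = pi_init, salpha2 = Sa2 > 0 ? Sa2 : 1e-4;
  NumericVector pmix(4, 0.25);                        // BayesR proportions

  // accumulators (post burn-in, every cycle)
  std::vector<double> alpha_sum(m, 0.0), incl_sum(m, 0.0), b_sum(p, 0.0);
  NumericMatrix comp_sum(m, 4);
  double pi_sum = 0, se2_sum = 0, vg_sum = 0;
  NumericVector pmix_sum(4, 0.0);
  int kept = 0;
  const int n_tr = n_iter / thin;
  NumericMatrix traces(n_tr, 3);  // sigma_e2, pi (or p1), var(Z alpha)
  int tr_row = 0;

  for (int it = 0; it < n_iter; ++it) {
    // --- fixed effects, single-site with flat prior ---
    for (int l = 0; l < p; ++l) {
      const double* x = &X(0, l);
      double rhs = 0;
      for (int i = 0; i < n; ++i) rhs += x[i] * e[i];
      rhs += xx[l] * b[l];
      double bn = R::rnorm(rhs / xx[l], std::sqrt(sigma_e2 / xx[l]));
      double diff = bn - b[l];
      if (diff != 0) for (int i = 0; i < n; ++i) e[i] -= x[i] * diff;
      b[l] = bn;
    }

    int m_in = 0;               // included markers this cycle (B/Cpi)
    double ssq_in = 0;          // sum alpha^2 over included (Cpi)
    int counts[4] = {0, 0, 0, 0};

    // --- marker effects, fixed ascending order ---
    for (int j = 0; j < m; ++j) {
      if (zz[j] <= 0) { alpha[j] = 0; continue; }
      const double* z = &Z(0, j);
      double rhs = 0;
      for (int i = 0; i < n; ++i) rhs += z[i] * e[i];
      rhs += zz[j] * alpha[j];
      double a_new = 0;

      if (model == 0) {                      // BayesA: every marker in
        double c = zz[j] + sigma_e2 / sj2[j];
        a_new = R::rnorm(rhs / c, std::sqrt(sigma_e2 / c));
        if (!fix_marker_var)
          sj2[j] = rscinvchisq(v_df + 1, v_df * Sa2 + a_new * a_new);
        ++m_in;
      } else if (model == 1 || model == 2) { // BayesB / BayesCpi
        double s2 = (model == 1) ? sj2[j] : salpha2;
        double c = zz[j] + sigma_e2 / s2;
        double log_odds = std::log((1.0 - pi) / pi) +
          0.5 * (std::log(sigma_e2 / s2) - std::log(c)) +
          rhs * rhs / (2.0 * sigma_e2 * c);
        double p_in = 1.0 / (1.0 + std::exp(-log_odds));
        bool incl = unif_rand() < p_in;
        if (incl) {
          a_new = R::rnorm(rhs / c, std::sqrt(sigma_e2 / c));
          ++m_in;
          if (model == 2) ssq_in += a_new * a_new;
          else if (!fix_marker_var)
            sj2[j] = rscinvchisq(v_df + 1, v_df * Sa2 + a_new * a_new);
        } else if (model == 1 && !fix_marker_var) {
          sj2[j] = rscinvchisq(v_df, v_df * Sa2);  // refresh from prior
        }
        if (it >= burn_in) incl_sum[j] += incl ? 1.0 : 0.0;
      } else {                               // BayesR: 4-component mixture
        double logw[4];
        double maxw = R_NegInf;
        for (int k = 0; k < 4; ++k) {
          double lw = std::log(pmix[k]);
          if (comp_var[k] > 0) {
            double c = zz[j] + sigma_e2 / comp_var[k];
            lw += 0.5 * (std::log(sigma_e2 / comp_var[k]) - std::log(c)) +
              rhs * rhs / (2.0 * sigma_e2 * c);
          }
          logw[k] = lw;
          if (lw > maxw) maxw = lw;
        }
        double tot = 0, w[4];
        for (int k = 0; k < 4; ++k) { w[k] = std::exp(logw[k] - maxw); tot += w[k]; }
        double u = unif_rand() * tot, acc = 0;
        int k_new = 3;
        for (int k = 0; k < 4; ++k) { acc += w[k]; if (u <= acc) { k_new = k; break; } }
        comp[j] = k_new;
        ++counts[k_new];
        if (comp_var[k_new] > 0) {
          double c = zz[j] + sigma_e2 / comp_var[k_new];
          a_new = R::rnorm(rhs / c, std::sqrt(sigma_e2 / c));
        }
        if (it >= burn_in) comp_sum(j, k_new) += 1.0;
      }

      double diff = a_new - alpha[j];
      if (diff != 0) for (int i = 0; i < n; ++i) e[i] -= z[i] * diff;
      alpha[j] = a_new;
    }

    // --- hyperparameters ---
    if (model == 2) {
      if (pi_update) pi = R::rbeta(m - m_in + 1.0, m_in + 1.0);
      if (!fix_marker_var) {
        // scale re-derived from the current pi so the prior mean effect
        // variance stays consistent with the genetic variance it encodes
        double sa2_cur = Sa2;
        if (adapt_scale && pi < 1.0 - 1e-8)
          sa2_cur = (v_df - 2.0) / v_df * vc_prior / ((1.0 - pi) * sum2pq);
        salpha2 = rscinvchisq(v_df + m_in, v_df * sa2_cur + ssq_in);
      }
    }
    if (model == 3) {
      double g[4], tot = 0;
      for (int k = 0; k < 4; ++k) { g[k] = R::rgamma(counts[k] + 1.0, 1.0); tot += g[k]; }
      for (int k = 0; k < 4; ++k) pmix[k] = g[k] / tot;
    }

    // genetic values g = Z alpha = y - X b - e
    double gmean = 0, gss = 0;
    {
      std::vector<double> xb(n, 0.0);
      for (int l = 0; l < p; ++l) {
        const double* x = &X(0, l);
        for (int i = 0; i < n; ++i) xb[i] += x[i] * b[l];
      }
      for (int i = 0; i < n; ++i) {
        double gi = y[i] - xb[i] - e[i];
        gmean += gi; gss += gi * gi;
      }
    }
    double var_g = n > 1 ? (gss - gmean * gmean / n) / (n - 1) : 0.0;
    if (model == 3 && update_vg && var_g > 0) {
      // refresh component variances from the current realized genetic variance
      comp_var[1] = 1e-4 * var_g; comp_var[2] = 1e-3 * var_g; comp_var[3] = 1e-2 * var_g;
    }

    // residual variance, flat scaled-inv-chi2 (df = -2, scale = 0)
    if (!fix_se2) {
      double sse = 0;
      for (int i = 0; i < n; ++i) sse += e[i] * e[i];
      sigma_e2 = rscinvchisq(n - 2.0, sse);
    }

    if ((it + 1) % thin == 0 && tr_row < n_tr) {
      traces(tr_row, 0) = sigma_e2;
      traces(tr_row, 1) = (model == 3) ? pmix[0] : pi;
      traces(tr_row, 2) = var_g;
      ++tr_row;
    }
    if (it >= burn_in) {
      for (int j = 0; j < m; ++j) alpha_sum[j] += alpha[j];
      for (int l = 0; l < p; ++l) b_sum[l] += b[l];
      pi_sum += pi; se2_sum += sigma_e2; vg_sum += var_g;
      for (int k = 0; k < 4; ++k) pmix_sum[k] += pmix[k];
      ++kept;
    }
  }

  NumericVector alpha_mean(m), incl_prob(m), b_mean(p);
  for (int j = 0; j < m; ++j) {
    alpha_mean[j] = alpha_sum[j] / kept;
    incl_prob[j] = incl_sum[j] / kept;
  }
  for (int l = 0; l < p; ++l) b_mean[l] = b_sum[l] / kept;
  NumericMatrix comp_prob(m, 4);
  if (model == 3)
    for (int j = 0; j < m; ++j)
      for (int k = 0; k < 4; ++k) comp_prob(j, k) = comp_sum(j, k) / kept;
  NumericVector pmix_mean(4);
  for (int k = 0; k < 4; ++k) pmix_mean[k] = pmix_sum[k] / kept;

  return List::create(_["alpha_mean"] = alpha_mean, _["b_mean"] = b_mean,
                      _["pi_mean"] = pi_sum / kept,
                      _["incl_prob"] = incl_prob,
                      _["comp_prob"] = comp_prob,
                      _["mix_props"] = pmix_mean,
                      _["sigma_e2_mean"] = se2_sum / kept,
                      _["genetic_variance_mean"] = vg_sum / kept,
                      _["traces"] = traces, _["n_kept"] = kept);
}
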