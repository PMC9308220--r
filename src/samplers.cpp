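// Gibbs samplers for single-trait Bayesian whole-genome regression:
//   y = 1 mu + W g + e
// with marker priors: i.i.d. normal (Bayesian ridge), spike-slab with
// sampled inclusion probability (BayesC), or double-exponential via the
// normal/exponential scale mixture (Bayesian lasso). All randomness comes
// from R's RNG so runs are reproducible from set.seed().

#include <Rcpp.h>
using namespace Rcpp;

static inline double rinvgauss(double mu, double lambda) {
  // Michael, Schucany & Haas
  double nu = R::norm_rand();
  double y = nu * nu;
  double x = mu + (mu * mu * y) / (2.0 * lambda) -
    (mu / (2.0 * lambda)) *
      std::sqrt(4.0 * mu * lambda * y + mu * mu * y * y);
  if (R::unif_rand() <= mu / (mu + x)) return x;
  return mu * mu / x;
}

static void check_finite(double x, const char* what) {
  if (!std::isfinite(x))
    stop("divergent chain: non-finite %s", what);
}

// [[Rcpp::export(name = ".gibbs_wgr")]]
List gibbs_wgr(NumericVector y, NumericMatrix W, int n_iter, int burn_in,
               int thin, std::string method, double df_e, double S_e,
               double df_g, double S_g, double pi_a, double pi_b,
               double lambda_shape, double lambda_rate,
               double fix_s2g = -1.0, double fix_s2e = -1.0) {
  int n = y.size(), m = W.ncol();
  if (W.nrow() != n) stop("dim mismatch between y and W");
  std::vector<double> xtx(m);
  for (int j = 0; j < m; ++j) {
    double s = 0.0;
    for (int i = 0; i < n; ++i) s += W(i, j) * W(i, j);
    xtx[j] = s;
  }
  bool bayesc = method == "bayesc", blasso = method == "blasso";
  std::vector<double> g(m, 0.0), tau2(m, 1.0);
  std::vector<int> incl(m, 1);
  double mu = mean(y);
  std::vector<double> e(n);
  for (int i = 0; i < n; ++i) e[i] = y[i] - mu;
  double vy = var(y);
  double s2e = 0.5 * vy, s2g = S_g * df_g / (df_g + 2.0);
  if (fix_s2g > 0.0) s2g = fix_s2g;
  if (fix_s2e > 0.0) s2e = fix_s2e;
  double pi = bayesc ? pi_a / (pi_a + pi_b) : 1.0;
  double lambda2 = blasso ? lambda_shape / lambda_rate : 0.0;

  std::vector<double> g_sum(m, 0.0), pip_sum(m, 0.0), u_sum(n, 0.0);
  double mu_sum = 0.0;
  int kept = 0, n_kept = 0;
  for (int it = burn_in; it < n_iter; it += thin) ++n_kept;
  NumericMatrix chains(std::max(n_kept, 1), 4); // s2g, s2e, pi, lambda2

  for (int it = 0; it < n_iter; ++it) {
    // intercept
    double es = 0.0;
    for (int i = 0; i < n; ++i) es += e[i] + mu;
    double mu_new = R::rnorm(es / n, std::sqrt(s2e / n));
    for (int i = 0; i < n; ++i) e[i] += mu - mu_new;
    mu = mu_new;
    // markers
    int m_in = 0;
    double ssg = 0.0, ssg_tau = 0.0;
    for (int j = 0; j < m; ++j) {
      double gj = g[j];
      double rhs = 0.0;
      if (gj != 0.0) {
        for (int i = 0; i < n; ++i) e[i] += W(i, j) * gj;
      }
      for (int i = 0; i < n; ++i) rhs += W(i, j) * e[i];
      double gnew = 0.0;
      if (bayesc) {
        double v0 = s2e * xtx[j];
        double v1 = v0 + xtx[j] * xtx[j] * s2g;
        double logr = 0.5 * (std::log(v0) - std::log(v1)) +
          0.5 * rhs * rhs * (1.0 / v0 - 1.0 / v1) +
          std::log(pi) - std::log(1.0 - pi);
        double p1 = 1.0 / (1.0 + std::exp(-logr));
        incl[j] = (R::unif_rand() < p1) ? 1 : 0;
        if (incl[j]) {
          double C = xtx[j] + s2e / s2g;
          gnew = R::rnorm(rhs / C, std::sqrt(s2e / C));
          ++m_in;
          ssg += gnew * gnew;
        }
      } else if (blasso) {
        double C = xtx[j] + 1.0 / tau2[j];
        gnew = R::rnorm(rhs / C, std::sqrt(s2e / C));
        ssg_tau += gnew * gnew / tau2[j];
      } else { // brr
        double C = xtx[j] + s2e / s2g;
        gnew = R::rnorm(rhs / C, std::sqrt(s2e / C));
        ssg += gnew * gnew;
      }
      if (gnew != 0.0)
        for (int i = 0; i < n; ++i) e[i] -= W(i, j) * gnew;
      g[j] = gnew;
    }
    // scale-mixture and hyper parameters
    if (blasso) {
      double sum_tau2 = 0.0;
      for (int j = 0; j < m; ++j) {
        double gj2 = g[j] * g[j];
        if (gj2 < 1e-12 * s2e) gj2 = 1e-12 * s2e;
        double itau = rinvgauss(std::sqrt(lambda2 * s2e / gj2), lambda2);
        if (itau < 1e-10) itau = 1e-10;
        tau2[j] = 1.0 / itau;
        sum_tau2 += tau2[j];
      }
      lambda2 = R::rgamma(lambda_shape + m,
                          1.0 / (lambda_rate + 0.5 * sum_tau2));
      check_finite(lambda2, "lambda2");
    } else if (bayesc) {
      if (fix_s2g <= 0.0)
        s2g = (ssg + df_g * S_g) / R::rchisq(df_g + m_in);
      pi = R::rbeta(pi_a + m_in, pi_b + m - m_in);
      if (pi < 1e-6) pi = 1e-6;
      if (pi > 1.0 - 1e-6) pi = 1.0 - 1e-6;
    } else if (fix_s2g <= 0.0) {
      s2g = (ssg + df_g * S_g) / R::rchisq(df_g + m);
    }
    double sse = 0.0;
    for (int i = 0; i < n; ++i) sse += e[i] * e[i];
    if (fix_s2e <= 0.0) {
      if (blasso)
        s2e = (sse + ssg_tau + df_e * S_e) / R::rchisq(df_e + n + m);
      else
        s2e = (sse + df_e * S_e) / R::rchisq(df_e + n);
    }
    check_finite(s2e, "residual variance");
    check_finite(s2g, "marker variance");
    if (it >= burn_in && (it - burn_in) % thin == 0) {
      for (int j = 0; j < m; ++j) {
        g_sum[j] += g[j];
        pip_sum[j] += incl[j];
      }
      for (int i = 0; i < n; ++i) u_sum[i] += (y[i] - mu - e[i]);
      mu_sum += mu;
      chains(kept, 0) = s2g; chains(kept, 1) = s2e;
      chains(kept, 2) = pi;  chains(kept, 3) = lambda2;
      ++kept;
    }
  }
  if (kept == 0) stop("chain kept no samples: check n_iter/burn_in/thin");
  NumericVector g_mean(m), pip(m), u_mean(n);
  for (int j = 0; j < m; ++j) {
    g_mean[j] = g_sum[j] / kept;
    pip[j] = pip_sum[j] / kept;
  }
  for (int i = 0; i < n; ++i) u_mean[i] = u_sum[i] / kept;
  return List::create(_["g"] = g_mean, _["pip"] = pip, _["u"] = u_mean,
                      _["mu"] = mu_sum / kept, _["chains"] = chains,
                      _["n_kept"] = kept);
}
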