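#include <Rcpp.h>
using namespace Rcpp;

// Hierarchical Bayesian regression of score changes, unconstrained
// parameterization used by the sampler and by bridge sampling.
//
// theta layout (length D = 2K + K(K-1)/2 + 1 + K*n_pi):
//   mu[K]                  hierarchical means
//   lz[K]                  log hierarchical scales zeta
//   y[K(K-1)/2]            atanh canonical partial correlations of Omega_chol,
//                          row-major (i = 2..K, j = 1..i-1)
//   ls                     log residual SD sigma
//   z[K * n_pi]            non-centered per-PI effects, column-major;
//                          beta_i = mu + zeta * (L z_i)
//
// The LKJ-Cholesky prior on Omega_chol is expressed through independent
// 2*Beta(b_j, b_j) - 1 densities on the partial correlations with
// column-dependent shape b_j = eta + (K - 1 - j)/2 (1-based column j), which
// is the normalized LKJ-Cholesky density after the stick-breaking change of
// variables. All prior terms are normalized (required for marginal
// likelihoods); tanh/exp Jacobians are included.

static double lp_core(const double* th, double* grad,
                      const NumericMatrix& X, const NumericVector& d,
                      const IntegerVector& gidx, int n_pi,
                      const NumericVector& mu_scale, double zeta_df,
                      double sigma_scale, double eta) {
  const int N = X.nrow(), K = X.ncol();
  const int P = K * (K - 1) / 2;
  const int D = 2 * K + P + 1 + K * n_pi;

  const double* mu = th;
  const double* lz = th + K;
  const double* y  = th + 2 * K;
  const double ls  = th[2 * K + P];
  const double* z  = th + 2 * K + P + 1;

  if (grad) std::fill(grad, grad + D, 0.0);

  // hard guards: outside this range the density is numerically degenerate
  for (int k = 0; k < K; ++k)
    if (!std::isfinite(mu[k]) || !std::isfinite(lz[k]) || std::fabs(lz[k]) > 40.0)
      return R_NegInf;
  for (int p = 0; p < P; ++p)
    if (!std::isfinite(y[p]) || std::fabs(y[p]) > 18.0) return R_NegInf;
  if (!std::isfinite(ls) || std::fabs(ls) > 40.0) return R_NegInf;

  std::vector<double> zeta(K), w(P);
  for (int k = 0; k < K; ++k) zeta[k] = std::exp(lz[k]);
  const double sigma = std::exp(ls);
  const double sig2 = sigma * sigma;
  for (int p = 0; p < P; ++p) w[p] = std::tanh(y[p]);

  // Omega Cholesky factor from partial correlations
  std::vector<double> L(K * K, 0.0), sq(P);
  L[0] = 1.0;
  {
    int p = 0;
    for (int i = 1; i < K; ++i) {
      double rem = 1.0;
      for (int j = 0; j < i; ++j, ++p) {
        sq[p] = std::sqrt(rem);
        L[i + K * j] = w[p] * sq[p];
        rem *= (1.0 - w[p] * w[p]);
      }
      L[i + K * i] = std::sqrt(rem);
    }
  }

  // per-PI effects
  std::vector<double> u(K * n_pi), beta(K * n_pi);
  for (int g = 0; g < n_pi; ++g) {
    for (int a = 0; a < K; ++a) {
      double s = 0.0;
      for (int b = 0; b <= a; ++b) s += L[a + K * b] * z[b + K * g];
      u[a + K * g] = s;
      beta[a + K * g] = mu[a] + zeta[a] * s;
    }
  }

  double lp = 0.0;

  // ---- likelihood: d ~ Normal(x' beta_i, sigma^2)
  std::vector<double> gbeta;
  if (grad) gbeta.assign(K * n_pi, 0.0);
  double rss = 0.0;
  for (int n = 0; n < N; ++n) {
    const int g = gidx[n];
    double m = 0.0;
    for (int k = 0; k < K; ++k) m += X(n, k) * beta[k + K * g];
    const double r = d[n] - m;
    rss += r * r;
    if (grad) {
      const double c = r / sig2;
      for (int k = 0; k < K; ++k) gbeta[k + K * g] += X(n, k) * c;
    }
  }
  lp += -0.5 * N * std::log(2.0 * M_PI) - N * ls - 0.5 * rss / sig2;
  double g_ls = grad ? (-(double)N + rss / sig2) : 0.0;

  // ---- priors
  // mu_k ~ Normal(0, mu_scale_k)
  for (int k = 0; k < K; ++k) {
    const double sc = mu_scale[k];
    lp += -0.5 * std::log(2.0 * M_PI) - std::log(sc) -
          0.5 * mu[k] * mu[k] / (sc * sc);
    if (grad) grad[k] += -mu[k] / (sc * sc);
  }
  // zeta_k ~ Student-t+(df, 0, 1), Jacobian of exp included
  const double nu = zeta_df;
  const double htc = std::log(2.0) + R::lgammafn(0.5 * (nu + 1.0)) -
                     R::lgammafn(0.5 * nu) - 0.5 * std::log(nu * M_PI);
  for (int k = 0; k < K; ++k) {
    const double z2 = zeta[k] * zeta[k];
    lp += htc - 0.5 * (nu + 1.0) * std::log1p(z2 / nu) + lz[k];
    if (grad) grad[K + k] += -(nu + 1.0) * z2 / (nu + z2) + 1.0;
  }
  // sigma ~ Normal+(0, sigma_scale), Jacobian of exp included
  lp += std::log(2.0) - 0.5 * std::log(2.0 * M_PI) - std::log(sigma_scale) -
        0.5 * sig2 / (sigma_scale * sigma_scale) + ls;
  if (grad) g_ls += -sig2 / (sigma_scale * sigma_scale) + 1.0;
  // partial correlations: LKJ(eta) via column-shaped Beta densities,
  // plus tanh Jacobian (combined exponent b instead of b - 1)
  {
    int p = 0;
    for (int i = 1; i < K; ++i) {
      for (int j = 0; j < i; ++j, ++p) {
        const double b = eta + 0.5 * (K - 2.0 - j);
        const double om = 1.0 - w[p] * w[p];
        if (om <= 0.0) return R_NegInf;
        lp += b * std::log(om) - (2.0 * b - 1.0) * std::log(2.0) -
              R::lbeta(b, b);
        if (grad) grad[2 * K + p] += -2.0 * b * w[p];
      }
    }
  }
  // z ~ Normal(0, 1)
  {
    double ssq = 0.0;
    const int M = K * n_pi;
    for (int m = 0; m < M; ++m) ssq += z[m] * z[m];
    lp += -0.5 * M * std::log(2.0 * M_PI) - 0.5 * ssq;
    if (grad)
      for (int m = 0; m < M; ++m) grad[2 * K + P + 1 + m] += -z[m];
  }

  if (!std::isfinite(lp)) return R_NegInf;
  if (!grad) return lp;

  // ---- chain rule from gbeta into mu, lz, z, y
  for (int g = 0; g < n_pi; ++g) {
    for (int a = 0; a < K; ++a) {
      const double gb = gbeta[a + K * g];
      grad[a] += gb;                                  // mu
      grad[K + a] += zeta[a] * gb * u[a + K * g];     // lz (zeta * d/dzeta)
    }
    for (int b = 0; b < K; ++b) {                     // z_i += L' (zeta*gbeta)
      double s = 0.0;
      for (int a = b; a < K; ++a) s += L[a + K * b] * zeta[a] * gbeta[a + K * g];
      grad[2 * K + P + 1 + b + K * g] += s;
    }
  }
  // G_L[a,b] = sum_g zeta_a gbeta[a,g] z[b,g]
  std::vector<double> GL(K * K, 0.0);
  for (int g = 0; g < n_pi; ++g) {
    for (int a = 0; a < K; ++a) {
      const double c = zeta[a] * gbeta[a + K * g];
      if (c == 0.0) continue;
      for (int b = 0; b <= a; ++b) GL[a + K * b] += c * z[b + K * g];
    }
  }
  // rows of L into partial correlations, then tanh Jacobian into y
  {
    int p = 0;
    for (int i = 1; i < K; ++i) {
      // Tk[k] = sum over j in (k, i] of GL[i,j] * L[i,j]
      std::vector<double> Tk(i);
      double T = GL[i + K * i] * L[i + K * i];
      for (int k = i - 1; k >= 0; --k) {
        Tk[k] = T;
        T += GL[i + K * k] * L[i + K * k];
      }
      for (int k = 0; k < i; ++k) {
        const int pp = p + k;
        const double om = 1.0 - w[pp] * w[pp];
        const double gw = GL[i + K * k] * sq[pp] - (w[pp] / om) * Tk[k];
        grad[2 * K + pp] += gw * om;
      }
      p += i;
    }
  }
  grad[2 * K + P] = g_ls;
  return lp;
}

// non-static entry point shared with the NUTS translation unit
double hbr_lp_grad_raw(const double* th, double* grad,
                       const NumericMatrix& X, const NumericVector& d,
                       const IntegerVector& gidx, int n_pi,
                       const NumericVector& mu_scale, double zeta_df,
                       double sigma_scale, double eta) {
  return lp_core(th, grad, X, d, gidx, n_pi, mu_scale, zeta_df,
                 sigma_scale, eta);
}

// [[Rcpp::export]]
List cpp_hbr_lp_grad(NumericVector theta, NumericMatrix X, NumericVector d,
                     IntegerVector gidx, int n_pi, NumericVector mu_scale,
                     double zeta_df, double sigma_scale, double eta) {
  const int K = X.ncol();
  const int D = 2 * K + K * (K - 1) / 2 + 1 + K * n_pi;
  if (theta.size() != D) stop("theta has wrong length");
  NumericVector grad(D);
  double lp = lp_core(theta.begin(), grad.begin(), X, d, gidx, n_pi,
                      mu_scale, zeta_df, sigma_scale, eta);
  if (!std::isfinite(lp)) std::fill(grad.begin(), grad.end(), 0.0);
  return List::create(_["lp"] = lp, _["grad"] = grad);
}

// [[Rcpp::export]]
NumericVector cpp_hbr_lp_mat(NumericMatrix Theta, NumericMatrix X,
                             NumericVector d, IntegerVector gidx, int n_pi,
                             NumericVector mu_scale, double zeta_df,
                             double sigma_scale, double eta) {
  const int M = Theta.nrow();
  const int K = X.ncol();
  const int D = 2 * K + K * (K - 1) / 2 + 1 + K * n_pi;
  if (Theta.ncol() != D) stop("Theta has wrong number of columns");
  NumericVector out(M);
  std::vector<double> row(D);
  for (int m = 0; m < M; ++m) {
    for (int j = 0; j < D; ++j) row[j] = Theta(m, j);
    out[m] = lp_core(row.data(), nullptr, X, d, gidx, n_pi, mu_scale,
                     zeta_df, sigma_scale, eta);
  }
  return out;
}
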