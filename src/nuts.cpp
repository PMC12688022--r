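#include <Rcpp.h>
using namespace Rcpp;

// No-U-Turn sampler specialised to the hierarchical model's log density
// (lp_core in hbr.cpp). Multiplicative dual-averaging step-size adaptation
// and a diagonal mass matrix estimated from the middle warmup window.
// Uses R's RNG throughout, so runs are reproducible under set.seed().

double hbr_lp_grad_raw(const double* th, double* grad,
                       const NumericMatrix& X, const NumericVector& d,
                       const IntegerVector& gidx, int n_pi,
                       const NumericVector& mu_scale, double zeta_df,
                       double sigma_scale, double eta);

namespace {

struct Model {
  const NumericMatrix& X;
  const NumericVector& d;
  const IntegerVector& gidx;
  int n_pi;
  const NumericVector& mu_scale;
  double zeta_df, sigma_scale, eta;
  mutable long n_evals = 0;
  double operator()(const std::vector<double>& th, std::vector<double>& grad) const {
    ++n_evals;
    return hbr_lp_grad_raw(th.data(), grad.data(), X, d, gidx, n_pi,
                           mu_scale, zeta_df, sigma_scale, eta);
  }
};

struct State {
  std::vector<double> theta, r, grad;
  double lp;
};

struct Tree {
  State minus_, plus_, prop;
  double prop_lp;
  int n;
  bool s, div;
  double alpha;
  int nalpha;
};

class Nuts {
public:
  Nuts(const Model& model, int D, double delta_max = 1000.0)
      : model_(model), D_(D), delta_max_(delta_max), minv_(D, 1.0) {}

  std::vector<double> minv_;
  const Model& model_;
  int D_;
  double delta_max_;
  double eps_ = 0.1;

  void leapfrog(State& st, double eps) const {
    for (int i = 0; i < D_; ++i) st.r[i] += 0.5 * eps * st.grad[i];
    for (int i = 0; i < D_; ++i) st.theta[i] += eps * minv_[i] * st.r[i];
    st.lp = model_(st.theta, st.grad);
    for (int i = 0; i < D_; ++i) st.r[i] += 0.5 * eps * st.grad[i];
  }

  double joint(const State& st) const {
    double k = 0.0;
    for (int i = 0; i < D_; ++i) k += minv_[i] * st.r[i] * st.r[i];
    double h = st.lp - 0.5 * k;
    return std::isfinite(h) ? h : R_NegInf;
  }

  void momentum(State& st) const {
    for (int i = 0; i < D_; ++i) st.r[i] = R::norm_rand() / std::sqrt(minv_[i]);
  }

  void find_eps(State st) {
    eps_ = 0.1;
    momentum(st);
    double h0 = joint(st);
    State tr = st;
    leapfrog(tr, eps_);
    double h1 = joint(tr);
    if (!std::isfinite(h1)) {
      while (!std::isfinite(h1) && eps_ > 1e-10) {
        eps_ *= 0.5;
        tr = st;
        leapfrog(tr, eps_);
        h1 = joint(tr);
      }
      return;
    }
    double a = (h1 - h0 > std::log(0.5)) ? 1.0 : -1.0;
    while (true) {
      tr = st;
      leapfrog(tr, eps_);
      double h = joint(tr);
      if (!std::isfinite(h)) { eps_ *= 0.5; break; }
      if (!(a * (h - h0) > -a * std::log(2.0))) break;
      eps_ *= std::pow(2.0, a);
      if (eps_ > 1e7 || eps_ < 1e-10) break;
    }
  }

  bool no_uturn(const State& m, const State& p) const {
    double a = 0.0, b = 0.0;
    for (int i = 0; i < D_; ++i) {
      const double dt = p.theta[i] - m.theta[i];
      a += dt * minv_[i] * m.r[i];
      b += dt * minv_[i] * p.r[i];
    }
    return a >= 0.0 && b >= 0.0;
  }

  Tree build(const State& st, double lu, int v, int j, double h0) {
    if (j == 0) {
      Tree t;
      State nx = st;
      leapfrog(nx, v * eps_);
      const double h = joint(nx);
      t.n = (lu <= h) ? 1 : 0;
      t.s = (lu < h + delta_max_);
      t.div = !t.s;
      t.alpha = std::min(1.0, std::exp(h - h0));
      if (!std::isfinite(t.alpha)) t.alpha = 0.0;
      t.nalpha = 1;
      t.minus_ = nx; t.plus_ = nx; t.prop = nx; t.prop_lp = nx.lp;
      return t;
    }
    Tree t1 = build(st, lu, v, j - 1, h0);
    if (t1.s) {
      Tree t2 = (v == -1) ? build(t1.minus_, lu, v, j - 1, h0)
                          : build(t1.plus_, lu, v, j - 1, h0);
      if (v == -1) t1.minus_ = t2.minus_; else t1.plus_ = t2.plus_;
      if (t2.n > 0 &&
          R::unif_rand() < (double)t2.n / std::max(1, t1.n + t2.n)) {
        t1.prop = t2.prop; t1.prop_lp = t2.prop_lp;
      }
      t1.s = t2.s && no_uturn(t1.minus_, t1.plus_);
      t1.n += t2.n;
      t1.alpha += t2.alpha;
      t1.nalpha += t2.nalpha;
      t1.div = t1.div || t2.div;
    }
    return t1;
  }
};

} // namespace

// [[Rcpp::export]]
List cpp_nuts_hbr(NumericVector theta0, int n_warmup, int n_iter,
                  double target_accept, int max_depth,
                  NumericMatrix X, NumericVector d, IntegerVector gidx,
                  int n_pi, NumericVector mu_scale, double zeta_df,
                  double sigma_scale, double eta) {
  const int K = X.ncol();
  const int D = 2 * K + K * (K - 1) / 2 + 1 + K * n_pi;
  if (theta0.size() != D) stop("theta0 has wrong length");
  Model model{X, d, gidx, n_pi, mu_scale, zeta_df, sigma_scale, eta};
  Nuts nuts(model, D);

  State cur;
  cur.theta.assign(theta0.begin(), theta0.end());
  cur.r.assign(D, 0.0);
  cur.grad.assign(D, 0.0);
  cur.lp = model(cur.theta, cur.grad);
  if (!std::isfinite(cur.lp))
    stop("non-finite log joint density at initialization");

  nuts.find_eps(cur);
  double da_mu = std::log(10.0 * nuts.eps_);
  double da_h = 0.0, da_logeps_bar = std::log(nuts.eps_);
  int da_count = 0;
  const double gamma = 0.05, t0 = 10.0, kappa = 0.75;

  const int w1 = std::max(1, (int)std::floor(0.25 * n_warmup));
  const int w2 = (int)std::floor(0.75 * n_warmup);
  NumericMatrix window(std::max(0, w2 - w1), D);

  NumericMatrix draws(n_iter, D);
  NumericVector lps(n_iter);
  int divergences = 0;

  const int total = n_warmup + n_iter;
  for (int it = 1; it <= total; ++it) {
    nuts.momentum(cur);
    const double h0 = nuts.joint(cur);
    const double lu = h0 - R::exp_rand();
    State minus_ = cur, plus_ = cur, sel = cur;
    double sel_lp = cur.lp;
    int n = 1, j = 0;
    bool s = true, diverged = false;
    double alpha = 1.0; int nalpha = 1;
    while (s && j < max_depth) {
      const int v = (R::unif_rand() < 0.5) ? -1 : 1;
      Tree t = (v == -1) ? nuts.build(minus_, lu, v, j, h0)
                         : nuts.build(plus_, lu, v, j, h0);
      if (v == -1) minus_ = t.minus_; else plus_ = t.plus_;
      if (t.s && R::unif_rand() < (double)t.n / n) {
        sel = t.prop; sel_lp = t.prop_lp;
      }
      n += t.n;
      s = t.s && nuts.no_uturn(minus_, plus_);
      alpha = t.alpha; nalpha = t.nalpha;
      diverged = diverged || t.div;
      ++j;
    }
    cur = sel; cur.lp = sel_lp;

    if (it <= n_warmup) {
      ++da_count;
      da_h = (1.0 - 1.0 / (da_count + t0)) * da_h +
             (target_accept - alpha / nalpha) / (da_count + t0);
      const double logeps = da_mu - std::sqrt((double)da_count) / gamma * da_h;
      const double w = std::pow((double)da_count, -kappa);
      da_logeps_bar = w * logeps + (1.0 - w) * da_logeps_bar;
      nuts.eps_ = std::exp(logeps);
      if (it > w1 && it <= w2)
        for (int i = 0; i < D; ++i) window(it - w1 - 1, i) = cur.theta[i];
      if (it == w2 && w2 > w1 + 10) {
        const int nw = w2 - w1;
        for (int i = 0; i < D; ++i) {
          double m = 0.0, ss = 0.0;
          for (int rrow = 0; rrow < nw; ++rrow) m += window(rrow, i);
          m /= nw;
          for (int rrow = 0; rrow < nw; ++rrow) {
            const double dev = window(rrow, i) - m;
            ss += dev * dev;
          }
          const double v = ss / (nw - 1);
          nuts.minv_[i] = v * nw / (nw + 5.0) + 1e-3 * 5.0 / (nw + 5.0);
        }
        // re-initialize step-size adaptation under the new metric
        nuts.find_eps(cur);
        da_mu = std::log(10.0 * std::max(nuts.eps_, 1e-6));
        da_h = 0.0; da_logeps_bar = std::log(std::max(nuts.eps_, 1e-6));
        da_count = 0;
      }
      if (it == n_warmup) nuts.eps_ = std::exp(da_logeps_bar);
    } else {
      for (int i = 0; i < D; ++i) draws(it - n_warmup - 1, i) = cur.theta[i];
      lps[it - n_warmup - 1] = cur.lp;
      if (diverged) ++divergences;
    }
  }
  return List::create(_["draws"] = draws, _["lp"] = lps,
                      _["divergences"] = divergences,
                      _["step_size"] = nuts.eps_,
                      _["inv_mass"] = NumericVector(nuts.minv_.begin(),
                                                    nuts.minv_.end()),
                      _["n_evals"] = (double)model.n_evals);
}
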