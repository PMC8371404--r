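// Adaptive coordinate-wise random-walk Metropolis samplers for the
// hierarchical slider-belief models.
//
// Prior-belief model (one slider per state):
//   kappa ~ Gamma(5, 5)          w ~ Gamma(2, 0.1)
//   sigma2 ~ inv.Gamma(1, 1)     mu_k ~ Dirichlet(1, ..., 1)
//   p_jk ~ Dirichlet(w * mu_k)
//   Q_i = p[m_i] / choose(k, m_i)
//   logit(P_i) ~ Normal(kappa * logit(Q_i), sqrt(sigma2))
//
// Posterior-belief model (sliders over focus-compatible states):
//   mu_alpha ~ Gamma(5, 5)       sigma2_alpha ~ inv.Gamma(1, 1)
//   alpha_j ~ Gamma(mu_alpha^2 / sigma2_alpha, mu_alpha / sigma2_alpha)
//   Q_post(i) propto S1(foc | i) * Q_prior(i) over compatible states,
//   with S1 the lexicon-normalized soft-max speaker (focus expressions for
//   every nonempty subset plus a costless null message, zero costs),
//   w and mu_k fixed at the prior fit's posterior means.
//
// Simplexes are parameterized by an additive-log-ratio transform with the
// first coordinate as reference; positive scalars by their logarithm; all
// Jacobians are included in the target.  R's RNG is used throughout so
// runs are reproducible from set.seed().

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

static inline double logit(double q) { return std::log(q) - std::log1p(-q); }

// beliefs saturate at the slider resolution before the logit link,
// mirroring clip_unit() on the R side
static inline double clip_logit(double q) {
  const double eps = 1e-3;
  if (q < eps) q = eps;
  if (q > 1.0 - eps) q = 1.0 - eps;
  return logit(q);
}

static inline int popcount(int x) {
  int n = 0;
  while (x) { n += x & 1; x >>= 1; }
  return n;
}

static inline double lp_gamma(double x, double shape, double rate) {
  return shape * std::log(rate) - R::lgammafn(shape) +
    (shape - 1.0) * std::log(x) - rate * x;
}

static inline double lp_invgamma(double x, double shape, double scale) {
  return shape * std::log(scale) - R::lgammafn(shape) -
    (shape + 1.0) * std::log(x) - scale / x;
}

// softmax of (0, eta); returns simplex of length eta.size() + 1
static void alr_to_simplex(const std::vector<double> &eta,
                           std::vector<double> &p) {
  const int n = (int) eta.size() + 1;
  p.resize(n);
  double mx = 0.0;
  for (double e : eta) if (e > mx) mx = e;
  double sum = std::exp(-mx);
  p[0] = std::exp(-mx);
  for (int c = 1; c < n; ++c) { p[c] = std::exp(eta[c - 1] - mx); sum += p[c]; }
  for (int c = 0; c < n; ++c) p[c] /= sum;
}

struct Adapt {
  std::vector<double> ls;   // log step size per coordinate
  explicit Adapt(int n, double init = -1.0) : ls(n, init) {}
  void tune(int c, bool acc, int sweep) {
    double g = std::min(0.25, 3.0 / std::sqrt((double) sweep + 1.0));
    ls[c] += g * ((acc ? 1.0 : 0.0) - 0.44);
  }
  double step(int c) const { return std::exp(ls[c]); }
};

// ---------------------------------------------------------------------------
// prior-belief model
// ---------------------------------------------------------------------------

struct PriorModel {
  // data
  std::vector<int> item_k, kslot, off, uk, msize_all; // msize per slider
  std::vector<double> y;
  int n_items, K, n_sliders;
  std::vector<std::vector<int>> slot_items;
  std::vector<std::vector<double>> lchoose_k; // per slot: log choose(k, m), m=0..k

  // state (unconstrained)
  double h[3]; // log kappa, log w, log sigma2
  std::vector<std::vector<double>> theta, mu;   // per slot
  std::vector<std::vector<double>> eta, p, logp; // per item
  std::vector<std::vector<double>> l;           // logit(Q) per slider, per item

  // caches
  std::vector<double> Syy, Sll, Syl, Sdir; // per item; Sdir = sum_c mu_c log p_c
  std::vector<double> G;                   // per slot: sum_c lgamma(w mu_c)
  std::vector<double> muJac;               // per slot: sum_c log mu_c
  double TSyy, TSll, TSyl;                 // totals over items
  std::vector<double> TSdir;               // per slot totals of Sdir

  double kappa() const { return std::exp(h[0]); }
  double w() const { return std::exp(h[1]); }
  double sig2() const { return std::exp(h[2]); }

  void compute_item(int i, const std::vector<double> &pi,
                    std::vector<double> &li, double &syy, double &sll,
                    double &syl, double &sdir,
                    const std::vector<double> &logpi) const {
    int s = kslot[i], k = uk[s], n = 1 << k;
    li.resize(n);
    syy = sll = syl = 0.0;
    for (int st = 0; st < n; ++st) {
      int m = msize_all[off[i] + st];
      double lg = clip_logit(std::exp(logpi[m] - lchoose_k[s][m]));
      li[st] = lg;
      double yy = y[off[i] + st];
      syy += yy * yy; sll += lg * lg; syl += yy * lg;
    }
    sdir = 0.0;
    for (size_t c = 0; c < mu[s].size(); ++c) sdir += mu[s][c] * logpi[c];
  }

  double lik_total() const {
    double kap = kappa(), s2 = sig2();
    double R2 = TSyy - 2.0 * kap * TSyl + kap * kap * TSll;
    return -0.5 * n_sliders * std::log(2.0 * M_PI * s2) - R2 / (2.0 * s2);
  }

  // Dirichlet population terms in eta space: the alr Jacobian sum(log p)
  // cancels the density's (-1) exponents exactly, leaving w * sum(mu log p)
  // plus mu-dependent normalizing constants
  double dir_total() const {
    double out = 0.0, ww = w();
    for (int s = 0; s < K; ++s)
      out += ww * TSdir[s] - (double) slot_items[s].size() * G[s] +
             (double) slot_items[s].size() * R::lgammafn(ww);
    return out;
  }
};

static double gauss_lik(double n, double Syy, double Sll, double Syl,
                        double kap, double s2) {
  double R2 = Syy - 2.0 * kap * Syl + kap * kap * Sll;
  return -0.5 * n * std::log(2.0 * M_PI * s2) - R2 / (2.0 * s2);
}

// [[Rcpp::export]]
List mcmc_prior_cpp(IntegerVector item_k, IntegerVector kslot,
                    IntegerVector item_off, NumericVector y,
                    IntegerVector msize, IntegerVector uk,
                    int n_iter, int n_warmup, int thin, double init_jitter) {
  PriorModel M;
  M.item_k = as<std::vector<int>>(item_k);
  M.kslot = as<std::vector<int>>(kslot);
  M.off = as<std::vector<int>>(item_off);
  M.uk = as<std::vector<int>>(uk);
  M.msize_all = as<std::vector<int>>(msize);
  M.y = as<std::vector<double>>(y);
  M.n_items = (int) M.item_k.size();
  M.K = (int) M.uk.size();
  M.n_sliders = (int) M.y.size();
  M.slot_items.resize(M.K);
  for (int i = 0; i < M.n_items; ++i) M.slot_items[M.kslot[i]].push_back(i);
  M.lchoose_k.resize(M.K);
  for (int s = 0; s < M.K; ++s) {
    int k = M.uk[s];
    M.lchoose_k[s].resize(k + 1);
    for (int m = 0; m <= k; ++m) M.lchoose_k[s][m] = R::lchoose(k, m);
  }

  RNGScope scope;
  // init
  M.h[0] = 0.0 + init_jitter * norm_rand();
  M.h[1] = std::log(10.0) + init_jitter * norm_rand();
  M.h[2] = std::log(0.5) + init_jitter * norm_rand();
  M.theta.resize(M.K); M.mu.resize(M.K);
  for (int s = 0; s < M.K; ++s) {
    M.theta[s].assign(M.uk[s], 0.0);
    for (double &t : M.theta[s]) t = init_jitter * norm_rand();
    alr_to_simplex(M.theta[s], M.mu[s]);
  }
  M.eta.resize(M.n_items); M.p.resize(M.n_items); M.logp.resize(M.n_items);
  M.l.resize(M.n_items);
  M.Syy.assign(M.n_items, 0); M.Sll.assign(M.n_items, 0);
  M.Syl.assign(M.n_items, 0); M.Sdir.assign(M.n_items, 0);
  for (int i = 0; i < M.n_items; ++i) {
    M.eta[i].assign(M.item_k[i], 0.0);
    for (double &e : M.eta[i]) e = init_jitter * norm_rand();
    alr_to_simplex(M.eta[i], M.p[i]);
    M.logp[i].resize(M.p[i].size());
    for (size_t c = 0; c < M.p[i].size(); ++c) M.logp[i][c] = std::log(M.p[i][c]);
  }
  M.G.assign(M.K, 0); M.muJac.assign(M.K, 0); M.TSdir.assign(M.K, 0);
  M.TSyy = M.TSll = M.TSyl = 0;
  for (int s = 0; s < M.K; ++s) {
    M.G[s] = 0; M.muJac[s] = 0;
    for (double m : M.mu[s]) {
      M.G[s] += R::lgammafn(M.w() * m);
      M.muJac[s] += std::log(m);
    }
  }
  for (int i = 0; i < M.n_items; ++i) {
    M.compute_item(i, M.p[i], M.l[i], M.Syy[i], M.Sll[i], M.Syl[i], M.Sdir[i],
                   M.logp[i]);
    M.TSyy += M.Syy[i]; M.TSll += M.Sll[i]; M.TSyl += M.Syl[i];
    M.TSdir[M.kslot[i]] += M.Sdir[i];
  }

  // coordinate bookkeeping: 3 hypers, theta coords, eta coords
  int n_theta = 0, n_eta = 0;
  for (int s = 0; s < M.K; ++s) n_theta += M.uk[s];
  for (int i = 0; i < M.n_items; ++i) n_eta += M.item_k[i];
  Adapt ad(3 + n_theta + n_eta, -1.0);

  int n_keep = 0;
  for (int it = n_warmup; it < n_iter; ++it) if ((it - n_warmup) % thin == 0) ++n_keep;
  int n_mu_cols = 0;
  for (int s = 0; s < M.K; ++s) n_mu_cols += M.uk[s] + 1;
  int n_p_cols = 0;
  for (int i = 0; i < M.n_items; ++i) n_p_cols += M.item_k[i] + 1;
  NumericMatrix draws(n_keep, 3 + n_mu_cols + n_p_cols);
  NumericMatrix mu_pred(n_keep, M.n_sliders);
  long n_acc = 0, n_prop = 0;

  int keep_row = 0;
  for (int it = 0; it < n_iter; ++it) {
    bool warm = it < n_warmup;
    int ci = 0;
    double kap = M.kappa(), ww = M.w(), s2 = M.sig2();

    // --- log kappa ---
    {
      double cur = lp_gamma(kap, 5, 5) + M.h[0] + M.lik_total();
      double h0 = M.h[0], hp = h0 + ad.step(ci) * norm_rand();
      double kp = std::exp(hp);
      double R2 = M.TSyy - 2.0 * kp * M.TSyl + kp * kp * M.TSll;
      double prop = lp_gamma(kp, 5, 5) + hp -
        0.5 * M.n_sliders * std::log(2.0 * M_PI * s2) - R2 / (2.0 * s2);
      bool acc = std::log(unif_rand()) < prop - cur;
      if (acc) { M.h[0] = hp; kap = kp; }
      ++n_prop; n_acc += acc; if (warm) ad.tune(ci, acc, it);
      ++ci;
    }
    // --- log w ---
    {
      double cur = lp_gamma(ww, 2, 0.1) + M.h[1] + M.dir_total();
      double h1 = M.h[1], hp = h1 + ad.step(ci) * norm_rand();
      double wp = std::exp(hp);
      // recompute G under wp
      std::vector<double> Gp(M.K, 0.0);
      double dirp = 0.0;
      for (int s = 0; s < M.K; ++s) {
        for (double m : M.mu[s]) Gp[s] += R::lgammafn(wp * m);
        dirp += wp * M.TSdir[s] - (double) M.slot_items[s].size() * Gp[s] +
                (double) M.slot_items[s].size() * R::lgammafn(wp);
      }
      double prop = lp_gamma(wp, 2, 0.1) + hp + dirp;
      bool acc = std::log(unif_rand()) < prop - cur;
      if (acc) { M.h[1] = hp; ww = wp; M.G = Gp; }
      ++n_prop; n_acc += acc; if (warm) ad.tune(ci, acc, it);
      ++ci;
    }
    // --- log sigma2 ---
    {
      double cur = lp_invgamma(s2, 1, 1) + M.h[2] + M.lik_total();
      double h2 = M.h[2], hp = h2 + ad.step(ci) * norm_rand();
      double sp = std::exp(hp);
      double R2 = M.TSyy - 2.0 * kap * M.TSyl + kap * kap * M.TSll;
      double prop = lp_invgamma(sp, 1, 1) + hp -
        0.5 * M.n_sliders * std::log(2.0 * M_PI * sp) - R2 / (2.0 * sp);
      bool acc = std::log(unif_rand()) < prop - cur;
      if (acc) { M.h[2] = hp; s2 = sp; }
      ++n_prop; n_acc += acc; if (warm) ad.tune(ci, acc, it);
      ++ci;
    }
    // --- theta coordinates (population size-class means) ---
    for (int s = 0; s < M.K; ++s) {
      for (int c = 0; c < M.uk[s]; ++c) {
        double cur = M.muJac[s] - (double) M.slot_items[s].size() * M.G[s];
        for (int i : M.slot_items[s]) cur += ww * M.Sdir[i];
        double old = M.theta[s][c];
        M.theta[s][c] = old + ad.step(ci) * norm_rand();
        std::vector<double> mup;
        alr_to_simplex(M.theta[s], mup);
        double Gp = 0.0, jac = 0.0;
        for (double m : mup) { Gp += R::lgammafn(ww * m); jac += std::log(m); }
        double prop = jac - (double) M.slot_items[s].size() * Gp;
        std::vector<double> Sdirp(M.slot_items[s].size());
        for (size_t ii = 0; ii < M.slot_items[s].size(); ++ii) {
          int i = M.slot_items[s][ii];
          double sd = 0.0;
          for (size_t cc = 0; cc < mup.size(); ++cc)
            sd += mup[cc] * M.logp[i][cc];
          Sdirp[ii] = sd;
          prop += ww * sd;
        }
        bool acc = std::log(unif_rand()) < prop - cur;
        if (acc) {
          M.mu[s] = mup; M.G[s] = Gp; M.muJac[s] = jac;
          double ts = 0.0;
          for (size_t ii = 0; ii < M.slot_items[s].size(); ++ii) {
            int i = M.slot_items[s][ii];
            M.Sdir[i] = Sdirp[ii]; ts += Sdirp[ii];
          }
          M.TSdir[s] = ts;
        } else {
          M.theta[s][c] = old;
        }
        ++n_prop; n_acc += acc; if (warm) ad.tune(ci, acc, it);
        ++ci;
      }
    }
    // --- eta coordinates (participant beliefs) ---
    for (int i = 0; i < M.n_items; ++i) {
      int s = M.kslot[i];
      for (int c = 0; c < M.item_k[i]; ++c) {
        double cur = ww * M.Sdir[i] +
          gauss_lik(1 << M.uk[s], M.Syy[i], M.Sll[i], M.Syl[i], kap, s2);
        double old = M.eta[i][c];
        M.eta[i][c] = old + ad.step(ci) * norm_rand();
        std::vector<double> pp, lpp, lip;
        alr_to_simplex(M.eta[i], pp);
        lpp.resize(pp.size());
        for (size_t cc = 0; cc < pp.size(); ++cc) lpp[cc] = std::log(pp[cc]);
        double syy, sll, syl, sdir;
        M.compute_item(i, pp, lip, syy, sll, syl, sdir, lpp);
        double prop = ww * sdir +
          gauss_lik(1 << M.uk[s], syy, sll, syl, kap, s2);
        bool acc = std::log(unif_rand()) < prop - cur;
        if (acc) {
          M.TSyy += syy - M.Syy[i]; M.TSll += sll - M.Sll[i];
          M.TSyl += syl - M.Syl[i]; M.TSdir[s] += sdir - M.Sdir[i];
          M.p[i] = pp; M.logp[i] = lpp; M.l[i] = lip;
          M.Syy[i] = syy; M.Sll[i] = sll; M.Syl[i] = syl; M.Sdir[i] = sdir;
        } else {
          M.eta[i][c] = old;
        }
        ++n_prop; n_acc += acc; if (warm) ad.tune(ci, acc, it);
        ++ci;
      }
    }

    // --- store ---
    if (!warm && (it - n_warmup) % thin == 0) {
      int col = 0;
      draws(keep_row, col++) = M.kappa();
      draws(keep_row, col++) = M.w();
      draws(keep_row, col++) = M.sig2();
      for (int s = 0; s < M.K; ++s)
        for (double m : M.mu[s]) draws(keep_row, col++) = m;
      for (int i = 0; i < M.n_items; ++i)
        for (double pc : M.p[i]) draws(keep_row, col++) = pc;
      double kapn = M.kappa();
      for (int i = 0; i < M.n_items; ++i)
        for (size_t st = 0; st < M.l[i].size(); ++st)
          mu_pred(keep_row, M.off[i] + st) = kapn * M.l[i][st];
      ++keep_row;
    }
  }

  return List::create(_["draws"] = draws, _["mu_pred"] = mu_pred,
                      _["accept_rate"] = (double) n_acc / (double) n_prop);
}

// ---------------------------------------------------------------------------
// posterior-belief model
// ---------------------------------------------------------------------------

// logit of Q_post over the focus-compatible states (odd bitmasks), given a
// size-class simplex p (length k + 1) and rationality alpha, under the
// focus-only-plus-null zero-cost lexicon
static void bridge_logit(int k, const std::vector<double> &p, double alpha,
                         const std::vector<double> &lchoose,
                         std::vector<double> &lout) {
  int n = 1 << k, nc = n >> 1;
  std::vector<double> lq(n), lmass(n);
  std::vector<double> Qf(n);
  for (int i = 0; i < n; ++i) {
    int m = popcount(i);
    lq[i] = std::log(p[m]) - lchoose[m];
    Qf[i] = std::exp(lq[i]);
  }
  for (int e = 1; e < n; ++e) {
    double ms = 0.0;
    for (int i = e; i < n; ++i) if ((i & e) == e) ms += Qf[i];
    lmass[e] = std::log(ms);
  }
  std::vector<double> wgt(nc);
  double tot = 0.0;
  for (int ii = 0; ii < nc; ++ii) {
    int i = 2 * ii + 1;           // compatible state: mentioned bit set
    double den = std::exp(alpha * lq[i]);  // null message, mass 1
    for (int e = i; e > 0; e = (e - 1) & i)
      den += std::exp(alpha * (lq[i] - lmass[e]));
    double num = std::exp(alpha * (lq[i] - lmass[1]));
    wgt[ii] = (num / den) * Qf[i];
    tot += wgt[ii];
  }
  lout.resize(nc);
  for (int ii = 0; ii < nc; ++ii) lout[ii] = clip_logit(wgt[ii] / tot);
}

struct PostModel {
  std::vector<int> item_k, kslot, item_part, off, uk;
  std::vector<double> y;
  std::vector<std::vector<double>> mu_fix, lchoose_k;
  double w_fix;
  int n_items, K, J, n_sliders;
  std::vector<std::vector<int>> part_items;

  double h[4]; // log kappa, log sigma2, log mu_alpha, log sigma2_alpha
  std::vector<double> a;                    // log alpha_j
  std::vector<std::vector<double>> eta, p, logp, l;
  std::vector<double> Syy, Sll, Syl, Sdir;
  double TSyy, TSll, TSyl;

  double kappa() const { return std::exp(h[0]); }
  double sig2() const { return std::exp(h[1]); }
  double mu_a() const { return std::exp(h[2]); }
  double s2_a() const { return std::exp(h[3]); }

  double lik_total() const {
    double kap = kappa(), s2 = sig2();
    double R2 = TSyy - 2.0 * kap * TSyl + kap * kap * TSll;
    return -0.5 * n_sliders * std::log(2.0 * M_PI * s2) - R2 / (2.0 * s2);
  }

  double lp_alpha(double aj_log) const {
    double ma = mu_a(), sa = s2_a();
    double shape = ma * ma / sa, rate = ma / sa;
    return lp_gamma(std::exp(aj_log), shape, rate) + aj_log;
  }

  void item_stats(int i, const std::vector<double> &pi, double alpha,
                  std::vector<double> &li, double &syy, double &sll,
                  double &syl) const {
    int s = kslot[i], k = uk[s];
    bridge_logit(k, pi, alpha, lchoose_k[s], li);
    syy = sll = syl = 0.0;
    for (size_t st = 0; st < li.size(); ++st) {
      double yy = y[off[i] + st];
      syy += yy * yy; sll += li[st] * li[st]; syl += yy * li[st];
    }
  }

  // Dirichlet term in eta space (alr Jacobian cancels the -1 exponents)
  double item_dir(int i, const std::vector<double> &logpi) const {
    int s = kslot[i];
    double out = R::lgammafn(w_fix), sd = 0.0;
    for (size_t c = 0; c < logpi.size(); ++c) {
      sd += mu_fix[s][c] * logpi[c];
      out -= R::lgammafn(w_fix * mu_fix[s][c]);
    }
    return out + w_fix * sd;
  }
};

// [[Rcpp::export]]
List mcmc_post_cpp(IntegerVector item_k, IntegerVector kslot,
                   IntegerVector item_part, IntegerVector item_off,
                   NumericVector y, IntegerVector uk, List mu_fixed,
                   double w_fixed, int n_part,
                   int n_iter, int n_warmup, int thin, double init_jitter) {
  PostModel M;
  M.item_k = as<std::vector<int>>(item_k);
  M.kslot = as<std::vector<int>>(kslot);
  M.item_part = as<std::vector<int>>(item_part);
  M.off = as<std::vector<int>>(item_off);
  M.uk = as<std::vector<int>>(uk);
  M.y = as<std::vector<double>>(y);
  M.w_fix = w_fixed;
  M.n_items = (int) M.item_k.size();
  M.K = (int) M.uk.size();
  M.J = n_part;
  M.n_sliders = (int) M.y.size();
  M.part_items.resize(M.J);
  for (int i = 0; i < M.n_items; ++i) M.part_items[M.item_part[i]].push_back(i);
  M.mu_fix.resize(M.K); M.lchoose_k.resize(M.K);
  for (int s = 0; s < M.K; ++s) {
    M.mu_fix[s] = as<std::vector<double>>(mu_fixed[s]);
    int k = M.uk[s];
    M.lchoose_k[s].resize(k + 1);
    for (int m = 0; m <= k; ++m) M.lchoose_k[s][m] = R::lchoose(k, m);
  }

  RNGScope scope;
  M.h[0] = 0.0 + init_jitter * norm_rand();
  M.h[1] = std::log(0.5) + init_jitter * norm_rand();
  M.h[2] = 0.0 + init_jitter * norm_rand();
  M.h[3] = 0.0 + init_jitter * norm_rand();
  M.a.assign(M.J, 0.0);
  for (double &aa : M.a) aa = init_jitter * norm_rand();
  M.eta.resize(M.n_items); M.p.resize(M.n_items); M.logp.resize(M.n_items);
  M.l.resize(M.n_items);
  M.Syy.assign(M.n_items, 0); M.Sll.assign(M.n_items, 0);
  M.Syl.assign(M.n_items, 0);
  M.TSyy = M.TSll = M.TSyl = 0;
  for (int i = 0; i < M.n_items; ++i) {
    M.eta[i].assign(M.item_k[i], 0.0);
    for (double &e : M.eta[i]) e = init_jitter * norm_rand();
    alr_to_simplex(M.eta[i], M.p[i]);
    M.logp[i].resize(M.p[i].size());
    for (size_t c = 0; c < M.p[i].size(); ++c) M.logp[i][c] = std::log(M.p[i][c]);
    M.item_stats(i, M.p[i], std::exp(M.a[M.item_part[i]]), M.l[i],
                 M.Syy[i], M.Sll[i], M.Syl[i]);
    M.TSyy += M.Syy[i]; M.TSll += M.Sll[i]; M.TSyl += M.Syl[i];
  }

  int n_eta = 0;
  for (int i = 0; i < M.n_items; ++i) n_eta += M.item_k[i];
  Adapt ad(4 + M.J + n_eta, -1.0);

  int n_keep = 0;
  for (int it = n_warmup; it < n_iter; ++it) if ((it - n_warmup) % thin == 0) ++n_keep;
  int n_p_cols = 0;
  for (int i = 0; i < M.n_items; ++i) n_p_cols += M.item_k[i] + 1;
  NumericMatrix draws(n_keep, 4 + M.J + n_p_cols);
  NumericMatrix mu_pred(n_keep, M.n_sliders);
  long n_acc = 0, n_prop = 0;

  int keep_row = 0;
  for (int it = 0; it < n_iter; ++it) {
    bool warm = it < n_warmup;
    int ci = 0;
    double kap = M.kappa(), s2 = M.sig2();

    // --- log kappa ---
    {
      double cur = lp_gamma(kap, 5, 5) + M.h[0] + M.lik_total();
      double hp = M.h[0] + ad.step(ci) * norm_rand();
      double kp = std::exp(hp);
      double R2 = M.TSyy - 2.0 * kp * M.TSyl + kp * kp * M.TSll;
      double prop = lp_gamma(kp, 5, 5) + hp -
        0.5 * M.n_sliders * std::log(2.0 * M_PI * s2) - R2 / (2.0 * s2);
      bool acc = std::log(unif_rand()) < prop - cur;
      if (acc) { M.h[0] = hp; kap = kp; }
      ++n_prop; n_acc += acc; if (warm) ad.tune(ci, acc, it);
      ++ci;
    }
    // --- log sigma2 ---
    {
      double cur = lp_invgamma(s2, 1, 1) + M.h[1] + M.lik_total();
      double hp = M.h[1] + ad.step(ci) * norm_rand();
      double sp = std::exp(hp);
      double R2 = M.TSyy - 2.0 * kap * M.TSyl + kap * kap * M.TSll;
      double prop = lp_invgamma(sp, 1, 1) + hp -
        0.5 * M.n_sliders * std::log(2.0 * M_PI * sp) - R2 / (2.0 * sp);
      bool acc = std::log(unif_rand()) < prop - cur;
      if (acc) { M.h[1] = hp; s2 = sp; }
      ++n_prop; n_acc += acc; if (warm) ad.tune(ci, acc, it);
      ++ci;
    }
    // --- log mu_alpha and log sigma2_alpha ---
    for (int hc = 2; hc <= 3; ++hc) {
      double cur = (hc == 2 ? lp_gamma(M.mu_a(), 5, 5) + M.h[2]
                            : lp_invgamma(M.s2_a(), 1, 1) + M.h[3]);
      for (int j = 0; j < M.J; ++j) cur += M.lp_alpha(M.a[j]);
      double old = M.h[hc];
      M.h[hc] = old + ad.step(ci) * norm_rand();
      double prop = (hc == 2 ? lp_gamma(M.mu_a(), 5, 5) + M.h[2]
                             : lp_invgamma(M.s2_a(), 1, 1) + M.h[3]);
      for (int j = 0; j < M.J; ++j) prop += M.lp_alpha(M.a[j]);
      bool acc = std::log(unif_rand()) < prop - cur;
      if (!acc) M.h[hc] = old;
      ++n_prop; n_acc += acc; if (warm) ad.tune(ci, acc, it);
      ++ci;
    }
    // --- log alpha_j ---
    for (int j = 0; j < M.J; ++j) {
      double cur = M.lp_alpha(M.a[j]);
      for (int i : M.part_items[j])
        cur += gauss_lik((double) (1 << (M.uk[M.kslot[i]] - 1)),
                         M.Syy[i], M.Sll[i], M.Syl[i], kap, s2);
      double old = M.a[j];
      M.a[j] = old + ad.step(ci) * norm_rand();
      double alp = std::exp(M.a[j]);
      double prop = M.lp_alpha(M.a[j]);
      std::vector<std::vector<double>> lis(M.part_items[j].size());
      std::vector<double> syyv, sllv, sylv;
      for (size_t ii = 0; ii < M.part_items[j].size(); ++ii) {
        int i = M.part_items[j][ii];
        double syy, sll, syl;
        M.item_stats(i, M.p[i], alp, lis[ii], syy, sll, syl);
        syyv.push_back(syy); sllv.push_back(sll); sylv.push_back(syl);
        prop += gauss_lik((double) (1 << (M.uk[M.kslot[i]] - 1)),
                          syy, sll, syl, kap, s2);
      }
      bool acc = std::log(unif_rand()) < prop - cur;
      if (acc) {
        for (size_t ii = 0; ii < M.part_items[j].size(); ++ii) {
          int i = M.part_items[j][ii];
          M.TSyy += syyv[ii] - M.Syy[i]; M.TSll += sllv[ii] - M.Sll[i];
          M.TSyl += sylv[ii] - M.Syl[i];
          M.Syy[i] = syyv[ii]; M.Sll[i] = sllv[ii]; M.Syl[i] = sylv[ii];
          M.l[i] = lis[ii];
        }
      } else {
        M.a[j] = old;
      }
      ++n_prop; n_acc += acc; if (warm) ad.tune(ci, acc, it);
      ++ci;
    }
    // --- eta coordinates ---
    for (int i = 0; i < M.n_items; ++i) {
      int s = M.kslot[i];
      double alp = std::exp(M.a[M.item_part[i]]);
      double nslid = (double) (1 << (M.uk[s] - 1));
      for (int c = 0; c < M.item_k[i]; ++c) {
        double cur = M.item_dir(i, M.logp[i]) +
          gauss_lik(nslid, M.Syy[i], M.Sll[i], M.Syl[i], kap, s2);
        double old = M.eta[i][c];
        M.eta[i][c] = old + ad.step(ci) * norm_rand();
        std::vector<double> pp, lpp, lip;
        alr_to_simplex(M.eta[i], pp);
        lpp.resize(pp.size());
        for (size_t cc = 0; cc < pp.size(); ++cc) lpp[cc] = std::log(pp[cc]);
        double syy, sll, syl;
        M.item_stats(i, pp, alp, lip, syy, sll, syl);
        double prop = M.item_dir(i, lpp) +
          gauss_lik(nslid, syy, sll, syl, kap, s2);
        bool acc = std::log(unif_rand()) < prop - cur;
        if (acc) {
          M.TSyy += syy - M.Syy[i]; M.TSll += sll - M.Sll[i];
          M.TSyl += syl - M.Syl[i];
          M.p[i] = pp; M.logp[i] = lpp; M.l[i] = lip;
          M.Syy[i] = syy; M.Sll[i] = sll; M.Syl[i] = syl;
        } else {
          M.eta[i][c] = old;
        }
        ++n_prop; n_acc += acc; if (warm) ad.tune(ci, acc, it);
        ++ci;
      }
    }

    if (!warm && (it - n_warmup) % thin == 0) {
      int col = 0;
      draws(keep_row, col++) = M.kappa();
      draws(keep_row, col++) = M.sig2();
      draws(keep_row, col++) = M.mu_a();
      draws(keep_row, col++) = M.s2_a();
      for (int j = 0; j < M.J; ++j) draws(keep_row, col++) = std::exp(M.a[j]);
      for (int i = 0; i < M.n_items; ++i)
        for (double pc : M.p[i]) draws(keep_row, col++) = pc;
      double kapn = M.kappa();
      for (int i = 0; i < M.n_items; ++i)
        for (size_t st = 0; st < M.l[i].size(); ++st)
          mu_pred(keep_row, M.off[i] + st) = kapn * M.l[i][st];
      ++keep_row;
    }
  }

  return List::create(_["draws"] = draws, _["mu_pred"] = mu_pred,
                      _["accept_rate"] = (double) n_acc / (double) n_prop);
}
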