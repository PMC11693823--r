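// Log posteriors (with analytic gradients) and a No-U-Turn sampler for the
// package's Bayesian models:
//  * the multilevel cumulative-logit (ordinal) item-response model of word
//    acquisition, with non-centered random effects, truncated-normal random
//    effect SD priors and LKJ(2) priors on the Cholesky factors of the
//    random-effect correlation matrices;
//  * a Gaussian linear model used by the syllabic-frequency control analysis.
// All randomness goes through R's RNG so runs are reproducible via set.seed().

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <limits>
#include <algorithm>

using namespace Rcpp;

static const double NEG_INF = -std::numeric_limits<double>::infinity();
static const double LOG_SQRT_2PI = 0.9189385332046727417803297364;

static inline double log_sigmoid(double x) {
  if (x > 0.0) return -log1p(std::exp(-x));
  return x - log1p(std::exp(x));
}

static inline double sigmoid(double x) {
  if (x >= 0.0) {
    double e = std::exp(-x);
    return 1.0 / (1.0 + e);
  }
  double e = std::exp(x);
  return e / (1.0 + e);
}

static inline double dnorm_lp(double x, double mu, double sd) {
  double z = (x - mu) / sd;
  return -0.5 * z * z - std::log(sd) - LOG_SQRT_2PI;
}

// ---------------------------------------------------------------------------
// LKJ(2) correlation block via the tanh stick-breaking Cholesky transform.
// Unconstrained vector y (row-major, rows i = 1..K-1, entries j = 0..i-1)
// maps to a lower-triangular Cholesky factor L with unit-norm rows. build()
// returns the LKJ(2) log density of L plus the log-Jacobian of the
// transform; grad() back-propagates d(logp)/dL into d(logp)/dy.
// ---------------------------------------------------------------------------
struct CorrBlock {
  int K;
  std::vector<double> zc, wc, L;

  explicit CorrBlock(int K_) : K(K_), zc(K_ * K_), wc(K_ * K_), L(K_ * K_, 0.0) {}

  int nfree() const { return K * (K - 1) / 2; }

  double build(const double* y) {
    double lp = 0.0;
    std::fill(L.begin(), L.end(), 0.0);
    L[0] = 1.0;
    int idx = 0;
    for (int i = 1; i < K; ++i) {
      double w = 1.0;
      for (int j = 0; j < i; ++j, ++idx) {
        double z = std::tanh(y[idx]);
        zc[i * K + j] = z;
        wc[i * K + j] = w;
        double Lij = z * std::sqrt(w);
        L[i * K + j] = Lij;
        double one_m_z2 = 1.0 - z * z;
        if (one_m_z2 <= 0.0) return NEG_INF;
        lp += std::log(one_m_z2) + 0.5 * std::log(w);
        w -= Lij * Lij;
        if (w < 1e-16) w = 1e-16;
      }
      wc[i * K + i] = w;
      double Lii = std::sqrt(w);
      L[i * K + i] = Lii;
      // LKJ(eta = 2) density on the Cholesky factor.
      lp += (K - i + 1) * std::log(Lii);
    }
    return lp;
  }

  // GL holds d(logp_data)/dL for the lower triangle including the diagonal.
  void grad(const double* GL, double* gy) const {
    int base = 0;
    for (int i = 1; i < K; ++i) {
      for (int js = 0; js < i; ++js) {
        double g = 0.0;
        double w = wc[i * K + js];
        double dw = 0.0;
        for (int j = js; j < i; ++j) {
          double z = zc[i * K + j];
          double sw = std::sqrt(w);
          double dsw = dw / (2.0 * sw);
          double Lij = z * sw;
          double dL;
          if (j == js) {
            double dz = 1.0 - z * z;      // dz/dy at the active element
            dL = dz * sw;                  // dw = 0 here
            g += GL[i * K + j] * dL;
            g += -2.0 * z;                 // d log(1 - z^2) / dy
          } else {
            dL = z * dsw;
            g += GL[i * K + j] * dL;
            g += 0.5 * dw / w;             // d 0.5 log(w) / dy
          }
          w -= Lij * Lij;
          dw -= 2.0 * Lij * dL;
          if (w < 1e-16) w = 1e-16;
        }
        double sw = std::sqrt(w);
        double dsw = dw / (2.0 * sw);
        g += GL[i * K + i] * dsw;
        g += (K - i + 1) * dsw / sw;
        gy[base + js] += g;
      }
      base += i;
    }
  }
};

// ---------------------------------------------------------------------------
// Generic model interface for the sampler.
// ---------------------------------------------------------------------------
struct Model {
  virtual ~Model() {}
  virtual int dim() const = 0;
  virtual double logp_grad(const std::vector<double>& q,
                           std::vector<double>& grad) = 0;
};

// ---------------------------------------------------------------------------
// Ordinal item-response model.
// Unconstrained parameters, in order:
//   tau1, log(tau2 - tau1), beta (P), then per random-effect block
//   log-sd (K) and correlation unconstrained (K(K-1)/2), then per block the
//   standard-normal deviates u (G x K, row-major by group).
// Priors: tau_k ~ N(-0.25, 0.50); beta ~ N(0, 1); sd ~ N+(1, 0.25);
//   corr ~ LKJ(2); u ~ N(0, 1). Likelihood: cumulative logit over
//   {No < Understands < Understands-and-Says}.
// ---------------------------------------------------------------------------
struct REData {
  int K = 0, G = 0;
  std::vector<int> gidx;     // length n, 0-based
  std::vector<double> Z;     // n x K row-major
};

struct OrdinalModel : Model {
  int n = 0, P = 0;
  std::vector<int> y;
  std::vector<double> X;     // n x P row-major
  std::vector<REData> re;
  bool with_prior = true;

  // layout
  int off_beta = 2;
  std::vector<int> off_lsig, off_ycorr, off_u;
  int D_ = 0;

  // scratch
  std::vector<CorrBlock> corr;
  std::vector<std::vector<double> > sigma, B, C, Gb, GL;

  void finalize() {
    off_lsig.clear(); off_ycorr.clear(); off_u.clear();
    corr.clear(); sigma.clear(); B.clear(); C.clear(); Gb.clear(); GL.clear();
    int off = 2 + P;
    for (size_t b = 0; b < re.size(); ++b) {
      int K = re[b].K;
      off_lsig.push_back(off); off += K;
      off_ycorr.push_back(off); off += K * (K - 1) / 2;
      corr.push_back(CorrBlock(K));
      sigma.push_back(std::vector<double>(K));
      B.push_back(std::vector<double>(re[b].G * K));
      C.push_back(std::vector<double>(re[b].G * K));
      Gb.push_back(std::vector<double>(re[b].G * K));
      GL.push_back(std::vector<double>(K * K));
    }
    for (size_t b = 0; b < re.size(); ++b) {
      off_u.push_back(off);
      off += re[b].G * re[b].K;
    }
    D_ = off;
  }

  int dim() const { return D_; }

  double logp_grad(const std::vector<double>& q, std::vector<double>& grad) {
    std::fill(grad.begin(), grad.end(), 0.0);
    double lp = 0.0;

    double tau1 = q[0], ld = q[1];
    if (!std::isfinite(tau1) || !std::isfinite(ld) || ld > 30.0) return NEG_INF;
    double delta = std::exp(ld);
    double tau2 = tau1 + delta;
    double gtau1 = 0.0, gtau2 = 0.0;

    if (with_prior) {
      lp += dnorm_lp(tau1, -0.25, 0.5) + dnorm_lp(tau2, -0.25, 0.5) + ld;
      gtau1 += -(tau1 + 0.25) / 0.25;
      gtau2 += -(tau2 + 0.25) / 0.25;
      for (int p = 0; p < P; ++p) {
        double b = q[off_beta + p];
        lp += dnorm_lp(b, 0.0, 1.0);
        grad[off_beta + p] += -b;
      }
    }

    // Random-effect blocks: transforms, priors, group coefficients.
    for (size_t b = 0; b < re.size(); ++b) {
      int K = re[b].K, G = re[b].G;
      for (int k = 0; k < K; ++k) {
        double ls = q[off_lsig[b] + k];
        if (ls > 30.0) return NEG_INF;
        double s = std::exp(ls);
        sigma[b][k] = s;
        if (with_prior) {
          lp += dnorm_lp(s, 1.0, 0.25) + ls;   // half-normal + log-Jacobian
          grad[off_lsig[b] + k] += -(s - 1.0) / 0.0625 * s + 1.0;
        }
      }
      double lkj = corr[b].build(&q[off_ycorr[b]]);
      if (!std::isfinite(lkj)) return NEG_INF;
      if (with_prior) lp += lkj;

      const double* u = &q[off_u[b]];
      const std::vector<double>& L = corr[b].L;
      for (int g = 0; g < G; ++g) {
        for (int m = 0; m < K; ++m) {
          double acc = 0.0;
          for (int k = 0; k <= m; ++k) acc += L[m * K + k] * u[g * K + k];
          C[b][g * K + m] = acc;
          B[b][g * K + m] = sigma[b][m] * acc;
        }
      }
      if (with_prior) {
        for (int g = 0; g < G * K; ++g) {
          lp += dnorm_lp(u[g], 0.0, 1.0);
          grad[off_u[b] + g] += -u[g];
        }
      }
      std::fill(Gb[b].begin(), Gb[b].end(), 0.0);
    }

    // Likelihood.
    const double* beta = &q[off_beta];
    double em = std::expm1(delta);
    double sum_t1 = 0.0, sum_t2 = 0.0;
    for (int i = 0; i < n; ++i) {
      double eta = 0.0;
      const double* xi = &X[(size_t)i * P];
      for (int p = 0; p < P; ++p) eta += xi[p] * beta[p];
      for (size_t b = 0; b < re.size(); ++b) {
        int K = re[b].K;
        const double* zi = &re[b].Z[(size_t)i * K];
        const double* Bg = &B[b][(size_t)re[b].gidx[i] * K];
        for (int m = 0; m < K; ++m) eta += zi[m] * Bg[m];
      }
      double a = tau1 - eta, bb = tau2 - eta;
      double lpi, dt1 = 0.0, dt2 = 0.0;
      int yi = y[i];
      if (yi == 0) {
        lpi = log_sigmoid(a);
        dt1 = sigmoid(-a);
      } else if (yi == 2) {
        lpi = log_sigmoid(-bb);
        dt2 = -sigmoid(bb);
      } else {
        double ls_a = log_sigmoid(a), ls_mb = log_sigmoid(-bb);
        lpi = ls_a + ls_mb + std::log(em);
        // stable ratios: d1/p and d2/p with p = s(a)(1-s(bb))expm1(delta)
        dt1 = -std::exp(log_sigmoid(-a) - ls_mb) / em;
        dt2 = std::exp(log_sigmoid(bb) - ls_a) / em;
      }
      if (!std::isfinite(lpi)) return NEG_INF;
      lp += lpi;
      sum_t1 += dt1;
      sum_t2 += dt2;
      double geta = -(dt1 + dt2);
      for (int p = 0; p < P; ++p) grad[off_beta + p] += geta * xi[p];
      for (size_t b = 0; b < re.size(); ++b) {
        int K = re[b].K;
        const double* zi = &re[b].Z[(size_t)i * K];
        double* Gbg = &Gb[b][(size_t)re[b].gidx[i] * K];
        for (int m = 0; m < K; ++m) Gbg[m] += geta * zi[m];
      }
    }

    gtau1 += sum_t1;
    gtau2 += sum_t2;
    grad[0] += gtau1 + gtau2;
    grad[1] += gtau2 * delta + (with_prior ? 1.0 : 0.0);

    // Back-propagate through the random-effect blocks.
    for (size_t b = 0; b < re.size(); ++b) {
      int K = re[b].K, G = re[b].G;
      const double* u = &q[off_u[b]];
      const std::vector<double>& L = corr[b].L;
      std::fill(GL[b].begin(), GL[b].end(), 0.0);
      for (int g = 0; g < G; ++g) {
        const double* Gbg = &Gb[b][(size_t)g * K];
        const double* ug = &u[(size_t)g * K];
        double* gu = &grad[off_u[b] + (size_t)g * K];
        for (int m = 0; m < K; ++m) {
          double gm = Gbg[m];
          if (gm == 0.0) continue;
          grad[off_lsig[b] + m] += gm * C[b][(size_t)g * K + m] * sigma[b][m];
          double sm = sigma[b][m];
          for (int k = 0; k <= m; ++k) {
            gu[k] += gm * sm * L[m * K + k];
            GL[b][m * K + k] += sm * gm * ug[k];
          }
        }
      }
      corr[b].grad(&GL[b][0], &grad[off_ycorr[b]]);
    }
    return lp;
  }
};

// ---------------------------------------------------------------------------
// Gaussian linear model (syllabic-frequency control analysis).
// Parameters: beta (P, including any intercept column of X), log sigma.
// Priors: beta_p ~ N(prior_mean_p, prior_sd_p); sigma ~ N+(1, 0.25).
// ---------------------------------------------------------------------------
struct GaussianModel : Model {
  int n = 0, P = 0;
  std::vector<double> y, X, prior_mean, prior_sd;

  int dim() const { return P + 1; }

  double logp_grad(const std::vector<double>& q, std::vector<double>& grad) {
    std::fill(grad.begin(), grad.end(), 0.0);
    double ls = q[P];
    if (!std::isfinite(ls) || ls > 30.0 || ls < -30.0) return NEG_INF;
    double s = std::exp(ls);
    double lp = dnorm_lp(s, 1.0, 0.25) + ls;
    double gls = -(s - 1.0) / 0.0625 * s + 1.0;
    for (int p = 0; p < P; ++p) {
      lp += dnorm_lp(q[p], prior_mean[p], prior_sd[p]);
      grad[p] += -(q[p] - prior_mean[p]) / (prior_sd[p] * prior_sd[p]);
    }
    double inv_s2 = 1.0 / (s * s);
    for (int i = 0; i < n; ++i) {
      double mu = 0.0;
      const double* xi = &X[(size_t)i * P];
      for (int p = 0; p < P; ++p) mu += xi[p] * q[p];
      double r = y[i] - mu;
      lp += -0.5 * r * r * inv_s2 - ls - LOG_SQRT_2PI;
      double gr = r * inv_s2;
      for (int p = 0; p < P; ++p) grad[p] += gr * xi[p];
      gls += r * r * inv_s2 - 1.0;
    }
    grad[P] += gls;
    return lp;
  }
};

// ---------------------------------------------------------------------------
// No-U-Turn sampler (slice variant) with dual-averaging step-size adaptation
// and windowed diagonal mass-matrix adaptation during warmup.
// ---------------------------------------------------------------------------
struct Nuts {
  Model& model;
  int D;
  std::vector<double> inv_mass;
  double eps = 1.0;
  int max_depth = 10;
  double adapt_delta = 0.8;

  // per-iteration state
  double logu = 0.0, H0j = 0.0;
  double alpha_sum = 0.0;
  int n_alpha = 0;
  bool divergent = false;

  explicit Nuts(Model& m) : model(m), D(m.dim()), inv_mass(m.dim(), 1.0) {}

  double joint(const std::vector<double>& p, double lp) const {
    if (!std::isfinite(lp)) return NEG_INF;
    double k = 0.0;
    for (int d = 0; d < D; ++d) k += inv_mass[d] * p[d] * p[d];
    return lp - 0.5 * k;
  }

  double leapfrog(std::vector<double>& q, std::vector<double>& p,
                  std::vector<double>& g, double step) {
    for (int d = 0; d < D; ++d) p[d] += 0.5 * step * g[d];
    for (int d = 0; d < D; ++d) q[d] += step * inv_mass[d] * p[d];
    double lp = model.logp_grad(q, g);
    for (int d = 0; d < D; ++d) p[d] += 0.5 * step * g[d];
    return lp;
  }

  bool uturn(const std::vector<double>& qm, const std::vector<double>& qp,
             const std::vector<double>& pm, const std::vector<double>& pp) const {
    double sm = 0.0, sp = 0.0;
    for (int d = 0; d < D; ++d) {
      double dq = qp[d] - qm[d];
      sm += dq * inv_mass[d] * pm[d];
      sp += dq * inv_mass[d] * pp[d];
    }
    return (sm < 0.0) || (sp < 0.0);
  }

  struct SubTree {
    std::vector<double> qm, pm, gm, qp, pp, gp, qprop;
    double lpm = 0.0, lpp = 0.0, lp_prop = 0.0;
    long n = 0;
    bool s = true;
  };

  SubTree build_tree(const std::vector<double>& q, const std::vector<double>& p,
                     const std::vector<double>& g, double lp, int depth, int dir) {
    SubTree t;
    if (depth == 0) {
      t.qm = q; t.pm = p; t.gm = g;
      double lpn = leapfrog(t.qm, t.pm, t.gm, dir * eps);
      t.lpm = lpn;
      double j = joint(t.pm, lpn);
      t.n = (std::isfinite(j) && logu <= j) ? 1 : 0;
      t.s = std::isfinite(j) && (logu < j + 1000.0);
      if (!t.s) divergent = true;
      t.qp = t.qm; t.pp = t.pm; t.gp = t.gm; t.lpp = lpn;
      t.qprop = t.qm; t.lp_prop = lpn;
      double a = std::isfinite(j) ? std::exp(std::min(0.0, j - H0j)) : 0.0;
      alpha_sum += a;
      n_alpha += 1;
      return t;
    }
    SubTree t1 = build_tree(q, p, g, lp, depth - 1, dir);
    if (!t1.s) return t1;
    SubTree t2;
    if (dir < 0) {
      t2 = build_tree(t1.qm, t1.pm, t1.gm, t1.lpm, depth - 1, dir);
      t1.qm = t2.qm; t1.pm = t2.pm; t1.gm = t2.gm; t1.lpm = t2.lpm;
    } else {
      t2 = build_tree(t1.qp, t1.pp, t1.gp, t1.lpp, depth - 1, dir);
      t1.qp = t2.qp; t1.pp = t2.pp; t1.gp = t2.gp; t1.lpp = t2.lpp;
    }
    long ntot = t1.n + t2.n;
    if (t2.n > 0 && unif_rand() * ntot < (double)t2.n) {
      t1.qprop = t2.qprop;
      t1.lp_prop = t2.lp_prop;
    }
    t1.n = ntot;
    t1.s = t2.s && !uturn(t1.qm, t1.qp, t1.pm, t1.pp);
    return t1;
  }

  void find_reasonable_eps(const std::vector<double>& q0, double lp0,
                           const std::vector<double>& g0) {
    eps = 1.0;
    std::vector<double> p(D), q, g;
    for (int d = 0; d < D; ++d) p[d] = norm_rand() / std::sqrt(inv_mass[d]);
    double j0 = joint(p, lp0);
    q = q0; g = g0;
    std::vector<double> pw = p;
    double lp = leapfrog(q, pw, g, eps);
    double j = joint(pw, lp);
    double ratio = j - j0;
    double a = (std::isfinite(ratio) && ratio > std::log(0.5)) ? 1.0 : -1.0;
    for (int it = 0; it < 50; ++it) {
      double r = std::isfinite(ratio) ? ratio : NEG_INF;
      if (a * r > -a * std::log(2.0)) {
        eps *= std::pow(2.0, a);
      } else break;
      q = q0; g = g0; pw = p;
      lp = leapfrog(q, pw, g, eps);
      j = joint(pw, lp);
      ratio = j - j0;
    }
    if (!std::isfinite(eps) || eps <= 0.0) eps = 1e-3;
  }
};

// One chain of NUTS for a given model. Returns unconstrained draws; callers
// transform to the constrained scale.
static List run_nuts(Model& model, NumericVector init, int warmup, int sampling,
                     double adapt_delta, int max_depth) {
  int D = model.dim();
  if (init.size() != D) stop("init has wrong length (expected %d)", D);
  Nuts nuts(model);
  nuts.max_depth = max_depth;
  nuts.adapt_delta = adapt_delta;

  std::vector<double> q(init.begin(), init.end());
  std::vector<double> g(D);
  double lp = model.logp_grad(q, g);
  if (!std::isfinite(lp)) stop("initial point has non-finite log posterior");

  nuts.find_reasonable_eps(q, lp, g);

  // dual averaging state
  double mu = std::log(10.0 * nuts.eps);
  double log_eps_bar = 0.0, Hbar = 0.0;
  const double gamma = 0.05, t0 = 10.0, kappa = 0.75;
  int da_count = 0;

  // mass-matrix adaptation windows (Stan-style)
  int init_buffer = 75, term_buffer = 50, base_window = 25;
  if (warmup < 150) {
    init_buffer = std::max(1, (int)std::floor(0.15 * warmup));
    term_buffer = std::max(1, (int)std::floor(0.10 * warmup));
    base_window = std::max(1, warmup - init_buffer - term_buffer);
  }
  int window_start = init_buffer;
  int window_size = base_window;
  int window_end = std::min(window_start + window_size, warmup - term_buffer);
  std::vector<double> welford_m(D, 0.0), welford_s(D, 0.0);
  long welford_n = 0;

  NumericMatrix draws(sampling, D);
  NumericVector lp_draws(sampling);
  IntegerVector depth_hits(sampling);
  int divergences = 0;
  double accept_sum = 0.0;

  int total = warmup + sampling;
  for (int iter = 0; iter < total; ++iter) {
    std::vector<double> p(D);
    for (int d = 0; d < D; ++d) p[d] = norm_rand() / std::sqrt(nuts.inv_mass[d]);
    double j0 = nuts.joint(p, lp);
    nuts.H0j = j0;
    nuts.logu = j0 - exp_rand();
    nuts.alpha_sum = 0.0;
    nuts.n_alpha = 0;
    nuts.divergent = false;

    std::vector<double> qm = q, qp = q, pm = p, pp = p, gm = g, gp = g;
    double lpm = lp, lpp = lp;
    std::vector<double> qprop = q;
    double lp_prop = lp;
    long n = 1;
    bool s = true;
    int depth = 0;
    while (s && depth < nuts.max_depth) {
      int dir = (unif_rand() < 0.5) ? -1 : 1;
      Nuts::SubTree t = (dir < 0)
        ? nuts.build_tree(qm, pm, gm, lpm, depth, -1)
        : nuts.build_tree(qp, pp, gp, lpp, depth, 1);
      if (dir < 0) { qm = t.qm; pm = t.pm; gm = t.gm; lpm = t.lpm; }
      else { qp = t.qp; pp = t.pp; gp = t.gp; lpp = t.lpp; }
      if (t.s && t.n > 0 && unif_rand() * n < (double)t.n) {
        qprop = t.qprop;
        lp_prop = t.lp_prop;
      }
      n += t.n;
      s = t.s && !nuts.uturn(qm, qp, pm, pp);
      depth += 1;
    }
    q = qprop;
    lp = model.logp_grad(q, g);   // refresh gradient at the accepted point

    double accept = (nuts.n_alpha > 0) ? nuts.alpha_sum / nuts.n_alpha : 0.0;

    if (iter < warmup) {
      // step size adaptation
      da_count += 1;
      double eta = 1.0 / (da_count + t0);
      Hbar = (1.0 - eta) * Hbar + eta * (adapt_delta - accept);
      double log_eps = mu - std::sqrt((double)da_count) / gamma * Hbar;
      double x = std::pow((double)da_count, -kappa);
      log_eps_bar = x * log_eps + (1.0 - x) * log_eps_bar;
      nuts.eps = std::exp(log_eps);

      // mass adaptation
      if (iter >= window_start && iter < warmup - term_buffer) {
        welford_n += 1;
        for (int d = 0; d < D; ++d) {
          double delta = q[d] - welford_m[d];
          welford_m[d] += delta / welford_n;
          welford_s[d] += delta * (q[d] - welford_m[d]);
        }
        if (iter + 1 == window_end) {
          if (welford_n > 1) {
            for (int d = 0; d < D; ++d) {
              double var = welford_s[d] / (welford_n - 1);
              nuts.inv_mass[d] = (welford_n / (welford_n + 5.0)) * var +
                1e-3 * (5.0 / (welford_n + 5.0));
              if (nuts.inv_mass[d] < 1e-10) nuts.inv_mass[d] = 1e-10;
            }
          }
          std::fill(welford_m.begin(), welford_m.end(), 0.0);
          std::fill(welford_s.begin(), welford_s.end(), 0.0);
          welford_n = 0;
          window_start = window_end;
          window_size *= 2;
          window_end = window_start + window_size;
          if (window_end + 2 * window_size > warmup - term_buffer) {
            window_end = warmup - term_buffer;
          }
          // restart step-size adaptation around the refreshed metric
          nuts.find_reasonable_eps(q, lp, g);
          mu = std::log(10.0 * nuts.eps);
          Hbar = 0.0;
          log_eps_bar = std::log(nuts.eps);
          da_count = 0;
        }
      }
      if (iter + 1 == warmup) nuts.eps = std::exp(log_eps_bar);
    } else {
      int k = iter - warmup;
      for (int d = 0; d < D; ++d) draws(k, d) = q[d];
      lp_draws[k] = lp;
      depth_hits[k] = depth;
      if (nuts.divergent) divergences += 1;
      accept_sum += accept;
    }
  }

  return List::create(
    _["draws"] = draws,
    _["lp"] = lp_draws,
    _["treedepth"] = depth_hits,
    _["divergences"] = divergences,
    _["accept_mean"] = sampling > 0 ? accept_sum / sampling : NA_REAL,
    _["stepsize"] = nuts.eps
  );
}

// ---------------------------------------------------------------------------
// R interface
// ---------------------------------------------------------------------------

static OrdinalModel make_ordinal_model(List data) {
  OrdinalModel m;
  IntegerVector y = data["y"];
  NumericMatrix X = data["X"];
  m.n = y.size();
  m.P = X.ncol();
  if (X.nrow() != m.n) stop("X rows must match length(y)");
  m.y.assign(y.begin(), y.end());
  m.X.resize((size_t)m.n * m.P);
  for (int i = 0; i < m.n; ++i)
    for (int p = 0; p < m.P; ++p) m.X[(size_t)i * m.P + p] = X(i, p);
  List blocks = data["re"];
  for (int b = 0; b < blocks.size(); ++b) {
    List blk = blocks[b];
    REData rd;
    IntegerVector gi = blk["group"];       // 1-based from R
    NumericMatrix Z = blk["Z"];
    rd.K = Z.ncol();
    rd.G = blk["n_groups"];
    if (gi.size() != m.n || Z.nrow() != m.n) stop("re block shape mismatch");
    rd.gidx.resize(m.n);
    for (int i = 0; i < m.n; ++i) {
      rd.gidx[i] = gi[i] - 1;
      if (rd.gidx[i] < 0 || rd.gidx[i] >= rd.G) stop("group index out of range");
    }
    rd.Z.resize((size_t)m.n * rd.K);
    for (int i = 0; i < m.n; ++i)
      for (int k = 0; k < rd.K; ++k) rd.Z[(size_t)i * rd.K + k] = Z(i, k);
    m.re.push_back(rd);
  }
  m.finalize();
  return m;
}

// [[Rcpp::export]]
int irt_n_params(List data) {
  OrdinalModel m = make_ordinal_model(data);
  return m.dim();
}

// [[Rcpp::export]]
List irt_logp_grad(List data, NumericVector q, bool with_prior = true) {
  OrdinalModel m = make_ordinal_model(data);
  m.with_prior = with_prior;
  std::vector<double> qq(q.begin(), q.end());
  std::vector<double> grad(m.dim(), 0.0);
  double lp = m.logp_grad(qq, grad);
  return List::create(_["lp"] = lp, _["grad"] = NumericVector(grad.begin(), grad.end()));
}

// [[Rcpp::export]]
List irt_nuts_chain(List data, NumericVector init, int warmup, int sampling,
                    double adapt_delta = 0.8, int max_depth = 10) {
  OrdinalModel m = make_ordinal_model(data);
  RNGScope scope;
  return run_nuts(m, init, warmup, sampling, adapt_delta, max_depth);
}

// [[Rcpp::export]]
List lm_logp_grad(NumericVector y, NumericMatrix X, NumericVector prior_mean,
                  NumericVector prior_sd, NumericVector q) {
  GaussianModel m;
  m.n = y.size();
  m.P = X.ncol();
  m.y.assign(y.begin(), y.end());
  m.X.resize((size_t)m.n * m.P);
  for (int i = 0; i < m.n; ++i)
    for (int p = 0; p < m.P; ++p) m.X[(size_t)i * m.P + p] = X(i, p);
  m.prior_mean.assign(prior_mean.begin(), prior_mean.end());
  m.prior_sd.assign(prior_sd.begin(), prior_sd.end());
  std::vector<double> qq(q.begin(), q.end());
  std::vector<double> grad(m.dim(), 0.0);
  double lp = m.logp_grad(qq, grad);
  return List::create(_["lp"] = lp, _["grad"] = NumericVector(grad.begin(), grad.end()));
}

// [[Rcpp::export]]
List lm_nuts_chain(NumericVector y, NumericMatrix X, NumericVector prior_mean,
                   NumericVector prior_sd, NumericVector init, int warmup,
                   int sampling, double adapt_delta = 0.8, int max_depth = 10) {
  GaussianModel m;
  m.n = y.size();
  m.P = X.ncol();
  m.y.assign(y.begin(), y.end());
  m.X.resize((size_t)m.n * m.P);
  for (int i = 0; i < m.n; ++i)
    for (int p = 0; p < m.P; ++p) m.X[(size_t)i * m.P + p] = X(i, p);
  m.prior_mean.assign(prior_mean.begin(), prior_mean.end());
  m.prior_sd.assign(prior_sd.begin(), prior_sd.end());
  RNGScope scope;
  return run_nuts(m, init, warmup, sampling, adapt_delta, max_depth);
}

// Build the Cholesky factor and correlation matrix implied by an
// unconstrained correlation vector (used when transforming draws).
// [[Rcpp::export]]
NumericMatrix corr_from_unconstrained(NumericVector y, int K) {
  CorrBlock cb(K);
  if (y.size() != cb.nfree()) stop("wrong length for correlation vector");
  std::vector<double> yy(y.begin(), y.end());
  cb.build(yy.empty() ? NULL : &yy[0]);
  NumericMatrix R(K, K);
  for (int i = 0; i < K; ++i)
    for (int j = 0; j < K; ++j) {
      double acc = 0.0;
      for (int k = 0; k <= std::min(i, j); ++k)
        acc += cb.L[i * K + k] * cb.L[j * K + k];
      R(i, j) = acc;
    }
  return R;
}
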