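#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <vector>
using namespace Rcpp;

// Self-contained PCG32 generator: evidence estimates must be bit-reproducible
// given a seed, independent of R's RNG state and platform.
struct Pcg32 {
  uint64_t state, inc;
  bool has_spare;
  double spare;
  Pcg32(uint64_t seed, uint64_t seq) : state(0u), inc((seq << 1u) | 1u),
                                       has_spare(false), spare(0.0) {
    next(); state += seed; next();
  }
  uint32_t next() {
    uint64_t old = state;
    state = old * 6364136223846793005ULL + inc;
    uint32_t xs = (uint32_t)(((old >> 18u) ^ old) >> 27u);
    uint32_t rot = (uint32_t)(old >> 59u);
    return (xs >> rot) | (xs << ((-rot) & 31u));
  }
  double unif() { return (next() + 0.5) * (1.0 / 4294967296.0); }
  double norm() {  // Marsaglia polar
    if (has_spare) { has_spare = false; return spare; }
    double u, v, s;
    do {
      u = 2.0 * unif() - 1.0;
      v = 2.0 * unif() - 1.0;
      s = u * u + v * v;
    } while (s >= 1.0 || s == 0.0);
    double m = std::sqrt(-2.0 * std::log(s) / s);
    spare = v * m; has_spare = true;
    return u * m;
  }
};

static const double LOG2PI = 1.8378770664093453;
static const double INVSQRT2 = 0.7071067811865476;
static const double INVSQRT2PI = 0.3989422804014327;

static inline double norm_cdf(double x) { return 0.5 * std::erfc(-x * INVSQRT2); }
static inline double norm_pdf(double x) { return INVSQRT2PI * std::exp(-0.5 * x * x); }

// The sampler works in (mu, v = log sigma): the uniform-mu / log-uniform-
// sigma prior is uniform in these coordinates, so Metropolis acceptance
// reduces to the tempered likelihood ratio.
// logL(mu, v) = -A - n v - (n/2) log 2pi - q(mu) e^{-2v} / 2,
// q(mu) = B - 2 mu A + n mu^2 (sufficient statistics of the group).
struct Chain { double mu, v, ll; };

static inline double loglik_mv(double n, double A, double B,
                               double mu, double v) {
  double q = B - 2.0 * mu * A + n * mu * mu;
  return -A - n * v - 0.5 * n * LOG2PI - 0.5 * q * std::exp(-2.0 * v);
}

// E_beta[logL | v]: mu given v at inverse temperature beta is
// N(A/n, e^{2v}/(beta n)) truncated to the prior box; recording its exact
// conditional expectation (Rao-Blackwellisation) removes the mu-direction
// Monte Carlo variance from the stored log-likelihoods.
static inline double loglik_rb_mu(double n, double A, double B, double v,
                                  double beta, double mu_lo, double mu_hi) {
  double m = A / n;
  double s = std::exp(v) / std::sqrt(beta * n);
  double lo = (mu_lo - m) / s, hi = (mu_hi - m) / s;
  double e1, e2;
  if (lo < -8.0 && hi > 8.0) {        // truncation negligible
    e1 = m; e2 = s * s + m * m;
  } else if (norm_cdf(hi) - norm_cdf(lo) < 1e-300) {
    e1 = m; e2 = m * m;
  } else {
    double Z = norm_cdf(hi) - norm_cdf(lo);
    double plo = norm_pdf(lo), phi = norm_pdf(hi);
    e1 = m + s * (plo - phi) / Z;
    double var = s * s * (1.0 + (lo * plo - hi * phi) / Z
                          - ((plo - phi) / Z) * ((plo - phi) / Z));
    if (var < 0) var = 0;
    e2 = var + e1 * e1;
  }
  double q = B - 2.0 * A * e1 + n * e2;
  return -A - n * v - 0.5 * n * LOG2PI - 0.5 * q * std::exp(-2.0 * v);
}

// One Metropolis update at inverse temperature beta. Near-prior rungs
// (beta * n <= 0.01) use an independence proposal from the prior itself
// (uniform in mu and v), giving near-iid sampling of the prior's heavy
// small-sigma tail; elsewhere a random walk with rung-level scales.
static inline void mh_update(Chain &c, double beta,
                             double s_mu, double s_v, bool prior_prop,
                             double n, double A, double B,
                             double mu_lo, double mu_hi,
                             double v_lo, double v_hi,
                             Pcg32 &rng, int &acc) {
  double mu2, v2;
  if (prior_prop) {
    mu2 = mu_lo + (mu_hi - mu_lo) * rng.unif();
    v2 = v_lo + (v_hi - v_lo) * rng.unif();
  } else {
    mu2 = c.mu + s_mu * rng.norm();
    v2 = c.v + s_v * rng.norm();
    if (mu2 < mu_lo || mu2 > mu_hi || v2 < v_lo || v2 > v_hi) return;
  }
  double ll2 = loglik_mv(n, A, B, mu2, v2);
  double la = beta * (ll2 - c.ll);
  if (la >= 0.0 || rng.unif() < std::exp(la)) {
    c.mu = mu2; c.v = v2; c.ll = ll2; ++acc;
  }
}

static void pt_core(double n, double A, double B,
                    double mu_lo, double mu_hi,
                    double sg_lo, double sg_hi,
                    const double *beta, int K,
                    int n_equil, double frac_equil,
                    int n_samp, double frac_samp,
                    double swap_prob, double seed,
                    int n_thin, double inflate_cap,
                    double *mean_ll_out, double *acc_eq_out, double *acc_sa_out,
                    double *swap_rate_out, double *best_out) {
  Pcg32 rng((uint64_t)seed, 0x5bd1e995u);
  double v_lo = std::log(sg_lo), v_hi = std::log(sg_hi);

  // initial value: moments of the log counts, clamped into the prior box
  double mu0 = A / n;
  double var0 = (n > 1.5) ? std::max((B - A * A / n) / (n - 1.0), 1e-6) : 0.01;
  double v0 = 0.5 * std::log(var0);
  mu0 = std::min(std::max(mu0, mu_lo), mu_hi);
  v0 = std::min(std::max(v0, v_lo), v_hi);

  // rung-level proposal scales: fractional step inflated by beta^-1/2
  // (capped), but never below the tempered-posterior width implied by the
  // empirical sigma, and never above half the prior box
  std::vector<double> s_mu_eq(K), s_v_eq(K), s_mu_sa(K), s_v_sa(K);
  std::vector<char> prior_prop(K);
  double sg0 = std::exp(v0);
  for (int k = 0; k < K; ++k) {
    double inflate = std::min(1.0 / std::sqrt(beta[k]), inflate_cap);
    double post_v = 0.8 / std::sqrt(beta[k] * n);
    // mu proposal must cover the mu spread at sigmas the tempered chain
    // visits (sigma posterior spans ~ sg0 * exp(+-1/sqrt(2 beta n)))
    double sg_typ = sg0 * std::exp(1.0 / std::sqrt(2.0 * beta[k] * n));
    double post_mu = 1.2 * sg_typ / std::sqrt(beta[k] * n);
    double mag = std::max(std::fabs(mu0), 1.0);
    s_mu_eq[k] = std::min(std::max(frac_equil * inflate * mag, post_mu),
                          0.5 * (mu_hi - mu_lo));
    s_v_eq[k] = std::min(std::max(frac_equil * inflate, post_v),
                         0.5 * (v_hi - v_lo));
    s_mu_sa[k] = std::min(std::max(frac_samp * inflate * mag, post_mu),
                          0.5 * (mu_hi - mu_lo));
    s_v_sa[k] = std::min(std::max(frac_samp * inflate, post_v),
                         0.5 * (v_hi - v_lo));
    prior_prop[k] = beta[k] * n <= 0.01;
  }

  std::vector<Chain> ch(K);
  for (int k = 0; k < K; ++k) {
    ch[k].mu = mu0; ch[k].v = v0;
    ch[k].ll = loglik_mv(n, A, B, mu0, v0);
  }

  double best_mu = mu0, best_v = v0, best_ll = ch[0].ll;
  std::vector<int> acc_eq(K, 0), acc_sa(K, 0);
  int swap_att = 0, swap_acc = 0;

  // Equilibration serves to locate the maximum-likelihood state from
  // which every rung restarts; running it on the two coldest rungs (with
  // temperature swaps between them) finds that state at a fraction of the
  // cost of equilibrating the full ladder. The initial state is already
  // the group's moment estimate (the lognormal MLE), so the search is
  // local refinement.
  int k_eq0 = K > 2 ? K - 2 : 0;
  for (int step = 0; step < n_equil; ++step) {
    for (int k = k_eq0; k < K; ++k) {
      mh_update(ch[k], beta[k], s_mu_eq[k], s_v_eq[k], prior_prop[k],
                n, A, B, mu_lo, mu_hi, v_lo, v_hi, rng, acc_eq[k]);
      if (ch[k].ll > best_ll) { best_ll = ch[k].ll; best_mu = ch[k].mu; best_v = ch[k].v; }
    }
    if (K - k_eq0 > 1 && rng.unif() < swap_prob) {
      int j = k_eq0 + (int)(rng.unif() * (K - 1 - k_eq0));
      if (j > K - 2) j = K - 2;
      ++swap_att;
      double la = (beta[j] - beta[j + 1]) * (ch[j + 1].ll - ch[j].ll);
      if (la >= 0.0 || rng.unif() < std::exp(la)) {
        std::swap(ch[j], ch[j + 1]);
        ++swap_acc;
      }
    }
  }

  // restart every rung from the best state found, then sample without swaps
  for (int k = 0; k < K; ++k) {
    ch[k].mu = best_mu; ch[k].v = best_v; ch[k].ll = best_ll;
  }
  std::vector<double> sum_ll(K, 0.0);
  for (int step = 0; step < n_samp; ++step) {
    for (int k = 0; k < K; ++k) {
      for (int t = 0; t < n_thin; ++t)
        mh_update(ch[k], beta[k], s_mu_sa[k], s_v_sa[k], prior_prop[k],
                  n, A, B, mu_lo, mu_hi, v_lo, v_hi, rng, acc_sa[k]);
      sum_ll[k] += loglik_rb_mu(n, A, B, ch[k].v, beta[k], mu_lo, mu_hi);
    }
  }

  for (int k = 0; k < K; ++k) {
    mean_ll_out[k] = sum_ll[k] / n_samp;
    if (acc_eq_out) acc_eq_out[k] = (double)acc_eq[k] / n_equil;
    if (acc_sa_out) acc_sa_out[k] = (double)acc_sa[k] / (n_samp * (double)n_thin);
  }
  if (swap_rate_out)
    *swap_rate_out = swap_att > 0 ? (double)swap_acc / swap_att : NA_REAL;
  if (best_out) { best_out[0] = best_mu; best_out[1] = std::exp(best_v); best_out[2] = best_ll; }
}

// Parallel-tempered sampling for one period-bin group. Returns the
// per-rung mean log-likelihood of the sampling phase plus diagnostics;
// thermodynamic integration over the ladder is assembled in R.
// [[Rcpp::export]]
List pt_group_sample(double n, double A, double B,
                     double mu_lo, double mu_hi,
                     double sg_lo, double sg_hi,
                     NumericVector beta,
                     int n_equil, double frac_equil,
                     int n_samp, double frac_samp,
                     double swap_prob, double seed,
                     int n_thin = 1, double inflate_cap = 1000.0) {
  int K = beta.size();
  NumericVector mean_ll(K), a_eq(K), a_sa(K), best(3);
  double swap_rate;
  pt_core(n, A, B, mu_lo, mu_hi, sg_lo, sg_hi, REAL(beta), K,
          n_equil, frac_equil, n_samp, frac_samp, swap_prob, seed,
          n_thin, inflate_cap,
          REAL(mean_ll), REAL(a_eq), REAL(a_sa), &swap_rate, REAL(best));
  best.names() = CharacterVector::create("mu", "sigma", "loglik");
  return List::create(
    _["mean_loglik"] = mean_ll,
    _["accept_equil"] = a_eq,
    _["accept_sample"] = a_sa,
    _["swap_rate"] = swap_rate,
    _["best"] = best);
}

// Batch version over many independent (group x cell-bin) units: columns of
// the returned matrix are the per-rung mean log-likelihoods of each unit,
// each run with its own sufficient statistics and derived seed.
// [[Rcpp::export]]
NumericMatrix pt_batch_sample(NumericVector n, NumericVector A, NumericVector B,
                              double mu_lo, double mu_hi,
                              double sg_lo, double sg_hi,
                              NumericVector beta,
                              int n_equil, double frac_equil,
                              int n_samp, double frac_samp,
                              double swap_prob, NumericVector seeds,
                              int n_thin = 1, double inflate_cap = 1000.0) {
  int M = n.size(), K = beta.size();
  NumericMatrix out(K, M);
  for (int m = 0; m < M; ++m) {
    pt_core(n[m], A[m], B[m], mu_lo, mu_hi, sg_lo, sg_hi, REAL(beta), K,
            n_equil, frac_equil, n_samp, frac_samp, swap_prob, seeds[m],
            n_thin, inflate_cap, &out(0, m), nullptr, nullptr, nullptr, nullptr);
    if (m % 256 == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}
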