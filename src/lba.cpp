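// Linear Ballistic Accumulator first-passage densities and the blocked
// DE-MCMC sampler for the two-group hierarchical model.  The sampler lives
// here because the per-iteration cost is dominated by ~1e5 density
// evaluations; everything user-facing is wrapped on the R side.

#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

static const int NP = 7;   // A, k, t0, v_c_face, v_e_face, v_c_oval, v_e_oval
static const int NH = 14;  // mu[7], sigma[7]
static const double DENS_FLOOR = 1e-300;
static const double A_LIMIT = 1e-6;  // below this, use the A -> 0 density

static const double INV_SQRT2 = 0.707106781186547524400844362105;
static const double INV_SQRT_2PI = 0.398942280401432677939946059934;

// standard normal CDF/PDF; erfc keeps relative accuracy deep in the tails
static inline double Phi(double z) { return 0.5 * std::erfc(-z * INV_SQRT2); }
static inline double phi(double z) { return INV_SQRT_2PI * std::exp(-0.5 * z * z); }

// density of the first-passage time of one accumulator:
// start ~ U[0, A], drift ~ N(v, s), threshold b
static double node_pdf(double t, double A, double b, double v, double s) {
  if (t <= 0.0) return 0.0;
  if (A < A_LIMIT) {
    // limiting case: start point collapses to 0, T = b / drift
    return (b / (s * t * t)) * phi((b / t - v) / s);
  }
  double ts = t * s;
  double z1 = (b - A - t * v) / ts;
  double z2 = (b - t * v) / ts;
  double f = (-v * Phi(z1) + s * phi(z1) + v * Phi(z2) - s * phi(z2)) / A;
  return f > 0.0 ? f : 0.0;
}

// survival 1 - F(t), computed directly to avoid cancellation near F = 1
static double node_surv(double t, double A, double b, double v, double s) {
  if (t <= 0.0) return 1.0;
  if (A < A_LIMIT) return Phi((b / t - v) / s);
  double ts = t * s;
  double z1 = (b - A - t * v) / ts;
  double z2 = (b - t * v) / ts;
  double S = -((b - A - t * v) / A) * Phi(z1) + ((b - t * v) / A) * Phi(z2)
             - (ts / A) * (phi(z1) - phi(z2));
  if (S < 0.0) S = 0.0;
  if (S > 1.0) S = 1.0;
  return S;
}

// defective log density of one observed trial (winner pdf x loser survivor)
static inline double trial_logdens(double rt, int correct, int cond,
                                   const double* th, double s) {
  double A = th[0], b = th[0] + th[1], t0 = th[2];
  double t = rt - t0;
  if (t <= 0.0) return R_NegInf;
  double vc = (cond == 0) ? th[3] : th[5];
  double ve = (cond == 0) ? th[4] : th[6];
  double vw = correct ? vc : ve;
  double vl = correct ? ve : vc;
  double dens = node_pdf(t, A, b, vw, s) * node_surv(t, A, b, vl, s);
  if (dens < DENS_FLOOR) dens = DENS_FLOOR;
  return std::log(dens);
}

static double subj_loglik(const double* th,
                          const double* rt, const int* correct, const int* cond,
                          int from, int to, double s) {
  if (th[0] <= 0.0 || th[1] <= 0.0 || th[2] <= 0.0) return R_NegInf;
  double ll = 0.0;
  for (int i = from; i < to; ++i) {
    double l = trial_logdens(rt[i], correct[i], cond[i], th, s);
    if (!R_finite(l)) return R_NegInf;
    ll += l;
  }
  return ll;
}

// log density of the positive-truncated normal
static inline double tnorm_lpdf(double x, double mu, double sigma) {
  if (x <= 0.0 || sigma <= 0.0) return R_NegInf;
  return R::dnorm(x, mu, sigma, 1) - R::pnorm(mu / sigma, 0.0, 1.0, 1, 1);
}

static double subj_lprior(const double* th, const double* hyp) {
  double lp = 0.0;
  for (int p = 0; p < NP; ++p) {
    double l = tnorm_lpdf(th[p], hyp[p], hyp[NP + p]);
    if (!R_finite(l)) return R_NegInf;
    lp += l;
  }
  return lp;
}

static double hyper_lprior(const double* hyp, const NumericMatrix& prior) {
  double lp = 0.0;
  for (int p = 0; p < NP; ++p) {
    double lm = tnorm_lpdf(hyp[p], prior(p, 0), prior(p, 1));
    double ls = tnorm_lpdf(hyp[NP + p], prior(p, 2), prior(p, 3));
    if (!R_finite(lm) || !R_finite(ls)) return R_NegInf;
    lp += lm + ls;
  }
  return lp;
}

// [[Rcpp::export]]
double cpp_subject_loglik(NumericVector theta, NumericVector rt,
                          IntegerVector correct, IntegerVector cond, double s) {
  if (theta.size() != NP) stop("theta must have length 7");
  return subj_loglik(REAL(theta), REAL(rt), INTEGER(correct), INTEGER(cond),
                     0, rt.size(), s);
}

// [[Rcpp::export]]
NumericVector cpp_node_pdf(NumericVector t, double A, double b, double v, double s) {
  int n = t.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = node_pdf(t[i], A, b, v, s);
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_node_surv(NumericVector t, double A, double b, double v, double s) {
  int n = t.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = node_surv(t[i], A, b, v, s);
  return out;
}

// pick two distinct partner chains, both different from `self`
static inline void pick_partners(int self, int n_chains, int& m, int& n) {
  m = (int)(unif_rand() * (n_chains - 1));
  if (m >= self) ++m;
  do {
    n = (int)(unif_rand() * (n_chains - 1));
    if (n >= self) ++n;
  } while (n == m);
}

// [[Rcpp::export]]
List cpp_run_sampler(NumericVector rt, IntegerVector correct, IntegerVector cond,
                     IntegerVector subj_off, IntegerVector subj_group, int n_groups,
                     NumericMatrix prior,
                     NumericVector init_theta, NumericVector init_hyper,
                     int n_chains, int n_samples, int burn_in,
                     double gamma_subj, double gamma_hyper,
                     double b0, double migrate_prob, double s,
                     bool store_subject) {
  const int n_subj = subj_off.size() - 1;
  const int n_iter = burn_in + n_samples;
  const double* RT = REAL(rt);
  const int* CO = INTEGER(correct);
  const int* CN = INTEGER(cond);

  // current states and cached posterior components
  std::vector<double> theta(init_theta.begin(), init_theta.end());
  std::vector<double> hyper(init_hyper.begin(), init_hyper.end());
  std::vector<double> ll(n_chains * n_subj), lpr(n_chains * n_subj);
  std::vector<double> hlp(n_chains * n_groups);

  for (int c = 0; c < n_chains; ++c) {
    for (int sj = 0; sj < n_subj; ++sj) {
      const double* th = theta.data() + (NP * (sj + (size_t)n_subj * c));
      const double* hy = hyper.data() + NH * (subj_group[sj] + (size_t)n_groups * c);
      ll[c * n_subj + sj] = subj_loglik(th, RT, CO, CN, subj_off[sj], subj_off[sj + 1], s);
      lpr[c * n_subj + sj] = subj_lprior(th, hy);
      if (!R_finite(ll[c * n_subj + sj]) || !R_finite(lpr[c * n_subj + sj]))
        stop("non-finite posterior at initialization (chain %d, subject %d)", c + 1, sj + 1);
    }
    for (int g = 0; g < n_groups; ++g) {
      hlp[c * n_groups + g] = hyper_lprior(hyper.data() + (NH * (g + (size_t)n_groups * c)), prior);
      if (!R_finite(hlp[c * n_groups + g]))
        stop("non-finite hyperprior at initialization (chain %d)", c + 1);
    }
  }

  const size_t n_sub_par = (size_t)n_subj * NP;
  const size_t n_hyp_par = (size_t)n_groups * NH;
  NumericVector theta_draws(store_subject ? n_sub_par * n_samples * n_chains : 0);
  NumericVector hyper_draws(n_hyp_par * n_samples * n_chains);

  double acc_subj = 0.0, try_subj = 0.0, acc_hyp = 0.0, try_hyp = 0.0;
  double acc_mig = 0.0, try_mig = 0.0;
  double prop[NH], snap_buf;
  (void)snap_buf;

  for (int iter = 0; iter < n_iter; ++iter) {
    for (int c = 0; c < n_chains; ++c) {
      // subject-level blocks, conditional on this chain's hypers
      for (int sj = 0; sj < n_subj; ++sj) {
        int m, n;
        pick_partners(c, n_chains, m, n);
        double* cur = theta.data() + (NP * (sj + (size_t)n_subj * c));
        const double* thm = theta.data() + (NP * (sj + (size_t)n_subj * m));
        const double* thn = theta.data() + (NP * (sj + (size_t)n_subj * n));
        for (int p = 0; p < NP; ++p)
          prop[p] = cur[p] + gamma_subj * (thm[p] - thn[p]) + R::runif(-b0, b0);
        const double* hy = hyper.data() + NH * (subj_group[sj] + (size_t)n_groups * c);
        try_subj += 1.0;
        double lp_new = subj_lprior(prop, hy);
        if (!R_finite(lp_new)) continue;
        double ll_new = subj_loglik(prop, RT, CO, CN, subj_off[sj], subj_off[sj + 1], s);
        if (!R_finite(ll_new)) continue;
        double delta = (ll_new + lp_new) - (ll[c * n_subj + sj] + lpr[c * n_subj + sj]);
        if (delta >= 0.0 || std::log(unif_rand()) < delta) {
          for (int p = 0; p < NP; ++p) cur[p] = prop[p];
          ll[c * n_subj + sj] = ll_new;
          lpr[c * n_subj + sj] = lp_new;
          acc_subj += 1.0;
        }
      }
      // group hyper updates, conditional on this chain's subject
      // parameters.  Given the subject values, the (mu_p, sigma_p) pairs
      // are independent across parameters, so each pair is its own
      // 2-dimensional crossover block (far better acceptance than one
      // 14-dimensional block against a tight conditional).
      for (int g = 0; g < n_groups; ++g) {
        double* cur = hyper.data() + (NH * (g + (size_t)n_groups * c));
        for (int p = 0; p < NP; ++p) {
          int m, n;
          pick_partners(c, n_chains, m, n);
          const double* hym = hyper.data() + (NH * (g + (size_t)n_groups * m));
          const double* hyn = hyper.data() + (NH * (g + (size_t)n_groups * n));
          double mu_new = cur[p] + gamma_hyper * (hym[p] - hyn[p]) + R::runif(-b0, b0);
          double sd_new = cur[NP + p] + gamma_hyper * (hym[NP + p] - hyn[NP + p]) + R::runif(-b0, b0);
          try_hyp += 1.0;
          double hp_new = tnorm_lpdf(mu_new, prior(p, 0), prior(p, 1)) +
                          tnorm_lpdf(sd_new, prior(p, 2), prior(p, 3));
          if (!R_finite(hp_new)) continue;
          double hp_old = tnorm_lpdf(cur[p], prior(p, 0), prior(p, 1)) +
                          tnorm_lpdf(cur[NP + p], prior(p, 2), prior(p, 3));
          double delta = hp_new - hp_old;
          bool ok = true;
          for (int sj = 0; sj < n_subj && ok; ++sj) {
            if (subj_group[sj] != g) continue;
            double x = theta[NP * (sj + (size_t)n_subj * c) + p];
            double l_new = tnorm_lpdf(x, mu_new, sd_new);
            if (!R_finite(l_new)) { ok = false; break; }
            delta += l_new - tnorm_lpdf(x, cur[p], cur[NP + p]);
          }
          if (!ok) continue;
          if (delta >= 0.0 || std::log(unif_rand()) < delta) {
            cur[p] = mu_new;
            cur[NP + p] = sd_new;
            acc_hyp += 1.0;
          }
        }
        // refresh the cached per-subject prior and group hyperprior sums
        for (int sj = 0; sj < n_subj; ++sj)
          if (subj_group[sj] == g)
            lpr[c * n_subj + sj] =
              subj_lprior(theta.data() + (NP * (sj + (size_t)n_subj * c)), cur);
        hlp[c * n_groups + g] = hyper_lprior(cur, prior);
      }
    }

    // migration: cyclic state-copy proposals among a small random chain
    // subset.  Restricted to the first half of burn-in: copying reduces
    // population diversity, so the second half lets crossover
    // re-equilibrate the chain spread before retention.
    if (iter < burn_in / 2 && migrate_prob > 0.0 && unif_rand() < migrate_prob) {
      int K_max = n_chains / 4 > 2 ? n_chains / 4 : 2;
      int K = 1 + (int)(unif_rand() * K_max);
      if (K > n_chains) K = n_chains;
      std::vector<int> pool(n_chains);
      for (int i = 0; i < n_chains; ++i) pool[i] = i;
      for (int i = 0; i < K; ++i) {
        int j = i + (int)(unif_rand() * (n_chains - i));
        std::swap(pool[i], pool[j]);
      }
      // snapshot the K chains' states and log posteriors
      std::vector<double> snap_theta((size_t)K * n_sub_par), snap_hyper((size_t)K * n_hyp_par);
      std::vector<double> snap_ll((size_t)K * n_subj), snap_lpr((size_t)K * n_subj);
      std::vector<double> snap_hlp((size_t)K * n_groups), snap_lp(K, 0.0);
      for (int i = 0; i < K; ++i) {
        int c = pool[i];
        std::copy(theta.data() + (n_sub_par * c), theta.data() + (n_sub_par * (c + 1)), snap_theta.data() + (n_sub_par * i));
        std::copy(hyper.data() + (n_hyp_par * c), hyper.data() + (n_hyp_par * (c + 1)), snap_hyper.data() + (n_hyp_par * i));
        std::copy(ll.data() + ((size_t)c * n_subj), ll.data() + ((size_t)(c + 1) * n_subj), snap_ll.data() + ((size_t)i * n_subj));
        std::copy(lpr.data() + ((size_t)c * n_subj), lpr.data() + ((size_t)(c + 1) * n_subj), snap_lpr.data() + ((size_t)i * n_subj));
        std::copy(hlp.data() + ((size_t)c * n_groups), hlp.data() + ((size_t)(c + 1) * n_groups), snap_hlp.data() + ((size_t)i * n_groups));
        double lp = 0.0;
        for (int sj = 0; sj < n_subj; ++sj) lp += ll[c * n_subj + sj] + lpr[c * n_subj + sj];
        for (int g = 0; g < n_groups; ++g) lp += hlp[c * n_groups + g];
        snap_lp[i] = lp;
      }
      for (int i = 0; i < K; ++i) {
        int donor = (i - 1 + K) % K;
        int c = pool[i];
        try_mig += 1.0;
        double delta = snap_lp[donor] - snap_lp[i];
        if (delta >= 0.0 || std::log(unif_rand()) < delta) {
          std::copy(snap_theta.data() + (n_sub_par * donor), snap_theta.data() + (n_sub_par * (donor + 1)), theta.data() + (n_sub_par * c));
          std::copy(snap_hyper.data() + (n_hyp_par * donor), snap_hyper.data() + (n_hyp_par * (donor + 1)), hyper.data() + (n_hyp_par * c));
          std::copy(snap_ll.data() + ((size_t)donor * n_subj), snap_ll.data() + ((size_t)(donor + 1) * n_subj), ll.data() + ((size_t)c * n_subj));
          std::copy(snap_lpr.data() + ((size_t)donor * n_subj), snap_lpr.data() + ((size_t)(donor + 1) * n_subj), lpr.data() + ((size_t)c * n_subj));
          std::copy(snap_hlp.data() + ((size_t)donor * n_groups), snap_hlp.data() + ((size_t)(donor + 1) * n_groups), hlp.data() + ((size_t)c * n_groups));
          acc_mig += 1.0;
        }
      }
    }

    if (iter >= burn_in) {
      int it = iter - burn_in;
      if (store_subject) {
        for (int c = 0; c < n_chains; ++c)
          std::copy(theta.data() + (n_sub_par * c), theta.data() + (n_sub_par * (c + 1)),
                    REAL(theta_draws) + (n_sub_par * (it + (size_t)n_samples * c)));
      }
      for (int c = 0; c < n_chains; ++c)
        std::copy(hyper.data() + (n_hyp_par * c), hyper.data() + (n_hyp_par * (c + 1)),
                  REAL(hyper_draws) + (n_hyp_par * (it + (size_t)n_samples * c)));
    }
    if (iter % 512 == 0) Rcpp::checkUserInterrupt();
  }

  return List::create(
    _["theta"] = theta_draws,
    _["hyper"] = hyper_draws,
    _["accept_subject"] = try_subj > 0 ? acc_subj / try_subj : NA_REAL,
    _["accept_hyper"] = try_hyp > 0 ? acc_hyp / try_hyp : NA_REAL,
    _["accept_migration"] = try_mig > 0 ? acc_mig / try_mig : NA_REAL);
}
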