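// Hierarchical sampler for the Horizon-Task learning + decision model.
//
// Subject-level parameters (13 per subject, one stimulation condition per
// fit): R0, alpha1, alpha_inf, A[h1,h6], B[4 cells], sigma[4 cells], with
// cells ordered h1_u13, h1_u22, h6_u13, h6_u22. Group level (26): mu/sd for
// R0, Beta(a,b) for the two learning rates, mu/sd for A per horizon and B
// per cell, Gamma(shape k, rate lambda) for sigma per cell.
//
// The likelihood is the Bernoulli probability of the first free choice of
// each game: p(right) = 1 / (1 + exp((dR + A*dI + B)/sigma)), with dR the
// left-minus-right Kalman value difference after the four forced trials,
// tracked in learning-rate space (omega = sigma^2/sigma_r^2).
//
// Updates: adaptive random-walk Metropolis per parameter (log scale for
// scales, logit for learning rates), conjugate Gibbs for the Gaussian
// group means and for the Gamma rate hyperparameter. Uses R's RNG so
// set.seed() on the R side makes chains reproducible.

#include <Rcpp.h>
#include <vector>
#include <array>
#include <cmath>
using namespace Rcpp;

// group-parameter indices
enum {
  G_MU_R0 = 0, G_SD_R0, G_A_A1, G_B_A1, G_A_AI, G_B_AI,
  G_MU_A_H1, G_MU_A_H6, G_SD_A_H1, G_SD_A_H6,
  G_MU_B0, G_MU_B1, G_MU_B2, G_MU_B3,
  G_SD_B0, G_SD_B1, G_SD_B2, G_SD_B3,
  G_K_S0, G_K_S1, G_K_S2, G_K_S3,
  G_L_S0, G_L_S1, G_L_S2, G_L_S3,
  N_GROUP
};
// subject-parameter rows
enum {
  P_R0 = 0, P_A1, P_AI, P_A_H1, P_A_H6,
  P_B0, P_B1, P_B2, P_B3, P_S0, P_S1, P_S2, P_S3, N_SUBJ
};

static inline double kalman_dr(const double* fr, const int* fa,
                               double R0, double a1, double ai, int mode) {
  double ad = ai * ai / (1.0 - ai);
  double w0 = (mode == 0 ? a1 / (1.0 - a1) : a1) - ad;
  double R[2] = {R0, R0};
  double w[2] = {w0, w0};
  for (int k = 0; k < 4; ++k) {
    int j = fa[k];
    double wpre = w[j] + ad;
    double al = wpre / (1.0 + wpre);
    R[j] += al * (fr[k] - R[j]);
    w[j] = al;
    w[1 - j] += ad;
  }
  return R[0] - R[1];
}

// log p(choice) given the exponent argument x = (dR + A dI + B)/sigma
static inline double bern_ll(double x, int choice_right) {
  double ll_right = (x > 0.0) ? -(x + log1p(std::exp(-x))) : -log1p(std::exp(x));
  return choice_right ? ll_right : ll_right + x;
}

struct Data {
  NumericMatrix fr;       // 4 x N forced rewards
  IntegerMatrix fa;       // 4 x N forced choices (0 left, 1 right)
  IntegerVector subj;     // 0-based subject index per observation
  IntegerVector cell;     // 0..3
  IntegerVector di;       // -1, 0, +1
  IntegerVector ch;       // free choice (0 left, 1 right)
  int S, N, mode;
  std::vector<std::vector<int>> by_subj;
  std::vector<std::array<std::vector<int>, 4>> by_subj_cell;
};

static double obs_ll(const Data& d, const NumericMatrix& sp,
                     const std::vector<double>& dR, int i) {
  int s = d.subj[i], c = d.cell[i];
  double A = 0.0;
  if (d.di[i] != 0) A = (c == 0) ? sp(P_A_H1, s) : sp(P_A_H6, s);
  double x = (dR[i] + A * d.di[i] + sp(P_B0 + c, s)) / sp(P_S0 + c, s);
  return bern_ll(x, d.ch[i]);
}

// log-prior of subject parameter row p for subject s under group params g
static double subj_lprior(int p, double val, const NumericVector& g) {
  switch (p) {
    case P_R0: return R::dnorm(val, g[G_MU_R0], g[G_SD_R0], 1);
    case P_A1: return R::dbeta(val, g[G_A_A1], g[G_B_A1], 1);
    case P_AI: return R::dbeta(val, g[G_A_AI], g[G_B_AI], 1);
    case P_A_H1: return R::dnorm(val, g[G_MU_A_H1], g[G_SD_A_H1], 1);
    case P_A_H6: return R::dnorm(val, g[G_MU_A_H6], g[G_SD_A_H6], 1);
    default:
      if (p >= P_B0 && p <= P_B3)
        return R::dnorm(val, g[G_MU_B0 + (p - P_B0)], g[G_SD_B0 + (p - P_B0)], 1);
      return R::dgamma(val, g[G_K_S0 + (p - P_S0)], 1.0 / g[G_L_S0 + (p - P_S0)], 1);
  }
}

// [[Rcpp::export(name = ".kalman_dr_cpp")]]
NumericVector kalman_dr_cpp(NumericMatrix fr, IntegerMatrix fa,
                            double R0, double alpha1, double alpha_inf,
                            int mode) {
  int N = fr.ncol();
  NumericVector out(N);
  std::vector<double> frbuf(4);
  std::vector<int> fabuf(4);
  for (int i = 0; i < N; ++i) {
    for (int k = 0; k < 4; ++k) { frbuf[k] = fr(k, i); fabuf[k] = fa(k, i); }
    out[i] = kalman_dr(frbuf.data(), fabuf.data(), R0, alpha1, alpha_inf, mode);
  }
  return out;
}

class Sampler {
public:
  Data d;
  NumericVector g;        // group params
  NumericMatrix sp;       // subject params, 13 x S
  LogicalVector fixg;
  LogicalMatrix fixs;
  std::vector<double> dR; // cached per observation
  NumericMatrix step_s;   // proposal log-steps
  NumericVector step_g;
  NumericMatrix acc_s; NumericMatrix try_s;
  NumericVector acc_g; NumericVector try_g;
  bool sample_group;

  Sampler(Data d_, NumericVector g0, NumericMatrix sp0,
          LogicalVector fixg_, LogicalMatrix fixs_, bool sample_group_)
    : d(d_), g(clone(g0)), sp(clone(sp0)), fixg(fixg_), fixs(fixs_),
      dR(d_.N), step_s(N_SUBJ, d_.S), step_g(N_GROUP),
      acc_s(N_SUBJ, d_.S), try_s(N_SUBJ, d_.S),
      acc_g(N_GROUP), try_g(N_GROUP), sample_group(sample_group_) {
    for (int s = 0; s < d.S; ++s) {
      step_s(P_R0, s) = 2.0; step_s(P_A1, s) = 0.8; step_s(P_AI, s) = 0.8;
      step_s(P_A_H1, s) = 2.0; step_s(P_A_H6, s) = 2.0;
      for (int c = 0; c < 4; ++c) { step_s(P_B0 + c, s) = 1.0; step_s(P_S0 + c, s) = 0.3; }
    }
    step_g[G_SD_R0] = 0.3; step_g[G_A_A1] = 0.5; step_g[G_B_A1] = 0.5;
    step_g[G_A_AI] = 0.5; step_g[G_B_AI] = 0.5;
    for (int h = 0; h < 2; ++h) step_g[G_SD_A_H1 + h] = 0.3;
    for (int c = 0; c < 4; ++c) { step_g[G_SD_B0 + c] = 0.3; step_g[G_K_S0 + c] = 0.3; }
    refresh_dr_all();
  }

  void refresh_dr_all() {
    for (int s = 0; s < d.S; ++s) refresh_dr_subj(s, dR);
  }
  void refresh_dr_subj(int s, std::vector<double>& buf) {
    double frb[4]; int fab[4];
    for (int i : d.by_subj[s]) {
      for (int k = 0; k < 4; ++k) { frb[k] = d.fr(k, i); fab[k] = d.fa(k, i); }
      buf[i] = kalman_dr(frb, fab, sp(P_R0, s), sp(P_A1, s), sp(P_AI, s), d.mode);
    }
  }

  double ll_subj(int s, const std::vector<double>& dr) {
    double ll = 0.0;
    for (int i : d.by_subj[s]) ll += obs_ll(d, sp, dr, i);
    return ll;
  }
  double ll_subj_cell(int s, int c) {
    double ll = 0.0;
    for (int i : d.by_subj_cell[s][c]) ll += obs_ll(d, sp, dR, i);
    return ll;
  }

  void adapt(double& step, double acc, bool accepted) {
    (void)acc;
    step *= std::exp(accepted ? 0.02 : -0.0157); // targets ~0.44 acceptance
    if (step < 1e-4) step = 1e-4;
    if (step > 50.0) step = 50.0;
  }

  // ---- subject-level updates --------------------------------------------
  void update_learning(int s, int p, bool adapting, std::vector<double>& prop_dr) {
    if (fixs(p, s)) return;
    double cur = sp(p, s), prop, lqratio = 0.0;
    if (p == P_R0) {
      prop = cur + R::norm_rand() * step_s(p, s);
    } else { // logit walk; Jacobian term log(x(1-x)) enters via proposal ratio
      double z = std::log(cur / (1.0 - cur)) + R::norm_rand() * step_s(p, s);
      prop = 1.0 / (1.0 + std::exp(-z));
      if (prop <= 1e-12 || prop >= 1.0 - 1e-12) return;
      lqratio = std::log(prop * (1.0 - prop)) - std::log(cur * (1.0 - cur));
    }
    double lp0 = subj_lprior(p, cur, g) + ll_subj(s, dR);
    sp(p, s) = prop;
    refresh_dr_subj(s, prop_dr);
    double lp1 = subj_lprior(p, prop, g) + ll_subj(s, prop_dr);
    bool ok = R_finite(lp1) && std::log(unif_rand()) < lp1 - lp0 + lqratio;
    try_s(p, s) += 1;
    if (ok) {
      acc_s(p, s) += 1;
      for (int i : d.by_subj[s]) dR[i] = prop_dr[i];
    } else {
      sp(p, s) = cur;
    }
    if (adapting) adapt(step_s(p, s), 0, ok);
  }

  void update_decision(int s, int p, bool adapting) {
    if (fixs(p, s)) return;
    int c = (p == P_A_H1) ? 0 : (p == P_A_H6) ? 2 :
            (p >= P_S0) ? p - P_S0 : p - P_B0;
    double cur = sp(p, s), prop, lqratio = 0.0;
    if (p >= P_S0) { // log walk for sigma
      prop = cur * std::exp(R::norm_rand() * step_s(p, s));
      lqratio = std::log(prop) - std::log(cur);
    } else {
      prop = cur + R::norm_rand() * step_s(p, s);
    }
    double lp0 = subj_lprior(p, cur, g) + ll_subj_cell(s, c);
    sp(p, s) = prop;
    double lp1 = subj_lprior(p, prop, g) + ll_subj_cell(s, c);
    bool ok = R_finite(lp1) && std::log(unif_rand()) < lp1 - lp0 + lqratio;
    try_s(p, s) += 1;
    if (ok) acc_s(p, s) += 1; else sp(p, s) = cur;
    if (adapting) adapt(step_s(p, s), 0, ok);
  }

  // ---- group-level updates ----------------------------------------------
  // Conjugate Gibbs for a Gaussian group mean: prior N(m0, s0), subject
  // values x_s ~ N(mu, sd).
  void gibbs_mu(int gi, int prow, double m0, double s0, int sd_gi) {
    if (fixg[gi]) return;
    double sd = g[sd_gi];
    double prec = 1.0 / (s0 * s0) + d.S / (sd * sd);
    double sum = 0.0;
    for (int s = 0; s < d.S; ++s) sum += sp(prow, s);
    double mean = (m0 / (s0 * s0) + sum / (sd * sd)) / prec;
    g[gi] = R::rnorm(mean, std::sqrt(1.0 / prec));
  }

  // Metropolis on log scale for a Gaussian group SD with Gamma(1, 0.001)
  // hyperprior (shape/rate) on the SD itself.
  void mh_sd(int gi, int prow, int mu_gi, bool adapting) {
    if (fixg[gi]) return;
    double cur = g[gi];
    double prop = cur * std::exp(R::norm_rand() * step_g[gi]);
    double lp0 = R::dgamma(cur, 1.0, 1000.0, 1);
    double lp1 = R::dgamma(prop, 1.0, 1000.0, 1);
    for (int s = 0; s < d.S; ++s) {
      lp0 += R::dnorm(sp(prow, s), g[mu_gi], cur, 1);
      lp1 += R::dnorm(sp(prow, s), g[mu_gi], prop, 1);
    }
    bool ok = R_finite(lp1) &&
      std::log(unif_rand()) < lp1 - lp0 + std::log(prop) - std::log(cur);
    try_g[gi] += 1;
    if (ok) { g[gi] = prop; acc_g[gi] += 1; }
    if (adapting) adapt(step_g[gi], 0, ok);
  }

  // Metropolis for a Beta shape hyperparameter with Uniform(lo, hi) prior.
  void mh_beta_shape(int gi, int prow, int other_gi, bool is_a,
                     double lo, double hi, bool adapting) {
    if (fixg[gi]) return;
    double cur = g[gi];
    double prop = cur + R::norm_rand() * step_g[gi];
    try_g[gi] += 1;
    if (prop < lo || prop > hi) { if (adapting) adapt(step_g[gi], 0, false); return; }
    double a0 = is_a ? cur : g[other_gi], b0 = is_a ? g[other_gi] : cur;
    double a1 = is_a ? prop : g[other_gi], b1 = is_a ? g[other_gi] : prop;
    double lp0 = 0.0, lp1 = 0.0;
    for (int s = 0; s < d.S; ++s) {
      lp0 += R::dbeta(sp(prow, s), a0, b0, 1);
      lp1 += R::dbeta(sp(prow, s), a1, b1, 1);
    }
    bool ok = R_finite(lp1) && std::log(unif_rand()) < lp1 - lp0;
    if (ok) { g[gi] = prop; acc_g[gi] += 1; }
    if (adapting) adapt(step_g[gi], 0, ok);
  }

  // Metropolis (log scale) for the Gamma shape of decision noise,
  // hyperprior Exp(0.1) (rate); Gibbs for the Gamma rate, hyperprior
  // Exp(10) = Gamma(1, 10), conjugate to the Gamma likelihood in its rate.
  void update_sigma_hypers(int c, bool adapting) {
    int gk = G_K_S0 + c, gl = G_L_S0 + c, prow = P_S0 + c;
    if (!fixg[gk]) {
      double cur = g[gk];
      double prop = cur * std::exp(R::norm_rand() * step_g[gk]);
      double lp0 = -0.1 * cur, lp1 = -0.1 * prop;
      for (int s = 0; s < d.S; ++s) {
        lp0 += R::dgamma(sp(prow, s), cur, 1.0 / g[gl], 1);
        lp1 += R::dgamma(sp(prow, s), prop, 1.0 / g[gl], 1);
      }
      bool ok = R_finite(lp1) &&
        std::log(unif_rand()) < lp1 - lp0 + std::log(prop) - std::log(cur);
      try_g[gk] += 1;
      if (ok) { g[gk] = prop; acc_g[gk] += 1; }
      if (adapting) adapt(step_g[gk], 0, ok);
    }
    if (!fixg[gl]) {
      double sum = 0.0;
      for (int s = 0; s < d.S; ++s) sum += sp(prow, s);
      g[gl] = R::rgamma(1.0 + d.S * g[gk], 1.0 / (10.0 + sum));
    }
  }

  // Translation move for a Gaussian family: shift every subject's value
  // and the group mean by a common delta. Subject-prior terms are
  // invariant, so the ratio is hyperprior(mu) + likelihood. Breaks the
  // slow random walk of group means along data-constrained ridges.
  double step_shift[9] = {1, 1, 1, 1, 1, 1, 1, 1, 1}; // R0, A_h1, A_h6, B0..3 (+spare)
  void shift_family(int which, int prow, int gmu, double m0, double s0,
                    bool adapting, std::vector<double>& prop_dr) {
    if (fixg[gmu]) return;
    for (int s = 0; s < d.S; ++s) if (fixs(prow, s)) return;
    double delta = R::norm_rand() * step_shift[which];
    double lp0 = R::dnorm(g[gmu], m0, s0, 1);
    double lp1 = R::dnorm(g[gmu] + delta, m0, s0, 1);
    if (prow == P_R0) {
      for (int s = 0; s < d.S; ++s) lp0 += ll_subj(s, dR);
      for (int s = 0; s < d.S; ++s) sp(prow, s) += delta;
      for (int s = 0; s < d.S; ++s) refresh_dr_subj(s, prop_dr);
      for (int s = 0; s < d.S; ++s) lp1 += ll_subj(s, prop_dr);
    } else {
      int c = (prow == P_A_H1) ? 0 : (prow == P_A_H6) ? 2 : prow - P_B0;
      for (int s = 0; s < d.S; ++s) lp0 += ll_subj_cell(s, c);
      for (int s = 0; s < d.S; ++s) sp(prow, s) += delta;
      for (int s = 0; s < d.S; ++s) lp1 += ll_subj_cell(s, c);
    }
    bool ok = R_finite(lp1) && std::log(unif_rand()) < lp1 - lp0;
    if (ok) {
      g[gmu] += delta;
      if (prow == P_R0) dR.swap(prop_dr);
    } else {
      for (int s = 0; s < d.S; ++s) sp(prow, s) -= delta;
    }
    if (adapting) adapt(step_shift[which], 0, ok);
  }

  void sweep(bool adapting, std::vector<double>& prop_dr) {
    for (int s = 0; s < d.S; ++s) {
      update_learning(s, P_R0, adapting, prop_dr);
      update_learning(s, P_A1, adapting, prop_dr);
      update_learning(s, P_AI, adapting, prop_dr);
      update_decision(s, P_A_H1, adapting);
      update_decision(s, P_A_H6, adapting);
      for (int p = P_B0; p <= P_S3; ++p) update_decision(s, p, adapting);
    }
    if (sample_group) {
      shift_family(0, P_R0, G_MU_R0, 50.0, 14.0, adapting, prop_dr);
      shift_family(1, P_A_H1, G_MU_A_H1, 0.0, 100.0, adapting, prop_dr);
      shift_family(2, P_A_H6, G_MU_A_H6, 0.0, 100.0, adapting, prop_dr);
      for (int c = 0; c < 4; ++c)
        shift_family(3 + c, P_B0 + c, G_MU_B0 + c, 0.0, 100.0, adapting, prop_dr);
    }
    if (sample_group) {
      gibbs_mu(G_MU_R0, P_R0, 50.0, 14.0, G_SD_R0);
      mh_sd(G_SD_R0, P_R0, G_MU_R0, adapting);
      mh_beta_shape(G_A_A1, P_A1, G_B_A1, true, 0.1, 10.0, adapting);
      mh_beta_shape(G_B_A1, P_A1, G_A_A1, false, 0.5, 10.0, adapting);
      mh_beta_shape(G_A_AI, P_AI, G_B_AI, true, 0.1, 10.0, adapting);
      mh_beta_shape(G_B_AI, P_AI, G_A_AI, false, 0.1, 10.0, adapting);
      gibbs_mu(G_MU_A_H1, P_A_H1, 0.0, 100.0, G_SD_A_H1);
      gibbs_mu(G_MU_A_H6, P_A_H6, 0.0, 100.0, G_SD_A_H6);
      mh_sd(G_SD_A_H1, P_A_H1, G_MU_A_H1, adapting);
      mh_sd(G_SD_A_H6, P_A_H6, G_MU_A_H6, adapting);
      for (int c = 0; c < 4; ++c) {
        gibbs_mu(G_MU_B0 + c, P_B0 + c, 0.0, 100.0, G_SD_B0 + c);
        mh_sd(G_SD_B0 + c, P_B0 + c, G_MU_B0 + c, adapting);
        update_sigma_hypers(c, adapting);
      }
    }
  }
};

// [[Rcpp::export(name = ".run_chain_cpp")]]
List run_chain_cpp(List data, NumericVector group_init, NumericMatrix subj_init,
                   LogicalVector fix_group, LogicalMatrix fix_subj,
                   bool sample_group, int n_burn, int n_keep, int thin) {
  Data d;
  d.fr = as<NumericMatrix>(data["fr"]);
  d.fa = as<IntegerMatrix>(data["fa"]);
  d.subj = as<IntegerVector>(data["subj"]);
  d.cell = as<IntegerVector>(data["cell"]);
  d.di = as<IntegerVector>(data["di"]);
  d.ch = as<IntegerVector>(data["ch"]);
  d.S = as<int>(data["S"]);
  d.N = d.subj.size();
  d.mode = as<int>(data["mode"]);
  d.by_subj.assign(d.S, {});
  d.by_subj_cell.assign(d.S, {});
  for (int i = 0; i < d.N; ++i) {
    d.by_subj[d.subj[i]].push_back(i);
    d.by_subj_cell[d.subj[i]][d.cell[i]].push_back(i);
  }

  Sampler smp(d, group_init, subj_init, fix_group, fix_subj, sample_group);
  std::vector<double> prop_dr(d.N);

  GetRNGstate();
  for (int it = 0; it < n_burn; ++it) smp.sweep(true, prop_dr);
  NumericMatrix gdraws(n_keep, N_GROUP);
  NumericVector sdraws(Dimension(n_keep, N_SUBJ, d.S));
  for (int it = 0; it < n_keep; ++it) {
    for (int t = 0; t < thin; ++t) smp.sweep(false, prop_dr);
    for (int j = 0; j < N_GROUP; ++j) gdraws(it, j) = smp.g[j];
    for (int s = 0; s < d.S; ++s)
      for (int p = 0; p < N_SUBJ; ++p)
        sdraws[it + n_keep * (p + N_SUBJ * s)] = smp.sp(p, s);
  }
  PutRNGstate();

  NumericMatrix acc(N_SUBJ, d.S);
  for (int s = 0; s < d.S; ++s)
    for (int p = 0; p < N_SUBJ; ++p)
      acc(p, s) = smp.try_s(p, s) > 0 ? smp.acc_s(p, s) / smp.try_s(p, s) : NA_REAL;
  NumericVector accg(N_GROUP);
  for (int j = 0; j < N_GROUP; ++j)
    accg[j] = smp.try_g[j] > 0 ? smp.acc_g[j] / smp.try_g[j] : NA_REAL;

  return List::create(
    _["group"] = gdraws, _["subject"] = sdraws,
    _["accept_subject"] = acc, _["accept_group"] = accg
  );
}

// Simulate one session's forced rewards and free choices for all games.
// Replicates the per-game RNG call order of the R-level generator
// (4 forced-reward normals, then per free trial one uniform for the choice
// and one normal for the reward), so the two paths agree draw-for-draw
// under the same RNG state. Rewards are rounded to the nearest integer
// point (R's round semantics via fround).
// [[Rcpp::export(name = ".sim_session_cpp")]]
List sim_session_cpp(IntegerVector horizon, IntegerVector equal_info,
                     NumericVector mean_left, NumericVector mean_right,
                     IntegerMatrix fa, double reward_sd,
                     double R0, double a1, double ai, int mode,
                     NumericVector A, NumericVector B, NumericVector sig) {
  int G = horizon.size();
  NumericMatrix fr(4, G);
  IntegerMatrix free_choice(6, G);
  NumericMatrix free_reward(6, G);
  std::fill(free_choice.begin(), free_choice.end(), NA_INTEGER);
  std::fill(free_reward.begin(), free_reward.end(), NA_REAL);
  double ad = ai * ai / (1.0 - ai);
  double w0 = (mode == 0 ? a1 / (1.0 - a1) : a1) - ad;
  GetRNGstate();
  for (int i = 0; i < G; ++i) {
    double R[2] = {R0, R0};
    double w[2] = {w0, w0};
    int nplay[2] = {0, 0};
    for (int k = 0; k < 4; ++k) {
      int j = fa(k, i); // 0 left, 1 right
      double mu = j == 0 ? mean_left[i] : mean_right[i];
      double r = R::fround(R::rnorm(mu, reward_sd), 0);
      fr(k, i) = r;
      double wpre = w[j] + ad;
      double al = wpre / (1.0 + wpre);
      R[j] += al * (r - R[j]);
      w[j] = al;
      w[1 - j] += ad;
      nplay[j] += 1;
    }
    int h = horizon[i];           // 1 or 6
    int cell = (h == 6 ? 2 : 0) + (equal_info[i] ? 1 : 0);
    int n_free = (h == 1) ? 1 : 6;
    for (int t = 0; t < n_free; ++t) {
      double dRv = R[0] - R[1];
      int di = 0;
      if (!equal_info[i]) {
        di = (nplay[1] > nplay[0]) ? 1 : (nplay[1] < nplay[0]) ? -1 : 0;
      }
      double Aterm = (di == 0) ? 0.0 : A[h == 6 ? 1 : 0] * di;
      double x = (dRv + Aterm + B[cell]) / sig[cell];
      double p_right = 1.0 / (1.0 + std::exp(x));
      int choice = (unif_rand() < p_right) ? 1 : 0;
      double mu = choice == 0 ? mean_left[i] : mean_right[i];
      double r = R::fround(R::rnorm(mu, reward_sd), 0);
      free_choice(t, i) = choice;
      free_reward(t, i) = r;
      double wpre = w[choice] + ad;
      double al = wpre / (1.0 + wpre);
      R[choice] += al * (r - R[choice]);
      w[choice] = al;
      w[1 - choice] += ad;
      nplay[choice] += 1;
    }
  }
  PutRNGstate();
  return List::create(_["fr"] = fr, _["free_choice"] = free_choice,
                      _["free_reward"] = free_reward);
}

// Total dataset log-likelihood under given subject parameters (used by the
// R-side likelihood cross-checks and the grid oracle test).
// [[Rcpp::export(name = ".study_loglik_cpp")]]
double study_loglik_cpp(List data, NumericMatrix subj_par) {
  Data d;
  d.fr = as<NumericMatrix>(data["fr"]);
  d.fa = as<IntegerMatrix>(data["fa"]);
  d.subj = as<IntegerVector>(data["subj"]);
  d.cell = as<IntegerVector>(data["cell"]);
  d.di = as<IntegerVector>(data["di"]);
  d.ch = as<IntegerVector>(data["ch"]);
  d.S = as<int>(data["S"]);
  d.N = d.subj.size();
  d.mode = as<int>(data["mode"]);
  double ll = 0.0;
  double frb[4]; int fab[4];
  std::vector<double> dr(d.N);
  for (int i = 0; i < d.N; ++i) {
    for (int k = 0; k < 4; ++k) { frb[k] = d.fr(k, i); fab[k] = d.fa(k, i); }
    int s = d.subj[i];
    dr[i] = kalman_dr(frb, fab, subj_par(P_R0, s), subj_par(P_A1, s),
                      subj_par(P_AI, s), d.mode);
    ll += obs_ll(d, subj_par, dr, i);
  }
  return ll;
}
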