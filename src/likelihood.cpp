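#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Belief-filtering core for the three-armed bandit active inference agent.
// Outcome coding: 1 = win, 0 = loss. Choices are 0-based here (R passes
// choice - 1). Beliefs reset fully at every block boundary.

namespace {

struct AifParams {
  double beta0, eta_win, eta_loss, omega, rho_p;
  bool beta_dynamic;
  double pref_win, prior_mass, beta_floor, prob_floor;
  double beta_step;
  bool beta_mult;
  double novelty_weight;
};

struct AifState {
  double a[2][3];   // row 0 = win counts, row 1 = loss counts
  double a0[2][3];
  double beta;
};

void aif_reset(AifState &s, const AifParams &p) {
  for (int j = 0; j < 3; ++j) {
    s.a0[0][j] = p.prior_mass * (1.0 - p.rho_p);
    s.a0[1][j] = p.prior_mass * p.rho_p;
    s.a[0][j] = s.a0[0][j];
    s.a[1][j] = s.a0[1][j];
  }
  s.beta = p.beta0;
}

// Expected free energy per option: negative expected reward utility minus a
// Dirichlet novelty bonus (expected information gain about that option's
// outcome probabilities). Lower G is better.
void aif_efe(const AifState &s, const AifParams &p, double *G,
             double *Awin) {
  for (int j = 0; j < 3; ++j) {
    double cs = s.a[0][j] + s.a[1][j];
    double Aw = s.a[0][j] / cs;
    double Al = s.a[1][j] / cs;
    double novelty = 0.5 * (Aw * (1.0 / s.a[0][j] - 1.0 / cs) +
                            Al * (1.0 / s.a[1][j] - 1.0 / cs));
    G[j] = -p.pref_win * Aw - p.novelty_weight * novelty;
    if (Awin) Awin[j] = Aw;
  }
}

void softmax_negG(const double *G, double gamma, double *pi) {
  double v[3], m = R_NegInf, z = 0.0;
  for (int j = 0; j < 3; ++j) {
    v[j] = -gamma * G[j];
    if (v[j] > m) m = v[j];
  }
  for (int j = 0; j < 3; ++j) {
    v[j] = std::exp(v[j] - m);
    z += v[j];
  }
  for (int j = 0; j < 3; ++j) pi[j] = v[j] / z;
}

// Post-outcome belief update. The pre-outcome policy distribution is
// reweighted by each action's outcome surprise F_j = -ln A(o | j) to give
// the post-outcome policy beliefs; the signed policy-belief change score
// G_error = (pi_post - pi_pre) . (-G_pre) is positive when the outcome
// pushes beliefs toward valuable actions (wins) and negative when it
// pushes them away (surprising losses), and drives the decision noise.
// Learning adds the rate-scaled count for the observed outcome after the
// accumulated evidence has decayed toward the prior (forgetting).
void aif_step(AifState &s, const AifParams &p, int choice, int outcome,
              const double *G_pre, const double *pi_pre,
              const double *Awin_pre,
              double *F, double *Gerr, double *bupd) {
  double Fvec[3];
  for (int j = 0; j < 3; ++j) {
    double A_oj = (outcome == 1) ? Awin_pre[j] : (1.0 - Awin_pre[j]);
    Fvec[j] = -std::log(std::max(A_oj, 1e-16));
  }
  *F = Fvec[choice];

  double gamma = 1.0 / s.beta;
  double v[3], m = R_NegInf, z = 0.0, pi_post[3];
  for (int j = 0; j < 3; ++j) {
    v[j] = -gamma * G_pre[j] - Fvec[j];
    if (v[j] > m) m = v[j];
  }
  for (int j = 0; j < 3; ++j) {
    v[j] = std::exp(v[j] - m);
    z += v[j];
  }
  for (int j = 0; j < 3; ++j) pi_post[j] = v[j] / z;

  double ge = 0.0;
  for (int j = 0; j < 3; ++j) ge += (pi_post[j] - pi_pre[j]) * (-G_pre[j]);
  *Gerr = ge;

  int jstar = 0;
  for (int j = 1; j < 3; ++j)
    if (pi_pre[j] > pi_pre[jstar]) jstar = j;
  *bupd = pi_post[jstar] - pi_pre[jstar];

  if (p.beta_dynamic) {
    if (p.beta_mult)
      s.beta = std::max(p.beta_floor, s.beta * std::exp(-p.beta_step * ge));
    else
      s.beta = std::max(p.beta_floor, s.beta - p.beta_step * ge);
  }

  for (int o = 0; o < 2; ++o)
    for (int j = 0; j < 3; ++j)
      s.a[o][j] = s.a0[o][j] + (1.0 - p.omega) * (s.a[o][j] - s.a0[o][j]);
  if (outcome == 1)
    s.a[0][choice] += p.eta_win;
  else
    s.a[1][choice] += p.eta_loss;
}

bool aif_params_ok(const AifParams &p) {
  return R_finite(p.beta0) && p.beta0 > 0.0 && R_finite(p.eta_win) &&
         p.eta_win >= 0.0 && R_finite(p.eta_loss) && p.eta_loss >= 0.0 &&
         R_finite(p.omega) && p.omega >= 0.0 && p.omega <= 1.0 &&
         R_finite(p.rho_p) && p.rho_p > 0.0 && p.rho_p < 1.0;
}

}  // namespace

// [[Rcpp::export]]
List aif_filter_cpp(IntegerVector block, IntegerVector choice,
                    IntegerVector outcome, double beta0, double eta_win,
                    double eta_loss, double omega, double rho_p,
                    bool beta_dynamic, double pref_win, double prior_mass,
                    double beta_floor, double prob_floor, double beta_step,
                    bool beta_mult, double novelty_weight) {
  const int n = block.size();
  AifParams p{beta0, eta_win, eta_loss, omega, rho_p,
              beta_dynamic, pref_win, prior_mass, beta_floor, prob_floor,
              beta_step, beta_mult, novelty_weight};
  if (!aif_params_ok(p)) return List::create(_["loglik"] = R_NegInf);

  AifState s;
  NumericVector ap(n), ent(n), Fv(n), ge(n), bu(n), betav(n);
  NumericMatrix pim(n, 3), Gm(n, 3);
  double ll = 0.0;
  int cur = -1;
  bool first = true;
  for (int t = 0; t < n; ++t) {
    if (first || block[t] != cur) {
      aif_reset(s, p);
      cur = block[t];
      first = false;
    }
    double G[3], Awin[3], pi[3];
    aif_efe(s, p, G, Awin);
    betav[t] = s.beta;
    softmax_negG(G, 1.0 / s.beta, pi);
    int c = choice[t];
    ap[t] = pi[c];
    ll += std::log(std::max(pi[c], p.prob_floor));
    double e = 0.0;
    for (int j = 0; j < 3; ++j) {
      pim(t, j) = pi[j];
      Gm(t, j) = G[j];
      if (pi[j] > 0) e -= pi[j] * std::log(pi[j]);
    }
    ent[t] = e;
    aif_step(s, p, c, outcome[t], G, pi, Awin, &Fv[t], &ge[t], &bu[t]);
  }
  return List::create(
      _["loglik"] = ll, _["action_prob"] = ap, _["pi"] = pim, _["G"] = Gm,
      _["entropy"] = ent, _["F"] = Fv, _["G_error"] = ge,
      _["belief_update"] = bu, _["beta"] = betav);
}

// [[Rcpp::export]]
List aif_sim_cpp(NumericMatrix probs, int n_trials, double beta0,
                 double eta_win, double eta_loss, double omega, double rho_p,
                 bool beta_dynamic, double pref_win, double prior_mass,
                 double beta_floor, double beta_step, bool beta_mult,
                 double novelty_weight) {
  const int nb = probs.nrow();
  const int n = nb * n_trials;
  AifParams p{beta0, eta_win, eta_loss, omega, rho_p,
              beta_dynamic, pref_win, prior_mass, beta_floor, 1e-10,
              beta_step, beta_mult, novelty_weight};
  if (!aif_params_ok(p)) stop("invalid agent parameters");

  AifState s;
  IntegerVector blockv(n), trialv(n), choicev(n), outcomev(n);
  NumericVector ap(n), ent(n), Fv(n), ge(n), bu(n), betav(n);
  NumericMatrix pim(n, 3), Gm(n, 3);
  int t = 0;
  for (int b = 0; b < nb; ++b) {
    aif_reset(s, p);
    for (int k = 0; k < n_trials; ++k, ++t) {
      double G[3], Awin[3], pi[3];
      aif_efe(s, p, G, Awin);
      betav[t] = s.beta;
      softmax_negG(G, 1.0 / s.beta, pi);
      double u = unif_rand(), acc = 0.0;
      int c = 2;
      for (int j = 0; j < 3; ++j) {
        acc += pi[j];
        if (u <= acc) { c = j; break; }
      }
      int o = (unif_rand() < probs(b, c)) ? 1 : 0;
      blockv[t] = b + 1;
      trialv[t] = k + 1;
      choicev[t] = c + 1;
      outcomev[t] = o;
      ap[t] = pi[c];
      double e = 0.0;
      for (int j = 0; j < 3; ++j) {
        pim(t, j) = pi[j];
        Gm(t, j) = G[j];
        if (pi[j] > 0) e -= pi[j] * std::log(pi[j]);
      }
      ent[t] = e;
      aif_step(s, p, c, o, G, pi, Awin, &Fv[t], &ge[t], &bu[t]);
    }
  }
  return List::create(
      _["block"] = blockv, _["trial"] = trialv, _["choice"] = choicev,
      _["outcome"] = outcomev, _["action_prob"] = ap, _["pi"] = pim,
      _["G"] = Gm, _["entropy"] = ent, _["F"] = Fv, _["G_error"] = ge,
      _["belief_update"] = bu, _["beta"] = betav);
}

// Rescorla-Wagner family: Q <- Q + eta_{win/loss} * (r - Q), r in {rs, 0},
// static softmax precision gamma = 1/beta0, Q reset to rs/2 at block start.

// [[Rcpp::export]]
List rw_filter_cpp(IntegerVector block, IntegerVector choice,
                   IntegerVector outcome, double beta0, double eta_win,
                   double eta_loss, double rs, double prob_floor) {
  const int n = block.size();
  if (!(R_finite(beta0) && beta0 > 0 && eta_win >= 0 && eta_win <= 1 &&
        eta_loss >= 0 && eta_loss <= 1 && R_finite(rs) && rs > 0))
    return List::create(_["loglik"] = R_NegInf);
  double Q[3];
  NumericVector ap(n), ent(n);
  NumericMatrix pim(n, 3);
  double gamma = 1.0 / beta0, ll = 0.0;
  int cur = -1;
  bool first = true;
  for (int t = 0; t < n; ++t) {
    if (first || block[t] != cur) {
      Q[0] = Q[1] = Q[2] = rs / 2.0;
      cur = block[t];
      first = false;
    }
    double v[3], m = R_NegInf, z = 0.0, pi[3];
    for (int j = 0; j < 3; ++j) {
      v[j] = gamma * Q[j];
      if (v[j] > m) m = v[j];
    }
    for (int j = 0; j < 3; ++j) {
      v[j] = std::exp(v[j] - m);
      z += v[j];
    }
    for (int j = 0; j < 3; ++j) pi[j] = v[j] / z;
    int c = choice[t];
    ap[t] = pi[c];
    ll += std::log(std::max(pi[c], prob_floor));
    double e = 0.0;
    for (int j = 0; j < 3; ++j) {
      pim(t, j) = pi[j];
      if (pi[j] > 0) e -= pi[j] * std::log(pi[j]);
    }
    ent[t] = e;
    double r = (outcome[t] == 1) ? rs : 0.0;
    double eta = (outcome[t] == 1) ? eta_win : eta_loss;
    Q[c] += eta * (r - Q[c]);
  }
  return List::create(_["loglik"] = ll, _["action_prob"] = ap,
                      _["pi"] = pim, _["entropy"] = ent);
}

// [[Rcpp::export]]
List rw_sim_cpp(NumericMatrix probs, int n_trials, double beta0,
                double eta_win, double eta_loss, double rs) {
  const int nb = probs.nrow();
  const int n = nb * n_trials;
  if (!(R_finite(beta0) && beta0 > 0 && eta_win >= 0 && eta_win <= 1 &&
        eta_loss >= 0 && eta_loss <= 1 && R_finite(rs) && rs > 0))
    stop("invalid Rescorla-Wagner parameters");
  double Q[3], gamma = 1.0 / beta0;
  IntegerVector blockv(n), trialv(n), choicev(n), outcomev(n);
  NumericVector ap(n), ent(n);
  NumericMatrix pim(n, 3);
  int t = 0;
  for (int b = 0; b < nb; ++b) {
    Q[0] = Q[1] = Q[2] = rs / 2.0;
    for (int k = 0; k < n_trials; ++k, ++t) {
      double v[3], m = R_NegInf, z = 0.0, pi[3];
      for (int j = 0; j < 3; ++j) {
        v[j] = gamma * Q[j];
        if (v[j] > m) m = v[j];
      }
      for (int j = 0; j < 3; ++j) {
        v[j] = std::exp(v[j] - m);
        z += v[j];
      }
      for (int j = 0; j < 3; ++j) pi[j] = v[j] / z;
      double u = unif_rand(), acc = 0.0;
      int c = 2;
      for (int j = 0; j < 3; ++j) {
        acc += pi[j];
        if (u <= acc) { c = j; break; }
      }
      int o = (unif_rand() < probs(b, c)) ? 1 : 0;
      blockv[t] = b + 1;
      trialv[t] = k + 1;
      choicev[t] = c + 1;
      outcomev[t] = o;
      ap[t] = pi[c];
      double e = 0.0;
      for (int j = 0; j < 3; ++j) {
        pim(t, j) = pi[j];
        if (pi[j] > 0) e -= pi[j] * std::log(pi[j]);
      }
      ent[t] = e;
      double r = (o == 1) ? rs : 0.0;
      double eta = (o == 1) ? eta_win : eta_loss;
      Q[c] += eta * (r - Q[c]);
    }
  }
  return List::create(_["block"] = blockv, _["trial"] = trialv,
                      _["choice"] = choicev, _["outcome"] = outcomev,
                      _["action_prob"] = ap, _["pi"] = pim,
                      _["entropy"] = ent);
}
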