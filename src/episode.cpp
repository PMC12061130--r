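#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Native episode engine. Mirrors the R-level step functions operation for
// operation, including the order in which random numbers are consumed, so
// that engine = "r" and engine = "cpp" produce identical traces from the
// same seed. Any change here must keep that parity (see the engine-parity
// tests).

namespace {

struct EnvSpec {
  int kind;              // 0 = bernoulli, 1 = gaussian
  int n_arms;
  std::vector<double> p1;      // success prob (bern) or mean (gauss)
  std::vector<double> p2;      // sigma (gauss only)
  std::vector<double> regret;  // per-arm expected regret
  int best_arm;                // 0-based, first optimal arm
};

EnvSpec unpack_env(const List& env) {
  EnvSpec e;
  e.kind = as<int>(env["kind"]);
  NumericVector p1 = env["p1"];
  e.n_arms = p1.size();
  e.p1.assign(p1.begin(), p1.end());
  if (e.kind == 1) {
    NumericVector p2 = env["p2"];
    e.p2.assign(p2.begin(), p2.end());
  }
  NumericVector reg = env["regret"];
  e.regret.assign(reg.begin(), reg.end());
  e.best_arm = as<int>(env["best_arm"]);  // already 0-based
  return e;
}

double draw_reward(const EnvSpec& e, int arm) {
  if (e.kind == 0) return unif_rand() < e.p1[arm] ? 1.0 : 0.0;
  return e.p1[arm] + e.p2[arm] * norm_rand();
}

// Softmax draw replicating the R-side arithmetic exactly:
// p = exp(x - max) / sum(exp(x - max)); arm = 1 + sum(u > cumsum(p)).
int softmax_draw(const std::vector<double>& x) {
  const int n = (int)x.size();
  double m = x[0];
  for (int i = 1; i < n; ++i) if (x[i] > m) m = x[i];
  std::vector<double> w(n);
  double z = 0.0;
  for (int i = 0; i < n; ++i) { w[i] = std::exp(x[i] - m); z += w[i]; }
  double u = unif_rand();
  double cum = 0.0;
  int arm = n - 1;
  for (int i = 0; i < n; ++i) {
    cum += w[i] / z;
    if (u <= cum) { arm = i; break; }
  }
  return arm;
}

struct Rec {
  IntegerVector arm;
  NumericVector reward, delta, rho, regret;
  Rec(int h) : arm(h), reward(h), delta(h), rho(h), regret(h) {}
};

List opal_episode(const List& agent, const EnvSpec& env, int horizon, Rec& rec) {
  const int n = env.n_arms;
  const double alpha_c = as<double>(agent["alpha_c"]);
  const double alpha_g = as<double>(agent["alpha_g"]);
  const double alpha_n = as<double>(agent["alpha_n"]);
  const double beta    = as<double>(agent["beta"]);
  const double k       = as<double>(agent["k"]);
  const double phi     = as<double>(agent["phi"]);
  const double T       = as<double>(agent["T_anneal"]);
  const double gn0     = as<double>(agent["gn0"]);
  const double floor_  = as<double>(agent["weight_floor"]);
  const double cap     = as<double>(agent["cap"]);  // Inf when uncapped
  const double eta0    = as<double>(agent["eta0"]);
  const double zeta0   = as<double>(agent["zeta0"]);
  const bool g_only    = as<bool>(agent["g_only"]);
  const bool freeze_n  = as<bool>(agent["freeze_n"]);
  const bool forced    = as<bool>(agent["forced_sampling"]);
  NumericVector v0 = agent["v0"];  // length n

  std::vector<double> V(v0.begin(), v0.end());
  std::vector<double> G(n, gn0), N(n, gn0), x(n);
  double eta = eta0, zeta = zeta0;
  int t = 0;

  for (int i = 0; i < horizon; ++i) {
    // dopamine modulation from the Beta meta-critic
    double rho = 0.0;
    if (k > 0.0) {
      double tot = eta + zeta;
      double mm = eta / tot;
      double ss = std::sqrt(eta * zeta / (tot * tot * (tot + 1.0)));
      if (mm - phi * ss > 0.5 || mm + phi * ss < 0.5) {
        rho = k * (mm - 0.5);
        if (rho > 1.0) rho = 1.0; else if (rho < -1.0) rho = -1.0;
      }
    }
    int arm;
    if (forced && t < n) {
      arm = t;  // one pull per arm before the policy is used
    } else {
      double bg = beta * (1.0 + rho), bn = beta * (1.0 - rho);
      for (int a = 0; a < n; ++a)
        x[a] = g_only ? bg * G[a] : bg * G[a] - bn * N[a];
      arm = softmax_draw(x);
    }
    double r = draw_reward(env, arm);
    double delta = r - V[arm];
    V[arm] += alpha_c * delta;
    double ann = 1.0 + (double)t / T;
    G[arm] += (alpha_g / ann) * G[arm] * delta;
    if (!freeze_n) N[arm] += (alpha_n / ann) * N[arm] * (-delta);
    if (G[arm] > cap) G[arm] = cap;
    if (N[arm] > cap) N[arm] = cap;
    if (G[arm] < floor_) G[arm] = floor_;
    if (N[arm] < floor_) N[arm] = floor_;
    if (delta > 0.0) eta += 1.0; else zeta += 1.0;
    ++t;
    rec.arm[i] = arm + 1;
    rec.reward[i] = r;
    rec.delta[i] = delta;
    rec.rho[i] = rho;
    rec.regret[i] = env.regret[arm];
  }
  return List::create(_["V"] = NumericVector(V.begin(), V.end()),
                      _["G"] = NumericVector(G.begin(), G.end()),
                      _["N"] = NumericVector(N.begin(), N.end()),
                      _["eta"] = eta, _["zeta"] = zeta, _["t"] = t);
}

List q_episode(const List& agent, const EnvSpec& env, int horizon, Rec& rec) {
  const int n = env.n_arms;
  const double alpha = as<double>(agent["alpha"]);
  const double beta  = as<double>(agent["beta"]);
  const double q0    = as<double>(agent["q0"]);
  std::vector<double> Q(n, q0), x(n);
  for (int i = 0; i < horizon; ++i) {
    for (int a = 0; a < n; ++a) x[a] = beta * Q[a];
    int arm = softmax_draw(x);
    double r = draw_reward(env, arm);
    double delta = r - Q[arm];
    Q[arm] += alpha * delta;
    rec.arm[i] = arm + 1;
    rec.reward[i] = r;
    rec.delta[i] = delta;
    rec.rho[i] = NA_REAL;
    rec.regret[i] = env.regret[arm];
  }
  return List::create(_["Q"] = NumericVector(Q.begin(), Q.end()),
                      _["t"] = horizon);
}

List ucb_episode(const List& agent, const EnvSpec& env, int horizon, Rec& rec) {
  const int n = env.n_arms;
  const double c = as<double>(agent["c"]);
  std::vector<double> means(n, 0.0), score(n);
  std::vector<int> counts(n, 0);
  for (int i = 0; i < horizon; ++i) {
    int arm;
    if (i < n) {
      arm = i;  // warm start: one forced pull per arm
    } else {
      double logt = std::log((double)i);
      for (int a = 0; a < n; ++a)
        score[a] = means[a] + c * std::sqrt(2.0 * logt / (double)counts[a]);
      double best = score[0];
      for (int a = 1; a < n; ++a) if (score[a] > best) best = score[a];
      std::vector<int> ties;
      for (int a = 0; a < n; ++a) if (score[a] == best) ties.push_back(a);
      if (ties.size() == 1) {
        arm = ties[0];
      } else {
        int j = (int)std::floor(unif_rand() * (double)ties.size());
        if (j >= (int)ties.size()) j = (int)ties.size() - 1;
        arm = ties[j];
      }
    }
    double r = draw_reward(env, arm);
    double delta = r - means[arm];
    counts[arm] += 1;
    means[arm] += (r - means[arm]) / (double)counts[arm];
    rec.arm[i] = arm + 1;
    rec.reward[i] = r;
    rec.delta[i] = delta;
    rec.rho[i] = NA_REAL;
    rec.regret[i] = env.regret[arm];
  }
  return List::create(_["counts"] = IntegerVector(counts.begin(), counts.end()),
                      _["means"] = NumericVector(means.begin(), means.end()),
                      _["t"] = horizon);
}

List simple_episode(const List& agent, const EnvSpec& env, int horizon,
                    Rec& rec, bool uniform) {
  const int n = env.n_arms;
  for (int i = 0; i < horizon; ++i) {
    int arm;
    if (uniform) {
      arm = (int)std::floor(unif_rand() * (double)n);
      if (arm >= n) arm = n - 1;
    } else {
      arm = env.best_arm;
    }
    double r = draw_reward(env, arm);
    rec.arm[i] = arm + 1;
    rec.reward[i] = r;
    rec.delta[i] = NA_REAL;
    rec.rho[i] = NA_REAL;
    rec.regret[i] = env.regret[arm];
  }
  return List::create(_["t"] = horizon);
}

}  // namespace

// [[Rcpp::export]]
List cpp_run_episode(List agent, List env, int horizon) {
  RNGScope scope;  // uses R's global RNG; seed with set.seed() beforehand
  EnvSpec e = unpack_env(env);
  std::string type = as<std::string>(agent["type"]);
  Rec rec(horizon);
  List fin;
  if (type == "opal")         fin = opal_episode(agent, e, horizon, rec);
  else if (type == "q")       fin = q_episode(agent, e, horizon, rec);
  else if (type == "ucb")     fin = ucb_episode(agent, e, horizon, rec);
  else if (type == "uniform") fin = simple_episode(agent, e, horizon, rec, true);
  else if (type == "oracle")  fin = simple_episode(agent, e, horizon, rec, false);
  else stop("unknown native agent type: " + type);
  return List::create(_["arm"] = rec.arm, _["reward"] = rec.reward,
                      _["delta"] = rec.delta, _["rho"] = rec.rho,
                      _["regret"] = rec.regret, _["final_state"] = fin);
}
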