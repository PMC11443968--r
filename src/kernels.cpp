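#include <Rcpp.h>
using namespace Rcpp;

// Semi-implicit Euler rollout of a point mass under a constant input,
// optionally with velocity-dependent resistance 0.5 + 0.005 v^2 and a
// non-negativity clamp on velocity. These kernels sit on the hot path of the
// per-step risk evaluation and the planner's candidate scan.

static inline double step_v(double v, double a, double dt, bool resist) {
  double drag = resist ? (0.5 + 0.005 * v * v) : 0.0;
  double vn = v + (a - drag) * dt;
  return vn > 0.0 ? vn : 0.0;
}

// Positions at every `stride`-th step over n_steps (front-bumper track
// coordinate). Returns n_steps / stride values.
// [[Rcpp::export]]
NumericVector cpp_rollout_pos(double s0, double v0, double a, int n_steps,
                              double dt, int stride, bool resist) {
  int n_out = n_steps / stride;
  NumericVector out(n_out);
  double s = s0, v = v0;
  int j = 0;
  for (int k = 1; k <= n_steps; ++k) {
    v = step_v(v, a, dt, resist);
    s += v * dt;
    if (k % stride == 0) out[j++] = s;
  }
  return out;
}

static inline double norm_cdf(double x) {
  return 0.5 * std::erfc(-x * M_SQRT1_2);
}

// probability mass of the half-half Gaussian mixture inside [lo, hi]
static inline double mix_prob(double mu, double sigma, double sqrt_phi,
                              double lo, double hi) {
  if (sigma <= 0.0) return (lo <= mu && mu <= hi) ? 1.0 : 0.0;
  double s2 = sigma * sqrt_phi;
  return 0.5 * (norm_cdf((hi - mu) / sigma) - norm_cdf((lo - mu) / sigma)) +
         0.5 * (norm_cdf((hi - mu) / s2) - norm_cdf((lo - mu) / s2));
}

// perceived risk of a sequence of ego positions at the belief times:
// per-point collision-band probability, aggregated by max (or capped sum)
static double risk_of_positions(const double* pos, const NumericVector& mu,
                                const NumericVector& sigma, int n,
                                double phi, double corridor, double L,
                                bool agg_max) {
  double sqrt_phi = std::sqrt(phi);
  double risk = 0.0;
  for (int k = 0; k < n; ++k) {
    double e = pos[k];
    if (e <= corridor) continue;
    double lo = e - L > corridor ? e - L : corridor;
    double p = mix_prob(mu[k], sigma[k], sqrt_phi, lo, e + L);
    if (agg_max) {
      if (p > risk) risk = p;
    } else {
      risk += p;
    }
  }
  return agg_max ? risk : (risk > 1.0 ? 1.0 : risk);
}

// For a grid of candidate constant inputs: the comfort/speed cost
// sum_k (v_k - v_d)^2 + n_steps * a^2 and the perceived risk of the
// candidate rollout against the belief (mu, sigma at the belief times).
// [[Rcpp::export]]
List cpp_plan_scan(double s0, double v0, NumericVector a_grid, int n_steps,
                   double dt, double v_d, int stride, bool resist,
                   NumericVector mu, NumericVector sigma, double phi,
                   double corridor, double L, bool agg_max) {
  int nA = a_grid.size();
  int n_out = n_steps / stride;
  NumericVector cost(nA), risk(nA);
  std::vector<double> pos(n_out);
  for (int i = 0; i < nA; ++i) {
    double a = a_grid[i];
    double s = s0, v = v0, J = 0.0;
    int j = 0;
    for (int k = 1; k <= n_steps; ++k) {
      v = step_v(v, a, dt, resist);
      s += v * dt;
      double dv = v - v_d;
      J += dv * dv;
      if (k % stride == 0) pos[j++] = s;
    }
    cost[i] = J + n_steps * a * a;
    risk[i] = risk_of_positions(pos.data(), mu, sigma, n_out, phi, corridor,
                                L, agg_max);
  }
  return List::create(_["cost"] = cost, _["risk"] = risk);
}

// single-plan risk from the current state (per-step risk evaluation)
// [[Rcpp::export]]
double cpp_plan_risk(double s0, double v0, double a, int n_steps, double dt,
                     int stride, bool resist, NumericVector mu,
                     NumericVector sigma, double phi, double corridor,
                     double L, bool agg_max) {
  int n_out = n_steps / stride;
  std::vector<double> pos(n_out);
  double s = s0, v = v0;
  int j = 0;
  for (int k = 1; k <= n_steps; ++k) {
    v = step_v(v, a, dt, resist);
    s += v * dt;
    if (k % stride == 0) pos[j++] = s;
  }
  return risk_of_positions(pos.data(), mu, sigma, n_out, phi, corridor, L,
                           agg_max);
}

// Full velocity trace under a constant input (length n_steps, excluding the
// initial state); used by plan_cost() and plan waypoint construction.
// [[Rcpp::export]]
NumericVector cpp_rollout_vel(double v0, double a, int n_steps, double dt,
                              bool resist) {
  NumericVector out(n_steps);
  double v = v0;
  for (int k = 0; k < n_steps; ++k) {
    v = step_v(v, a, dt, resist);
    out[k] = v;
  }
  return out;
}
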