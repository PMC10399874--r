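#include <Rcpp.h>
using namespace Rcpp;

// Brownian-dynamics photon-count integrators. Both use R's RNG stream
// (GetRNGstate/PutRNGstate via Rcpp attributes), so set.seed() on the R side
// makes every trace bit-reproducible.

// Box-Muller normals driven by R's uniform stream: deterministic under
// set.seed() and considerably faster than inversion for long trajectories.
static double bm_spare;
static bool bm_have = false;

static inline double fast_norm() {
  if (bm_have) { bm_have = false; return bm_spare; }
  double u1 = R::unif_rand(), u2 = R::unif_rand();
  double r = std::sqrt(-2.0 * std::log(u1)), a = 2.0 * M_PI * u2;
  bm_spare = r * std::sin(a);
  bm_have = true;
  return r * std::cos(a);
}

static inline double wrap(double x, double half) {
  // periodic boundary for |step| << box
  if (x > half) return x - 2.0 * half;
  if (x < -half) return x + 2.0 * half;
  return x;
}

//' @noRd
// [[Rcpp::export(name = ".sim_trace_2d")]]
IntegerVector sim_trace_2d(int n_steps, double dt,
                           NumericVector x0, NumericVector y0,
                           IntegerVector q0,
                           double box_x, double box_y,
                           double step_sd,
                           double w0, double wy,
                           double rate_per_fluor,
                           double bleach_coef,
                           double bg_mean) {
  const int np = x0.size();
  std::vector<double> x(x0.begin(), x0.end());
  std::vector<double> y(y0.begin(), y0.end());
  std::vector<int> q(q0.begin(), q0.end());
  IntegerVector counts(n_steps);
  const double hx = box_x / 2.0, hy = box_y / 2.0;
  const double cx = 2.0 / (w0 * w0), cy = 2.0 / (wy * wy);
  bm_have = false;   // seed-reproducible regardless of call history
  for (int t = 0; t < n_steps; ++t) {
    double lam = 0.0;
    for (int i = 0; i < np; ++i) {
      if (step_sd > 0.0) {
        x[i] = wrap(x[i] + fast_norm() * step_sd, hx);
        y[i] = wrap(y[i] + fast_norm() * step_sd, hy);
      }
      if (q[i] == 0) continue;
      double w = std::exp(-cx * x[i] * x[i] - cy * y[i] * y[i]);
      lam += q[i] * w;
      if (bleach_coef > 0.0) {
        double p = bleach_coef * w;
        if (p > 1.0) p = 1.0;
        q[i] -= (int) R::rbinom(q[i], p);
      }
    }
    counts[t] = (int) R::rpois(lam * rate_per_fluor + bg_mean);
  }
  return counts;
}

//' @noRd
// [[Rcpp::export(name = ".sim_trace_3d")]]
IntegerVector sim_trace_3d(int n_steps, double dt,
                           NumericVector x0, NumericVector y0, NumericVector z0,
                           IntegerVector q0,
                           double box_xy, double box_z,
                           double step_sd,
                           double w0, double wz,
                           double rate_per_fluor,
                           double bleach_coef,
                           double bg_mean,
                           double p_to_dark, double p_to_bright) {
  const int np = x0.size();
  std::vector<double> x(x0.begin(), x0.end());
  std::vector<double> y(y0.begin(), y0.end());
  std::vector<double> z(z0.begin(), z0.end());
  std::vector<int> q(q0.begin(), q0.end());
  std::vector<int> bright(np, 1);
  const bool blink = (p_to_dark > 0.0 && p_to_bright > 0.0);
  IntegerVector counts(n_steps);
  const double hxy = box_xy / 2.0, hz = box_z / 2.0;
  const double cxy = 2.0 / (w0 * w0), cz = 2.0 / (wz * wz);
  bm_have = false;
  for (int t = 0; t < n_steps; ++t) {
    double lam = 0.0;
    for (int i = 0; i < np; ++i) {
      if (step_sd > 0.0) {
        x[i] = wrap(x[i] + fast_norm() * step_sd, hxy);
        y[i] = wrap(y[i] + fast_norm() * step_sd, hxy);
        z[i] = wrap(z[i] + fast_norm() * step_sd, hz);
      }
      if (blink) {
        if (bright[i]) {
          if (R::unif_rand() < p_to_dark) bright[i] = 0;
        } else {
          if (R::unif_rand() < p_to_bright) bright[i] = 1;
        }
      }
      if (q[i] == 0 || !bright[i]) continue;
      double w = std::exp(-cxy * (x[i] * x[i] + y[i] * y[i]) - cz * z[i] * z[i]);
      lam += q[i] * w;
      if (bleach_coef > 0.0) {
        double p = bleach_coef * w;
        if (p > 1.0) p = 1.0;
        q[i] -= (int) R::rbinom(q[i], p);
      }
    }
    counts[t] = (int) R::rpois(lam * rate_per_fluor + bg_mean);
  }
  return counts;
}
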