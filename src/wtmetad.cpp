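#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <random>
#include <vector>
using namespace Rcpp;

// Exact Gaussian-hill summation: V(s_j) = sum_k h_k exp(-(s_j-c_k)^2/(2 sigma_k^2)).
// [[Rcpp::export]]
NumericVector bias_sum_cpp(NumericVector s, NumericVector center,
                           NumericVector sigma, NumericVector height) {
  const R_xlen_t ns = s.size(), nh = center.size();
  NumericVector out(ns);
  for (R_xlen_t j = 0; j < ns; ++j) {
    double acc = 0.0, sj = s[j];
    for (R_xlen_t k = 0; k < nh; ++k) {
      double d = sj - center[k];
      acc += height[k] * std::exp(-d * d / (2.0 * sigma[k] * sigma[k]));
    }
    out[j] = acc;
  }
  return out;
}

// Deterministic Gaussian stream: mt19937_64 + Box-Muller (own implementation
// so trajectories are bit-reproducible regardless of the C++ standard library).
struct GaussRng {
  std::mt19937_64 eng;
  double spare;
  bool has_spare;
  explicit GaussRng(uint64_t seed) : eng(seed), spare(0.0), has_spare(false) {}
  double unif() {
    // in (0, 1]
    return (static_cast<double>(eng() >> 11) + 1.0) * (1.0 / 9007199254740992.0);
  }
  double norm() {
    if (has_spare) { has_spare = false; return spare; }
    double u1 = unif(), u2 = unif();
    double r = std::sqrt(-2.0 * std::log(u1));
    double a = 6.283185307179586476925286766559 * u2;
    spare = r * std::sin(a);
    has_spare = true;
    return r * std::cos(a);
  }
};

// Overdamped Langevin dynamics in a 1D model potential with well-tempered
// hill deposition. The accumulated bias and its force are tabulated on a
// uniform grid (linear interpolation between nodes); each new hill is added
// over a +/- 6 sigma window. The coordinate reflects at s = 0 (RMSD-like CV).
//
// pot_form: 0 = gaussian_well, 1 = double_well, 2 = harmonic
// [[Rcpp::export]]
List run_wtmetad_cpp(int pot_form, double depth, double width,
                     double center1, double center2,
                     double wall_pos, double wall_k,
                     double dt, double friction, double kT,
                     int n_steps, int seed,
                     int pace, double w0, double sigma, double gamma,
                     double grid_min, double grid_max, int grid_n,
                     double s0) {
  if (grid_n < 2) stop("bias grid needs at least 2 points");
  if (gamma <= 1.0) stop("well-tempered bias factor gamma must be > 1");
  const double ds = (grid_max - grid_min) / (grid_n - 1);
  std::vector<double> V(grid_n, 0.0), Fb(grid_n, 0.0);

  const int n_hills_max = n_steps / pace;
  NumericVector h_time(n_hills_max), h_center(n_hills_max), h_height(n_hills_max);

  GaussRng rng(static_cast<uint64_t>(static_cast<int64_t>(seed)) + 0x9E3779B97F4A7C15ULL);
  const double dtf = dt / friction;
  const double amp = std::sqrt(2.0 * kT * dt / friction);
  const double inv2s2 = 1.0 / (2.0 * sigma * sigma);
  const double invs2 = 1.0 / (sigma * sigma);

  double s = s0;
  int n_hills = 0;

  auto bias_at = [&](double x, double &f) -> double {
    if (x <= grid_min) { f = Fb[0]; return V[0]; }
    if (x >= grid_max) { f = Fb[grid_n - 1]; return V[grid_n - 1]; }
    double u = (x - grid_min) / ds;
    int i = static_cast<int>(u);
    if (i >= grid_n - 1) i = grid_n - 2;
    double w = u - i;
    f = Fb[i] * (1.0 - w) + Fb[i + 1] * w;
    return V[i] * (1.0 - w) + V[i + 1] * w;
  };

  for (int step = 1; step <= n_steps; ++step) {
    // potential force
    double f;
    if (pot_form == 2) {
      f = -wall_k * (s - center1);
    } else {
      double d1 = s - center1;
      f = -depth * d1 / (width * width) * std::exp(-d1 * d1 / (2.0 * width * width));
      if (pot_form == 1) {
        double d2 = s - center2;
        f += -depth * d2 / (width * width) * std::exp(-d2 * d2 / (2.0 * width * width));
      }
      if (s > wall_pos) f -= wall_k * (s - wall_pos);
    }
    double fb;
    bias_at(s, fb);
    f += fb;

    s += f * dtf + amp * rng.norm();
    if (s < 0.0) s = -s;  // reflecting boundary: CV is RMSD-like

    if (step % pace == 0 && n_hills < n_hills_max) {
      double dummy;
      double v_here = bias_at(s, dummy);
      double h = w0 * std::exp(-v_here / ((gamma - 1.0) * kT));
      h_time[n_hills] = step * dt;
      h_center[n_hills] = s;
      h_height[n_hills] = h;
      ++n_hills;
      // add the hill to the tabulated bias over +/- 6 sigma
      int lo = static_cast<int>(std::floor((s - 6.0 * sigma - grid_min) / ds));
      int hi = static_cast<int>(std::ceil((s + 6.0 * sigma - grid_min) / ds));
      if (lo < 0) lo = 0;
      if (hi > grid_n - 1) hi = grid_n - 1;
      for (int i = lo; i <= hi; ++i) {
        double x = grid_min + i * ds;
        double d = x - s;
        double g = h * std::exp(-d * d * inv2s2);
        V[i] += g;
        Fb[i] += g * d * invs2;  // -dV/ds of the Gaussian
      }
    }
  }

  return List::create(_["time"] = h_time, _["center"] = h_center,
                      _["height"] = h_height, _["s_final"] = s);
}
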