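#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Quartic double well in x plus harmonic y:
//   V(x, y) = h ((x/a)^2 - 1)^2 + ky y^2 / 2
// Minima at (+-a, 0) with V = 0, saddle at the origin with V = h.
// Unit mass and kB = 1 throughout; temperatures are in energy units.

static inline double pot_energy(double x, double y, double h, double a,
                                double ky) {
  double u = (x / a) * (x / a) - 1.0;
  return h * u * u + 0.5 * ky * y * y;
}

static inline void pot_force(double x, double y, double h, double a, double ky,
                             double &fx, double &fy) {
  double u = (x / a) * (x / a) - 1.0;
  fx = -4.0 * h * u * x / (a * a);
  fy = -ky * y;
}

// [[Rcpp::export]]
List toy_energy_force_cpp(NumericVector pos, double h, double a, double ky) {
  double fx, fy;
  pot_force(pos[0], pos[1], h, a, ky, fx, fy);
  return List::create(_["energy"] = pot_energy(pos[0], pos[1], h, a, ky),
                      _["force"] = NumericVector::create(fx, fy));
}

// One BAOAB step in place.  friction = 0 reduces to velocity Verlet because
// the O block becomes the identity.
static inline void baoab_step(double &x, double &y, double &vx, double &vy,
                              double dt, double gamma, double temp, double h,
                              double a, double ky) {
  double fx, fy;
  pot_force(x, y, h, a, ky, fx, fy);
  vx += 0.5 * dt * fx;
  vy += 0.5 * dt * fy;
  x += 0.5 * dt * vx;
  y += 0.5 * dt * vy;
  if (gamma > 0.0) {
    double c1 = std::exp(-gamma * dt);
    double c2 = std::sqrt(temp * (1.0 - c1 * c1));
    vx = c1 * vx + c2 * norm_rand();
    vy = c1 * vy + c2 * norm_rand();
  }
  x += 0.5 * dt * vx;
  y += 0.5 * dt * vy;
  pot_force(x, y, h, a, ky, fx, fy);
  vx += 0.5 * dt * fx;
  vy += 0.5 * dt * fy;
}

// Integrate n_steps, saving the state every save_every steps (plus the
// initial state).  Returns a matrix with columns x, y, vx, vy.
// [[Rcpp::export]]
NumericMatrix baoab_run_cpp(NumericVector state, int n_steps, int save_every,
                            double dt, double gamma, double temp, double h,
                            double a, double ky) {
  double x = state[0], y = state[1], vx = state[2], vy = state[3];
  int n_save = n_steps / save_every + 1;
  NumericMatrix out(n_save, 4);
  out(0, 0) = x;
  out(0, 1) = y;
  out(0, 2) = vx;
  out(0, 3) = vy;
  int row = 1;
  for (int i = 1; i <= n_steps; ++i) {
    baoab_step(x, y, vx, vy, dt, gamma, temp, h, a, ky);
    if (i % save_every == 0 && row < n_save) {
      out(row, 0) = x;
      out(row, 1) = y;
      out(row, 2) = vx;
      out(row, 3) = vy;
      ++row;
    }
  }
  return out;
}

// Propagate until the order parameter (lambda = x) drops below stop_low or
// rises above stop_high, storing every step.  The initial state is checked
// first: if it is already outside (stop_low, stop_high) no step is taken.
// terminal: 0 = max_steps exhausted, 1 = crossed stop_low, 2 = stop_high.
// [[Rcpp::export]]
List propagate_toy_cpp(NumericVector state, double dt, double gamma,
                       double temp, double h, double a, double ky,
                       double stop_low, double stop_high, int max_steps) {
  double x = state[0], y = state[1], vx = state[2], vy = state[3];
  std::vector<double> buf;
  buf.reserve(1024);
  int terminal = 0;
  int steps = 0;
  buf.push_back(x);
  buf.push_back(y);
  buf.push_back(vx);
  buf.push_back(vy);
  if (x < stop_low)
    terminal = 1;
  else if (x > stop_high)
    terminal = 2;
  else {
    for (steps = 1; steps <= max_steps; ++steps) {
      baoab_step(x, y, vx, vy, dt, gamma, temp, h, a, ky);
      if (!std::isfinite(x) || !std::isfinite(vx) || !std::isfinite(y) ||
          !std::isfinite(vy))
        stop("non-finite state during propagation");
      buf.push_back(x);
      buf.push_back(y);
      buf.push_back(vx);
      buf.push_back(vy);
      if (x < stop_low) {
        terminal = 1;
        break;
      }
      if (x > stop_high) {
        terminal = 2;
        break;
      }
    }
    if (steps > max_steps) steps = max_steps;
  }
  int n = (int)(buf.size() / 4);
  NumericMatrix frames(n, 4);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < 4; ++j) frames(i, j) = buf[4 * i + j];
  return List::create(_["frames"] = frames, _["n_steps"] = n - 1,
                      _["terminal"] = terminal);
}

// Long direct run counting A <-> B transitions with hysteresis: the system
// is in A until lambda = x exceeds lam_b, then in B until x < lam_a.
// [[Rcpp::export]]
List mfpt_run_cpp(NumericVector state, double n_steps_d, double dt,
                  double gamma, double temp, double h, double a, double ky,
                  double lam_a, double lam_b) {
  double x = state[0], y = state[1], vx = state[2], vy = state[3];
  long long n_steps = (long long)n_steps_d;
  int basin = (x > lam_b) ? 1 : 0;  // 0 = A, 1 = B
  long long n_ab = 0, n_ba = 0, steps_a = 0, steps_b = 0;
  std::vector<double> ab_times;  // time of each A->B event (for SE blocks)
  for (long long i = 0; i < n_steps; ++i) {
    baoab_step(x, y, vx, vy, dt, gamma, temp, h, a, ky);
    if (basin == 0) {
      ++steps_a;
      if (x > lam_b) {
        basin = 1;
        ++n_ab;
        ab_times.push_back((double)(i + 1) * dt);
      }
    } else {
      ++steps_b;
      if (x < lam_a) {
        basin = 0;
        ++n_ba;
      }
    }
  }
  return List::create(
      _["n_ab"] = (double)n_ab, _["n_ba"] = (double)n_ba,
      _["time_a"] = (double)steps_a * dt, _["time_b"] = (double)steps_b * dt,
      _["ab_times"] = NumericVector(ab_times.begin(), ab_times.end()),
      _["final_state"] = NumericVector::create(x, y, vx, vy));
}

// Permanent of a square matrix by Ryser's formula, O(2^n n).  Used for the
// infinite-swap occupancy weights; n is the number of replicas (<= 25).
// [[Rcpp::export]]
double permanent_cpp(NumericMatrix m) {
  int n = m.nrow();
  if (n != m.ncol()) stop("permanent requires a square matrix");
  if (n == 0) return 1.0;
  if (n > 25) stop("permanent limited to n <= 25");
  double total = 0.0;
  unsigned long nsub = 1UL << n;
  std::vector<double> rowsum(n, 0.0);
  for (unsigned long s = 1; s < nsub; ++s) {
    int nbits = __builtin_popcountl(s);
    for (int i = 0; i < n; ++i) {
      double acc = 0.0;
      for (int j = 0; j < n; ++j)
        if (s & (1UL << j)) acc += m(i, j);
      rowsum[i] = acc;
    }
    double prod = 1.0;
    for (int i = 0; i < n; ++i) prod *= rowsum[i];
    total += ((n - nbits) % 2 == 0 ? 1.0 : -1.0) * prod;
  }
  return total;
}
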