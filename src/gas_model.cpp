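#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Sector detection zone at the arena centre: radius r, opening angle theta
// (restricted to (0, pi]), fixed azimuth. For theta <= pi the sector is
// convex: disk(r) intersected with the two half-planes bounded by its edge
// rays. A movement step is a straight segment; an encounter is logged iff
// the segment meets the sector and its start point lies outside — exact,
// state-free entry counting (a convex region intersects a segment in at
// most one interval, so one step can yield at most one entry).

struct Sector {
  double r, r2;
  double u1x, u1y;  // edge ray at azimuth - theta/2
  double u2x, u2y;  // edge ray at azimuth + theta/2
  void init(double r_, double theta, double azimuth) {
    r = r_; r2 = r_ * r_;
    double a1 = azimuth - theta / 2.0, a2 = azimuth + theta / 2.0;
    u1x = std::cos(a1); u1y = std::sin(a1);
    u2x = std::cos(a2); u2y = std::sin(a2);
  }
  inline bool inside(double px, double py) const {
    if (px * px + py * py > r2) return false;
    if (u1x * py - u1y * px < 0.0) return false;   // cross(u1, p) >= 0
    if (u2x * py - u2y * px > 0.0) return false;   // cross(u2, p) <= 0
    return true;
  }
  // does segment p0 -> p0 + d intersect the sector?
  inline bool hits(double p0x, double p0y, double dx, double dy) const {
    double lo = 0.0, hi = 1.0;
    // disk: |p0 + t d|^2 <= r^2
    double A = dx * dx + dy * dy;
    double B = 2.0 * (p0x * dx + p0y * dy);
    double C = p0x * p0x + p0y * p0y - r2;
    if (A <= 0.0) return C <= 0.0 && inside(p0x, p0y);
    double disc = B * B - 4.0 * A * C;
    if (disc < 0.0) return false;
    double sq = std::sqrt(disc);
    double t1 = (-B - sq) / (2.0 * A), t2 = (-B + sq) / (2.0 * A);
    if (t1 > lo) lo = t1;
    if (t2 < hi) hi = t2;
    if (lo > hi) return false;
    // half-plane cross(u1, p(t)) >= 0 : g0 + t g1 >= 0
    double g0 = u1x * p0y - u1y * p0x, g1 = u1x * dy - u1y * dx;
    if (g1 == 0.0) { if (g0 < 0.0) return false; }
    else if (g1 > 0.0) { double t = -g0 / g1; if (t > lo) lo = t; }
    else { double t = -g0 / g1; if (t < hi) hi = t; }
    if (lo > hi) return false;
    // half-plane cross(u2, p(t)) <= 0 : h0 + t h1 <= 0
    double h0 = u2x * p0y - u2y * p0x, h1 = u2x * dy - u2y * dx;
    if (h1 == 0.0) { if (h0 > 0.0) return false; }
    else if (h1 < 0.0) { double t = -h0 / h1; if (t > lo) lo = t; }
    else { double t = -h0 / h1; if (t < hi) hi = t; }
    return lo <= hi;
  }
};

// von Mises(0, kappa) sampler, Best & Fisher (1979); uses R's RNG.
static double rvm0(double kappa) {
  if (kappa < 1e-8) return (unif_rand() * 2.0 - 1.0) * M_PI;
  double a = 1.0 + std::sqrt(1.0 + 4.0 * kappa * kappa);
  double b = (a - std::sqrt(2.0 * a)) / (2.0 * kappa);
  double rr = (1.0 + b * b) / (2.0 * b);
  for (;;) {
    double u1 = unif_rand(), u2 = unif_rand();
    double z = std::cos(M_PI * u1);
    double f = (1.0 + rr * z) / (rr + z);
    double c = kappa * (rr - f);
    if (c * (2.0 - c) - u2 > 0.0 || std::log(c / u2) + 1.0 - c >= 0.0) {
      double u3 = unif_rand();
      return (u3 > 0.5 ? 1.0 : -1.0) * std::acos(f);
    }
  }
}

// Simulate n_rep independent arenas (one detector each, at the centre).
// turn_model: 0 = straight (heading redrawn uniformly each day),
//             1 = correlated (von Mises(kappa) turn every step).
// Returns an n_rep x days matrix of daily encounter counts.
// [[Rcpp::export]]
IntegerMatrix sim_gas_core(int n_rep, int n_animals, double side,
                           double r, double theta, double azimuth,
                           double v, int steps_per_day, int days,
                           int turn_model, double kappa) {
  IntegerMatrix out(n_rep, days);
  Sector sec;
  sec.init(r, theta, azimuth);
  const double step_len = v / (double)steps_per_day;
  const double cx = side / 2.0, cy = side / 2.0;
  const double guard = r + step_len;

  std::vector<double> x(n_animals), y(n_animals), hd(n_animals);

  for (int rep = 0; rep < n_rep; ++rep) {
    for (int a = 0; a < n_animals; ++a) {
      x[a] = unif_rand() * side;
      y[a] = unif_rand() * side;
      hd[a] = unif_rand() * 2.0 * M_PI;
    }
    for (int day = 0; day < days; ++day) {
      if (turn_model == 0)
        for (int a = 0; a < n_animals; ++a) hd[a] = unif_rand() * 2.0 * M_PI;
      int count = 0;
      for (int a = 0; a < n_animals; ++a) {
        double ax = x[a], ay = y[a], h = hd[a];
        double dx = step_len * std::cos(h), dy = step_len * std::sin(h);
        for (int s = 0; s < steps_per_day; ++s) {
          if (turn_model == 1) {
            h += rvm0(kappa);
            dx = step_len * std::cos(h);
            dy = step_len * std::sin(h);
          }
          double relx = ax - cx, rely = ay - cy;
          if (relx < guard && relx > -guard && rely < guard && rely > -guard) {
            if (!sec.inside(relx, rely) && sec.hits(relx, rely, dx, dy))
              ++count;
          }
          ax += dx; ay += dy;
          if (ax >= side) ax -= side; else if (ax < 0.0) ax += side;
          if (ay >= side) ay -= side; else if (ay < 0.0) ay += side;
        }
        x[a] = ax; y[a] = ay; hd[a] = h;
      }
      out(rep, day) = count;
    }
    if (rep % 8 == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}
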