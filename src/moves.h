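#ifndef KNOTGO_MOVES_H
#define KNOTGO_MOVES_H

#include "knotgo.h"

// A crankshaft or pivot proposal on a contiguous moving block [a, b]
// (0-based, inclusive).  The axis is a point plus unit direction.
struct Move {
  bool crank;        // crankshaft (true) or pivot (false)
  int a, b;          // moving block
  double p[3];       // axis point
  double u[3];       // axis unit direction
};

// Largest number of movable beads: the largest integer strictly smaller
// than 3N/4 (uniform selection range is {1, ..., m_max}).
inline int max_moved(int n) {
  int m = (int)std::floor(3.0 * n / 4.0);
  if (4 * m == 3 * n) m -= 1;  // 3N/4 integral: strictly smaller
  return m < 1 ? 1 : m;
}

// Draw a (kind, m, window) proposal; infeasible draws are redrawn.
inline Move draw_move(const Chain &c, Xoshiro &rng) {
  int n = c.n;
  int mmax = max_moved(n);
  Move mv;
  for (;;) {
    bool crank = rng.unif() < 0.5;
    int m = 1 + rng.unif_int(mmax);
    if (crank) {
      if (m > n - 2) continue;                 // needs two flanking beads
      int a = 1 + rng.unif_int(n - m - 1);     // window start in [1, n-m-1]
      mv.crank = true; mv.a = a; mv.b = a + m - 1;
      const double *p0 = c.at(a - 1), *p1 = c.at(mv.b + 1);
      double d[3]; vsub(p1, p0, d);
      double dn = vnorm(d);
      for (int k = 0; k < 3; k++) { mv.p[k] = p0[k]; mv.u[k] = d[k] / dn; }
      return mv;
    } else {
      if (m > n - 1) continue;                 // axis bead must exist
      bool nterm = rng.unif() < 0.5;
      int axis = nterm ? m : n - 1 - m;
      mv.crank = false;
      if (nterm) { mv.a = 0; mv.b = m - 1; } else { mv.a = n - m; mv.b = n - 1; }
      const double *p0 = c.at(axis);
      for (int k = 0; k < 3; k++) mv.p[k] = p0[k];
      rng.unit_vector(mv.u);                   // isotropic pivot axis
      return mv;
    }
  }
}

// Free rotation interval [lo, hi] (lo <= 0 <= hi) of the moving block: the
// maximal clash-free arc of rotation angles containing 0, i.e. rotate until
// the first bead-bead contact in each direction.  Each (moving, fixed) pair
// blocks a single arc (the pair distance is a single-harmonic function of
// the angle), so the free arc is the intersection of the per-pair arcs
// containing 0.  The bounds are NOT clipped to [-pi, pi]: the arc length is
// what makes the proposal symmetric between a state and its trial.  A fully
// unrestricted rotation reports (-pi, pi].
inline void free_interval(const Chain &c, const Move &mv, double radius,
                          double *lo_out, double *hi_out) {
  double lo = -2.0 * M_PI, hi = 2.0 * M_PI;
  bool restricted = false;
  double lim2 = 4.0 * radius * radius;
  int n = c.n;
  for (int i = mv.a; i <= mv.b; i++) {
    // decompose moving bead about the axis
    double v[3]; vsub(c.at(i), mv.p, v);
    double z = vdot(v, mv.u);
    double cpt[3], rvec[3];
    for (int d = 0; d < 3; d++) { cpt[d] = mv.p[d] + z * mv.u[d]; }
    vsub(c.at(i), cpt, rvec);
    double R = vnorm(rvec);
    if (R < 1e-12) continue;                    // on the axis: immobile
    double e1[3], e2[3];
    for (int d = 0; d < 3; d++) e1[d] = rvec[d] / R;
    vcross(mv.u, e1, e2);
    for (int j = 0; j < n; j++) {
      if (j >= mv.a && j <= mv.b) continue;     // fixed beads only
      if (std::abs(i - j) < 2) continue;        // bonded pairs are exempt
      double dv[3]; vsub(c.at(j), cpt, dv);
      double A = vdot(dv, dv) + R * R;
      if (A - 2.0 * R * vnorm(dv) > lim2) continue;  // can never touch
      double B = 2.0 * R * vdot(dv, e1);
      double C = 2.0 * R * vdot(dv, e2);
      double M = std::sqrt(B * B + C * C);
      if (M < 1e-12) continue;                  // constant distance
      // dist^2(theta) = A - M cos(theta - phi0); blocked when < 4 r^2
      double t = (A - lim2) / M;
      if (t >= 1.0) continue;                   // never blocked
      if (t < -1.0) {
        if (t > -1.0 - 1e-12) t = -1.0;         // grazing: clamp
        else Rcpp::stop("free_interval: current conformation clashes");
      }
      double alpha = std::acos(t);              // blocked arc half-width
      double phi0 = std::atan2(C, B);           // closest-approach azimuth
      // blocked arc is centred on phi0 with half-width (pi - alpha)...
      // dist^2 minimal at theta = phi0 +- pi?  cos(theta-phi0) = 1 gives
      // dist^2 = A - M (minimum), so blocked where cos(theta-phi0) > t:
      // arc (phi0 - alpha, phi0 + alpha).
      double delta = phi0;
      while (delta > M_PI) delta -= 2.0 * M_PI;
      while (delta <= -M_PI) delta += 2.0 * M_PI;
      double plo, phi;  // free interval bounds contributed by this pair
      if (std::fabs(delta) < alpha - 1e-12) {
        // numerically the current angle sits inside the blocked arc; this
        // can only be a grazing contact at machine precision
        if (std::fabs(delta) > alpha - 1e-6) {
          plo = 0.0; phi = 0.0;
        } else {
          Rcpp::stop("free_interval: angle 0 inside a blocked arc");
        }
      } else if (delta >= 0.0) {
        phi = delta - alpha;
        plo = delta + alpha - 2.0 * M_PI;
      } else {
        plo = delta + alpha;
        phi = delta - alpha + 2.0 * M_PI;
      }
      restricted = true;
      if (plo > lo) lo = plo;
      if (phi < hi) hi = phi;
    }
  }
  if (!restricted) { lo = -M_PI; hi = M_PI; }
  if (lo > 0.0) lo = 0.0;
  if (hi < 0.0) hi = 0.0;
  *lo_out = lo; *hi_out = hi;
}

// Rigidly rotate the moving block by angle theta (writes into out chain,
// which must start as a copy of c).
inline void apply_rotation(const Chain &c, const Move &mv, double theta,
                           Chain &out) {
  double ct = std::cos(theta), st = std::sin(theta);
  for (int i = mv.a; i <= mv.b; i++)
    rotate_about(mv.p, mv.u, ct, st, c.at(i), out.at(i));
}

// Steric screen restricted to (moving, fixed) non-bonded pairs.
inline bool block_clashes(const Chain &c, const Move &mv, double radius) {
  double lim = 2.0 * radius;
  for (int i = mv.a; i <= mv.b; i++)
    for (int j = 0; j < c.n; j++) {
      if (j >= mv.a && j <= mv.b) continue;
      if (std::abs(i - j) < 2) continue;
      if (dist3(c.at(i), c.at(j)) < lim) return true;
    }
  return false;
}

// Incremental energy/Q update: a native contact term can only change if its
// dependency set {i-1..i+1, j-1..j+1} straddles the moving block boundary.
inline bool contact_affected(int i, int j, int a, int b, int n) {
  int i0 = i > 0 ? i - 1 : 0, i1 = i < n - 1 ? i + 1 : n - 1;
  int j0 = j > 0 ? j - 1 : 0, j1 = j < n - 1 ? j + 1 : n - 1;
  bool subset = (i0 >= a) && (j1 <= b);
  bool disjoint = (i1 < a || i0 > b) && (j1 < a || j0 > b);
  return !(subset || disjoint);
}

#endif
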