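#ifndef KNOTGO_H
#define KNOTGO_H

#include <Rcpp.h>
#include <cstdint>
#include <cmath>
#include <vector>

// ---------------------------------------------------------------------------
// Counter-seeded RNG: splitmix64 expands (master seed, stream id) into the
// 256-bit state of xoshiro256++.  One independent stream per replica plus one
// for exchange decisions keeps runs reproducible regardless of scheduling.
// ---------------------------------------------------------------------------
struct Xoshiro {
  uint64_t s[4];

  static uint64_t splitmix64(uint64_t &x) {
    uint64_t z = (x += 0x9e3779b97f4a7c15ULL);
    z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
    z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
    return z ^ (z >> 31);
  }

  void seed(uint64_t master, uint64_t stream) {
    uint64_t x = master * 0x9e3779b97f4a7c15ULL + stream;
    for (int i = 0; i < 4; i++) s[i] = splitmix64(x);
    // avoid the all-zero state (probability ~0, but cheap to guard)
    if (!(s[0] | s[1] | s[2] | s[3])) s[0] = 1;
  }

  static uint64_t rotl(uint64_t x, int k) { return (x << k) | (x >> (64 - k)); }

  uint64_t next() {
    uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return result;
  }

  // uniform on [0, 1)
  double unif() { return (next() >> 11) * 0x1.0p-53; }

  // uniform integer on {0, ..., n-1}
  int unif_int(int n) {
    return (int)(unif() * n) % n;  // n is tiny here; modulo guards the edge
  }

  // isotropic unit vector (Marsaglia)
  void unit_vector(double out[3]) {
    double a, b, s2;
    do {
      a = 2.0 * unif() - 1.0;
      b = 2.0 * unif() - 1.0;
      s2 = a * a + b * b;
    } while (s2 >= 1.0 || s2 == 0.0);
    double f = 2.0 * std::sqrt(1.0 - s2);
    out[0] = a * f; out[1] = b * f; out[2] = 1.0 - 2.0 * s2;
  }
};

// ---------------------------------------------------------------------------
// Small 3-vector helpers on raw double triples
// ---------------------------------------------------------------------------
inline void vsub(const double *a, const double *b, double *out) {
  out[0] = a[0] - b[0]; out[1] = a[1] - b[1]; out[2] = a[2] - b[2];
}
inline double vdot(const double *a, const double *b) {
  return a[0] * b[0] + a[1] * b[1] + a[2] * b[2];
}
inline void vcross(const double *a, const double *b, double *out) {
  out[0] = a[1] * b[2] - a[2] * b[1];
  out[1] = a[2] * b[0] - a[0] * b[2];
  out[2] = a[0] * b[1] - a[1] * b[0];
}
inline double vnorm(const double *a) { return std::sqrt(vdot(a, a)); }
inline double dist3(const double *a, const double *b) {
  double d[3]; vsub(a, b, d); return vnorm(d);
}

// Rotate point x about the axis (p, unit u) by angle theta (Rodrigues).
inline void rotate_about(const double *p, const double *u, double ct, double st,
                         const double *x, double *out) {
  double v[3]; vsub(x, p, v);
  double k[3]; vcross(u, v, k);
  double du = vdot(u, v);
  for (int d = 0; d < 3; d++)
    out[d] = p[d] + v[d] * ct + k[d] * st + u[d] * du * (1.0 - ct);
}

// ---------------------------------------------------------------------------
// Chain container: coords stored row-major N x 3
// ---------------------------------------------------------------------------
struct Chain {
  int n;
  std::vector<double> xyz;  // n*3

  double *at(int i) { return &xyz[3 * i]; }
  const double *at(int i) const { return &xyz[3 * i]; }
};

inline Chain chain_from_matrix(const Rcpp::NumericMatrix &m) {
  Chain c; c.n = m.nrow(); c.xyz.resize(3 * c.n);
  for (int i = 0; i < c.n; i++)
    for (int d = 0; d < 3; d++) c.xyz[3 * i + d] = m(i, d);
  return c;
}

inline Rcpp::NumericMatrix matrix_from_chain(const Chain &c) {
  Rcpp::NumericMatrix m(c.n, 3);
  for (int i = 0; i < c.n; i++)
    for (int d = 0; d < 3; d++) m(i, d) = c.xyz[3 * i + d];
  return m;
}

// ---------------------------------------------------------------------------
// Go model primitives
// ---------------------------------------------------------------------------

// Signed contact chirality of the ordered pair (i, j): Heaviside of the
// scalar triple product (r_i - r_j) . [(r_{j+1} - r_j) x (r_{j-1} - r_j)],
// minus 1/2.  Requires 0 < j < n-1 (0-based); the caller enforces that.
// The step is epsilon-stabilized: a numerically zero triple product
// (coplanar beads up to rounding, e.g. lattice geometries after rigid
// rotations) deterministically counts as non-positive, per Theta(0) = 0.
#define KNOTGO_CHI_EPS 1e-9
inline double chirality_ij(const Chain &c, int i, int j) {
  double a[3], b1[3], b2[3], cr[3];
  vsub(c.at(i), c.at(j), a);
  vsub(c.at(j + 1), c.at(j), b1);
  vsub(c.at(j - 1), c.at(j), b2);
  vcross(b1, b2, cr);
  return (vdot(a, cr) > KNOTGO_CHI_EPS) ? 0.5 : -0.5;
}

// Native-contact table in flat arrays (0-based indices, i < j).
// chi_nat entries are NaN where the native chirality is undefined (terminal
// bead); the corresponding chi*chi_nat product is then replaced by +1/4,
// its native-matching value.
struct ContactTable {
  int nc;
  std::vector<int> ci, cj;
  std::vector<double> dnat, chin_ij, chin_ji;
};

inline ContactTable contacts_from_R(const Rcpp::IntegerVector &ci,
                                    const Rcpp::IntegerVector &cj,
                                    const Rcpp::NumericVector &dnat,
                                    const Rcpp::NumericVector &chin_ij,
                                    const Rcpp::NumericVector &chin_ji) {
  ContactTable t; t.nc = ci.size();
  t.ci.assign(ci.begin(), ci.end());
  t.cj.assign(cj.begin(), cj.end());
  t.dnat.assign(dnat.begin(), dnat.end());
  t.chin_ij.assign(chin_ij.begin(), chin_ij.end());
  t.chin_ji.assign(chin_ji.begin(), chin_ji.end());
  return t;
}

// Energy term and formed-flag for one native contact.
// well = [((d - dnat)/w)^2 + 1]^-1 ; factor = x_ij + x_ji + 1/2 with
// x_ab = chi_ab * chi_ab^nat where defined, else +1/4.
struct ContactEval { double energy; bool formed; };

inline ContactEval eval_contact(const Chain &c, const ContactTable &t, int k,
                                double eps, double w) {
  int i = t.ci[k], j = t.cj[k];
  double d = dist3(c.at(i), c.at(j));
  double u = (d - t.dnat[k]) / w;
  double well = 1.0 / (u * u + 1.0);
  double xij = std::isnan(t.chin_ij[k])
                   ? 0.25 : chirality_ij(c, i, j) * t.chin_ij[k];
  double xji = std::isnan(t.chin_ji[k])
                   ? 0.25 : chirality_ij(c, j, i) * t.chin_ji[k];
  ContactEval e;
  e.energy = eps * well * (xij + xji + 0.5);
  e.formed = std::fabs(d - t.dnat[k]) < w;
  return e;
}

inline double total_energy_chain(const Chain &c, const ContactTable &t,
                                 double eps, double w, int *formed_count) {
  double E = 0.0; int nf = 0;
  for (int k = 0; k < t.nc; k++) {
    ContactEval e = eval_contact(c, t, k, eps, w);
    E += e.energy;
    if (e.formed) nf++;
  }
  if (formed_count) *formed_count = nf;
  return E;
}

// Any non-bonded pair (|i-j| >= 2) with centre distance < 2*radius?
inline bool chain_has_clash(const Chain &c, double radius) {
  double lim = 2.0 * radius;
  for (int i = 0; i < c.n; i++)
    for (int j = i + 2; j < c.n; j++)
      if (dist3(c.at(i), c.at(j)) < lim) return true;
  return false;
}

// ---------------------------------------------------------------------------
// Knot analysis entry points shared between modules (defined in knots.cpp)
// ---------------------------------------------------------------------------
Chain kmt_reduce_chain(const Chain &c);
Chain close_chain_internal(const Chain &c, int arc_points);
void knot_invariants_loop(const Chain &loop, int max_tries,
                          double *det1, double *det2odd, int *ncross);
void knot_state_chain(const Chain &c, int ndirs, double *det1,
                      double *det2odd, int *votes);
bool chain_is_knotted(const Chain &c);

#endif
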