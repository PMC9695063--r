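#include "knotgo.h"
using namespace Rcpp;

static const double KEPS = 1e-9;

// ---------------------------------------------------------------------------
// Segment / triangle intersection (3D), epsilon-tolerant.
// Segments sharing a triangle vertex do not count as piercing when the
// intersection point coincides (within eps) with the shared vertex.
// ---------------------------------------------------------------------------
static bool seg_hits_triangle(const double *p, const double *q,
                              const double *t0, const double *t1,
                              const double *t2) {
  double e1[3], e2[3], nrm[3];
  vsub(t1, t0, e1); vsub(t2, t0, e2); vcross(e1, e2, nrm);
  double nl = vnorm(nrm);
  if (nl < KEPS) return false;  // degenerate triangle cannot be pierced

  double dir[3]; vsub(q, p, dir);
  double denom = vdot(nrm, dir);
  double w0[3]; vsub(t0, p, w0);
  double num = vdot(nrm, w0);
  if (std::fabs(denom) < KEPS * nl) return false;  // parallel to plane
  double s = num / denom;
  if (s < -KEPS || s > 1.0 + KEPS) return false;   // beyond segment ends

  double hit[3];
  for (int d = 0; d < 3; d++) hit[d] = p[d] + s * dir[d];

  // barycentric test
  double v2[3]; vsub(hit, t0, v2);
  double d00 = vdot(e1, e1), d01 = vdot(e1, e2), d11 = vdot(e2, e2);
  double d20 = vdot(v2, e1), d21 = vdot(v2, e2);
  double den = d00 * d11 - d01 * d01;
  if (std::fabs(den) < KEPS) return false;
  double bv = (d11 * d20 - d01 * d21) / den;
  double bw = (d00 * d21 - d01 * d20) / den;
  double bu = 1.0 - bv - bw;
  double tol = 1e-9;
  if (bu < -tol || bv < -tol || bw < -tol) return false;

  // touching a triangle vertex (shared endpoint case) is not a pierce
  if (dist3(hit, t0) < 1e-7 || dist3(hit, t1) < 1e-7 || dist3(hit, t2) < 1e-7)
    return false;
  return true;
}

// ---------------------------------------------------------------------------
// KMT reduction of an open polyline: delete interior vertex i whenever
// triangle (i-1, i, i+1) is pierced by no other chain segment; iterate to a
// fixed point.  Endpoints are never removed.
// ---------------------------------------------------------------------------
Chain kmt_reduce_chain(const Chain &input) {
  std::vector<double> pts(input.xyz);
  int n = input.n;
  bool changed = true;
  while (changed && n > 3) {
    changed = false;
    for (int i = 1; i < n - 1 && n > 3; i++) {
      const double *t0 = &pts[3 * (i - 1)];
      const double *t1 = &pts[3 * i];
      const double *t2 = &pts[3 * (i + 1)];
      bool pierced = false;
      for (int s = 0; s + 1 < n; s++) {
        if (s >= i - 1 && s <= i) continue;  // the two triangle edges
        if (seg_hits_triangle(&pts[3 * s], &pts[3 * (s + 1)], t0, t1, t2)) {
          pierced = true; break;
        }
      }
      if (!pierced) {
        pts.erase(pts.begin() + 3 * i, pts.begin() + 3 * i + 3);
        n--; i--;
        changed = true;
      }
    }
  }
  Chain out; out.n = n; out.xyz = pts;
  return out;
}

// ---------------------------------------------------------------------------
// Deterministic radial closure: extend each terminus radially outward from
// the chain centroid to a sphere of radius 10x the maximal centroid
// distance, then join the two sphere points by a discretized great-circle
// arc.  The arc stays at ~10x the chain's extent, so it introduces no new
// crossings.
// ---------------------------------------------------------------------------
Chain close_chain_internal(const Chain &c, int arc_points) {
  int n = c.n;
  double cen[3] = {0, 0, 0};
  for (int i = 0; i < n; i++)
    for (int d = 0; d < 3; d++) cen[d] += c.at(i)[d] / n;
  double rmax = 0.0;
  for (int i = 0; i < n; i++) {
    double r = dist3(c.at(i), cen);
    if (r > rmax) rmax = r;
  }
  double Rs = 10.0 * std::max(rmax, 1.0);

  auto radial = [&](const double *x, double *out) {
    double v[3]; vsub(x, cen, v);
    double vn = vnorm(v);
    if (vn < KEPS) { v[0] = 1; v[1] = 0; v[2] = 0; vn = 1; }
    for (int d = 0; d < 3; d++) out[d] = cen[d] + v[d] / vn * Rs;
  };

  double aN[3], aC[3];
  radial(c.at(0), aN);
  radial(c.at(n - 1), aC);

  // unit vectors on the closure sphere
  double uN[3], uC[3];
  vsub(aN, cen, uN); vsub(aC, cen, uC);
  for (int d = 0; d < 3; d++) { uN[d] /= Rs; uC[d] /= Rs; }
  double cosang = std::max(-1.0, std::min(1.0, vdot(uN, uC)));
  double ang = std::acos(cosang);

  // orthonormal frame for the great-circle arc from uC to uN
  double e2[3];
  double proj = vdot(uN, uC);
  for (int d = 0; d < 3; d++) e2[d] = uN[d] - proj * uC[d];
  double e2n = vnorm(e2);
  if (e2n < 1e-8) {
    // termini (anti)parallel on the sphere: pick any perpendicular
    double alt[3] = {1, 0, 0};
    if (std::fabs(uC[0]) > 0.9) { alt[0] = 0; alt[1] = 1; }
    vcross(uC, alt, e2);
    e2n = vnorm(e2);
    if (cosang < 0) ang = M_PI;
  }
  for (int d = 0; d < 3; d++) e2[d] /= e2n;

  Chain out;
  out.n = n + 2 + arc_points;
  out.xyz.resize(3 * out.n);
  for (int i = 0; i < n; i++)
    for (int d = 0; d < 3; d++) out.xyz[3 * i + d] = c.at(i)[d];
  for (int d = 0; d < 3; d++) out.xyz[3 * n + d] = aC[d];
  for (int k = 1; k <= arc_points; k++) {
    double th = ang * k / (arc_points + 1);
    for (int d = 0; d < 3; d++)
      out.xyz[3 * (n + k) + d] =
          cen[d] + Rs * (std::cos(th) * uC[d] + std::sin(th) * e2[d]);
  }
  for (int d = 0; d < 3; d++) out.xyz[3 * (n + 1 + arc_points) + d] = aN[d];
  // loop closes implicitly with the edge (last vertex -> vertex 0)
  return out;
}

// ---------------------------------------------------------------------------
// Alexander invariants of a closed polygonal loop.
//
// The loop is projected onto the xy-plane after a deterministic pseudo-random
// rotation; crossings of the generic projection give the underpass
// presentation of the Alexander matrix, whose (c-1)x(c-1) minor is evaluated
// at t = -1 and t = -2.  |det(-1)| is the knot determinant; det(-2) is
// defined up to sign and powers of two, so its odd part is reported.
// ---------------------------------------------------------------------------

struct Crossing2D {
  int seg_over, seg_under;    // segment indices along the loop
  double t_over, t_under;     // parameters within each segment
  int sign;                   // orientation sign of (over, under) tangents
};

static void rotation_from_counter(uint64_t k, double R[3][3]) {
  // deterministic quasi-random rotation: axis + angle from splitmix64
  uint64_t x = 0x2545F4914F6CDD1DULL + k * 0x9e3779b97f4a7c15ULL;
  auto nextu = [&]() { return Xoshiro::splitmix64(x) * 0x1.0p-64; };
  double z = 2.0 * nextu() - 1.0, phi = 2.0 * M_PI * nextu();
  double rxy = std::sqrt(std::max(0.0, 1.0 - z * z));
  double ax = rxy * std::cos(phi), ay = rxy * std::sin(phi), az = z;
  double th = 2.0 * M_PI * nextu();
  if (k == 0) { th = 0; ax = 0; ay = 0; az = 1; }  // first try: no rotation
  double ct = std::cos(th), st = std::sin(th), omc = 1 - ct;
  R[0][0] = ct + ax * ax * omc;      R[0][1] = ax * ay * omc - az * st; R[0][2] = ax * az * omc + ay * st;
  R[1][0] = ay * ax * omc + az * st; R[1][1] = ct + ay * ay * omc;      R[1][2] = ay * az * omc - ax * st;
  R[2][0] = az * ax * omc - ay * st; R[2][1] = az * ay * omc + ax * st; R[2][2] = ct + az * az * omc;
}

// 2D segment intersection with genericity checks; returns false if degenerate
static bool cross2d(const double *a0, const double *a1, const double *b0,
                    const double *b1, double &ta, double &tb, bool &degenerate) {
  double r[2] = {a1[0] - a0[0], a1[1] - a0[1]};
  double s[2] = {b1[0] - b0[0], b1[1] - b0[1]};
  double den = r[0] * s[1] - r[1] * s[0];
  double qp[2] = {b0[0] - a0[0], b0[1] - a0[1]};
  double scale = std::sqrt((r[0]*r[0]+r[1]*r[1]) * (s[0]*s[0]+s[1]*s[1]));
  degenerate = false;
  if (std::fabs(den) < 1e-10 * std::max(scale, 1e-12)) {
    // parallel in projection; if they also overlap, flag degenerate
    double cr = qp[0] * r[1] - qp[1] * r[0];
    if (std::fabs(cr) < 1e-8 * std::max(scale, 1e-12)) degenerate = true;
    return false;
  }
  ta = (qp[0] * s[1] - qp[1] * s[0]) / den;
  tb = (qp[0] * r[1] - qp[1] * r[0]) / den;
  if (ta <= 0.0 || ta >= 1.0 || tb <= 0.0 || tb >= 1.0) {
    // near-endpoint intersections are degenerate projections
    double tol = 1e-9;
    if (ta > -tol && ta < 1 + tol && tb > -tol && tb < 1 + tol &&
        (std::fabs(ta) < tol || std::fabs(ta - 1) < tol ||
         std::fabs(tb) < tol || std::fabs(tb - 1) < tol))
      degenerate = true;
    return false;
  }
  double tol = 1e-7;
  if (ta < tol || ta > 1 - tol || tb < tol || tb > 1 - tol) degenerate = true;
  return true;
}

// attempt one projection; returns false if degenerate
static bool alexander_attempt(const Chain &loop, uint64_t try_id,
                              double *det1, double *det2odd, int *ncross) {
  int n = loop.n;
  double R[3][3];
  rotation_from_counter(try_id, R);
  std::vector<double> P(3 * n);
  for (int i = 0; i < n; i++) {
    const double *x = loop.at(i);
    for (int d = 0; d < 3; d++)
      P[3 * i + d] = R[d][0] * x[0] + R[d][1] * x[1] + R[d][2] * x[2];
  }
  auto pt = [&](int i) { return &P[3 * (i % n)]; };

  std::vector<Crossing2D> cr;
  for (int a = 0; a < n; a++) {
    for (int b = a + 1; b < n; b++) {
      if (b == a + 1 || (a == 0 && b == n - 1)) continue;  // adjacent edges
      double ta, tb; bool degen;
      if (!cross2d(pt(a), pt(a + 1), pt(b), pt(b + 1), ta, tb, degen)) {
        if (degen) return false;
        continue;
      }
      double za = pt(a)[2] + ta * (pt(a + 1)[2] - pt(a)[2]);
      double zb = pt(b)[2] + tb * (pt(b + 1)[2] - pt(b)[2]);
      if (std::fabs(za - zb) < 1e-7) return false;
      Crossing2D c;
      bool a_over = za > zb;
      c.seg_over = a_over ? a : b;
      c.seg_under = a_over ? b : a;
      c.t_over = a_over ? ta : tb;
      c.t_under = a_over ? tb : ta;
      double ro[2] = {pt(c.seg_over + 1)[0] - pt(c.seg_over)[0],
                      pt(c.seg_over + 1)[1] - pt(c.seg_over)[1]};
      double ru[2] = {pt(c.seg_under + 1)[0] - pt(c.seg_under)[0],
                      pt(c.seg_under + 1)[1] - pt(c.seg_under)[1]};
      c.sign = (ro[0] * ru[1] - ro[1] * ru[0]) > 0 ? 1 : -1;
      cr.push_back(c);
    }
  }

  int ncr = (int)cr.size();
  *ncross = ncr;
  if (ncr <= 2) { *det1 = 1.0; *det2odd = 1.0; return true; }

  // order the 2*ncr crossing passages along the loop
  struct Event { int seg; double t; int cross_id; bool over; };
  std::vector<Event> ev;
  for (int k = 0; k < ncr; k++) {
    ev.push_back({cr[k].seg_over, cr[k].t_over, k, true});
    ev.push_back({cr[k].seg_under, cr[k].t_under, k, false});
  }
  std::sort(ev.begin(), ev.end(), [](const Event &a, const Event &b) {
    if (a.seg != b.seg) return a.seg < b.seg;
    return a.t < b.t;
  });
  for (size_t e = 1; e < ev.size(); e++)
    if (ev[e].seg == ev[e - 1].seg &&
        std::fabs(ev[e].t - ev[e - 1].t) < 1e-9)
      return false;  // coincident passages: degenerate

  // generator index of each event = number of underpasses passed before it;
  // underpass order defines rows.
  int c_under = 0;
  std::vector<int> underpass_row(ncr, -1);   // crossing id -> underpass index
  std::vector<int> over_gen(ncr, -1);        // crossing id -> generator of over pass
  std::vector<int> event_gen(ev.size());
  for (size_t e = 0; e < ev.size(); e++) {
    event_gen[e] = c_under;
    if (!ev[e].over) {
      underpass_row[ev[e].cross_id] = c_under;
      c_under++;
    }
  }
  // arcs before the first underpass belong to the last generator (cyclic)
  for (size_t e = 0; e < ev.size(); e++) {
    if (ev[e].over) {
      int g = event_gen[e] % ncr;
      over_gen[ev[e].cross_id] = g;
    }
  }
  // generator labelling: generator g is the arc between underpass g and g+1;
  // events seen before the first underpass lie on the arc closing from the
  // last underpass, i.e. generator ncr-1... equivalently (count-1) mod ncr
  for (int k = 0; k < ncr; k++)
    over_gen[k] = (over_gen[k] + ncr - 1) % ncr;

  // Alexander matrix in the underpass presentation: row k for the k-th
  // underpass along the loop, generator g = arc between underpasses g, g+1.
  auto alexander_det = [&](double tval) {
    int m = ncr - 1;
    std::vector<double> M(ncr * ncr, 0.0);
    for (int cid = 0; cid < ncr; cid++) {
      int k = underpass_row[cid];       // underpass index of this crossing
      int gin = (k + ncr - 1) % ncr;
      int gout = k % ncr;
      int i = over_gen[cid];
      int row = k;
      if (i == gin || i == gout) {
        M[row * ncr + gin] += -1.0;
        M[row * ncr + gout] += 1.0;
      } else if (cr[cid].sign > 0) {
        M[row * ncr + gin] += 1.0;
        M[row * ncr + gout] += -tval;
        M[row * ncr + i] += tval - 1.0;
      } else {
        M[row * ncr + gin] += -tval;
        M[row * ncr + gout] += 1.0;
        M[row * ncr + i] += tval - 1.0;
      }
    }
    std::vector<double> A(m * m);
    for (int r = 0; r < m; r++)
      for (int cc = 0; cc < m; cc++) A[r * m + cc] = M[r * ncr + cc];
    double det = 1.0;
    for (int col = 0; col < m; col++) {
      int piv = col;
      for (int r = col + 1; r < m; r++)
        if (std::fabs(A[r * m + col]) > std::fabs(A[piv * m + col])) piv = r;
      if (std::fabs(A[piv * m + col]) < 1e-12) return 0.0;
      if (piv != col) {
        for (int cc = col; cc < m; cc++)
          std::swap(A[piv * m + cc], A[col * m + cc]);
        det = -det;
      }
      det *= A[col * m + col];
      for (int r = col + 1; r < m; r++) {
        double f = A[r * m + col] / A[col * m + col];
        for (int cc = col; cc < m; cc++) A[r * m + cc] -= f * A[col * m + cc];
      }
    }
    return det;
  };

  double d1 = std::fabs(alexander_det(-1.0));
  double d2 = std::fabs(alexander_det(-2.0));
  double d1r = std::round(d1);
  double d2r = std::round(d2);
  if (std::fabs(d1 - d1r) > 1e-4 || std::fabs(d2 - d2r) > 1e-3 * std::max(d2, 1.0))
    return false;  // numerically unreliable projection
  if (d1r < 0.5) d1r = 0.0;
  // odd part of det(-2): strip factors of two (ambiguity is +-2^m)
  if (d2r > 9e15) return false;  // beyond exact integer range: re-project
  long long v = (long long)(d2r + 0.5);
  while (v > 0 && v % 2 == 0) v /= 2;
  *det1 = d1r;
  *det2odd = (double)v;
  return true;
}

void knot_invariants_loop(const Chain &loop, int max_tries, double *det1,
                          double *det2odd, int *ncross) {
  for (int k = 0; k < max_tries; k++) {
    if (alexander_attempt(loop, (uint64_t)k, det1, det2odd, ncross)) return;
  }
  stop("degenerate projection persists after %d retries", max_tries);
}

// ---------------------------------------------------------------------------
// Cyclic KMT reduction of a closed loop: unlike the open-chain variant this
// checks every segment including the closure edges, so each deletion is a
// genuine isotopy of the closed curve and the knot type is provably
// preserved.
// ---------------------------------------------------------------------------
static Chain kmt_reduce_cyclic(const Chain &input) {
  std::vector<double> pts(input.xyz);
  int n = input.n;
  bool changed = true;
  while (changed && n > 3) {
    changed = false;
    for (int i = 0; i < n && n > 3; i++) {
      int ip = (i + n - 1) % n, in = (i + 1) % n;
      const double *t0 = &pts[3 * ip];
      const double *t1 = &pts[3 * i];
      const double *t2 = &pts[3 * in];
      bool pierced = false;
      for (int s = 0; s < n; s++) {
        if (s == ip || s == i) continue;  // the two triangle edges
        int sn = (s + 1) % n;
        if (seg_hits_triangle(&pts[3 * s], &pts[3 * sn], t0, t1, t2)) {
          pierced = true; break;
        }
      }
      if (!pierced) {
        pts.erase(pts.begin() + 3 * i, pts.begin() + 3 * i + 3);
        n--; i--;
        changed = true;
      }
    }
  }
  Chain out; out.n = n; out.xyz = pts;
  return out;
}

// quasi-uniform unit directions (Fibonacci sphere)
static void fib_direction(int i, int k, double d[3]) {
  double z = 1.0 - 2.0 * (i + 0.5) / k;
  double r = std::sqrt(std::max(0.0, 1.0 - z * z));
  double th = M_PI * (1.0 + std::sqrt(5.0)) * (i + 0.5);
  d[0] = r * std::cos(th); d[1] = r * std::sin(th); d[2] = z;
}

// uniform (parallel) closure: both termini are sent far out along the same
// direction and joined by a distant segment; the closure never crosses the
// chain because it stays ~10x the chain extent away.
static Chain close_parallel(const Chain &c, const double d[3]) {
  int n = c.n;
  double cen[3] = {0, 0, 0};
  for (int i = 0; i < n; i++)
    for (int k = 0; k < 3; k++) cen[k] += c.at(i)[k] / n;
  double rmax = 1.0;
  for (int i = 0; i < n; i++) {
    double r = dist3(c.at(i), cen);
    if (r > rmax) rmax = r;
  }
  double R = 20.0 * rmax;
  Chain out; out.n = n + 2; out.xyz.resize(3 * out.n);
  std::copy(c.xyz.begin(), c.xyz.end(), out.xyz.begin());
  for (int k = 0; k < 3; k++) {
    out.xyz[3 * n + k] = c.at(n - 1)[k] + R * d[k];
    out.xyz[3 * (n + 1) + k] = c.at(0)[k] + R * d[k];
  }
  return out;
}

// Majority knot state of an open chain over a fixed set of closure
// directions (the standard statistical treatment of the open-knot closure
// ambiguity, kept deterministic by fixing the direction set).
void knot_state_chain(const Chain &c, int ndirs, double *det1, double *det2odd,
                      int *votes) {
  std::vector<double> k1, k2;
  std::vector<int> count;
  for (int i = 0; i < ndirs; i++) {
    double d[3];
    fib_direction(i, ndirs, d);
    Chain loop = close_parallel(c, d);
    loop = kmt_reduce_cyclic(loop);
    double d1, d2; int nc;
    knot_invariants_loop(loop, 50, &d1, &d2, &nc);
    bool found = false;
    for (size_t j = 0; j < k1.size(); j++)
      if (k1[j] == d1 && k2[j] == d2) { count[j]++; found = true; break; }
    if (!found) { k1.push_back(d1); k2.push_back(d2); count.push_back(1); }
  }
  int best = 0;
  for (size_t j = 1; j < k1.size(); j++)
    if (count[j] > count[best]) best = (int)j;
  *det1 = k1[best]; *det2odd = k2[best]; *votes = count[best];
}

bool chain_is_knotted(const Chain &c) {
  if (c.n < 5) return false;
  double d1, d2; int v;
  knot_state_chain(c, 15, &d1, &d2, &v);
  return !(d1 == 1.0 && d2 == 1.0);
}

// ------------------------------ R interface -------------------------------

// [[Rcpp::export]]
NumericMatrix cpp_kmt_reduce(NumericMatrix coords) {
  Chain c = chain_from_matrix(coords);
  return matrix_from_chain(kmt_reduce_chain(c));
}

// [[Rcpp::export]]
NumericMatrix cpp_close_chain(NumericMatrix coords, int arc_points) {
  Chain c = chain_from_matrix(coords);
  return matrix_from_chain(close_chain_internal(c, arc_points));
}

// [[Rcpp::export]]
List cpp_knot_invariants(NumericMatrix loop, int max_tries) {
  Chain c = chain_from_matrix(loop);
  double d1, d2; int nc;
  knot_invariants_loop(c, max_tries, &d1, &d2, &nc);
  return List::create(_["det1"] = d1, _["det2_odd"] = d2, _["ncross"] = nc);
}

// [[Rcpp::export]]
bool cpp_is_knotted(NumericMatrix coords) {
  Chain c = chain_from_matrix(coords);
  return chain_is_knotted(c);
}

// Majority-vote knot invariants of an open chain over `ndirs` fixed
// uniform closure directions.
// [[Rcpp::export]]
List cpp_knot_state(NumericMatrix coords, int ndirs) {
  Chain c = chain_from_matrix(coords);
  double d1, d2; int v;
  knot_state_chain(c, ndirs, &d1, &d2, &v);
  return List::create(_["det1"] = d1, _["det2_odd"] = d2, _["votes"] = v,
                      _["ndirs"] = ndirs);
}

// [[Rcpp::export]]
NumericMatrix cpp_kmt_reduce_cyclic(NumericMatrix coords) {
  Chain c = chain_from_matrix(coords);
  return matrix_from_chain(kmt_reduce_cyclic(c));
}
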