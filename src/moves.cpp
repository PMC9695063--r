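#include "moves.h"
using namespace Rcpp;

static Move move_from_args(const Chain &c, bool crank, int a, int b,
                           NumericVector axis_p, NumericVector axis_u) {
  Move mv;
  mv.crank = crank; mv.a = a; mv.b = b;
  double un = std::sqrt(axis_u[0] * axis_u[0] + axis_u[1] * axis_u[1] +
                        axis_u[2] * axis_u[2]);
  for (int d = 0; d < 3; d++) {
    mv.p[d] = axis_p[d];
    mv.u[d] = axis_u[d] / un;
  }
  if (a < 0 || b >= c.n || a > b) stop("invalid moving block");
  return mv;
}

// Analytic free rotation interval (lo <= 0 <= hi), in radians.
// [[Rcpp::export]]
NumericVector cpp_free_interval(NumericMatrix coords, bool crank, int a, int b,
                                NumericVector axis_p, NumericVector axis_u,
                                double radius) {
  Chain c = chain_from_matrix(coords);
  Move mv = move_from_args(c, crank, a, b, axis_p, axis_u);
  double lo, hi;
  free_interval(c, mv, radius, &lo, &hi);
  return NumericVector::create(lo, hi);
}

// Dense-scan oracle for the free interval: rotate over a uniform angular
// grid and report the maximal clash-free run containing angle 0.  Kept as an
// independent code path (plain rotation + pair distances) for testing.
// [[Rcpp::export]]
NumericVector cpp_free_interval_scan(NumericMatrix coords, bool crank, int a,
                                     int b, NumericVector axis_p,
                                     NumericVector axis_u, double radius,
                                     double step) {
  Chain c = chain_from_matrix(coords);
  Move mv = move_from_args(c, crank, a, b, axis_p, axis_u);
  Chain trial = c;
  double lo = 0.0, hi = 0.0;
  bool lo_hit = false, hi_hit = false;
  for (double th = step; th <= 2.0 * M_PI + 1e-12; th += step) {
    if (!hi_hit) {
      apply_rotation(c, mv, th, trial);
      if (block_clashes(trial, mv, radius)) { hi = th - step; hi_hit = true; }
    }
    if (!lo_hit) {
      apply_rotation(c, mv, -th, trial);
      if (block_clashes(trial, mv, radius)) { lo = -(th - step); lo_hit = true; }
    }
    if (lo_hit && hi_hit) break;
  }
  if (!lo_hit && !hi_hit) { lo = -M_PI; hi = M_PI; }
  else if (!lo_hit) lo = hi - 2.0 * M_PI;
  else if (!hi_hit) hi = lo + 2.0 * M_PI;
  return NumericVector::create(lo, hi);
}

// [[Rcpp::export]]
NumericMatrix cpp_rotate_block(NumericMatrix coords, int a, int b,
                               NumericVector axis_p, NumericVector axis_u,
                               double angle) {
  Chain c = chain_from_matrix(coords);
  Move mv = move_from_args(c, true, a, b, axis_p, axis_u);
  Chain out = c;
  apply_rotation(c, mv, angle, out);
  return matrix_from_chain(out);
}

// [[Rcpp::export]]
bool cpp_block_clashes(NumericMatrix coords, int a, int b, double radius) {
  Chain c = chain_from_matrix(coords);
  Move mv; mv.a = a; mv.b = b; mv.crank = true;
  return block_clashes(c, mv, radius);
}
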