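#include "knotgo.h"
using namespace Rcpp;

// [[Rcpp::export]]
double cpp_chirality(NumericMatrix coords, int i, int j) {
  int n = coords.nrow();
  if (j <= 0 || j >= n - 1) stop("undefined-chirality: bead j is terminal");
  if (i == j) stop("i and j must differ");
  Chain c = chain_from_matrix(coords);
  return chirality_ij(c, i, j);
}

// [[Rcpp::export]]
double cpp_total_energy(NumericMatrix coords, IntegerVector ci, IntegerVector cj,
                        NumericVector dnat, NumericVector chin_ij,
                        NumericVector chin_ji, double eps, double w) {
  Chain c = chain_from_matrix(coords);
  ContactTable t = contacts_from_R(ci, cj, dnat, chin_ij, chin_ji);
  return total_energy_chain(c, t, eps, w, nullptr);
}

// [[Rcpp::export]]
List cpp_energy_q(NumericMatrix coords, IntegerVector ci, IntegerVector cj,
                  NumericVector dnat, NumericVector chin_ij,
                  NumericVector chin_ji, double eps, double w) {
  Chain c = chain_from_matrix(coords);
  ContactTable t = contacts_from_R(ci, cj, dnat, chin_ij, chin_ji);
  int nf = 0;
  double E = total_energy_chain(c, t, eps, w, &nf);
  return List::create(_["energy"] = E, _["formed"] = nf);
}

// Per-contact energy terms and formed flags (diagnostics / unit tests).
// [[Rcpp::export]]
List cpp_contact_terms(NumericMatrix coords, IntegerVector ci, IntegerVector cj,
                       NumericVector dnat, NumericVector chin_ij,
                       NumericVector chin_ji, double eps, double w) {
  Chain c = chain_from_matrix(coords);
  ContactTable t = contacts_from_R(ci, cj, dnat, chin_ij, chin_ji);
  NumericVector en(t.nc);
  LogicalVector fo(t.nc);
  for (int k = 0; k < t.nc; k++) {
    ContactEval e = eval_contact(c, t, k, eps, w);
    en[k] = e.energy; fo[k] = e.formed;
  }
  return List::create(_["energy"] = en, _["formed"] = fo);
}

// [[Rcpp::export]]
bool cpp_has_clash(NumericMatrix coords, double radius) {
  Chain c = chain_from_matrix(coords);
  return chain_has_clash(c, radius);
}

// [[Rcpp::export]]
double cpp_min_nonbonded_dist(NumericMatrix coords) {
  Chain c = chain_from_matrix(coords);
  double best = R_PosInf;
  for (int i = 0; i < c.n; i++)
    for (int j = i + 2; j < c.n; j++) {
      double d = dist3(c.at(i), c.at(j));
      if (d < best) best = d;
    }
  return best;
}

// Freely jointed chain with the given bond lengths: iid isotropic bond
// directions.  Used as a cheap conformation generator for bound checks and
// as the measure of the rejection-sampling equilibrium oracle.
// [[Rcpp::export]]
NumericMatrix cpp_random_chain(NumericVector bond_lengths, double seed,
                               double stream) {
  int n = bond_lengths.size() + 1;
  Xoshiro rng; rng.seed((uint64_t)seed, (uint64_t)stream);
  NumericMatrix out(n, 3);
  double pos[3] = {0, 0, 0}, u[3];
  for (int i = 1; i < n; i++) {
    rng.unit_vector(u);
    for (int d = 0; d < 3; d++) {
      pos[d] += bond_lengths[i - 1] * u[d];
      out(i, d) = pos[d];
    }
  }
  return out;
}
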