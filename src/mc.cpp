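#include "moves.h"
using namespace Rcpp;

// ---------------------------------------------------------------------------
// Metropolis RE-MC engine.  One mcs = one elementary move proposed in every
// replica.  Replica exchange between temperature-adjacent slots every
// exchange_period mcs (alternating even/odd pairing); samples recorded every
// sample_period mcs once the relaxation budget has elapsed.
// ---------------------------------------------------------------------------

struct Replica {
  Chain conf;
  double E;
  int qcount;
  int token;
  Xoshiro rng;
};

static double delta_energy(const Chain &cur, const Chain &trial,
                           const ContactTable &t, const Move &mv, double eps,
                           double w, int *dq) {
  double dE = 0.0; int dQ = 0;
  int n = cur.n;
  for (int k = 0; k < t.nc; k++) {
    if (!contact_affected(t.ci[k], t.cj[k], mv.a, mv.b, n)) continue;
    ContactEval eo = eval_contact(cur, t, k, eps, w);
    ContactEval en = eval_contact(trial, t, k, eps, w);
    dE += en.energy - eo.energy;
    dQ += (en.formed ? 1 : 0) - (eo.formed ? 1 : 0);
  }
  *dq = dQ;
  return dE;
}

// one elementary move in one replica; returns true if accepted
static bool mc_step(Replica &rep, Chain &scratch, const ContactTable &tab,
                    double temp, double eps, double w, double radius,
                    bool ltyp, bool ltyp_assert) {
  Chain &c = rep.conf;
  Move mv = draw_move(c, rep.rng);
  double theta;
  if (ltyp) {
    double lo, hi;
    free_interval(c, mv, radius, &lo, &hi);
    theta = lo + rep.rng.unif() * (hi - lo);
  } else {
    theta = -M_PI + rep.rng.unif() * 2.0 * M_PI;
  }
  scratch.xyz = c.xyz;
  apply_rotation(c, mv, theta, scratch);
  if (!ltyp) {
    if (block_clashes(scratch, mv, radius)) return false;  // steric reject
  } else if (ltyp_assert) {
    if (block_clashes(scratch, mv, radius))
      stop("LTyP violation: clash in a topology-preserving trial");
  }
  int dq = 0;
  double dE = delta_energy(c, scratch, tab, mv, eps, w, &dq);
  bool accept = dE <= 0.0 || rep.rng.unif() < std::exp(-dE / temp);
  if (accept) {
    for (int i = mv.a; i <= mv.b; i++)
      for (int d = 0; d < 3; d++) c.xyz[3 * i + d] = scratch.xyz[3 * i + d];
    rep.E += dE;
    rep.qcount += dq;
  }
  return accept;
}

static void pack_state(const std::vector<Replica> &reps, const Xoshiro &ex,
                       IntegerMatrix &out) {
  int K = reps.size();
  for (int k = 0; k <= K; k++) {
    const uint64_t *s = (k < K) ? reps[k].rng.s : ex.s;
    for (int j = 0; j < 4; j++) {
      out(k, 2 * j) = (int32_t)(s[j] >> 32);
      out(k, 2 * j + 1) = (int32_t)(s[j] & 0xffffffffULL);
    }
  }
}

static void unpack_state(const IntegerMatrix &in, std::vector<Replica> &reps,
                         Xoshiro &ex) {
  int K = reps.size();
  for (int k = 0; k <= K; k++) {
    uint64_t *s = (k < K) ? reps[k].rng.s : ex.s;
    for (int j = 0; j < 4; j++) {
      uint64_t hi = (uint32_t)in(k, 2 * j);
      uint64_t lo = (uint32_t)in(k, 2 * j + 1);
      s[j] = (hi << 32) | lo;
    }
  }
}

// [[Rcpp::export]]
List cpp_run_remc(List start_coords, NumericVector temps, IntegerVector ci,
                  IntegerVector cj, NumericVector dnat, NumericVector chin_ij,
                  NumericVector chin_ji, NumericVector bond_lengths,
                  double eps, double w, double radius, double total_mcs,
                  double relax_mcs, double exchange_period,
                  double sample_period, bool ltyp, bool ltyp_assert,
                  double seed, bool record_knots, IntegerVector tokens0,
                  Nullable<IntegerMatrix> rng_state, double mcs_offset,
                  double assert_period) {
  int K = temps.size();
  if ((int)start_coords.size() != K) stop("one start conformation per replica required");
  ContactTable tab = contacts_from_R(ci, cj, dnat, chin_ij, chin_ji);
  int nc_contacts = tab.nc;

  std::vector<Replica> reps(K);
  for (int k = 0; k < K; k++) {
    reps[k].conf = chain_from_matrix(as<NumericMatrix>(start_coords[k]));
    reps[k].E = total_energy_chain(reps[k].conf, tab, eps, w, &reps[k].qcount);
    reps[k].token = tokens0[k];
    reps[k].rng.seed((uint64_t)seed, (uint64_t)(k + 1));
  }
  Xoshiro exrng; exrng.seed((uint64_t)seed, 0);
  if (rng_state.isNotNull()) {
    IntegerMatrix st(rng_state);
    unpack_state(st, reps, exrng);
  }
  int n = reps[0].conf.n;
  Chain scratch = reps[0].conf;

  // sample bookkeeping
  long long first_sample = 0, nsamples = 0;
  if (sample_period > 0) {
    long long sp = (long long)sample_period;
    long long t0 = (long long)mcs_offset, t1 = (long long)total_mcs;
    long long rel = (long long)relax_mcs;
    long long start = std::max(t0, rel);
    first_sample = ((start / sp) + 1) * sp;
    if (first_sample <= t1) nsamples = (t1 - first_sample) / sp + 1;
  }
  NumericMatrix samples(nsamples * K, 7);
  colnames(samples) = CharacterVector::create("mcs", "slot", "temperature",
                                              "token", "E", "Q", "knotted");
  long long srow = 0;

  long long ex_per = (long long)exchange_period;
  long long sp_per = (long long)sample_period;
  long long as_per = (long long)assert_period;
  long long accepted = 0, attempted = 0, swaps_acc = 0, swaps_att = 0;

  for (long long mcs = (long long)mcs_offset + 1; mcs <= (long long)total_mcs;
       mcs++) {
    for (int k = 0; k < K; k++) {
      attempted++;
      if (mc_step(reps[k], scratch, tab, temps[k], eps, w, radius, ltyp,
                  ltyp_assert))
        accepted++;
    }

    if (ex_per > 0 && mcs % ex_per == 0 && K > 1) {
      long long sweep = mcs / ex_per;
      int parity = (int)(sweep % 2);
      for (int j = parity; j + 1 < K; j += 2) {
        swaps_att++;
        double arg = (1.0 / temps[j] - 1.0 / temps[j + 1]) *
                     (reps[j].E - reps[j + 1].E);
        if (arg >= 0.0 || exrng.unif() < std::exp(arg)) {
          std::swap(reps[j].conf.xyz, reps[j + 1].conf.xyz);
          std::swap(reps[j].E, reps[j + 1].E);
          std::swap(reps[j].qcount, reps[j + 1].qcount);
          std::swap(reps[j].token, reps[j + 1].token);
          swaps_acc++;
        }
      }
    }

    if (sp_per > 0 && mcs % sp_per == 0 && mcs > (long long)relax_mcs) {
      for (int k = 0; k < K; k++) {
        samples(srow, 0) = (double)mcs;
        samples(srow, 1) = k + 1;
        samples(srow, 2) = temps[k];
        samples(srow, 3) = reps[k].token;
        samples(srow, 4) = reps[k].E;
        samples(srow, 5) = nc_contacts > 0
                               ? (double)reps[k].qcount / nc_contacts : NA_REAL;
        samples(srow, 6) = record_knots
                               ? (chain_is_knotted(reps[k].conf) ? 1.0 : 0.0)
                               : NA_REAL;
        srow++;
      }
    }

    if (as_per > 0 && mcs % as_per == 0) {
      // spot-check cache consistency, bond exactness and excluded volume
      for (int k = 0; k < K; k++) {
        int qc = 0;
        double E = total_energy_chain(reps[k].conf, tab, eps, w, &qc);
        if (std::fabs(E - reps[k].E) > 1e-6)
          stop("energy cache drift %g at mcs %lld (replica %d)", E - reps[k].E, mcs, k);
        reps[k].E = E; reps[k].qcount = qc;
        for (int i = 0; i + 1 < n; i++) {
          double bl = dist3(reps[k].conf.at(i), reps[k].conf.at(i + 1));
          if (std::fabs(bl - bond_lengths[i]) > 1e-6)
            stop("bond length drift at mcs %lld", mcs);
        }
        if (chain_has_clash(reps[k].conf, radius))
          stop("steric clash in accepted conformation at mcs %lld", mcs);
      }
    }
    if (mcs % 16384 == 0) Rcpp::checkUserInterrupt();
  }

  List final_coords(K);
  IntegerVector tokens(K);
  NumericVector energies(K), qs(K);
  for (int k = 0; k < K; k++) {
    final_coords[k] = matrix_from_chain(reps[k].conf);
    tokens[k] = reps[k].token;
    energies[k] = reps[k].E;
    qs[k] = nc_contacts > 0 ? (double)reps[k].qcount / nc_contacts : NA_REAL;
  }
  IntegerMatrix state(K + 1, 8);
  pack_state(reps, exrng, state);

  return List::create(
      _["samples"] = samples, _["final_coords"] = final_coords,
      _["tokens"] = tokens, _["energies"] = energies, _["q"] = qs,
      _["rng_state"] = state, _["mcs"] = (double)total_mcs,
      _["acceptance"] = attempted > 0 ? (double)accepted / attempted : NA_REAL,
      _["swap_rate"] = swaps_att > 0 ? (double)swaps_acc / swaps_att : NA_REAL);
}
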