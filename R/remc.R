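#' Replica-exchange run configuration
#'
#' Bundles and validates the knobs of a replica-exchange Monte Carlo run.
#' Defaults mirror the production protocol: replica exchange attempted
#' every 10^3 mcs, samples collected every 10^4 mcs, and the relaxation
#' (equilibration) budget derived from the total length by
#' [relaxation_budget()]. One mcs is one proposed elementary move per
#' replica.
#'
#' @param temperatures strictly increasing reduced temperatures, one per
#'   replica (production runs use 64; tests use fewer).
#' @param total_mcs total Monte Carlo steps.
#' @param exchange_period mcs between replica-exchange sweeps.
#' @param sample_period mcs between samples; must be a multiple of
#'   `exchange_period`.
#' @param ltyp use the linear-topology-preserving move variant.
#' @param start `"native"` or `"denatured"`.
#' @param seed master seed; all replica streams derive from it.
#' @param start_conformation coordinates used when `start = "denatured"`
#'   (all replicas start from this same conformation).
#' @param relax_unit the mcs unit of the relaxation rule (default 1e9;
#'   configurable so that scaled-down runs follow the same split).
#' @param record_knots detect the topological state of every sample
#'   (disable for unknotted systems to save time).
#' @param ltyp_assert run the steric screen on LTyP trials and stop on any
#'   clash (the trials are clash-free by construction; this is the
#'   assert-mode check).
#' @param assert_period mcs between internal consistency spot-checks of
#'   energy caches, bond lengths and excluded volume (0 disables).
#' @param relax_override explicit relaxation budget in mcs, bypassing
#'   [relaxation_budget()]; meant for diagnostics such as deliberately
#'   under-relaxed runs in equilibration studies.
#' @return An object of class `run_config`.
#' @export
run_config <- function(temperatures, total_mcs,
                       exchange_period = 1e3, sample_period = 1e4,
                       ltyp = TRUE, start = c("native", "denatured"),
                       seed = 1, start_conformation = NULL,
                       relax_unit = 1e9, record_knots = TRUE,
                       ltyp_assert = FALSE, assert_period = 1e5,
                       relax_override = NULL) {
  start <- match.arg(start)
  temperatures <- as.numeric(temperatures)
  if (length(temperatures) < 1 || any(diff(temperatures) <= 0))
    stop("temperatures must be strictly increasing")
  if (any(temperatures <= 0)) stop("temperatures must be positive")
  if (total_mcs < 1) stop("total_mcs must be positive")
  if (sample_period %% exchange_period != 0)
    stop("sample_period must be a multiple of exchange_period")
  if (start == "denatured" && is.null(start_conformation))
    stop("start = 'denatured' requires a start_conformation")
  structure(list(temperatures = temperatures, total_mcs = total_mcs,
                 exchange_period = exchange_period,
                 sample_period = sample_period, ltyp = ltyp, start = start,
                 seed = seed, start_conformation = start_conformation,
                 relax_unit = relax_unit, record_knots = record_knots,
                 ltyp_assert = ltyp_assert, assert_period = assert_period,
                 relax_override = relax_override),
            class = "run_config")
}

#' Relaxation (equilibration) budget of a run
#'
#' Short runs, shorter than two relaxation units, assign their initial
#' half to equilibration; longer runs of n units (n >= 2) assign n - 1
#' units. Samples are only recorded after this budget.
#'
#' @param total_mcs total run length in mcs.
#' @param unit the rule's unit in mcs (production value 1e9).
#' @return Number of mcs assigned to relaxation.
#' @examples
#' relaxation_budget(1e8)    # 5e7
#' relaxation_budget(3e9)    # 2e9
#' @export
relaxation_budget <- function(total_mcs, unit = 1e9) {
  if (total_mcs < 2 * unit) floor(total_mcs / 2) else total_mcs - unit
}

#' Build a temperature ladder for replica exchange
#'
#' Geometric spacing over `[t_lo, t_hi]`, optionally refined with a
#' three-fold denser linear sub-grid on `[0.9, 1.1] * tm_hint` so the
#' canonical energy distributions of temperature-adjacent replicas overlap
#' amply around the folding transition.
#'
#' @param t_lo,t_hi ladder end points (reduced temperature).
#' @param n number of temperatures (production value 64).
#' @param tm_hint approximate melting temperature from a pilot run, or
#'   `NULL` for a plain geometric ladder.
#' @return Strictly increasing numeric vector of length `n`.
#' @export
temperature_ladder <- function(t_lo, t_hi, n = 64, tm_hint = NULL) {
  if (t_lo <= 0 || t_hi <= t_lo) stop("need 0 < t_lo < t_hi")
  base <- exp(seq(log(t_lo), log(t_hi), length.out = n))
  if (is.null(tm_hint)) return(base)
  w_lo <- max(t_lo, 0.9 * tm_hint)
  w_hi <- min(t_hi, 1.1 * tm_hint)
  if (w_hi <= w_lo) return(base)
  inside <- sum(base >= w_lo & base <= w_hi)
  n_dense <- min(n - 2, max(3, 3 * inside))
  n_out <- n - n_dense
  lo_frac <- (log(w_lo) - log(t_lo)) /
    ((log(w_lo) - log(t_lo)) + (log(t_hi) - log(w_hi)) + 1e-12)
  n_lo <- max(1, round(n_out * lo_frac))
  n_hi <- max(1, n_out - n_lo)
  ladder <- c(exp(seq(log(t_lo), log(w_lo), length.out = n_lo + 1))[-(n_lo + 1)],
              seq(w_lo, w_hi, length.out = n_dense),
              exp(seq(log(w_hi), log(t_hi), length.out = n_hi + 1))[-1])
  ladder <- sort(unique(ladder))
  # numerical duplicates can shorten the ladder; pad by interpolation
  while (length(ladder) < n) {
    gaps <- diff(ladder)
    k <- which.max(gaps)
    ladder <- sort(c(ladder, ladder[k] + gaps[k] / 2))
  }
  ladder[seq_len(n)]
}

#' Run a replica-exchange Monte Carlo simulation
#'
#' Metropolis MC with the crankshaft/pivot move set (LTyP or non-LTyP per
#' the configuration), replica exchange between temperature-adjacent slots
#' (alternating even/odd pairing) every `exchange_period` mcs, and sample
#' collection every `sample_period` mcs after the relaxation budget. Each
#' replica carries a token that travels with the conformation during
#' exchanges; token round trips along the full ladder diagnose mixing.
#' Fully reproducible from (seed, config).
#'
#' @param topo a [native_topology()].
#' @param params a [go_params()] object.
#' @param config a [run_config()].
#' @return An object of class `remc_run`: `samples` (data.frame with
#'   columns mcs, slot, temperature, token, E, Q, knotted), `final`
#'   (per-slot coordinates, tokens, energies, RNG state), `config`,
#'   `acceptance`, `swap_rate`, `relax_mcs`.
#' @export
run_remc <- function(topo, params, config) {
  stopifnot(inherits(topo, "native_topology"), inherits(config, "run_config"))
  K <- length(config$temperatures)
  start_xyz <- if (config$start == "native") topo$coords else
    conf_coords(config$start_conformation)
  if (nrow(start_xyz) != topo$n_beads)
    stop("start conformation / topology size mismatch")
  if (config$start == "denatured" && cpp_is_knotted(start_xyz))
    stop("requested an unknotted (denatured) start but the supplied conformation is knotted")
  validate_conformation(start_xyz, topo, params, tol = 1e-6)

  relax <- if (!is.null(config$relax_override)) config$relax_override else
    relaxation_budget(config$total_mcs, config$relax_unit)
  a <- topo_arrays(topo)
  res <- cpp_run_remc(
    start_coords = rep(list(start_xyz), K),
    temps = config$temperatures,
    ci = a$ci, cj = a$cj, dnat = a$dnat,
    chin_ij = a$chin_ij, chin_ji = a$chin_ji,
    bond_lengths = topo$bond_lengths,
    eps = params$epsilon, w = params$w, radius = params$bead_radius,
    total_mcs = config$total_mcs, relax_mcs = relax,
    exchange_period = config$exchange_period,
    sample_period = config$sample_period,
    ltyp = config$ltyp, ltyp_assert = config$ltyp_assert,
    seed = config$seed, record_knots = config$record_knots,
    tokens0 = seq_len(K),
    rng_state = NULL, mcs_offset = 0,
    assert_period = config$assert_period)
  new_remc_run(res, topo, params, config, relax)
}

new_remc_run <- function(res, topo, params, config, relax) {
  samples <- as.data.frame(res$samples)
  structure(list(samples = samples,
                 final = list(coords = res$final_coords,
                              tokens = res$tokens,
                              energies = res$energies, q = res$q,
                              rng_state = res$rng_state,
                              mcs = res$mcs),
                 config = config, params = params,
                 topo_nc = nrow(topo$contacts),
                 acceptance = res$acceptance, swap_rate = res$swap_rate,
                 relax_mcs = relax),
            class = "remc_run")
}

#' @export
print.remc_run <- function(x, ...) {
  cat(sprintf(
    "RE-MC run: %d replicas, %.3g mcs (%.3g relaxation), %s moves\n",
    length(x$config$temperatures), x$config$total_mcs, x$relax_mcs,
    if (x$config$ltyp) "LTyP" else "non-LTyP"))
  cat(sprintf("  %d samples, acceptance %.3f, swap rate %.3f\n",
              nrow(x$samples), x$acceptance, x$swap_rate))
  invisible(x)
}

#' Resume a run from its final checkpointed state
#'
#' Continues a finished [run_remc()] run to a larger total mcs. Because
#' the per-replica RNG streams are part of the checkpoint, an interrupted
#' and resumed run is bit-identical to an uninterrupted one of the same
#' total length.
#'
#' @param run an `remc_run`.
#' @param topo,params the topology and parameters the run used.
#' @param total_mcs new total (must exceed the run's current mcs).
#' @return An `remc_run` whose samples cover the full (resumed) history.
#' @export
resume_run <- function(run, topo, params, total_mcs) {
  cfg <- run$config
  if (total_mcs <= run$final$mcs) stop("total_mcs must exceed the current run length")
  relax <- relaxation_budget(total_mcs, cfg$relax_unit)
  a <- topo_arrays(topo)
  res <- cpp_run_remc(
    start_coords = run$final$coords,
    temps = cfg$temperatures,
    ci = a$ci, cj = a$cj, dnat = a$dnat,
    chin_ij = a$chin_ij, chin_ji = a$chin_ji,
    bond_lengths = topo$bond_lengths,
    eps = params$epsilon, w = params$w, radius = params$bead_radius,
    total_mcs = total_mcs, relax_mcs = relax,
    exchange_period = cfg$exchange_period,
    sample_period = cfg$sample_period,
    ltyp = cfg$ltyp, ltyp_assert = cfg$ltyp_assert,
    seed = cfg$seed, record_knots = cfg$record_knots,
    tokens0 = run$final$tokens,
    rng_state = run$final$rng_state, mcs_offset = run$final$mcs,
    assert_period = cfg$assert_period)
  cfg$total_mcs <- total_mcs
  out <- new_remc_run(res, topo, params, cfg, relax)
  out$samples <- rbind(run$samples[run$samples$mcs > relax, , drop = FALSE],
                       out$samples)
  rownames(out$samples) <- NULL
  out
}

#' Token round trips along the temperature ladder
#'
#' A round trip is one completed bottom -> top -> bottom traversal of the
#' full ladder by a token (the walker identity that travels with a
#' conformation through replica exchanges). Several round trips per token
#' indicate the exchange process mixes adequately.
#'
#' @param samples the sample table of an `remc_run` (or the run itself).
#' @return Named integer vector of round-trip counts per token.
#' @export
token_roundtrips <- function(samples) {
  if (inherits(samples, "remc_run")) samples <- samples$samples
  if (!all(c("token", "slot", "mcs") %in% names(samples)))
    stop("samples must carry token, slot and mcs columns")
  kmin <- min(samples$slot); kmax <- max(samples$slot)
  tokens <- sort(unique(samples$token))
  if (kmin == kmax)   # degenerate ladder: no traversal is possible
    return(setNames(integer(length(tokens)), tokens))
  counts <- vapply(tokens, function(tk) {
    s <- samples[samples$token == tk, , drop = FALSE]
    s <- s[order(s$mcs), , drop = FALSE]
    state <- 0L  # 0: waiting for bottom, 1: going up, 2: coming down
    trips <- 0L
    for (slot in s$slot) {
      if (state == 0L && slot == kmin) state <- 1L
      else if (state == 1L && slot == kmax) state <- 2L
      else if (state == 2L && slot == kmin) { trips <- trips + 1L; state <- 1L }
    }
    trips
  }, integer(1))
  names(counts) <- tokens
  counts
}

#' Pilot estimate of the melting temperature
#'
#' Short non-LTyP replica-exchange run on a coarse geometric ladder,
#' followed by a direct heat-capacity maximisation over the ladder
#' temperatures. Used to place the dense part of the production ladder.
#'
#' @param topo a [native_topology()].
#' @param params a [go_params()] object.
#' @param t_range ladder range `c(t_lo, t_hi)`.
#' @param n_temps pilot ladder size.
#' @param total_mcs pilot run length.
#' @param seed pilot seed.
#' @return Estimated Tm (the pilot ladder temperature of maximal CV).
#' @export
estimate_tm <- function(topo, params, t_range, n_temps = 12,
                        total_mcs = 2e5, seed = 1) {
  cfg <- run_config(temperature_ladder(t_range[1], t_range[2], n_temps),
                    total_mcs = total_mcs, exchange_period = 100,
                    sample_period = 100, ltyp = FALSE, start = "native",
                    seed = seed, relax_unit = 1e9, record_knots = FALSE)
  run <- run_remc(topo, params, cfg)
  th <- thermo_direct(run$samples)
  th$temperature[which.max(th$CV)]
}
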