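# Synthetic native topologies for download-free testing. These fixtures use
# a C-alpha distance proxy for the contact map (contact iff native C-alpha
# distance <= 6.5 A, separation >= 2) because they have no side-chain heavy
# atoms; the rule is recorded in the topology metadata so it is never
# mistaken for the heavy-atom criterion used on real structures.

FIXTURE_CONTACT_CUTOFF <- 6.5

fixture_contacts <- function(coords, cutoff = FIXTURE_CONTACT_CUTOFF) {
  n <- nrow(coords)
  d <- as.matrix(stats::dist(coords))
  idx <- which(upper.tri(d) & d <= cutoff, arr.ind = TRUE)
  idx <- idx[idx[, 2] - idx[, 1] >= 2, , drop = FALSE]
  idx
}

#' Synthetic toy native topologies
#'
#' Deterministic C-alpha geometries with 3.8 A bonds and the fixture
#' contact proxy (native C-alpha distance <= 6.5 A, separation >= 2):
#'
#' * `hairpin`: two antiparallel strands joined by a turn; the contact map
#'   is symmetric about the turn. The geometry is planar, so every triple
#'   product is zero and all chiralities are -1/2 by the Theta(0) = 0
#'   convention.
#' * `helix`: an alpha-helix-like spiral with (i, i+2) to (i, i+4)
#'   contacts and generically nonzero triple products.
#' * `compact_globule`: a space-filling meander through a cubic lattice of
#'   spacing 3.8 A (many exactly coplanar triples; a stress test for the
#'   epsilon-stabilized chirality).
#'
#' The native state of every fixture is clash-free at the 1.7 A bead
#' radius, and its energy is exactly `epsilon * Nc`. Contacts involving a
#' chain terminus have undefined chirality in that pair order (stored as
#' `NA`); the energy replaces those products by the native-matching +1/4.
#'
#' @param kind `"hairpin"`, `"helix"` or `"compact_globule"`.
#' @param n total number of beads (>= 8).
#' @param seed accepted for interface stability; the geometries are
#'   deterministic.
#' @return A [native_topology()].
#' @export
make_toy_topology <- function(kind = c("hairpin", "helix", "compact_globule"),
                              n = 16, seed = 1) {
  kind <- match.arg(kind)
  if (n < 8) stop("n must be at least 8")
  if (kind == "hairpin" && n %% 2 == 1)
    stop("the hairpin fixture needs an even number of beads")
  coords <- switch(kind,
    hairpin = {
      # stacked ladder: bead i and its strand-swap image n+1-i share the
      # same x, so the contact map is exactly symmetric under i <-> n+1-i
      half <- n %/% 2
      up <- cbind(3.8 * (seq_len(half) - 1), 0, 0)
      down <- cbind(3.8 * (n - (half + 1):n), 3.8, 0)
      rbind(up, down)
    },
    helix = {
      t <- seq_len(n) - 1
      radius <- 2.3; rise <- 1.5
      turn <- 2 * asin(sqrt(3.8^2 - rise^2) / 2 / radius)
      cbind(radius * cos(t * turn), radius * sin(t * turn), rise * t)
    },
    compact_globule = {
      side <- ceiling(n^(1 / 3))
      snake_lattice(n, side) * 3.8
    })
  coords <- coords[seq_len(n), , drop = FALSE]
  topo <- native_topology(coords, fixture_contacts(coords),
                          contact_rule = sprintf("calpha-proxy-%g",
                                                 FIXTURE_CONTACT_CUTOFF),
                          source = sprintf("synthetic %s (n=%d)", kind, n))
  if (cpp_has_clash(topo$coords, 1.7))
    stop("internal error: fixture native state has steric clashes")
  topo
}

# boustrophedon path through a side^3 cubic lattice (unit spacing):
# every step moves to a face-adjacent site, so all bonds have unit length
snake_lattice <- function(n, side) {
  pts <- matrix(0, n, 3)
  x <- 0L; y <- 0L; z <- 0L; dx <- 1L; dy <- 1L
  for (i in seq_len(n)) {
    pts[i, ] <- c(x, y, z)
    if (i == n) break
    if (x + dx >= 0L && x + dx < side) {
      x <- x + dx
    } else if (y + dy >= 0L && y + dy < side) {
      y <- y + dy; dx <- -dx
    } else {
      z <- z + 1L; dy <- -dy; dx <- -dx
    }
  }
  pts
}

#' Open trefoil benchmark curve
#'
#' The standard parametric trefoil
#' `(sin t + 2 sin 2t, cos t - 2 cos 2t, -sin 3t)` truncated away from
#' closure and resampled to uniform arc length: an open arc that carries a
#' 3_1 knot.
#'
#' @param n number of points.
#' @param t_margin truncation away from the closed curve's endpoints
#'   (radians of the parameter).
#' @param scale multiplicative coordinate scale.
#' @param phase parameter offset of the truncation gap. With the default
#'   0 the gap sits at the curve's innermost point and the open knot is
#'   loose (its ends are buried between the lobes); with `phase = pi` the
#'   gap sits at an outer lobe and the knot is deep.
#' @return An `n` x 3 matrix.
#' @export
trefoil_curve <- function(n = 60, t_margin = 0.1, scale = 1, phase = 0) {
  t_dense <- seq(t_margin, 2 * pi - t_margin, length.out = 40 * n) + phase
  p <- cbind(sin(t_dense) + 2 * sin(2 * t_dense),
             cos(t_dense) - 2 * cos(2 * t_dense),
             -sin(3 * t_dense))
  resample_arclength(p, n) * scale
}

# resample a dense polyline to n points at uniform arc length
resample_arclength <- function(p, n) {
  seg <- sqrt(rowSums(diff(p)^2))
  s <- c(0, cumsum(seg))
  target <- seq(0, s[length(s)], length.out = n)
  idx <- findInterval(target, s, rightmost.closed = TRUE)
  idx[idx >= nrow(p)] <- nrow(p) - 1
  frac <- (target - s[idx]) / pmax(s[idx + 1] - s[idx], 1e-300)
  p[idx, , drop = FALSE] +
    (p[idx + 1, , drop = FALSE] - p[idx, , drop = FALSE]) * frac
}

#' Synthetic knotted native topology (open trefoil)
#'
#' Beads placed along the open parametric trefoil cut at an outer lobe
#' (`phase = pi`), rescaled so that consecutive beads are 3.8 A apart,
#' with the fixture contact proxy. Cutting at the outer lobe leaves the
#' chain termini on the outside of the structure and the knot body in the
#' middle, so the native state is decisively knotted (every closure
#' direction agrees); cutting at the innermost point instead gives a
#' loose slip-knot-like arc whose detection is closure-ambiguous.
#' Construction is rejected (internal error) if any non-bonded pair comes
#' closer than 3.4 A or if the native state fails the knot detector: the
#' returned native state is always clash-free at the 1.7 A bead radius
#' and 3_1-knotted. A desk-scale stand-in for small trefoil proteins.
#'
#' @param n number of beads (>= 30).
#' @param t_margin truncation of the parametric curve (controls how much
#'   of the knot's arc is present).
#' @return A [native_topology()].
#' @export
make_knotted_topology <- function(n = 35, t_margin = 0.1) {
  if (n < 30) stop("n must be at least 30")
  # anisotropic shape factors tighten the knot body (compressed in the
  # lobe plane, stretched axially) so the native fold is contact-rich
  # (about 21 contacts at n = 35) and the folded basin pins the topology;
  # the isotropic arc has so few contacts that Q = 1 conformations can be
  # unknotted.
  td <- seq(t_margin, 2 * pi - t_margin, length.out = 40 * n) + pi
  p <- cbind(0.6 * (sin(td) + 2 * sin(2 * td)),
             0.6 * (cos(td) - 2 * cos(2 * td)),
             1.5 * (-sin(3 * td)))
  raw <- resample_arclength(p, n)
  bond <- sqrt(sum((raw[2, ] - raw[1, ])^2))
  coords <- raw * (3.8 / bond)
  if (cpp_min_nonbonded_dist(coords) < 3.4)
    stop("internal error: knotted fixture violates excluded volume")
  topo <- native_topology(coords, fixture_contacts(coords),
                          contact_rule = sprintf("calpha-proxy-%g",
                                                 FIXTURE_CONTACT_CUTOFF),
                          source = sprintf("synthetic open trefoil (n=%d)", n))
  if (!cpp_is_knotted(topo$coords))
    stop("internal error: knotted fixture is not detected as knotted")
  topo
}

#' Generate a denatured, unknotted starting conformation
#'
#' Runs a single-temperature non-LTyP Monte Carlo simulation well above
#' the melting temperature, starting from the native state, and returns
#' the final conformation; the run is repeated with a fresh sub-seed until
#' the result is unknotted and has Q < 0.2 (at most `max_attempts`
#' times).
#'
#' @param topo a [native_topology()].
#' @param params a [go_params()] object.
#' @param t_hot reduced temperature of the unfolding run (above Tm).
#' @param budget_mcs length of each attempt.
#' @param seed base seed; attempt k uses `seed + 7919 * (k - 1)`.
#' @param max_attempts maximal number of re-runs.
#' @return An N x 3 coordinate matrix.
#' @export
generate_denatured <- function(topo, params, t_hot = 4, budget_mcs = 2e4,
                               seed = 1, max_attempts = 10) {
  a <- topo_arrays(topo)
  for (k in seq_len(max_attempts)) {
    res <- cpp_run_remc(
      start_coords = list(topo$coords), temps = t_hot,
      ci = a$ci, cj = a$cj, dnat = a$dnat,
      chin_ij = a$chin_ij, chin_ji = a$chin_ji,
      bond_lengths = topo$bond_lengths,
      eps = params$epsilon, w = params$w, radius = params$bead_radius,
      total_mcs = budget_mcs, relax_mcs = budget_mcs,
      exchange_period = 0, sample_period = 0,
      ltyp = FALSE, ltyp_assert = FALSE,
      seed = seed + 7919 * (k - 1), record_knots = FALSE,
      tokens0 = 1L, rng_state = NULL, mcs_offset = 0,
      assert_period = 0)
    x <- res$final_coords[[1]]
    q <- if (nrow(topo$contacts) > 0) res$q[1] else 0
    if (!cpp_is_knotted(x) && q < 0.2) return(x)
  }
  stop("could not generate an unknotted denatured conformation in ",
       max_attempts, " attempts (raise t_hot or budget_mcs)")
}

#' Synthetic stand-ins for the benchmark protein topologies
#'
#' Deterministic C-alpha chains engineered to mirror the topological
#' bookkeeping of four benchmark proteins; they are *synthetic* geometric
#' constructions (a tight open trefoil plus straight exit tails, or an
#' unknotted compact meander), not experimental structures, and are
#' intended for download-free testing of chain loading, knot typing,
#' knotted-core mapping and tail classification:
#'
#' * `"rds3p_like"`: 109 beads; 3_1 knot, knotted core at residues
#'   21-74, tails 20/35 - a deep trefoil like Rds3p.
#' * `"mj0366_like"`: 92 beads; 3_1 knot, core 11-82, tails 10/10 - a
#'   shallow trefoil like MJ0366.
#' * `"fn3_like"`: 90 beads, unknotted compact chain (Fn-III size).
#' * `"b2m_like"`: 98 beads, unknotted compact chain (beta-2-microglobulin
#'   size).
#'
#' @param kind which stand-in to build.
#' @return An N x 3 C-alpha coordinate matrix with 3.8 A bonds.
#' @export
synthetic_protein_trace <- function(kind = c("rds3p_like", "mj0366_like",
                                             "fn3_like", "b2m_like")) {
  kind <- match.arg(kind)
  tight_arc <- function(n, m) {
    td <- seq(m, 2 * pi - m, length.out = 40 * n) + pi
    p <- cbind(0.6 * (sin(td) + 2 * sin(2 * td)),
               0.6 * (cos(td) - 2 * cos(2 * td)),
               1.5 * (-sin(3 * td)))
    raw <- resample_arclength(p, n)
    raw * 3.8 / sqrt(sum((raw[2, ] - raw[1, ])^2))
  }
  compose <- function(arc, tn, tc) {
    cen <- colMeans(arc); n <- nrow(arc)
    dN <- arc[1, ] - cen; dN <- dN / sqrt(sum(dN^2))
    dC <- arc[n, ] - cen; dC <- dC / sqrt(sum(dC^2))
    out <- arc
    if (tn > 0)
      out <- rbind(t(vapply(tn:1, function(s) arc[1, ] + 3.8 * s * dN,
                            numeric(3))), out)
    if (tc > 0)
      out <- rbind(out, t(vapply(1:tc, function(s) arc[n, ] + 3.8 * s * dC,
                                 numeric(3))))
    out
  }
  x <- switch(kind,
    rds3p_like = compose(tight_arc(68, 0.1), 10, 31),
    mj0366_like = compose(tight_arc(84, 0.4), 0, 8),
    fn3_like = {
      t <- make_toy_topology("compact_globule", 90); t$coords
    },
    b2m_like = {
      t <- make_toy_topology("compact_globule", 98); t$coords
    })
  if (cpp_min_nonbonded_dist(x) < 3.4)
    stop("internal error: synthetic trace violates excluded volume")
  x
}
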