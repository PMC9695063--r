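#' Inverse-quadratic native-contact well
#'
#' The pairwise well term of the Go potential:
#' `[((d - d_nat) / w)^2 + 1]^-1`. It equals 1 at the native distance and
#' 1/2 when the displacement equals the half-width `w`.
#'
#' @param d current bead-centre distance (Angstrom).
#' @param d_nat native C-alpha distance of the pair (Angstrom).
#' @param w well half-width (Angstrom), positive.
#' @return Value in (0, 1]; vectorised over `d` and `d_nat`.
#' @examples
#' pair_energy_term(5, 5, 1)    # 1
#' pair_energy_term(6, 5, 1)    # 1/2
#' pair_energy_term(7, 5, 1)    # 1/5
#' @export
pair_energy_term <- function(d, d_nat, w) {
  if (any(w <= 0)) stop("w must be positive")
  1 / (((d - d_nat) / w)^2 + 1)
}

#' Signed contact chirality of an ordered bead pair
#'
#' Evaluates the Heaviside step of the scalar triple product
#' `(r_i - r_j) . [(r_{j+1} - r_j) x (r_{j-1} - r_j)]` minus 1/2, i.e.
#' +1/2 when the triple product is positive and -1/2 otherwise (the step
#' function is 0 at 0, so exactly coplanar geometries give -1/2). The value
#' flips sign under mirror reflection whenever the triple product is
#' nonzero, which is what lets the energy distinguish a fold from its
#' mirror image.
#'
#' @param conf conformation coordinates (N x 3 matrix or `go_conformation`).
#' @param i,j 1-based bead indices; both neighbours of `j` must exist.
#' @return `+0.5` or `-0.5`.
#' @export
contact_chirality <- function(conf, i, j) {
  x <- conf_coords(conf)
  n <- nrow(x)
  if (i == j) stop("i and j must differ")
  if (j <= 1 || j >= n)
    stop("undefined-chirality: bead j is a chain terminus")
  cpp_chirality(x, as.integer(i - 1L), as.integer(j - 1L))
}

#' Total Go-model energy of a conformation
#'
#' Sum over native contacts of `epsilon * well * chirality_factor`, where
#' the well is [pair_energy_term()] and the chirality factor is
#' `chi_ij * chi_ij_nat + chi_ji * chi_ji_nat + 1/2`, which is 1 when both
#' ordered chiralities match the native ones, 0 for the full mirror, and
#' 1/2 when exactly one matches. Where a chirality is undefined (terminal
#' bead) its product is replaced by the native-matching value +1/4.
#' The native conformation attains the global minimum `epsilon * Nc`.
#'
#' @param conf conformation coordinates (N x 3 matrix or `go_conformation`).
#' @param topo a [native_topology()].
#' @param params a [go_params()] object.
#' @return Total energy in reduced units.
#' @export
total_energy <- function(conf, topo, params = go_params()) {
  x <- conf_coords(conf)
  if (nrow(x) != topo$n_beads)
    stop("conformation / topology size mismatch")
  a <- topo_arrays(topo)
  cpp_total_energy(x, a$ci, a$cj, a$dnat, a$chin_ij, a$chin_ji,
                   params$epsilon, params$w)
}

#' Fraction of native contacts formed (reaction coordinate Q)
#'
#' A native contact counts as formed when the bead-centre distance differs
#' from the native C-alpha distance by strictly less than the well
#' half-width `w`.
#'
#' @inheritParams total_energy
#' @return Q in [0, 1].
#' @export
fraction_native <- function(conf, topo, params = go_params()) {
  if (nrow(topo$contacts) == 0)
    stop("no-contacts: degenerate topology with an empty contact map")
  x <- conf_coords(conf)
  if (nrow(x) != topo$n_beads)
    stop("conformation / topology size mismatch")
  a <- topo_arrays(topo)
  r <- cpp_energy_q(x, a$ci, a$cj, a$dnat, a$chin_ij, a$chin_ji,
                    params$epsilon, params$w)
  r$formed / nrow(topo$contacts)
}

#' Energy and Q in one pass
#'
#' @inheritParams total_energy
#' @return A list with elements `energy` and `q`.
#' @export
energy_and_q <- function(conf, topo, params = go_params()) {
  x <- conf_coords(conf)
  a <- topo_arrays(topo)
  r <- cpp_energy_q(x, a$ci, a$cj, a$dnat, a$chin_ij, a$chin_ji,
                    params$epsilon, params$w)
  nc <- nrow(topo$contacts)
  list(energy = r$energy, q = if (nc > 0) r$formed / nc else NA_real_)
}

#' Per-contact energy terms and formed flags
#'
#' Diagnostic view of the energy sum: one well-times-chirality term per
#' native contact, plus the strict-inequality formed flag used by Q.
#'
#' @inheritParams total_energy
#' @return A data.frame with columns `i`, `j`, `energy`, `formed`.
#' @export
contact_terms <- function(conf, topo, params = go_params()) {
  x <- conf_coords(conf)
  a <- topo_arrays(topo)
  r <- cpp_contact_terms(x, a$ci, a$cj, a$dnat, a$chin_ij, a$chin_ji,
                         params$epsilon, params$w)
  data.frame(i = topo$contacts$i, j = topo$contacts$j,
             energy = r$energy, formed = r$formed)
}
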