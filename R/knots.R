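#' KMT reduction of an open chain
#'
#' Koniaris-Muthukumar-Taylor triangle elimination: an interior vertex is
#' deleted whenever the triangle formed with its two neighbours is pierced
#' by no other chain segment, and the sweep is iterated to a fixed point.
#' The reduced polyline is ambient-isotopic (relative to its endpoints) to
#' the input, so the knotted state is unchanged; unknotted chains typically
#' collapse to the two endpoints.
#'
#' @param coords N x 3 polyline coordinate matrix (N >= 3).
#' @return The reduced polyline as a matrix.
#' @export
kmt_reduce <- function(coords) {
  x <- conf_coords(coords)
  if (nrow(x) < 3) stop("need at least 3 points")
  cpp_kmt_reduce(x)
}

#' Close an open chain into a loop
#'
#' Deterministic radial closure: each terminus is extended radially
#' outward from the chain centroid to a sphere of radius ten times the
#' maximal centroid distance, and the two sphere points are joined by a
#' discretized great-circle arc. Because the arc stays far outside the
#' chain it introduces no new crossings, so the closure choice does not
#' change which conformations count as knotted beyond the usual open-knot
#' convention.
#'
#' @param coords N x 3 polyline coordinate matrix.
#' @param arc_points number of interior points discretizing the closure
#'   arc.
#' @return An M x 3 matrix of loop vertices; the loop closes with the
#'   implicit edge from the last vertex back to the first.
#' @export
close_chain <- function(coords, arc_points = 32) {
  x <- conf_coords(coords)
  if (nrow(x) < 3) stop("need at least 3 points")
  cpp_close_chain(x, as.integer(arc_points))
}

# Alexander invariant lookup: |Delta(-1)| and the odd part of |Delta(-2)|
# (the determinant from the underpass presentation is only defined up to
# sign and powers of two at t = -2). These separate all prime knots up to
# six crossings that occur in proteins.
knot_label_from_invariants <- function(det1, det2_odd) {
  key <- paste(det1, det2_odd)
  tab <- c("1 1" = "unknot", "3 7" = "3_1", "5 11" = "4_1",
           "5 31" = "5_1", "7 1" = "5_2", "9 5" = "6_1")
  lab <- tab[key]
  if (is.na(lab)) "other" else unname(lab)
}

#' Knot type of a chain or closed loop
#'
#' A closed loop is typed by the Alexander polynomial evaluated at t = -1
#' and t = -2 on a generic planar projection (degenerate projections are
#' retried under deterministic random rotations) after a cyclic KMT
#' reduction. An open chain is first closed: both termini are extended
#' far out along the same direction and joined at a distance where the
#' closure cannot cross the chain, and the label is the majority vote
#' over a fixed quasi-uniform set of closure directions (the standard
#' statistical resolution of the open-chain closure ambiguity, kept
#' deterministic by fixing the direction set). The label is one of
#' `"unknot"`, `"3_1"`, `"4_1"`, `"5_1"`, `"5_2"`, `"6_1"` or `"other"`
#' (which includes composites). The Alexander determinant is blind to
#' chirality, so a knot and its mirror get the same label.
#'
#' @param coords N x 3 coordinate matrix.
#' @param closed is the input already a closed loop (implicit last-first
#'   edge)? Default `FALSE`: treat as an open chain.
#' @param ndirs number of closure directions voted over (open chains).
#' @param max_tries maximal number of re-projections for degenerate
#'   geometries.
#' @return The type label, with the invariants attached as attribute
#'   `invariants` (`det1`, `det2_odd`, and `ncross` or the vote split).
#' @export
knot_type <- function(coords, closed = FALSE, ndirs = 15, max_tries = 50) {
  x <- conf_coords(coords)
  if (!closed) {
    if (nrow(x) < 5)
      return(structure("unknot",
                       invariants = list(det1 = 1, det2_odd = 1, votes = ndirs)))
    inv <- cpp_knot_state(x, as.integer(ndirs))
  } else {
    x <- cpp_kmt_reduce_cyclic(x)
    inv <- cpp_knot_invariants(x, as.integer(max_tries))
  }
  structure(knot_label_from_invariants(inv$det1, inv$det2_odd),
            invariants = inv)
}

#' Is an open chain knotted?
#'
#' @param coords N x 3 coordinate matrix of an open chain.
#' @return Logical.
#' @export
is_knotted <- function(coords) {
  x <- conf_coords(coords)
  cpp_is_knotted(x)
}

#' Knotted core of a knotted open chain
#'
#' The minimal contiguous segment that remains knotted: residues are
#' trimmed one at a time from the N-terminus while the remaining sub-chain
#' stays knotted, then likewise from the C-terminus. Bounds are reported
#' in the supplied residue numbering.
#'
#' @param coords N x 3 coordinate matrix; must be knotted.
#' @param residue_numbers source residue numbers (default `1:N`).
#' @return `c(core_start, core_end)` residue numbers.
#' @export
knotted_core <- function(coords, residue_numbers = NULL) {
  x <- conf_coords(coords)
  n <- nrow(x)
  if (is.null(residue_numbers)) residue_numbers <- seq_len(n)
  if (!cpp_is_knotted(x)) stop("chain is not knotted")
  a <- 1L
  while (a < n - 2 && cpp_is_knotted(x[(a + 1L):n, , drop = FALSE]))
    a <- a + 1L
  b <- n
  while (b > a + 2 && cpp_is_knotted(x[a:(b - 1L), , drop = FALSE]))
    b <- b - 1L
  c(core_start = residue_numbers[a], core_end = residue_numbers[b])
}

#' Full knot report for an open chain
#'
#' Combines typing, knotted-core mapping and tail classification. A knot
#' is shallow when both tails are shorter than 15 residues, deep
#' otherwise.
#'
#' @param coords N x 3 coordinate matrix.
#' @param residue_numbers source residue numbers (default `1:N`).
#' @param shallow_cutoff tail length below which a tail counts as short.
#' @return An object of class `knot_report`: `knotted`, `knot_type`,
#'   `core_start`, `core_end`, `n_tail_len`, `c_tail_len`, `depth_class`.
#' @export
knot_report <- function(coords, residue_numbers = NULL, shallow_cutoff = 15) {
  x <- conf_coords(coords)
  n <- nrow(x)
  if (is.null(residue_numbers)) residue_numbers <- seq_len(n)
  type <- knot_type(x)
  knotted <- !identical(as.character(type), "unknot")
  rep <- list(knotted = knotted, knot_type = as.character(type),
              core_start = NA_integer_, core_end = NA_integer_,
              n_tail_len = NA_integer_, c_tail_len = NA_integer_,
              depth_class = NA_character_)
  if (knotted) {
    core <- knotted_core(x, residue_numbers)
    rep$core_start <- core[["core_start"]]
    rep$core_end <- core[["core_end"]]
    rep$n_tail_len <- match(core[["core_start"]], residue_numbers) - 1L
    rep$c_tail_len <- n - match(core[["core_end"]], residue_numbers)
    rep$depth_class <- if (rep$n_tail_len < shallow_cutoff &&
                           rep$c_tail_len < shallow_cutoff)
      "shallow" else "deep"
  }
  structure(rep, class = "knot_report")
}

#' @export
print.knot_report <- function(x, ...) {
  if (!x$knotted) {
    cat("unknotted chain\n")
  } else {
    cat(sprintf("knot %s, core %d-%d, tails %d/%d (%s)\n", x$knot_type,
                x$core_start, x$core_end, x$n_tail_len, x$c_tail_len,
                x$depth_class))
  }
  invisible(x)
}
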