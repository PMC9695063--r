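#' Construct a native topology from C-alpha coordinates and a contact list
#'
#' The native topology is the reference object of the structure-based model:
#' bead (C-alpha) coordinates, rigid-stick bond lengths, the native contact
#' map over pairs with sequence separation >= 2, the native contact
#' distances, and the native contact chiralities (the Heaviside signed
#' triple products evaluated on the native coordinates, in both pair
#' orders). Chirality is undefined for a pair order whose second index is a
#' chain terminus; such entries are stored as `NA` and the corresponding
#' energy product is replaced by its native-matching value +1/4.
#'
#' @param coords N x 3 matrix of native C-alpha coordinates (Angstrom).
#' @param contacts two-column matrix or data.frame of 1-based bead index
#'   pairs (i, j) with j >= i + 2.
#' @param contact_rule label recording how the contact map was derived
#'   (e.g. `"heavy-atom-4.5"` or `"calpha-proxy-6.5"`).
#' @param residue_numbers integer vector of source residue numbers
#'   (defaults to `1:N`).
#' @param source free-text provenance label.
#' @return An object of class `native_topology`.
#' @export
native_topology <- function(coords, contacts,
                            contact_rule = "unspecified",
                            residue_numbers = NULL, source = "") {
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  n <- nrow(coords)
  if (n < 4) stop("a topology needs at least 4 beads")
  if (ncol(coords) != 3) stop("coords must be N x 3")
  if (is.null(residue_numbers)) residue_numbers <- seq_len(n)
  if (length(residue_numbers) != n)
    stop("residue_numbers length must match the number of beads")

  bonds <- sqrt(rowSums((coords[-1, , drop = FALSE] -
                         coords[-n, , drop = FALSE])^2))

  contacts <- as.matrix(contacts)
  if (ncol(contacts) != 2) stop("contacts must have two columns")
  storage.mode(contacts) <- "integer"
  if (nrow(contacts) > 0) {
    ii <- pmin(contacts[, 1], contacts[, 2])
    jj <- pmax(contacts[, 1], contacts[, 2])
    keep <- !duplicated(cbind(ii, jj))
    ii <- ii[keep]; jj <- jj[keep]
    ord <- order(ii, jj)
    ii <- ii[ord]; jj <- jj[ord]
    if (any(jj - ii < 2))
      stop("contacts must have sequence separation >= 2")
    if (any(ii < 1) || any(jj > n)) stop("contact index out of range")
  } else {
    ii <- integer(0); jj <- integer(0)
  }

  d_nat <- if (length(ii)) {
    sqrt(rowSums((coords[ii, , drop = FALSE] - coords[jj, , drop = FALSE])^2))
  } else numeric(0)

  chi_one <- function(i, j) {
    if (j <= 1 || j >= n) return(NA_real_)
    cpp_chirality(coords, i - 1L, j - 1L)
  }
  chi_ij <- mapply(chi_one, ii, jj)
  chi_ji <- mapply(chi_one, jj, ii)
  if (!length(ii)) { chi_ij <- numeric(0); chi_ji <- numeric(0) }

  structure(list(
    n_beads = n,
    coords = coords,
    bond_lengths = bonds,
    contacts = data.frame(i = ii, j = jj, d_nat = d_nat,
                          chi_nat_ij = as.numeric(chi_ij),
                          chi_nat_ji = as.numeric(chi_ji)),
    contact_rule = contact_rule,
    residue_numbers = as.integer(residue_numbers),
    source = source
  ), class = "native_topology")
}

#' @export
print.native_topology <- function(x, ...) {
  cat(sprintf("Native topology: %d beads, %d native contacts (%s)\n",
              x$n_beads, nrow(x$contacts), x$contact_rule))
  cat(sprintf("  bond lengths %.2f-%.2f A; source: %s\n",
              min(x$bond_lengths), max(x$bond_lengths),
              if (nzchar(x$source)) x$source else "<none>"))
  invisible(x)
}

#' Number of native contacts of a topology
#' @param topo a `native_topology`.
#' @return Integer count.
#' @export
n_contacts <- function(topo) nrow(topo$contacts)

#' Native contact map as a symmetric logical matrix
#' @param topo a `native_topology`.
#' @return N x N logical matrix, `TRUE` at native contact pairs.
#' @export
contact_map <- function(topo) {
  n <- topo$n_beads
  m <- matrix(FALSE, n, n)
  if (nrow(topo$contacts)) {
    m[cbind(topo$contacts$i, topo$contacts$j)] <- TRUE
    m[cbind(topo$contacts$j, topo$contacts$i)] <- TRUE
  }
  m
}

# flat 0-based arrays handed to the C++ kernels
topo_arrays <- function(topo) {
  ct <- topo$contacts
  list(ci = as.integer(ct$i - 1L), cj = as.integer(ct$j - 1L),
       dnat = as.numeric(ct$d_nat),
       chin_ij = as.numeric(ct$chi_nat_ij),
       chin_ji = as.numeric(ct$chi_nat_ji))
}

# accept a conformation object or a bare coordinate matrix
conf_coords <- function(conf) {
  if (inherits(conf, "go_conformation")) return(conf$coords)
  m <- as.matrix(conf)
  storage.mode(m) <- "double"
  m
}

#' Validate a conformation against its topology
#'
#' Checks the rigid-stick constraint (consecutive bead distances equal the
#' native bond lengths to within `tol`) and, optionally, excluded volume
#' (no non-bonded pair closer than twice the bead radius).
#'
#' @param conf conformation coordinates (N x 3 matrix or `go_conformation`).
#' @param topo the `native_topology`.
#' @param params a [go_params()] object (for the bead radius).
#' @param tol bond-length tolerance in Angstrom.
#' @param check_clash also check excluded volume (default `TRUE`).
#' @return `TRUE` invisibly; errors describe any violation.
#' @export
validate_conformation <- function(conf, topo, params = go_params(),
                                  tol = 1e-9, check_clash = TRUE) {
  x <- conf_coords(conf)
  n <- nrow(x)
  if (n != topo$n_beads) stop("conformation / topology size mismatch")
  b <- sqrt(rowSums((x[-1, , drop = FALSE] - x[-n, , drop = FALSE])^2))
  dev <- max(abs(b - topo$bond_lengths))
  if (dev > tol)
    stop(sprintf("bond length deviation %.3g A exceeds tolerance", dev))
  if (check_clash && cpp_has_clash(x, params$bead_radius))
    stop("steric clash: non-bonded beads closer than twice the bead radius")
  invisible(TRUE)
}
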