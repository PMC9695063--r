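#' Read a protein chain from a PDB file
#'
#' Minimal fixed-column PDB reader for the structure-preparation pipeline.
#' Reads `ATOM` records of one chain and one model, resolves alternate
#' locations by keeping the highest-occupancy copy of each atom, and drops
#' hydrogens (and deuteriums). No installed R package in this stack parses
#' PDB, so the format is read directly.
#'
#' @param path path to a PDB file.
#' @param chain chain identifier; `NULL` picks the first protein chain.
#' @param model 1-based model index for multi-model (NMR) entries;
#'   the first model is the default.
#' @return A list of class `pdb_chain` with per-residue heavy-atom
#'   coordinate sets, the C-alpha trace in residue order, and the source
#'   residue numbering.
#' @export
load_structure <- function(path, chain = NULL, model = 1) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)

  # restrict to the requested model
  mstart <- grep("^MODEL", lines)
  if (length(mstart) > 0) {
    if (model > length(mstart)) stop("model ", model, " not present")
    mend <- grep("^ENDMDL", lines)
    to <- if (length(mend) >= model) mend[model] else length(lines)
    lines <- lines[mstart[model]:to]
  } else if (model != 1) {
    stop("model ", model, " not present (single-model file)")
  }

  at <- lines[startsWith(lines, "ATOM")]
  if (length(at) == 0) stop("no ATOM records found")
  fld <- function(a, b) trimws(substr(at, a, b))
  rec <- data.frame(
    name = fld(13, 16), alt = fld(17, 17), resname = fld(18, 20),
    chain = fld(22, 22), resno = as.integer(fld(23, 26)),
    icode = fld(27, 27),
    x = as.numeric(fld(31, 38)), y = as.numeric(fld(39, 46)),
    z = as.numeric(fld(47, 54)),
    occ = suppressWarnings(as.numeric(fld(55, 60))),
    element = fld(77, 78), stringsAsFactors = FALSE)
  rec$occ[is.na(rec$occ)] <- 1

  if (is.null(chain)) chain <- rec$chain[1]
  rec <- rec[rec$chain == chain, , drop = FALSE]
  if (nrow(rec) == 0) stop("chain '", chain, "' not found")

  # element fallback from the atom name; drop hydrogens
  noelt <- !nzchar(rec$element)
  if (any(noelt)) {
    nm <- gsub("[0-9']", "", rec$name[noelt])
    rec$element[noelt] <- toupper(substr(nm, 1, 1))
  }
  rec <- rec[!(toupper(rec$element) %in% c("H", "D")), , drop = FALSE]

  # altloc: keep the highest-occupancy copy of each atom, file order intact
  rec$ord <- seq_len(nrow(rec))
  key <- paste(rec$resno, rec$icode, rec$name)
  rec <- rec[order(-rec$occ), , drop = FALSE]
  rec <- rec[!duplicated(paste(rec$resno, rec$icode, rec$name)), ,
             drop = FALSE]
  rec <- rec[order(rec$ord), , drop = FALSE]
  rkey <- paste(rec$resno, rec$icode)

  residues <- lapply(unique(rkey), function(k) {
    rr <- rec[rkey == k, , drop = FALSE]
    list(resno = rr$resno[1], icode = rr$icode[1], resname = rr$resname[1],
         atoms = rr$name,
         xyz = as.matrix(rr[, c("x", "y", "z")]))
  })

  ca_idx <- vapply(residues, function(r) match("CA", r$atoms), integer(1))
  miss <- which(is.na(ca_idx))
  if (length(miss) > 0)
    stop("missing C-alpha in residue(s): ",
         paste(vapply(residues[miss], function(r) r$resno, integer(1)),
               collapse = ", "))
  ca <- t(vapply(seq_along(residues),
                 function(i) residues[[i]]$xyz[ca_idx[i], ], numeric(3)))
  dimnames(ca) <- NULL

  structure(list(residues = residues, ca = ca,
                 resno = vapply(residues, function(r) r$resno, integer(1)),
                 chain = chain, path = path),
            class = "pdb_chain")
}

#' @export
print.pdb_chain <- function(x, ...) {
  cat(sprintf("PDB chain %s: %d residues (%s)\n", x$chain,
              length(x$residues), basename(x$path)))
  invisible(x)
}

#' Build a native topology from an all-atom chain
#'
#' Native contacts are residue pairs with sequence separation >= 2 whose
#' closest heavy atoms lie within `params$contact_cutoff` (inclusive).
#' Bond lengths come from consecutive C-alpha distances; bonds outside
#' [2.7, 4.1] A trigger a warning (likely chain break), outside [1, 6] A a
#' hard error. Native chiralities are evaluated on the C-alpha trace.
#'
#' @param chain a `pdb_chain` from [load_structure()], or a bare N x 3
#'   C-alpha coordinate matrix (each bead then counts as its own single
#'   heavy atom).
#' @param params a [go_params()] object.
#' @return A [native_topology()].
#' @export
build_native_topology <- function(chain, params = go_params()) {
  if (inherits(chain, "pdb_chain")) {
    ca <- chain$ca
    atoms <- lapply(chain$residues, function(r) r$xyz)
    resno <- chain$resno
    src <- sprintf("%s chain %s", basename(chain$path), chain$chain)
  } else {
    ca <- as.matrix(chain)
    atoms <- lapply(seq_len(nrow(ca)), function(i) ca[i, , drop = FALSE])
    resno <- seq_len(nrow(ca))
    src <- "coordinates"
  }
  n <- nrow(ca)
  if (n < 4) stop("need at least 4 residues")

  bonds <- sqrt(rowSums((ca[-1, , drop = FALSE] - ca[-n, , drop = FALSE])^2))
  if (any(bonds < 1 | bonds > 6))
    stop(sprintf("bond length outside [1, 6] A (%.2f A): broken backbone",
                 bonds[which(bonds < 1 | bonds > 6)[1]]))
  if (any(bonds < 2.7 | bonds > 4.1))
    warning(sprintf("%d bond(s) outside [2.7, 4.1] A: possible chain break",
                    sum(bonds < 2.7 | bonds > 4.1)))

  cutoff <- params$contact_cutoff
  reach <- vapply(seq_len(n), function(i) {
    max(sqrt(rowSums((atoms[[i]] -
                      matrix(ca[i, ], nrow(atoms[[i]]), 3, byrow = TRUE))^2)))
  }, numeric(1))

  pairs <- list()
  for (i in seq_len(n - 2)) {
    for (j in seq(i + 2, n)) {
      dca <- sqrt(sum((ca[i, ] - ca[j, ])^2))
      if (dca > cutoff + reach[i] + reach[j]) next
      ai <- atoms[[i]]; aj <- atoms[[j]]
      d2 <- outer(rowSums(ai^2), rowSums(aj^2), "+") - 2 * ai %*% t(aj)
      if (min(d2) <= cutoff^2 + 1e-12)
        pairs[[length(pairs) + 1L]] <- c(i, j)
    }
  }
  contacts <- if (length(pairs)) do.call(rbind, pairs) else
    matrix(integer(0), 0, 2)

  native_topology(ca, contacts, contact_rule = sprintf("heavy-atom-%g", cutoff),
                  residue_numbers = resno, source = src)
}

#' Extend the chain termini with straight unstructured tails
#'
#' Appends `n_added` beads to each terminus, collinear with the mean
#' direction of the last three native bonds at that terminus and spaced
#' 3.8 A apart. The construction emulates engineering longer knot tails
#' onto a protein: a purely topological burden that leaves the original
#' contact map, native distances and native chiralities untouched. Added
#' beads contribute new contacts only if their C-alpha placement, treated
#' as a lone heavy atom, falls within the contact cutoff of an existing
#' bead (for a straight-line extension this is not expected to happen).
#'
#' @param topo a [native_topology()].
#' @param n_added number of beads added per terminus (>= 0).
#' @param params a [go_params()] object (contact cutoff for added beads).
#' @return A new [native_topology()] with `2 * n_added` more beads.
#' @export
extend_tails <- function(topo, n_added, params = go_params()) {
  if (!is.numeric(n_added) || n_added < 0)
    stop("n_added must be a non-negative count")
  n_added <- as.integer(n_added)
  if (n_added == 0) return(topo)

  x <- topo$coords
  n <- nrow(x)
  mean_dir <- function(vs) {
    v <- colMeans(vs)
    v / sqrt(sum(v^2))
  }
  k <- min(3, n - 1)
  dirN <- mean_dir(x[1:k, , drop = FALSE] - x[2:(k + 1), , drop = FALSE])
  dirC <- mean_dir(x[(n - k + 1):n, , drop = FALSE] -
                   x[(n - k):(n - 1), , drop = FALSE])

  newN <- t(vapply(n_added:1, function(s) x[1, ] + s * 3.8 * dirN, numeric(3)))
  newC <- t(vapply(1:n_added, function(s) x[n, ] + s * 3.8 * dirC, numeric(3)))
  coords2 <- rbind(newN, x, newC)
  n2 <- nrow(coords2)

  off <- n_added
  ct <- topo$contacts
  shifted <- data.frame(i = ct$i + off, j = ct$j + off, d_nat = ct$d_nat,
                        chi_nat_ij = ct$chi_nat_ij,
                        chi_nat_ji = ct$chi_nat_ji)

  # possible new contacts involving added beads: lone-heavy-atom rule
  added <- c(seq_len(n_added), n2 - n_added + seq_len(n_added))
  extra <- list()
  for (i in added) {
    d <- sqrt(rowSums((coords2 - matrix(coords2[i, ], n2, 3, byrow = TRUE))^2))
    hit <- which(d <= params$contact_cutoff & abs(seq_len(n2) - i) >= 2)
    for (j in hit)
      extra[[length(extra) + 1L]] <- c(min(i, j), max(i, j))
  }
  chi_one <- function(i, j) {
    if (j <= 1 || j >= n2) return(NA_real_)
    cpp_chirality(coords2, i - 1L, j - 1L)
  }
  if (length(extra)) {
    em <- unique(do.call(rbind, extra))
    em <- em[!(paste(em[, 1], em[, 2]) %in% paste(shifted$i, shifted$j)), ,
             drop = FALSE]
    if (nrow(em)) {
      dn <- sqrt(rowSums((coords2[em[, 1], , drop = FALSE] -
                          coords2[em[, 2], , drop = FALSE])^2))
      shifted <- rbind(shifted, data.frame(
        i = em[, 1], j = em[, 2], d_nat = dn,
        chi_nat_ij = mapply(chi_one, em[, 1], em[, 2]),
        chi_nat_ji = mapply(chi_one, em[, 2], em[, 1])))
    }
  }
  ord <- order(shifted$i, shifted$j)
  shifted <- shifted[ord, , drop = FALSE]

  rn <- topo$residue_numbers
  rn2 <- c(rn[1] - (n_added:1), rn, rn[length(rn)] + seq_len(n_added))

  out <- structure(list(
    n_beads = n2,
    coords = coords2,
    bond_lengths = sqrt(rowSums((coords2[-1, , drop = FALSE] -
                                 coords2[-n2, , drop = FALSE])^2)),
    contacts = shifted,
    contact_rule = topo$contact_rule,
    residue_numbers = as.integer(rn2),
    source = sprintf("%s + %d-bead tails", topo$source, n_added)
  ), class = "native_topology")
  out
}

#' Write a C-alpha trace as a PDB file
#'
#' One `ATOM` record per bead (CA atoms, residue type ALA for synthetic
#' beads), preserving the topology's residue numbering.
#'
#' @param coords N x 3 coordinate matrix.
#' @param path output file path.
#' @param residue_numbers residue numbers (default `1:N`).
#' @param chain chain identifier (default `"A"`).
#' @return The path, invisibly.
#' @export
write_calpha_pdb <- function(coords, path, residue_numbers = NULL,
                             chain = "A") {
  x <- conf_coords(coords)
  n <- nrow(x)
  if (is.null(residue_numbers)) residue_numbers <- seq_len(n)
  lines <- vapply(seq_len(n), function(i) {
    sprintf("ATOM  %5d  CA  ALA %s%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
            i, chain, residue_numbers[i], x[i, 1], x[i, 2], x[i, 3])
  }, character(1))
  writeLines(c(lines, "TER", "END"), path)
  invisible(path)
}

#' Read / write plain xyz conformation dumps
#'
#' @param coords N x 3 coordinate matrix (for writing).
#' @param path file path.
#' @return `write_xyz` returns the path invisibly; `read_xyz` an N x 3
#'   matrix.
#' @export
write_xyz <- function(coords, path) {
  x <- conf_coords(coords)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(as.character(nrow(x)), con)
  writeLines("knotgo conformation", con)
  writeLines(sprintf("CA %.10g %.10g %.10g", x[, 1], x[, 2], x[, 3]), con)
  invisible(path)
}

#' @rdname write_xyz
#' @export
read_xyz <- function(path) {
  lines <- readLines(path, warn = FALSE)
  n <- as.integer(lines[1])
  parts <- strsplit(trimws(lines[3:(2 + n)]), "\\s+")
  t(vapply(parts, function(p) as.numeric(p[2:4]), numeric(3)))
}
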