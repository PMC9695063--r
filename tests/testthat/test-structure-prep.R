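# hand-written miniature PDB texts exercise the fixed-column reader

mini_pdb <- function(lines, path = tempfile(fileext = ".pdb")) {
  writeLines(lines, path)
  path
}

atom_line <- function(serial, name, resname, chain, resno, xyz, occ = 1,
                      alt = " ", element = "C") {
  sprintf("ATOM  %5d %-4s%s%-3s %s%4d    %8.3f%8.3f%8.3f%6.2f  0.00          %2s",
          serial, name, alt, resname, chain, resno, xyz[1], xyz[2], xyz[3],
          occ, element)
}

test_that("PDB reader round-trips a written C-alpha trace exactly", {
  x <- make_toy_topology("helix", 12)$coords
  f <- tempfile(fileext = ".pdb")
  write_calpha_pdb(x, f, residue_numbers = 101:112, chain = "B")
  ch <- load_structure(f, chain = "B")
  expect_equal(nrow(ch$ca), 12)
  expect_equal(ch$ca, round(x, 3), tolerance = 1e-12)
  expect_identical(ch$resno, 101:112)
  expect_error(load_structure(f, chain = "Z"), "not found")
})

test_that("missing C-alpha atoms are reported with residue numbers", {
  f <- mini_pdb(c(
    atom_line(1, " CA ", "ALA", "A", 1, c(0, 0, 0)),
    atom_line(2, " CB ", "ALA", "A", 2, c(3.8, 0, 0)),
    atom_line(3, " CA ", "ALA", "A", 3, c(7.6, 0, 0)),
    "END"))
  expect_error(load_structure(f), "missing C-alpha.*2")
})

test_that("altloc duplicates resolve to the highest occupancy and hydrogens drop", {
  f <- mini_pdb(c(
    atom_line(1, " CA ", "ALA", "A", 1, c(0, 0, 0), occ = 0.4, alt = "A"),
    atom_line(2, " CA ", "ALA", "A", 1, c(9, 9, 9), occ = 0.6, alt = "B"),
    atom_line(3, " H  ", "ALA", "A", 1, c(1, 1, 1), element = "H"),
    atom_line(4, " CA ", "ALA", "A", 2, c(3.8, 0, 0)),
    "END"))
  ch <- load_structure(f)
  expect_equal(ch$ca[1, ], c(9, 9, 9))
  expect_false(any(ch$residues[[1]]$atoms == "H"))
})

test_that("heavy-atom contact rule is inclusive at the cutoff and skips neighbours", {
  # four residues in a line; side atoms of residues 1 and 3 exactly 4.5 apart,
  # residues 1 and 4 far apart
  f <- mini_pdb(c(
    atom_line(1, " CA ", "ALA", "A", 1, c(0, 0, 0)),
    atom_line(2, " CB ", "ALA", "A", 1, c(0, 2, 0)),
    atom_line(3, " CA ", "ALA", "A", 2, c(3.8, 0, 0)),
    atom_line(4, " CA ", "ALA", "A", 3, c(7.6, 0, 0)),
    atom_line(5, " CB ", "ALA", "A", 3, c(0, 6.5, 0)),
    atom_line(6, " CA ", "ALA", "A", 4, c(11.4, 0, 0)),
    "END"))
  topo <- build_native_topology(load_structure(f))
  cm <- contact_map(topo)
  expect_true(cm[1, 3])          # closest heavy atoms at exactly 4.5
  expect_false(cm[1, 4])
  expect_false(any(diag(cm[-1, ])))  # adjacent residues never in contact
  # and a pair 4.501 apart is out
  f2 <- mini_pdb(c(
    atom_line(1, " CA ", "ALA", "A", 1, c(0, 0, 0)),
    atom_line(2, " CB ", "ALA", "A", 1, c(0, 2, 0)),
    atom_line(3, " CA ", "ALA", "A", 2, c(3.8, 0, 0)),
    atom_line(4, " CA ", "ALA", "A", 3, c(7.6, 0, 0)),
    atom_line(5, " CB ", "ALA", "A", 3, c(0, 6.502, 0)),
    atom_line(6, " CA ", "ALA", "A", 4, c(11.4, 0, 0)),
    "END"))
  expect_equal(sum(contact_map(build_native_topology(load_structure(f2)))), 0)
})

test_that("bond-length screening warns on chain breaks and errors on gaps", {
  mk <- function(step) {
    x <- cbind(step * (0:4), 0, 0)
    f <- tempfile(fileext = ".pdb")
    write_calpha_pdb(x, f)
    load_structure(f)
  }
  expect_warning(build_native_topology(mk(4.5)), "chain break")
  expect_error(suppressWarnings(build_native_topology(mk(6.5))), "backbone")
  expect_silent(build_native_topology(mk(3.8)))
})

test_that("trans and cis C-alpha distances pass the bond screen", {
  x <- cbind(c(0, 3.85, 3.85 + 2.9, 3.85 + 2.9 + 3.8), 0, 0)
  f <- tempfile(fileext = ".pdb")
  write_calpha_pdb(x, f)
  topo <- build_native_topology(load_structure(f))
  expect_equal(topo$bond_lengths, c(3.85, 2.9, 3.8))
})

test_that("tail extension preserves the original topology exactly", {
  p <- go_params()
  topo <- make_knotted_topology(35)
  expect_identical(extend_tails(topo, 0), topo)
  ext <- extend_tails(topo, 5, p)
  expect_equal(ext$n_beads, 45)
  # every original contact survives with shifted indices, identical native
  # distance and identical native chirality (match by pair key: any new
  # tail contacts interleave in the sorted table)
  key0 <- paste(topo$contacts$i + 5, topo$contacts$j + 5)
  pos <- match(key0, paste(ext$contacts$i, ext$contacts$j))
  expect_false(anyNA(pos))
  expect_equal(ext$contacts$d_nat[pos], topo$contacts$d_nat)
  expect_equal(ext$contacts$chi_nat_ij[pos], topo$contacts$chi_nat_ij)
  expect_equal(ext$contacts$chi_nat_ji[pos], topo$contacts$chi_nat_ji)
  # contacts beyond the originals involve only added beads
  extra <- setdiff(seq_len(n_contacts(ext)), pos)
  added <- c(1:5, 41:45)
  expect_true(all(ext$contacts$i[extra] %in% added |
                  ext$contacts$j[extra] %in% added))
  # the tails are a topological burden: same knotted core, longer tails
  rep0 <- knot_report(topo$coords, topo$residue_numbers)
  rep1 <- knot_report(ext$coords, ext$residue_numbers)
  expect_equal(rep1$core_start, rep0$core_start)
  expect_equal(rep1$core_end, rep0$core_end)
  expect_equal(rep1$n_tail_len, rep0$n_tail_len + 5)
  expect_equal(rep1$c_tail_len, rep0$c_tail_len + 5)
  # energy of the extended native state is still -Nc
  expect_identical(total_energy(ext$coords, ext, p),
                   -as.numeric(n_contacts(ext)))
  expect_error(extend_tails(topo, -1), "non-negative")
})

test_that("straight tails add no contacts on a compact toy fixture", {
  p <- go_params()
  topo <- make_toy_topology("compact_globule", 16)
  ext <- extend_tails(topo, 4, p)
  expect_equal(n_contacts(ext), n_contacts(topo))
  expect_equal(ext$n_beads, 24)
})

test_that("topology construction is deterministic", {
  a <- make_toy_topology("compact_globule", 20)
  b <- make_toy_topology("compact_globule", 20)
  expect_identical(a$coords, b$coords)
  expect_identical(a$contacts, b$contacts)
})
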