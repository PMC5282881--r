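# Shared helpers: a curated hand-written PDB text fixture and small
# jittered structures used across the unit tests.

# Fixed-column ATOM/HETATM line (PDB v3.3 layout).
pdb_line <- function(record = "ATOM", serial, name, alt = " ",
                     resn = "GLY", chain = "A", resno, icode = " ",
                     x, y, z, occ = 1.00, b = 0.00, element = "") {
  nm <- if (nchar(name) < 4L) sprintf(" %-3s", name) else name
  sprintf("%-6s%5d %4s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          record, serial, nm, alt, resn, chain, resno, icode,
          x, y, z, occ, b, element)
}

# A small hand-curated structure exercising the parser corner cases:
# - residue 1: backbone with an alt-loc pair on CA (A occ 0.4, B occ 0.6)
# - residue 2: alt-loc tie on CB (both occ 0.5) and one hydrogen
# - residue 3: CA only
# - a chain-B residue, a water and a ligand HETATM
toy_pdb_lines <- function() {
  c(
    "HEADER    TOY STRUCTURE",
    pdb_line(serial = 1, name = "N",  resn = "ALA", resno = 1,
             x = 0, y = 0, z = 0, element = "N"),
    pdb_line(serial = 2, name = "CA", alt = "A", resn = "ALA", resno = 1,
             x = 1.5, y = 0, z = 0, occ = 0.40, element = "C"),
    pdb_line(serial = 3, name = "CA", alt = "B", resn = "ALA", resno = 1,
             x = 1.6, y = 0, z = 0, occ = 0.60, element = "C"),
    pdb_line(serial = 4, name = "C",  resn = "ALA", resno = 1,
             x = 2.9, y = 0.8, z = 0, element = "C"),
    pdb_line(serial = 5, name = "CA", resn = "SER", resno = 2,
             x = 4.0, y = 1.5, z = 0.5, element = "C"),
    pdb_line(serial = 6, name = "CB", alt = "A", resn = "SER", resno = 2,
             x = 4.8, y = 2.6, z = 0.1, occ = 0.50, element = "C"),
    pdb_line(serial = 7, name = "CB", alt = "B", resn = "SER", resno = 2,
             x = 4.9, y = 2.7, z = 0.2, occ = 0.50, element = "C"),
    pdb_line(serial = 8, name = "HB2", resn = "SER", resno = 2,
             x = 5.2, y = 3.0, z = 0.4, element = "H"),
    pdb_line(serial = 9, name = "CA", resn = "GLY", resno = 3,
             x = 6.5, y = 1.0, z = 1.2, element = "C"),
    pdb_line(serial = 10, name = "CA", resn = "VAL", chain = "B",
             resno = 3, x = 20, y = 20, z = 20, element = "C"),
    pdb_line(record = "HETATM", serial = 11, name = "O", resn = "HOH",
             resno = 101, x = 9, y = 9, z = 9, element = "O"),
    pdb_line(record = "HETATM", serial = 12, name = "ZN", resn = "ZN",
             resno = 102, x = 8, y = 8, z = 8, element = "ZN"),
    "END"
  )
}

write_toy_pdb <- function(lines = toy_pdb_lines()) {
  path <- tempfile(fileext = ".pdb")
  writeLines(lines, path)
  path
}

# Generic non-degenerate small fixtures for oracle loops.
small_fixtures <- function() {
  list(
    tetra = make_fixture("tetrahedron", spacing = 3, jitter = 0.25, seed = 11),
    triangle = make_fixture("triangle", spacing = 3, jitter = 0.2, seed = 12),
    lattice8 = make_fixture("lattice", n_atoms = 8, spacing = 3,
                            jitter = 0.3, seed = 13),
    helix10 = make_fixture("helix", n_atoms = 10, spacing = 3.8,
                           jitter = 0.2, seed = 14)
  )
}

termini_pair <- function(sel) {
  n <- n_atoms(sel)
  pulling_pair(sel, 1, n)
}
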