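# Fixtures built in code at test time.

# hand-written 3-residue PDB text (one chain, backbone only + one OXT)
mini_pdb_lines <- function() {
  c("REMARK  tiny hand-built chain",
    "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA  ALA A   1       1.458   0.000   0.000  1.00  0.00           C",
    "ATOM      3  C   ALA A   1       2.009   1.420   0.000  1.00  0.00           C",
    "ATOM      4  O   ALA A   1       1.251   2.390   0.000  1.00  0.00           O",
    "ATOM      5  N   GLY A   2       3.332   1.536   0.000  1.00  0.00           N",
    "ATOM      6  CA  GLY A   2       3.988   2.839   0.000  1.00  0.00           C",
    "ATOM      7  C   GLY A   2       5.504   2.693   0.000  1.00  0.00           C",
    "ATOM      8  O   GLY A   2       6.030   1.580   0.000  1.00  0.00           O",
    "ATOM      9  N   SER A   3       6.235   3.803   0.000  1.00  0.00           N",
    "ATOM     10  CA  SER A   3       7.690   3.770   0.000  1.00  0.00           C",
    "ATOM     11  C   SER A   3       8.250   5.180   0.000  1.00  0.00           C",
    "ATOM     12  O   SER A   3       7.520   6.170   0.000  1.00  0.00           O",
    "ATOM     13  OG  SER A   3       8.210   3.050   1.150  1.00  0.00           O",
    "ATOM     14  OXT SER A   3       9.480   5.280   0.000  1.00  0.00           O",
    "END")
}

write_mini_pdb <- function(path = tempfile(fileext = ".pdb")) {
  writeLines(mini_pdb_lines(), path)
  path
}

# straight poly-ALA chain: n residues, chain `chain`, numbering `start..`
straight_chain_atoms <- function(n, chain = "A", start = 1L, y = 0, z = 0) {
  rows <- NULL
  for (i in seq_len(n)) {
    x <- 3.8 * (i - 1)
    rows <- rbind(rows,
      data.frame(name = c("N", "CA", "C", "O", "CB"),
                 resname = "ALA", chain = chain,
                 resno = start + i - 1L,
                 x = x + c(-1.4, 0, 1.2, 1.2, 0),
                 y = y + c(0.5, 0, 0.5, 1.7, -0.8),
                 z = z + c(0, 0, 0.2, 0.2, 1.2)))
  }
  rows
}

straight_chain <- function(n, ...) new_structure(straight_chain_atoms(n, ...))

# two parallel PHE rings (full 6-ring geometry) at a given centroid
# separation; optionally rotated to a T-shaped arrangement
phe_ring_atoms <- function(chain, resno, centre, normal_axis = "z") {
  r <- 1.39
  ang <- seq(0, 2 * pi, length.out = 7)[1:6]
  ring <- cbind(r * cos(ang), r * sin(ang), 0)
  if (normal_axis == "x") ring <- ring[, c(3, 1, 2)]
  ring <- sweep(ring, 2, centre, `+`)
  nm <- c("CG", "CD1", "CD2", "CE1", "CE2", "CZ")
  rbind(
    data.frame(name = c("N", "CA", "C", "O", "CB"), resname = "PHE",
               chain = chain, resno = resno,
               x = centre[1] + c(-8, -7, -6.5, -6.4, -7),
               y = centre[2] + c(0.5, 0, 0.5, 1.7, -0.9),
               z = centre[3] + c(0, 0, 0.2, 0.3, 1.0)),
    data.frame(name = nm, resname = "PHE", chain = chain, resno = resno,
               x = ring[, 1], y = ring[, 2], z = ring[, 3]))
}

stacked_phe_complex <- function(sep = 4.0, tshape = FALSE) {
  a <- rbind(phe_ring_atoms("A", 1, c(0, 0, 0)),
             phe_ring_atoms("B", 1, c(0, 0, sep),
                            normal_axis = if (tshape) "x" else "z"))
  new_structure(a, roles = c(A = "receptor", B = "ligand"))
}

default_toy <- function(seed = 1) build_toy_complex(toy_spec(seed = seed))

ligand_heavy_rmsd_to_truth <- function(gen, pose_coords) {
  lh <- select_atoms(gen$ensemble$ligand_template, heavy = TRUE)
  coord_rmsd(pose_coords[lh, , drop = FALSE],
             gen$truth_coords[lh, , drop = FALSE])
}
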