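# Fixture builders shared across test files. Everything is generated in
# code; no binary fixtures.

# Fixed-column PDB ATOM line
pdb_atom_line <- function(serial, name, resid, chain, resno, x, y, z,
                          record = "ATOM", altloc = " ", occ = 1.00,
                          elesy = substr(trimws(name), 1, 1)) {
  sprintf("%-6s%5d %-4s%s%-3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          record, serial, name, altloc, resid, chain, resno, x, y, z, occ,
          0.0, elesy)
}

# A two-chain PDB: chain A with `na` glycine residues, chain B with `nb`,
# plus a HETATM ligand and waters.
two_chain_pdb <- function(na = 3, nb = 5) {
  lines <- character()
  serial <- 0
  for (i in seq_len(na)) {
    serial <- serial + 1
    lines <- c(lines, pdb_atom_line(serial, "CA", "GLY", "A", i,
                                    i * 4, 0, 0))
  }
  for (i in seq_len(nb)) {
    serial <- serial + 1
    lines <- c(lines, pdb_atom_line(serial, "CA", "ALA", "B", i,
                                    0, i * 4, 0))
  }
  lines <- c(lines,
             pdb_atom_line(900, "C1", "LIG", "A", 200, 1, 1, 1,
                           record = "HETATM"),
             pdb_atom_line(901, "O", "HOH", "A", 300, 2, 2, 2,
                           record = "HETATM"))
  paste(c(lines, "END"), collapse = "\n")
}

# Hand-built structure: atoms at explicit coordinates
toy_structure <- function(codes, coords, numbers = seq_along(codes),
                          id = "toy") {
  protein_structure(data.frame(
    serial = seq_along(codes), atom_name = "CA", residue_code = codes,
    residue_number = numbers, chain_id = "A",
    x = coords[, 1], y = coords[, 2], z = coords[, 3],
    stringsAsFactors = FALSE), structure_id = id, source = "synthetic")
}

# Raw activity record row
act_row <- function(molecule_id = "M1", target_id = "T1", type = "Ki",
                    relation = "=", value = 100, units = "nM",
                    comment = NA, year = 2010) {
  data.frame(molecule_id = molecule_id, target_id = target_id,
             activity_type = type, relation = relation, value = value,
             units = units, comment = comment, year = year,
             stringsAsFactors = FALSE)
}

# Well-spread activity block for one target: n molecules, spki spread
spread_target <- function(target_id, n, seed = 1) {
  ki <- proteofp:::with_seed(seed, 10^runif(n, 0.5, 3.5))
  do.call(rbind, lapply(seq_len(n), function(i)
    act_row(molecule_id = paste0(target_id, "_M", i), target_id = target_id,
            value = ki[i])))
}
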