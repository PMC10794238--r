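# Shared fixtures built in code.

AA <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
        "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

uniform_bg <- stats::setNames(rep(0.05, 20), AA)

# alignment from a character vector of equal-length strings
aln_from_strings <- function(strs, domain_ranges = NULL, ids = NULL) {
  m <- do.call(rbind, strsplit(strs, ""))
  paired_alignment(m, ids %||% paste0("s", seq_along(strs)),
                   domain_ranges %||% list(all = c(0L, ncol(m))))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# tiny hand-placed structure: n single-atom (CA) residues at given coords
structure_from_coords <- function(xyz, chain = "A", aa = "A",
                                  resno = NULL) {
  n <- nrow(xyz)
  protein_structure(data.frame(
    chain = rep(chain, length.out = n),
    resno = resno %||% seq_len(n),
    aa = rep(aa, length.out = n), elety = "CA",
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    stringsAsFactors = FALSE))
}

# contact map listing explicit pairs over n residues (single chain)
cmap_from_pairs <- function(pairs, n_res, min_sep = 2L) {
  ct <- data.frame(i = as.integer(pairs[, 1]),
                   j = as.integer(pairs[, 2]),
                   partition = rep("intra_A", nrow(pairs)),
                   min_distance = rep(NA_real_, nrow(pairs)))
  structure(list(contacts = ct, n_res = n_res,
                 chain = rep("A", n_res), resno = seq_len(n_res),
                 cutoff = 5.0, min_sep = min_sep),
            class = "contact_map")
}

# shared small PDB fixture text (3 residues, one with A/B altlocs,
# a hydrogen, and a HETATM water)
write_fixture_pdb <- function(path) {
  lines <- c(
    "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA  ALA A   1       1.400   0.000   0.000  1.00  0.00           C",
    "ATOM      3  HA  ALA A   1       1.400   1.000   0.000  1.00  0.00           H",
    "ATOM      4  CA ALEU A   2       4.500   0.000   0.000  0.70  0.00           C",
    "ATOM      5  CA BLEU A   2       4.700   0.300   0.000  0.30  0.00           C",
    "ATOM      6  CA  GLY A   3       9.000   0.000   0.000  1.00  0.00           C",
    "HETATM    7  O   HOH A   4      12.000   0.000   0.000  1.00  0.00           O",
    "END")
  writeLines(lines, path)
  path
}

# small MJ-style symmetric energy model with distinct entries, for tests
# that need controlled energies
diag_energy_model <- function(scale = -1) {
  m <- outer(seq_len(20), seq_len(20), function(a, b) scale * (a + b) / 10)
  dimnames(m) <- list(AA, AA)
  structure(list(table = m, provenance = "test"), class = "energy_model")
}
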