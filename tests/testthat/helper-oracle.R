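# Independent brute-force mass oracle: expands a peptide into a flat list
# of atoms (its own residue -> atom-string table, typed separately from the
# package's residue compositions) and sums per-atom masses one by one.

.oracle_atom_mass <- c(
  C = 12.0,
  H = 1.00782503207,
  N = 14.0030740048,
  O = 15.9949146196,
  S = 31.97207100
)

# residue -> explicit atom string (amino acid minus water)
.oracle_atoms <- c(
  G = "CCHHHNO",
  A = "CCCHHHHHNO",
  S = "CCCHHHHHNOO",
  P = "CCCCCHHHHHHHNO",
  V = "CCCCCHHHHHHHHHNO",
  T = "CCCCHHHHHHHNOO",
  C = "CCCHHHHHNOS",
  L = "CCCCCCHHHHHHHHHHHNO",
  I = "CCCCCCHHHHHHHHHHHNO",
  N = "CCCCHHHHHHNNOO",
  D = "CCCCHHHHHNOOO",
  Q = "CCCCCHHHHHHHHNNOO",
  K = "CCCCCCHHHHHHHHHHHHNNO",
  E = "CCCCCHHHHHHHNOOO",
  M = "CCCCCHHHHHHHHHNOS",
  H = "CCCCCCHHHHHHHNNNO",
  F = "CCCCCCCCCHHHHHHHHHNO",
  R = "CCCCCCHHHHHHHHHHHHNNNNO",
  Y = "CCCCCCCCCHHHHHHHHHNOO",
  W = "CCCCCCCCCCCHHHHHHHHHHNNO"
)

oracle_mass <- function(seq, topology = "linear") {
  atoms <- unlist(strsplit(strsplit(
    paste(.oracle_atoms[strsplit(seq, "")[[1]]], collapse = ""), "")[[1]],
    ""))
  total <- 0
  for (a in atoms) total <- total + .oracle_atom_mass[[a]]
  if (topology == "linear")
    total <- total + 2 * .oracle_atom_mass[["H"]] + .oracle_atom_mass[["O"]]
  total
}

random_peptide <- function(min_len = 2, max_len = 12) {
  len <- sample(min_len:max_len, 1)
  paste(sample(names(.oracle_atoms), len, replace = TRUE), collapse = "")
}

# a simple direct MS/MS spectrum for a core: all y/b/immonium peaks
noiseless_spectrum <- function(core) {
  ions <- theoretical_ions(core, c("y", "b", "immonium"))
  ms2_spectrum(data.frame(mz = ions$mz, intensity = 1000),
               precursor_mz = adduct_mz(peptide_mass(core, "cyclic"), "H"))
}
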