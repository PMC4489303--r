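# Generates the plain-text property tables under inst/extdata/.
#
# The DNA/RNA nucleotide tables and the SYNTHETIC-AA supplement carry
# synthetic calibration values (fixed seed below): the authoritative
# compilations are not redistributable here, and every feature formula
# standardizes indices before use, so the mathematics is value-agnostic.
# Canonical property names are retained so default selections match field
# conventions; named nucleotide properties are drawn from physically
# plausible ranges (degrees / angstroms for the helical step parameters).
# The three classic amino-acid scales in protein_classic3.tsv are real,
# hand-entered values (Eisenberg consensus hydrophobicity, Hopp-Woods
# hydrophilicity, side-chain mass in Daltons).
#
# Run from the package root: Rscript data-raw/make_property_tables.R

source("R/alphabets.R")
set.seed(7151)
dir.create("inst/extdata", recursive = TRUE, showWarnings = FALSE)

fmt_row <- function(name, values) {
  paste(c(name, formatC(values, digits = 4, format = "g")), collapse = "\t")
}

write_table <- function(file, oligos, names, values) {
  stopifnot(nrow(values) == length(names), ncol(values) == length(oligos))
  lines <- c(
    paste(c("property", oligos), collapse = "\t"),
    vapply(seq_along(names), function(i) fmt_row(names[i], values[i, ]), "")
  )
  writeLines(lines, file.path("inst/extdata", file))
}

# ---- DNA dinucleotides: 6 named structural step parameters + 142 synthetic
di <- pse_oligomers("DNA", 2)
named_dna <- rbind(
  Twist = round(runif(16, 31, 40), 2), # degrees
  Tilt  = round(runif(16, -4, 4), 2),  # degrees
  Roll  = round(runif(16, -6, 10), 2), # degrees
  Shift = round(runif(16, -0.3, 0.3), 3), # angstrom
  Slide = round(runif(16, -1.2, 1.0), 3), # angstrom
  Rise  = round(runif(16, 3.1, 3.6), 3)   # angstrom
)
synth_dna <- matrix(round(rnorm(142 * 16), 3), nrow = 142)
write_table(
  "dna_dinucleotide_indices.synthetic.tsv", di,
  c(rownames(named_dna), sprintf("SYNTH-DNA-DI-%03d", 1:142)),
  rbind(named_dna, synth_dna)
)

# standalone copy of the six structural properties, used as a small stable
# fixture so math tests never depend on the full table
write_table("dna_structural6.tsv", di, rownames(named_dna), named_dna)

# ---- DNA trinucleotides: 12 indices (2 named defaults + 10 synthetic)
tri <- pse_oligomers("DNA", 3)
tri_vals <- matrix(round(rnorm(12 * 64), 3), nrow = 12)
write_table(
  "dna_trinucleotide_indices.synthetic.tsv", tri,
  c("Bendability", "Nucleosome", sprintf("SYNTH-DNA-TRI-%03d", 1:10)),
  tri_vals
)

# ---- RNA dinucleotides: 22 indices (6 named structural analogues + 16 synthetic)
rdi <- pse_oligomers("RNA", 2)
named_rna <- rbind(
  `Twist-RNA` = round(runif(16, 28, 35), 2),
  `Tilt-RNA`  = round(runif(16, -4, 4), 2),
  `Roll-RNA`  = round(runif(16, 2, 12), 2),
  `Shift-RNA` = round(runif(16, -0.3, 0.3), 3),
  `Slide-RNA` = round(runif(16, -2.0, -1.0), 3),
  `Rise-RNA`  = round(runif(16, 2.8, 3.5), 3)
)
synth_rna <- matrix(round(rnorm(16 * 16), 3), nrow = 16)
write_table(
  "rna_dinucleotide_indices.synthetic.tsv", rdi,
  c(rownames(named_rna), sprintf("SYNTH-RNA-DI-%03d", 1:16)),
  rbind(named_rna, synth_rna)
)

# ---- amino acids: 3 classic scales (real values) + 13 synthetic top-ups.
# Values are entered per residue by name, then emitted in lexicographic
# one-letter order.
aa <- pse_oligomers("PROTEIN", 1)
hydrophobicity <- c(
  A = 0.62, R = -2.53, N = -0.78, D = -0.90, C = 0.29, Q = -0.85,
  E = -0.74, G = 0.48, H = -0.40, I = 1.38, L = 1.06, K = -1.50,
  M = 0.64, F = 1.19, P = 0.12, S = -0.18, T = -0.05, W = 0.81,
  Y = 0.26, V = 1.08
)
hydrophilicity <- c(
  A = -0.5, R = 3.0, N = 0.2, D = 3.0, C = -1.0, Q = 0.2, E = 3.0,
  G = 0.0, H = -0.5, I = -1.8, L = -1.8, K = 3.0, M = -1.3, F = -2.5,
  P = 0.0, S = 0.3, T = -0.4, W = -3.4, Y = -2.3, V = -1.5
)
side_chain_mass <- c(
  A = 15, R = 101, N = 58, D = 59, C = 47, Q = 72, E = 73, G = 1,
  H = 82, I = 57, L = 57, K = 73, M = 75, F = 91, P = 42, S = 31,
  T = 45, W = 130, Y = 107, V = 43
)
write_table(
  "protein_classic3.tsv", aa,
  c("Hydrophobicity", "Hydrophilicity", "SideChainMass"),
  rbind(hydrophobicity[aa], hydrophilicity[aa], side_chain_mass[aa])
)
write_table(
  "protein_supplement.synthetic.tsv", aa,
  sprintf("SYNTHETIC-AA-%03d", 1:13),
  matrix(round(rnorm(13 * 20), 3), nrow = 13)
)

cat("property tables written to inst/extdata/\n")
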