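# Shared fixtures, built in code.

# Build a validated sequence tibble from bare residue strings.
make_seqs <- function(strings, alphabet, ids = NULL) {
  if (is.null(ids)) ids <- sprintf("s%d", seq_along(strings))
  validate_alphabet(
    tibble::tibble(
      id = ids, description = "", seq = strings, alphabet = NA_character_
    ),
    alphabet
  )
}

# The six-property dinucleotide fixture shipped as a standalone file, so
# math tests never depend on the full built-in table.
structural6 <- function() {
  parse_user_index(
    system.file("extdata", "dna_structural6.tsv", package = "psekit"),
    "DNA", 2
  )
}

# Tiny raw amino-acid property table for protein-mode tests.
toy_protein_props <- function(n = 2) {
  aa <- pse_oligomers("PROTEIN", 1)
  set.seed(42)
  vals <- matrix(round(rnorm(n * 20), 3), nrow = n)
  colnames(vals) <- aa
  txt <- paste(
    c(
      paste(aa, collapse = "\t"),
      vapply(seq_len(n), function(i) {
        paste(c(paste0("toy", i), vals[i, ]), collapse = "\t")
      }, character(1))
    ),
    collapse = "\n"
  )
  parse_user_index(txt, "PROTEIN", 1)
}

# align oracle output (tibble with id + features) to a feature matrix
oracle_matrix <- function(o) {
  m <- as.matrix(o[, setdiff(names(o), "id"), drop = FALSE])
  rownames(m) <- o$id
  m
}
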