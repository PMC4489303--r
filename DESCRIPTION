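Package: psekit
Title: Pseudo-Component Feature Vectors for DNA, RNA and Protein Sequences
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Converts DNA, RNA and protein sequences into fixed-dimension
    numeric feature vectors for machine learning, covering 28 published
    feature modes in three families: oligomer composition (Kmer, reverse
    complementary Kmer), physicochemical autocorrelation (DAC, DCC, DACC,
    TAC, TCC, TACC, AC, CC, ACC) and pseudo-component composition (PseDNC,
    PseKNC and the parallel- and series-correlation pseudo compositions for
    nucleotides and amino acids). Ships built-in physicochemical index
    tables for dinucleotides, trinucleotides and amino acids, supports
    user-defined index files, and writes LIBSVM, CSV and tab-delimited
    output. Includes seeded synthetic-sequence generation and independent
    brute-force oracles for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    purrr,
    rlang,
    stringr,
    readr,
    tidyr,
    generics,
    ggplot2,
    Biostrings,
    seqinr
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
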