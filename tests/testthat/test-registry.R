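published_modes <- list(
  DNA = c(
    "Kmer", "RevKmer", "DAC", "DCC", "DACC", "TAC", "TCC", "TACC",
    "PseDNC", "PseKNC", "PC-PseDNC-General", "PC-PseTNC-General",
    "SC-PseDNC-General", "SC-PseTNC-General"
  ),
  RNA = c("Kmer", "DAC", "DCC", "DACC", "PC-PseDNC-General", "SC-PseDNC-General"),
  PROTEIN = c(
    "Kmer", "AC", "CC", "ACC", "PC-PseAAC", "SC-PseAAC",
    "PC-PseAAC-General", "SC-PseAAC-General"
  )
)

probe_features <- function(mode_row, seqs) {
  cat_ <- mode_row$category
  props <- switch(paste(mode_row$alphabet, cat_),
    "DNA autocorrelation" = if (grepl("^T", mode_row$mode)) {
      load_builtin("DNA", 3)[1:2, ]
    } else {
      structural6()[1:2, ]
    },
    "RNA autocorrelation" = load_builtin("RNA", 2)[1:2, ],
    "PROTEIN autocorrelation" = load_builtin("PROTEIN", 1)[1:2, ],
    NULL
  )
  extract_features(
    seqs, mode_row$mode,
    k = if (grepl("k", mode_row$parameters)) 2 else NULL,
    lag = if (cat_ == "autocorrelation") 2 else NULL,
    lambda = if (cat_ == "pseudo") 3 else NULL,
    props = props
  )
}

test_that("the registry exposes 28 modes: 14 DNA, 6 RNA, 8 protein", {
  all_modes <- list_modes()
  expect_equal(nrow(all_modes), 28)
  for (a in names(published_modes)) {
    got <- list_modes(a)
    expect_equal(nrow(got), length(published_modes[[a]]))
    expect_setequal(got$mode, published_modes[[a]])
    expect_false(anyDuplicated(got$mode) > 0)
  }
})

test_that("every registered mode runs on a probe batch and matches its dimension formula", {
  probes <- list(
    DNA = random_sequences("DNA", 2, 40, 40, seed = 1),
    RNA = random_sequences("RNA", 2, 40, 40, seed = 2),
    PROTEIN = random_sequences("PROTEIN", 2, 40, 40, seed = 3)
  )
  modes <- list_modes()
  for (i in seq_len(nrow(modes))) {
    row <- modes[i, ]
    v <- probe_features(row, probes[[row$alphabet]])
    expect_s3_class(v, "pse_features")
    expect_equal(nrow(v), 2)
    g <- glance(v)
    expect_equal(g$mode, row$mode)
    expect_gte(g$dimension, 1)
    # every mode's output feeds every writer without error
    expect_no_error(write_libsvm(v))
    expect_no_error(write_delimited(v, "comma"))
    expect_no_error(heatmap_matrix(v, ncols = 5))
  }
})

test_that("identical inputs give bitwise-identical outputs", {
  seqs <- random_sequences("DNA", 3, 30, 50, seed = 6)
  a <- extract_features(seqs, "PseKNC", k = 2, lambda = 4)
  b <- extract_features(seqs, "PseKNC", k = 2, lambda = 4)
  expect_identical(a, b)
})

test_that("batch runs concatenate: split input equals whole input", {
  seqs <- random_sequences("PROTEIN", 6, 25, 45, seed = 13)
  whole <- feature_matrix(extract_features(seqs, "PC-PseAAC", lambda = 4))
  parts <- rbind(
    feature_matrix(extract_features(seqs[1:2, ], "PC-PseAAC", lambda = 4)),
    feature_matrix(extract_features(seqs[3:6, ], "PC-PseAAC", lambda = 4))
  )
  expect_identical(whole, parts)
})

test_that("unknown modes fail listing the valid names for the alphabet", {
  seqs <- random_sequences("RNA", 1, 30, 30, seed = 4)
  err <- expect_error(extract_features(seqs, "RevKmer"), "Unknown mode")
  expect_match(conditionMessage(err), "SC-PseDNC-General")
  expect_error(extract_features(seqs, "TAC", lag = 1), "Unknown mode")
})

test_that("parameter schemas are enforced with informative bounds", {
  dna <- random_sequences("DNA", 1, 60, 60, seed = 5)
  prot <- random_sequences("PROTEIN", 1, 60, 60, seed = 5)
  expect_error(extract_features(dna, "Kmer"), "requires `k`")
  expect_error(extract_features(dna, "Kmer", k = 7), "\\[1, 6\\]")
  expect_error(extract_features(prot, "Kmer", k = 4), "\\[1, 3\\]")
  expect_equal(
    ncol(extract_features(prot, "Kmer", k = 4, allow_large_k = TRUE)) - 1,
    20^4
  )
  expect_error(extract_features(dna, "DAC"), "requires `lag`")
  expect_error(extract_features(dna, "DAC", lag = 2), "no canonical default")
  expect_error(extract_features(dna, "PseDNC"), "requires `lambda`")
  expect_error(extract_features(dna, "PseDNC", lambda = 3, w = -0.1), "w")
})

test_that("batch semantics are all-or-nothing on length failures", {
  seqs <- make_seqs(c("ACGTACGTACGT", "ACGT"), "DNA", ids = c("long", "tiny"))
  err <- expect_error(extract_features(seqs, "DAC", lag = 5, props = structural6()[1:2, ]))
  expect_match(conditionMessage(err), "tiny")
  expect_error(extract_features(seqs, "Kmer", k = 5), "tiny")
})

test_that("user-defined property files drive the General modes", {
  seqs <- random_sequences("DNA", 2, 30, 40, seed = 10)
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(write_property_index(structural6()[1:2, ]), path)
  v <- extract_features(seqs, "PC-PseDNC-General", lambda = 3, props_file = path)
  expect_equal(ncol(v) - 1, 19)
  direct <- extract_features(seqs, "PC-PseDNC-General",
    lambda = 3,
    props = c("Twist", "Tilt")
  )
  expect_equal(feature_matrix(v), feature_matrix(direct), tolerance = 1e-9)
})
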