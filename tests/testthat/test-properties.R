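test_that("built-in tables have the documented cardinalities and slots", {
  expect_equal(nrow(load_builtin("DNA", 2)), 148)
  expect_equal(nrow(load_builtin("DNA", 3)), 12)
  expect_equal(nrow(load_builtin("RNA", 2)), 22)
  expect_equal(nrow(load_builtin("PROTEIN", 1)), 547)
  expect_error(load_builtin("RNA", 3), "No built-in")
  expect_error(load_builtin("PROTEIN", 2), "No built-in")
})

test_that("load_builtin is deterministic and names are unique", {
  for (slot in list(c("DNA", 2), c("DNA", 3), c("RNA", 2), c("PROTEIN", 1))) {
    a <- load_builtin(slot[1], as.integer(slot[2]))
    b <- load_builtin(slot[1], as.integer(slot[2]))
    expect_identical(a, b)
    expect_false(anyDuplicated(a$property) > 0)
    expect_true(all(is.finite(prop_values(a))))
  }
})

test_that("every built-in property standardizes (no constant rows)", {
  for (slot in list(c("DNA", 2), c("DNA", 3), c("RNA", 2), c("PROTEIN", 1))) {
    z <- normalize_index(load_builtin(slot[1], as.integer(slot[2])))
    m <- prop_values(z)
    expect_lt(max(abs(rowMeans(m))), 1e-9)
    expect_lt(max(abs(sqrt(rowMeans(m^2)) - 1)), 1e-9)
  }
})

test_that("normalize_index matches direct z-score arithmetic and keeps rank order", {
  # mononucleotide analogue {A:1, C:2, G:3, T:4}: mean 2.5, population SD
  # sqrt(1.25), z-scores symmetric about 0
  txt <- "A\tC\tG\tT\nramp\t1\t2\t3\t4"
  p <- parse_user_index(txt, "DNA", 1)
  z <- prop_values(normalize_index(p))[1, ]
  expected <- (c(1, 2, 3, 4) - 2.5) / sqrt(1.25)
  expect_equal(unname(z), expected, tolerance = 1e-12)
  expect_equal(sum(z), 0, tolerance = 1e-12)
  expect_equal(order(z), order(c(1, 2, 3, 4)))
})

test_that("normalize_index is idempotent within 1e-12", {
  p <- normalize_index(structural6())
  p2 <- normalize_index(p)
  expect_lt(max(abs(prop_values(p2) - prop_values(p))), 1e-12)
})

test_that("constant properties raise a degenerate-property error", {
  txt <- "A\tC\tG\tT\nflat\t5\t5\t5\t5"
  expect_error(normalize_index(parse_user_index(txt, "DNA", 1)), "flat")
})

test_that("parse_user_index accepts a minimal valid dinucleotide file", {
  header <- paste(pse_oligomers("DNA", 2), collapse = "\t")
  row <- paste(c("mine", 1:16), collapse = "\t")
  p <- parse_user_index(paste(header, row, sep = "\n"), "DNA", 2)
  expect_equal(p$property, "mine")
  expect_equal(unname(prop_values(p)[1, ]), as.numeric(1:16))
  # comma-delimited variant parses identically
  pc <- parse_user_index(
    paste(gsub("\t", ",", header), gsub("\t", ",", row), sep = "\n"), "DNA", 2
  )
  expect_equal(prop_values(pc), prop_values(p))
})

test_that("parse errors carry row/column coordinates", {
  header <- paste(pse_oligomers("DNA", 2), collapse = "\t")
  short_row <- paste(c("mine", 1:15), collapse = "\t")
  expect_error(
    parse_user_index(paste(header, short_row, sep = "\n"), "DNA", 2),
    "Row 2"
  )
  bad_cell <- paste(c("mine", 1:15, "oops"), collapse = "\t")
  err <- expect_error(
    parse_user_index(paste(header, bad_cell, sep = "\n"), "DNA", 2),
    "Row 2"
  )
  expect_match(conditionMessage(err), "oops")
  dup <- paste(
    header,
    paste(c("same", 1:16), collapse = "\t"),
    paste(c("same", 16:1), collapse = "\t"),
    sep = "\n"
  )
  expect_error(parse_user_index(dup, "DNA", 2), "Duplicate")
  bad_header <- paste(c("AA", "AC", paste(rep("ZZ", 14))), collapse = "\t")
  expect_error(
    parse_user_index(paste(bad_header, paste(c("m", 1:16), collapse = "\t"), sep = "\n"), "DNA", 2),
    "missing oligomer"
  )
})

test_that("write + parse of a property table is the identity", {
  p <- structural6()
  lines <- write_property_index(p, digits = 10)
  back <- parse_user_index(paste(lines, collapse = "\n"), "DNA", 2)
  expect_equal(back$property, p$property)
  expect_equal(prop_values(back), prop_values(p), tolerance = 1e-9)
})

test_that("select_props preserves order and suggests near-matches", {
  p <- load_builtin("DNA", 2)
  sel <- select_props(p, c("Rise", "Twist"))
  expect_equal(sel$property, c("Rise", "Twist"))
  err <- expect_error(select_props(p, "Twst"), "Unknown")
  expect_match(conditionMessage(err), "Twist")
})

test_that("the shipped six-property fixture agrees with the full table", {
  full <- select_props(load_builtin("DNA", 2), structural6()$property)
  expect_equal(prop_values(full), prop_values(structural6()), tolerance = 1e-9)
})
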