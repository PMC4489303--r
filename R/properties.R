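#' Physicochemical property tables
#'
#' A property table (`pse_props`) is a tibble with a `property` column and
#' one numeric column per oligomer of a fixed length, covering the
#' complete oligomer set (16 dinucleotides, 64 trinucleotides or 20 amino
#' acids) in lexicographic order. Attributes record the alphabet, the
#' oligomer length and whether the values have been standardized.
#'
#' @name pse_props
NULL

new_pse_props <- function(df, alphabet, oligo_len, normalized) {
  out <- tibble::as_tibble(df)
  attr(out, "alphabet") <- alphabet
  attr(out, "oligo_len") <- oligo_len
  attr(out, "normalized") <- normalized
  class(out) <- c("pse_props", class(tibble::tibble()))
  out
}

#' @export
print.pse_props <- function(x, ...) {
  cat(sprintf(
    "# Property table: %d %s propert%s over %d oligomers (length %d)%s\n",
    nrow(x), attr(x, "alphabet"), if (nrow(x) == 1) "y" else "ies",
    ncol(x) - 1L, attr(x, "oligo_len"),
    if (isTRUE(attr(x, "normalized"))) ", standardized" else ""
  ))
  NextMethod()
}

#' @export
`[.pse_props` <- function(x, ...) {
  out <- NextMethod()
  if (is.data.frame(out)) {
    attr(out, "alphabet") <- attr(x, "alphabet")
    attr(out, "oligo_len") <- attr(x, "oligo_len")
    attr(out, "normalized") <- attr(x, "normalized")
    class(out) <- class(x)
  }
  out
}

check_props <- function(props, alphabet = NULL) {
  if (!is.data.frame(props) || !"property" %in% names(props)) {
    rlang::abort("`props` must be a property table (see `load_builtin()` or `parse_user_index()`).")
  }
  a <- attr(props, "alphabet")
  g <- attr(props, "oligo_len")
  if (is.null(a) || is.null(g)) {
    rlang::abort("`props` is missing its alphabet/oligomer-length metadata; build it with the package constructors.")
  }
  if (!is.null(alphabet) && a != match_alphabet(alphabet)) {
    rlang::abort(sprintf(
      "Property table is for %s but the sequences are %s.", a, alphabet
    ))
  }
  expected <- pse_oligomers(a, g)
  if (!identical(setdiff(names(props), "property"), expected)) {
    rlang::abort(sprintf(
      "Property table must have exactly the %d length-%d %s oligomer columns in lexicographic order.",
      length(expected), g, a
    ))
  }
  if (nrow(props) == 0L) rlang::abort("`props` contains no properties.")
  props
}

prop_matrix <- function(props) {
  m <- as.matrix(props[, setdiff(names(props), "property"), drop = FALSE])
  rownames(m) <- props$property
  m
}

# cache for assembled built-in tables
.builtin_cache <- new.env(parent = emptyenv())

#' Load built-in physicochemical index tables
#'
#' Returns the packaged property table for one of the four supported
#' slots: DNA dinucleotides (148 indices), DNA trinucleotides (12), RNA
#' dinucleotides (22) or amino acids (547). Order and values are stable
#' across calls and across runs.
#'
#' The amino-acid table is assembled from three parts: the three classic
#' pseudo-composition scales (hydrophobicity, hydrophilicity, side-chain
#' mass), the 531 complete non-constant entries of the AAindex
#' compilation shipped with the seqinr package (named by AAindex
#' accession), and 13 clearly labelled synthetic entries
#' (`SYNTHETIC-AA-*`). The nucleotide tables ship canonical property
#' names (Twist, Tilt, Roll, Shift, Slide, Rise, ...) but their numeric
#' values are synthetic calibration values; see the package vignette.
#' All feature formulas standardize indices before use, so results are
#' comparable across property sources.
#'
#' @param alphabet `"DNA"`, `"RNA"` or `"PROTEIN"`.
#' @param oligo_len Oligomer length: 2 or 3 for DNA, 2 for RNA, 1 for
#'   protein.
#' @return A [pse_props] table with raw (unstandardized) values.
#' @examples
#' nrow(load_builtin("DNA", 2))   # 148
#' nrow(load_builtin("PROTEIN", 1))  # 547
#' @export
load_builtin <- function(alphabet, oligo_len) {
  alphabet <- match_alphabet(alphabet)
  oligo_len <- check_count(oligo_len, "oligo_len", min = 1L)
  key <- paste(alphabet, oligo_len, sep = ".")
  if (!is.null(.builtin_cache[[key]])) {
    return(.builtin_cache[[key]])
  }
  slot <- paste(alphabet, oligo_len)
  tbl <- switch(slot,
    "DNA 2" = read_builtin_file("dna_dinucleotide_indices.synthetic.tsv", "DNA", 2L),
    "DNA 3" = read_builtin_file("dna_trinucleotide_indices.synthetic.tsv", "DNA", 3L),
    "RNA 2" = read_builtin_file("rna_dinucleotide_indices.synthetic.tsv", "RNA", 2L),
    "PROTEIN 1" = assemble_protein_builtin(),
    rlang::abort(sprintf(
      "No built-in property table for alphabet %s with oligomer length %d; supported slots: DNA/2, DNA/3, RNA/2, PROTEIN/1.",
      alphabet, oligo_len
    ))
  )
  .builtin_cache[[key]] <- tbl
  tbl
}

read_builtin_file <- function(name, alphabet, oligo_len) {
  path <- system.file("extdata", name, package = "psekit", mustWork = TRUE)
  parse_user_index(path, alphabet, oligo_len)
}

assemble_protein_builtin <- function() {
  aa <- pse_alphabet("PROTEIN")
  classic <- read_builtin_file("protein_classic3.tsv", "PROTEIN", 1L)
  synth <- read_builtin_file("protein_supplement.synthetic.tsv", "PROTEIN", 1L)

  env <- new.env()
  utils::data("aaindex", package = "seqinr", envir = env)
  aaindex <- env$aaindex
  # seqinr stores values under three-letter names; map to one-letter order
  three <- c(
    A = "Ala", C = "Cys", D = "Asp", E = "Glu", F = "Phe", G = "Gly",
    H = "His", I = "Ile", K = "Lys", L = "Leu", M = "Met", N = "Asn",
    P = "Pro", Q = "Gln", R = "Arg", S = "Ser", T = "Thr", V = "Val",
    W = "Trp", Y = "Tyr"
  )
  rows <- lapply(aaindex, function(entry) {
    v <- entry$I[three[aa]]
    if (all(is.finite(v)) && stats::sd(v) > 0) unname(v) else NULL
  })
  keep <- !vapply(rows, is.null, logical(1))
  m <- do.call(rbind, rows[keep])
  colnames(m) <- aa
  aat <- tibble::as_tibble(m)
  aat <- tibble::add_column(aat, property = names(aaindex)[keep], .before = 1)

  out <- dplyr::bind_rows(
    tibble::as_tibble(classic),
    aat,
    tibble::as_tibble(synth)
  )
  stopifnot(!anyDuplicated(out$property))
  new_pse_props(out, "PROTEIN", 1L, normalized = FALSE)
}

#' Standardize a property table to zero mean and unit variance
#'
#' Each property (row) is converted to z-scores over the complete
#' oligomer set using the population standard deviation (divide by N,
#' not N-1): the oligomer set is the full population, not a sample. The
#' operation is idempotent and preserves the rank order of oligomers
#' within each property.
#'
#' @param props A [pse_props] table.
#' @return The table with standardized values and the `normalized`
#'   attribute set.
#' @examples
#' p <- load_builtin("DNA", 2)
#' z <- normalize_index(p)
#' rowMeans(prop_values(z))  # ~0
#' @export
normalize_index <- function(props) {
  props <- check_props(props)
  m <- prop_matrix(props)
  mu <- rowMeans(m)
  # population SD: divide by N
  sd_pop <- sqrt(rowMeans((m - mu)^2))
  if (any(sd_pop == 0)) {
    bad <- props$property[sd_pop == 0]
    rlang::abort(sprintf(
      "Degenerate (constant) propert%s cannot be standardized: %s",
      if (length(bad) == 1) "y" else "ies", paste(bad, collapse = ", ")
    ))
  }
  z <- (m - mu) / sd_pop
  out <- props
  out[, colnames(m)] <- tibble::as_tibble(z)
  attr(out, "normalized") <- TRUE
  out
}

#' Extract the numeric value matrix of a property table
#'
#' @param props A [pse_props] table.
#' @return Numeric matrix, properties in rows (rownames), oligomers in
#'   lexicographic order in columns.
#' @export
prop_values <- function(props) {
  prop_matrix(check_props(props))
}

#' Parse a user-defined physicochemical index file
#'
#' The file format is tab- or comma-delimited plain text: the first row
#' lists the complete oligomer set in lexicographic order (an optional
#' leading `property` cell is allowed); each subsequent row gives a
#' property name followed by one numeric value per oligomer.
#' Completeness is validated against the full oligomer set, and parse
#' errors report row/column coordinates.
#'
#' @param file Path to the index file, or a character scalar containing
#'   the file text (recognised by an embedded newline).
#' @param alphabet `"DNA"`, `"RNA"` or `"PROTEIN"`.
#' @param oligo_len Oligomer length the file must cover (1, 2 or 3).
#' @return A [pse_props] table with raw values.
#' @examples
#' txt <- paste(
#'   paste(pse_oligomers("DNA", 1), collapse = "\t"),
#'   paste("toy", 1, 2, 3, 4, sep = "\t"),
#'   sep = "\n"
#' )
#' parse_user_index(txt, "DNA", 1)
#' @export
parse_user_index <- function(file, alphabet, oligo_len) {
  alphabet <- match_alphabet(alphabet)
  oligo_len <- check_count(oligo_len, "oligo_len", min = 1L)
  lines <- if (grepl("\n", file, fixed = TRUE)) {
    strsplit(file, "\n", fixed = TRUE)[[1]]
  } else {
    if (!file.exists(file)) rlang::abort(sprintf("Index file not found: %s", file))
    readLines(file, warn = FALSE)
  }
  lines <- sub("\r$", "", lines)
  lines <- lines[trimws(lines) != ""]
  if (length(lines) < 2L) {
    rlang::abort("Index file must contain a header row and at least one property row.")
  }
  delim <- if (grepl("\t", lines[1], fixed = TRUE)) "\t" else ","
  cells <- strsplit(lines, delim, fixed = TRUE)
  cells <- lapply(cells, trimws)

  expected <- pse_oligomers(alphabet, oligo_len)
  header <- cells[[1]]
  if (length(header) > 0 && tolower(header[1]) %in% c("property", "name", "")) {
    header <- header[-1]
  }
  if (length(header) != length(expected)) {
    rlang::abort(sprintf(
      "Row 1: header lists %d oligomers but the complete length-%d %s set has %d.",
      length(header), oligo_len, alphabet, length(expected)
    ))
  }
  missing <- setdiff(expected, toupper(header))
  if (length(missing) > 0) {
    rlang::abort(sprintf(
      "Row 1: header is missing oligomer column(s): %s",
      paste(utils::head(missing, 5), collapse = ", ")
    ))
  }
  ord <- match(expected, toupper(header))

  n_oligo <- length(expected)
  vals <- matrix(NA_real_, nrow = length(cells) - 1L, ncol = n_oligo)
  nm <- character(nrow(vals))
  for (r in seq_len(nrow(vals))) {
    row <- cells[[r + 1L]]
    if (length(row) != n_oligo + 1L) {
      rlang::abort(sprintf(
        "Row %d: expected %d cells (property name + %d values) but found %d.",
        r + 1L, n_oligo + 1L, n_oligo, length(row)
      ))
    }
    nm[r] <- row[1]
    num <- suppressWarnings(as.numeric(row[-1]))
    if (anyNA(num)) {
      col <- which(is.na(num))[1]
      rlang::abort(sprintf(
        "Row %d, column %d: non-numeric value '%s'.",
        r + 1L, col + 1L, row[col + 1L]
      ))
    }
    vals[r, ] <- num[ord]
  }
  if (anyDuplicated(nm)) {
    dup <- unique(nm[duplicated(nm)])
    rlang::abort(sprintf(
      "Duplicate property name(s): %s", paste(dup, collapse = ", ")
    ))
  }
  colnames(vals) <- expected
  out <- tibble::add_column(tibble::as_tibble(vals), property = nm, .before = 1)
  new_pse_props(out, alphabet, oligo_len, normalized = FALSE)
}

#' Write a property table in the user-index format
#'
#' @param props A [pse_props] table.
#' @param file Optional output path; when `NULL` the lines are returned.
#' @param digits Significant digits for values.
#' @return Character vector of lines (invisibly when written to a file).
#' @export
write_property_index <- function(props, file = NULL, digits = 8L) {
  props <- check_props(props)
  digits <- check_count(digits, "digits", min = 1L, max = 17L)
  oligos <- setdiff(names(props), "property")
  m <- prop_matrix(props)
  lines <- c(
    paste(c("property", oligos), collapse = "\t"),
    vapply(seq_len(nrow(m)), function(i) {
      paste(c(rownames(m)[i], sprintf("%.*g", digits, m[i, ])),
        collapse = "\t"
      )
    }, character(1))
  )
  if (!is.null(file)) {
    writeLines(lines, file)
    return(invisible(lines))
  }
  lines
}

#' Select properties by name
#'
#' Subsets a property table to the named properties, preserving the
#' requested order. Unknown names fail fast, listing near-matches.
#'
#' @param props A [pse_props] table.
#' @param names Character vector of property names.
#' @return The subset [pse_props] table.
#' @export
select_props <- function(props, names) {
  props <- check_props(props)
  idx <- match(names, props$property)
  if (anyNA(idx)) {
    unknown <- names[is.na(idx)]
    hints <- unlist(lapply(unknown, function(u) {
      utils::head(agrep(u, props$property, value = TRUE, ignore.case = TRUE), 3)
    }))
    hint_txt <- if (length(hints)) {
      sprintf(" Did you mean: %s?", paste(unique(hints), collapse = ", "))
    } else {
      ""
    }
    rlang::abort(sprintf(
      "Unknown propert%s: %s.%s",
      if (length(unknown) == 1) "y" else "ies",
      paste(unknown, collapse = ", "), hint_txt
    ))
  }
  out <- props[idx, ]
  new_pse_props(out, attr(props, "alphabet"), attr(props, "oligo_len"),
    normalized = isTRUE(attr(props, "normalized"))
  )
}

# Default property selections per mode family (documented in the vignette).
default_prop_names <- function(alphabet, oligo_len, kind = "parallel") {
  slot <- paste(alphabet, oligo_len)
  switch(slot,
    "DNA 2" = c("Twist", "Tilt", "Roll", "Shift", "Slide", "Rise"),
    "RNA 2" = c(
      "Twist-RNA", "Tilt-RNA", "Roll-RNA",
      "Shift-RNA", "Slide-RNA", "Rise-RNA"
    ),
    "DNA 3" = c("Bendability", "Nucleosome"),
    "PROTEIN 1" = if (identical(kind, "series")) {
      c("Hydrophobicity", "Hydrophilicity")
    } else {
      c("Hydrophobicity", "Hydrophilicity", "SideChainMass")
    },
    rlang::abort(sprintf("No default properties for %s.", slot))
  )
}
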