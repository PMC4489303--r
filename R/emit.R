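#' Write feature vectors in LIBSVM sparse format
#'
#' One line per sequence: a class label followed by space-separated
#' `index:value` pairs with 1-based, strictly ascending indices.
#' Zero-valued features are omitted (the sparse convention), so an
#' all-zero vector yields a bare label line.
#'
#' @param features A `pse_features` tibble.
#' @param labels Class labels, one per sequence (recycled if length 1);
#'   default `"+1"` for unlabeled feature-generation runs. Labels must
#'   not contain whitespace.
#' @param file Optional output path; when `NULL` the lines are returned.
#' @param digits Significant digits for values (default 8).
#' @return Character vector of LIBSVM lines (invisibly when written).
#' @examples
#' s <- validate_alphabet(read_fasta(">x\nACGT\n"), "DNA")
#' write_libsvm(kmer_vector(s, 2))
#' @export
write_libsvm <- function(features, labels = NULL, file = NULL, digits = 8L) {
  m <- feature_matrix(features)
  digits <- check_count(digits, "digits", min = 1L, max = 17L)
  labels <- resolve_class_labels(labels, nrow(m))
  lines <- vapply(seq_len(nrow(m)), function(i) {
    v <- m[i, ]
    nz <- which(v != 0)
    if (length(nz) == 0L) {
      return(labels[i])
    }
    paste(
      labels[i],
      paste0(nz, ":", sprintf("%.*g", digits, v[nz]),
        collapse = " "
      )
    )
  }, character(1))
  if (!is.null(file)) {
    writeLines(lines, file)
    return(invisible(lines))
  }
  lines
}

resolve_class_labels <- function(labels, n) {
  if (is.null(labels)) labels <- "+1"
  labels <- as.character(labels)
  if (length(labels) == 1L) labels <- rep(labels, n)
  if (length(labels) != n) {
    rlang::abort(sprintf(
      "Expected %d class labels (one per sequence), got %d.", n, length(labels)
    ))
  }
  if (any(grepl("[[:space:]]", labels))) {
    rlang::abort("Class labels must not contain whitespace.")
  }
  labels
}

#' Write feature vectors as dense delimited text (CSV / tab)
#'
#' Dense rows with a header of feature labels: first column `id`, then
#' one column per feature, one data row per sequence. CSV quotes fields
#' containing the delimiter per the usual CSV convention; the
#' tab-delimited writer rejects labels containing a tab.
#'
#' @inheritParams write_libsvm
#' @param delimiter `"comma"` (CSV) or `"tab"` (TSV).
#' @return Character vector of lines (invisibly when written to `file`).
#' @examples
#' s <- validate_alphabet(read_fasta(">x\nACGT\n"), "DNA")
#' write_delimited(kmer_vector(s, 1), delimiter = "comma")
#' @export
write_delimited <- function(features, delimiter = c("comma", "tab"),
                            file = NULL, digits = 8L) {
  delimiter <- match.arg(delimiter)
  m <- feature_matrix(features)
  digits <- check_count(digits, "digits", min = 1L, max = 17L)
  labs <- colnames(m)
  txt <- matrix(sprintf("%.*g", digits, m),
    nrow = nrow(m),
    dimnames = list(NULL, labs)
  )
  df <- tibble::add_column(tibble::as_tibble(txt), id = rownames(m), .before = 1)
  out <- if (delimiter == "comma") {
    readr::format_csv(df)
  } else {
    if (any(grepl("\t", c("id", labs), fixed = TRUE))) {
      rlang::abort("Feature labels must not contain tab characters in tab-delimited output.")
    }
    readr::format_tsv(df)
  }
  lines <- strsplit(out, "\n", fixed = TRUE)[[1]]
  if (!is.null(file)) {
    writeLines(lines, file)
    return(invisible(lines))
  }
  lines
}

#' Heat-map matrix of a feature vector
#'
#' Reshapes one feature vector into the row-major grid underlying the
#' heat-map display: the vector fills a matrix with `ncols` columns left
#' to right, top to bottom, the last row padded with `NA`. A parallel
#' character matrix of feature labels (attribute `"labels"`) maps each
#' cell back to its feature; padding cells are `NA` there too. Data
#' only — no plotting (see [ggplot2::autoplot()] for a graphical view).
#'
#' @param features A `pse_features` tibble.
#' @param ncols Number of grid columns (>= 1).
#' @param sequence Row of `features` to reshape (index or id; default
#'   the first).
#' @return Numeric matrix with attribute `"labels"`; flattening it
#'   row-major and dropping the padding reproduces the vector.
#' @examples
#' s <- validate_alphabet(read_fasta(">x\nACGTAC\n"), "DNA")
#' heatmap_matrix(kmer_vector(s, 2), ncols = 8)  # 2 x 8 grid
#' @export
heatmap_matrix <- function(features, ncols, sequence = 1L) {
  m <- feature_matrix(features)
  ncols <- check_count(ncols, "ncols", min = 1L)
  if (is.character(sequence)) {
    sequence <- match(sequence, rownames(m))
    if (is.na(sequence)) rlang::abort("No sequence with that id in `features`.")
  }
  sequence <- check_count(sequence, "sequence", min = 1L, max = nrow(m))
  v <- m[sequence, ]
  labs <- colnames(m)
  nrows <- ceiling(length(v) / ncols)
  pad <- nrows * ncols - length(v)
  grid <- matrix(c(v, rep(NA_real_, pad)), nrow = nrows, ncol = ncols, byrow = TRUE)
  lab_grid <- matrix(c(labs, rep(NA_character_, pad)),
    nrow = nrows, ncol = ncols, byrow = TRUE
  )
  attr(grid, "labels") <- lab_grid
  grid
}
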