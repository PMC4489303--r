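#' Residue alphabets
#'
#' Canonical residue orderings used throughout the package: `A < C < G < T`
#' for DNA, `A < C < G < U` for RNA, and the 20 standard amino acids in
#' alphabetical one-letter order for protein. All feature labels (k-mers,
#' oligomer columns of property tables) follow these orderings, so label
#' order is reproducible across runs.
#'
#' @param alphabet One of `"DNA"`, `"RNA"`, `"PROTEIN"`.
#' @return Character vector of single-letter residues in canonical order.
#' @examples
#' pse_alphabet("DNA")
#' pse_alphabet("PROTEIN")
#' @export
pse_alphabet <- function(alphabet) {
  alphabet <- match_alphabet(alphabet)
  switch(alphabet,
    DNA = c("A", "C", "G", "T"),
    RNA = c("A", "C", "G", "U"),
    PROTEIN = c(
      "A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
      "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y"
    )
  )
}

match_alphabet <- function(alphabet) {
  if (length(alphabet) != 1L || !is.character(alphabet)) {
    rlang::abort("`alphabet` must be one of \"DNA\", \"RNA\", \"PROTEIN\".")
  }
  out <- toupper(alphabet)
  if (!out %in% c("DNA", "RNA", "PROTEIN")) {
    rlang::abort(sprintf(
      "Unknown alphabet \"%s\"; must be one of \"DNA\", \"RNA\", \"PROTEIN\".",
      alphabet
    ))
  }
  out
}

#' Enumerate all oligomers of a given length
#'
#' Returns every length-`k` oligomer over an alphabet in lexicographic
#' order under the canonical residue ordering (see [pse_alphabet()]).
#'
#' @param alphabet `"DNA"`, `"RNA"` or `"PROTEIN"`.
#' @param k Positive integer oligomer length.
#' @return Character vector of length `A^k` where `A` is the alphabet size.
#' @examples
#' pse_oligomers("DNA", 2)  # AA, AC, ..., TT (16)
#' @export
pse_oligomers <- function(alphabet, k) {
  letters <- pse_alphabet(alphabet)
  k <- check_count(k, "k", min = 1L)
  # expand.grid varies the first factor fastest; feed positions in reverse so
  # the last sequence position varies fastest, i.e. lexicographic order
  grid <- expand.grid(rep(list(letters), k), stringsAsFactors = FALSE)
  do.call(paste0, rev(grid))
}

#' Reverse complement of DNA k-mers
#'
#' @param x Character vector of DNA oligomers (A/C/G/T only).
#' @return Character vector of the same length with each element reverse
#'   complemented.
#' @examples
#' reverse_complement(c("AC", "GT", "AAAT"))
#' @export
reverse_complement <- function(x) {
  comp <- chartr("ACGT", "TGCA", x)
  vapply(
    strsplit(comp, "", fixed = TRUE),
    function(ch) paste(rev(ch), collapse = ""),
    character(1)
  )
}

# -- small argument checkers ---------------------------------------------

check_count <- function(x, name, min = 0L, max = Inf) {
  if (length(x) != 1L || !is.numeric(x) || is.na(x) || x != as.integer(x)) {
    rlang::abort(sprintf("`%s` must be a single integer.", name))
  }
  x <- as.integer(x)
  if (x < min || x > max) {
    rlang::abort(sprintf(
      "`%s` must be in [%s, %s]; got %d.", name,
      format(min), format(max), x
    ))
  }
  x
}

check_number <- function(x, name, min = -Inf) {
  if (length(x) != 1L || !is.numeric(x) || is.na(x) || !is.finite(x)) {
    rlang::abort(sprintf("`%s` must be a single finite number.", name))
  }
  if (x < min) {
    rlang::abort(sprintf("`%s` must be >= %s; got %s.", name, format(min), format(x)))
  }
  as.numeric(x)
}
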