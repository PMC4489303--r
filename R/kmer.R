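#' K-mer composition vectors
#'
#' Slides a window of length `k` (step 1) along each sequence and tallies
#' the occurrence of every possible k-mer. By default the tallies are
#' normalized by the window count `L - k + 1`, so each vector is a
#' frequency distribution summing to 1; `raw_counts = TRUE` emits the raw
#' tallies instead. Labels are all `A^k` k-mers in lexicographic order
#' over the canonical alphabet ordering.
#'
#' @param seqs Sequence tibble with a declared alphabet (see
#'   [validate_alphabet()]).
#' @param k Positive integer k-mer length, at most the shortest sequence
#'   length.
#' @param raw_counts Emit raw window counts instead of frequencies.
#' @return A `pse_features` tibble, one row per sequence, `A^k` feature
#'   columns.
#' @examples
#' s <- validate_alphabet(read_fasta(">x\nACGT\n"), "DNA")
#' kmer_vector(s, 2)
#' @export
kmer_vector <- function(seqs, k, raw_counts = FALSE) {
  seqs <- check_seq_tbl(seqs)
  alphabet <- seq_alphabet(seqs)
  k <- check_count(k, "k", min = 1L)
  check_seq_lengths(seqs, min_len = k, what = sprintf("k = %d (need L >= k)", k))
  labels <- pse_oligomers(alphabet, k)
  values <- rows_vapply(
    seqs$seq,
    function(s) kmer_tally(s, k, labels, raw_counts),
    length(labels)
  )
  new_pse_features(seqs$id, values, labels,
    mode = "Kmer", alphabet = alphabet,
    params = list(k = k, raw_counts = raw_counts)
  )
}

kmer_tally <- function(s, k, labels, raw_counts) {
  L <- nchar(s)
  n_win <- L - k + 1L
  win <- substring(s, seq_len(n_win), seq_len(n_win) + k - 1L)
  counts <- tabulate(match(win, labels), nbins = length(labels))
  if (raw_counts) as.numeric(counts) else counts / n_win
}

#' Reverse complementary k-mer vectors (DNA only)
#'
#' As [kmer_vector()], but a k-mer and its reverse complement are counted
#' as one strand-independent feature. Each k-mer maps to its canonical
#' class representative, the lexicographic minimum of the k-mer and its
#' reverse complement; counts of all class members are summed and (by
#' default) divided by the total window count. The number of classes is
#' `4^k / 2` for odd `k` and `(4^k + 4^(k/2)) / 2` for even `k`.
#'
#' @inheritParams kmer_vector
#' @return A `pse_features` tibble with one column per canonical class,
#'   labelled by the class representative.
#' @examples
#' s <- validate_alphabet(read_fasta(">x\nACGT\n"), "DNA")
#' revkmer_vector(s, 2)  # 10 classes
#' @export
revkmer_vector <- function(seqs, k, raw_counts = FALSE) {
  seqs <- check_seq_tbl(seqs)
  alphabet <- seq_alphabet(seqs)
  if (alphabet != "DNA") {
    rlang::abort(sprintf(
      "RevKmer is defined for DNA only (reverse complementation); sequences are %s.",
      alphabet
    ))
  }
  k <- check_count(k, "k", min = 1L)
  check_seq_lengths(seqs, min_len = k, what = sprintf("k = %d (need L >= k)", k))

  kmers <- pse_oligomers("DNA", k)
  canon <- pmin(kmers, reverse_complement(kmers))
  classes <- sort(unique(canon))
  collapse <- match(canon, classes)

  values <- rows_vapply(seqs$seq, function(s) {
    counts <- kmer_tally(s, k, kmers, raw_counts = TRUE)
    merged <- as.numeric(rowsum(counts, collapse))
    if (raw_counts) merged else merged / (nchar(s) - k + 1L)
  }, length(classes))

  new_pse_features(seqs$id, values, classes,
    mode = "RevKmer", alphabet = "DNA",
    params = list(k = k, raw_counts = raw_counts)
  )
}

check_seq_lengths <- function(seqs, min_len, what) {
  short <- nchar(seqs$seq) < min_len
  if (any(short)) {
    rlang::abort(sprintf(
      "Sequence(s) too short for %s: %s (all sequences in a batch must satisfy the mode's length requirement).",
      what, paste(seqs$id[short], collapse = ", ")
    ))
  }
  invisible(seqs)
}
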