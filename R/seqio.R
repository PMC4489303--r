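#' Read sequences from FASTA
#'
#' Parses a multi-record FASTA file (or a literal FASTA string) into a
#' sequence tibble with one row per record, in input order. The token
#' before the first whitespace of each header is the canonical `id`; the
#' remainder of the header is kept in `description`. Residues are
#' uppercased and whitespace (including `\r`) inside sequence lines is
#' stripped. The `alphabet` column is left `NA` until
#' [validate_alphabet()] is applied.
#'
#' @param file Path to a FASTA file, or a character scalar containing
#'   FASTA-formatted text (recognised by a leading `>` or embedded
#'   newline).
#' @return A tibble with columns `id`, `description`, `seq`, `alphabet`.
#'   An empty input yields a zero-row tibble.
#' @examples
#' read_fasta(">s1 first\nACGT\n>s2\nacg\ntt\n")
#' @seealso [validate_alphabet()], [write_fasta()]
#' @export
read_fasta <- function(file) {
  if (length(file) != 1L || !is.character(file)) {
    rlang::abort("`file` must be a single path or FASTA string.")
  }
  is_literal <- grepl("^>", file) || grepl("\n", file, fixed = TRUE) || file == ""
  lines <- if (is_literal) {
    if (file == "") character(0) else strsplit(file, "\n", fixed = TRUE)[[1]]
  } else {
    if (!file.exists(file)) {
      rlang::abort(sprintf("FASTA file not found: %s", file))
    }
    readLines(file, warn = FALSE)
  }
  lines <- sub("\r$", "", lines)

  nonblank <- which(trimws(lines) != "")
  if (length(nonblank) == 0L) {
    return(empty_seq_tbl())
  }
  first <- nonblank[1]
  if (!startsWith(lines[first], ">")) {
    rlang::abort(sprintf(
      "Malformed FASTA: line %d contains sequence data before any '>' header.",
      first
    ))
  }

  # strip blank lines and intra-line whitespace, then delegate record
  # assembly (header/body grouping, line joining) to Biostrings
  keep <- lines[nonblank]
  body <- !startsWith(keep, ">")
  keep[body] <- gsub("[[:space:]]", "", keep[body])
  tmp <- tempfile(fileext = ".fasta")
  on.exit(unlink(tmp), add = TRUE)
  writeLines(keep, tmp)
  set <- Biostrings::readBStringSet(tmp)

  headers <- names(set)
  ids <- sub("[[:space:]].*$", "", headers)
  desc <- ifelse(
    grepl("[[:space:]]", headers),
    trimws(sub("^[^[:space:]]*[[:space:]]+", "", headers)),
    ""
  )
  if (any(ids == "")) {
    rlang::abort(sprintf(
      "FASTA record %d has an empty identifier.", which(ids == "")[1]
    ))
  }
  seqs <- toupper(as.character(set))
  if (any(nchar(seqs) == 0L)) {
    bad <- ids[nchar(seqs) == 0L]
    rlang::abort(sprintf(
      "FASTA record(s) with empty sequence body: %s",
      paste(bad, collapse = ", ")
    ))
  }
  tibble::tibble(
    id = unname(ids),
    description = unname(desc),
    seq = unname(seqs),
    alphabet = NA_character_
  )
}

empty_seq_tbl <- function() {
  tibble::tibble(
    id = character(0),
    description = character(0),
    seq = character(0),
    alphabet = character(0)
  )
}

#' Declare and validate the alphabet of parsed sequences
#'
#' Checks every residue of every sequence against the declared alphabet
#' and returns the tibble with the `alphabet` column set. Any residue
#' outside the alphabet — including ambiguity codes such as `N`, gap
#' characters, `U` in DNA, `T` in RNA, or `B/J/O/U/X/Z` in protein — is a
#' validation error reporting the sequence id, position and offending
#' character. Rejection (rather than skipping) is deliberate: every
#' downstream formula indexes exact oligomers, so an unresolvable
#' position would poison every window containing it.
#'
#' @param seqs Sequence tibble from [read_fasta()] (columns `id`, `seq`).
#' @param alphabet `"DNA"`, `"RNA"` or `"PROTEIN"`.
#' @return `seqs` with `alphabet` set on every row.
#' @examples
#' validate_alphabet(read_fasta(">s1\nACGT\n"), "DNA")
#' @export
validate_alphabet <- function(seqs, alphabet) {
  alphabet <- match_alphabet(alphabet)
  seqs <- check_seq_tbl(seqs, need_alphabet = FALSE)
  legal <- pse_alphabet(alphabet)
  pattern <- sprintf("[^%s]", paste(legal, collapse = ""))
  bad <- stringr::str_locate(seqs$seq, pattern)[, "start"]
  if (any(!is.na(bad))) {
    i <- which(!is.na(bad))
    msgs <- vapply(i, function(j) {
      pos <- bad[j]
      sprintf(
        "sequence '%s': illegal %s residue '%s' at position %d",
        seqs$id[j], alphabet, substr(seqs$seq[j], pos, pos), pos
      )
    }, character(1))
    rlang::abort(paste(
      c("Alphabet validation failed:", msgs), collapse = "\n  "
    ))
  }
  seqs$alphabet <- alphabet
  seqs
}

#' Write sequences to FASTA
#'
#' @param seqs Sequence tibble (columns `id`, `description`, `seq`).
#' @param file Optional path; when `NULL` the FASTA lines are returned.
#' @param width Line-wrap width for sequence bodies.
#' @return Character vector of FASTA lines (invisibly when written to a
#'   file).
#' @export
write_fasta <- function(seqs, file = NULL, width = 60L) {
  seqs <- check_seq_tbl(seqs, need_alphabet = FALSE)
  width <- check_count(width, "width", min = 1L)
  lines <- unlist(lapply(seq_len(nrow(seqs)), function(i) {
    desc <- if ("description" %in% names(seqs)) seqs$description[i] else ""
    header <- if (!is.na(desc) && nzchar(desc)) {
      paste0(">", seqs$id[i], " ", desc)
    } else {
      paste0(">", seqs$id[i])
    }
    s <- seqs$seq[i]
    starts <- seq(1L, nchar(s), by = width)
    c(header, substring(s, starts, pmin(starts + width - 1L, nchar(s))))
  }))
  if (is.null(lines)) lines <- character(0)
  if (!is.null(file)) {
    writeLines(lines, file)
    return(invisible(lines))
  }
  lines
}

# Validate the sequence-tibble contract shared by all feature functions.
check_seq_tbl <- function(seqs, need_alphabet = TRUE) {
  if (!is.data.frame(seqs) || !all(c("id", "seq") %in% names(seqs))) {
    rlang::abort("`seqs` must be a data frame with columns `id` and `seq` (see `read_fasta()`).")
  }
  seqs <- tibble::as_tibble(seqs)
  if (nrow(seqs) == 0L) {
    rlang::abort("`seqs` contains no sequences.")
  }
  if (need_alphabet) {
    if (!"alphabet" %in% names(seqs) || anyNA(seqs$alphabet)) {
      rlang::abort("Sequences have no declared alphabet; apply `validate_alphabet()` first.")
    }
    if (length(unique(seqs$alphabet)) != 1L) {
      rlang::abort("All sequences in a batch must share one alphabet.")
    }
  }
  seqs
}

seq_alphabet <- function(seqs) match_alphabet(unique(seqs$alphabet))
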