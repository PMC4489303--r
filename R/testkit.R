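#' Generate reproducible random sequences
#'
#' Draws sequences uniformly over the chosen alphabet with lengths
#' uniform on `[min_len, max_len]`, under a fixed seed: the same seed
#' always yields the same batch, and the caller's RNG state is left
#' untouched.
#'
#' @param alphabet `"DNA"`, `"RNA"` or `"PROTEIN"`.
#' @param n Number of sequences (>= 1).
#' @param min_len,max_len Inclusive length range (>= 1).
#' @param seed Integer seed.
#' @return A sequence tibble with the alphabet declared, ids
#'   `seq001, seq002, ...`.
#' @examples
#' random_sequences("DNA", 3, 10, 20, seed = 1)
#' @export
random_sequences <- function(alphabet, n, min_len = 50L, max_len = 100L,
                             seed = 1L) {
  alphabet <- match_alphabet(alphabet)
  n <- check_count(n, "n", min = 1L)
  min_len <- check_count(min_len, "min_len", min = 1L)
  max_len <- check_count(max_len, "max_len", min = min_len)
  seed <- check_count(seed, "seed")

  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)

  letters <- pse_alphabet(alphabet)
  lens <- min_len + sample.int(max_len - min_len + 1L, n, replace = TRUE) - 1L
  seqs <- vapply(lens, function(L) {
    paste(sample(letters, L, replace = TRUE), collapse = "")
  }, character(1))
  tibble::tibble(
    id = sprintf("seq%03d", seq_len(n)),
    description = "",
    seq = seqs,
    alphabet = alphabet
  )
}

#' Brute-force oracle recomputation of any mode
#'
#' Recomputes a mode's feature vectors with deliberately naive,
#' structurally independent code: its own alphabet tables, recursive
#' k-mer enumeration, dictionary tallies and explicit double loops, with
#' every normalization written out. It shares no code with the optimized
#' engines and exists purely to cross-validate them in the test suite.
#'
#' @param seqs Sequence tibble with a declared alphabet.
#' @param mode Mode name (as in [list_modes()]).
#' @param k,lag,lambda,w Mode parameters, as in [extract_features()].
#' @param props A [pse_props] table (raw values) for modes that use
#'   properties; the oracle performs its own standardization.
#' @return A `pse_features`-shaped tibble (plain tibble with `id` plus
#'   feature columns).
#' @export
oracle_features <- function(seqs, mode, k = NULL, lag = NULL, lambda = NULL,
                            w = 0.05, props = NULL) {
  stopifnot(is.data.frame(seqs), all(c("id", "seq", "alphabet") %in% names(seqs)))
  alphabet <- unique(seqs$alphabet)
  rows <- lapply(seqs$seq, function(s) {
    oracle_one(s, alphabet, mode, k, lag, lambda, w, props)
  })
  labels <- names(rows[[1]])
  m <- do.call(rbind, lapply(rows, unname))
  colnames(m) <- labels
  tibble::add_column(tibble::as_tibble(m), id = seqs$id, .before = 1)
}

# ---- everything below is intentionally naive and self-contained -------

oracle_letters <- function(alphabet) {
  if (alphabet == "DNA") {
    c("A", "C", "G", "T")
  } else if (alphabet == "RNA") {
    c("A", "C", "G", "U")
  } else {
    unlist(strsplit("ACDEFGHIKLMNPQRSTVWY", ""))
  }
}

oracle_enumerate <- function(letters, k) {
  if (k == 0) {
    return("")
  }
  shorter <- oracle_enumerate(letters, k - 1)
  out <- character(length(shorter) * length(letters))
  i <- 0
  for (s in shorter) {
    for (l in letters) {
      i <- i + 1
      out[i] <- paste0(s, l)
    }
  }
  out
}

oracle_revcomp <- function(kmer) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  chars <- unlist(strsplit(kmer, ""))
  out <- ""
  for (ch in chars) out <- paste0(comp[[ch]], out)
  out
}

oracle_windows <- function(s, g) {
  chars <- unlist(strsplit(s, ""))
  n <- length(chars) - g + 1
  out <- character(n)
  for (i in seq_len(n)) out[i] <- paste(chars[i:(i + g - 1)], collapse = "")
  out
}

# dictionary tally (hashed environment) -> frequency vector over `labels`
oracle_kmer_freq <- function(s, k, labels) {
  dict <- new.env(hash = TRUE, parent = emptyenv())
  for (lab in labels) assign(lab, 0, envir = dict)
  win <- oracle_windows(s, k)
  for (w_ in win) assign(w_, get(w_, envir = dict) + 1, envir = dict)
  out <- numeric(length(labels))
  names(out) <- labels
  for (i in seq_along(labels)) out[i] <- get(labels[i], envir = dict)
  out / length(win)
}

# z-score a raw property row over the full oligomer set, population SD
oracle_standardize <- function(v) {
  mu <- sum(v) / length(v)
  sd_pop <- sqrt(sum((v - mu)^2) / length(v))
  (v - mu) / sd_pop
}

# per-window property value lookups for each property (list of tracks)
oracle_tracks <- function(s, g, props) {
  oligos <- colnames(props$values)
  win <- oracle_windows(s, g)
  lapply(seq_len(nrow(props$values)), function(u) {
    z <- oracle_standardize(props$values[u, ])
    out <- numeric(length(win))
    for (i in seq_along(win)) out[i] <- z[[match(win[i], oligos)]]
    out
  })
}

oracle_props <- function(props) {
  m <- as.matrix(props[, setdiff(names(props), "property"), drop = FALSE])
  rownames(m) <- props$property
  list(values = m, names = props$property)
}

oracle_one <- function(s, alphabet, mode, k, lag, lambda, w, props) {
  letters <- oracle_letters(alphabet)
  if (mode == "Kmer") {
    labels <- oracle_enumerate(letters, k)
    return(oracle_kmer_freq(s, k, labels))
  }
  if (mode == "RevKmer") {
    kmers <- oracle_enumerate(letters, k)
    classes <- character(0)
    for (m_ in kmers) {
      rc <- oracle_revcomp(m_)
      canon <- if (m_ <= rc) m_ else rc
      if (!canon %in% classes) classes <- c(classes, canon)
    }
    classes <- sort(classes)
    dict <- new.env(hash = TRUE, parent = emptyenv())
    for (cl in classes) assign(cl, 0, envir = dict)
    win <- oracle_windows(s, k)
    for (w_ in win) {
      rc <- oracle_revcomp(w_)
      canon <- if (w_ <= rc) w_ else rc
      assign(canon, get(canon, envir = dict) + 1, envir = dict)
    }
    tally <- numeric(length(classes))
    names(tally) <- classes
    for (i in seq_along(classes)) tally[i] <- get(classes[i], envir = dict)
    return(tally / length(win))
  }

  p <- oracle_props(props)
  g <- nchar(colnames(p$values)[1])
  if (mode %in% c("DAC", "TAC", "AC", "DCC", "TCC", "CC", "DACC", "TACC", "ACC")) {
    tracks <- oracle_tracks(s, g, p)
    T_ <- length(tracks[[1]])
    means <- vapply(tracks, function(t_) sum(t_) / T_, numeric(1))
    auto <- numeric(0)
    for (u in seq_along(tracks)) {
      for (l in seq_len(lag)) {
        acc <- 0
        for (i in seq_len(T_ - l)) {
          acc <- acc + (tracks[[u]][i] - means[u]) * (tracks[[u]][i + l] - means[u])
        }
        auto <- c(auto, stats::setNames(acc / (T_ - l), paste0(p$names[u], ".lag", l)))
      }
    }
    cross <- numeric(0)
    for (u1 in seq_along(tracks)) {
      for (u2 in seq_along(tracks)) {
        if (u1 == u2) next
        for (l in seq_len(lag)) {
          acc <- 0
          for (i in seq_len(T_ - l)) {
            acc <- acc + (tracks[[u1]][i] - means[u1]) * (tracks[[u2]][i + l] - means[u2])
          }
          cross <- c(
            cross,
            stats::setNames(acc / (T_ - l), paste0(p$names[u1], ".", p$names[u2], ".lag", l))
          )
        }
      }
    }
    if (mode %in% c("DAC", "TAC", "AC")) {
      return(auto)
    }
    if (mode %in% c("DCC", "TCC", "CC")) {
      return(cross)
    }
    return(c(auto, cross))
  }

  # pseudo-composition family; comp tuple size and coupling per mode
  comp_k <- if (mode == "PseKNC") k else if (grepl("TNC", mode)) 3L else if (alphabet == "PROTEIN") 1L else 2L
  kind <- if (grepl("^SC-", mode)) "series" else "parallel"
  labels <- oracle_enumerate(letters, comp_k)
  f <- oracle_kmer_freq(s, comp_k, labels)
  tracks <- oracle_tracks(s, g, p)
  T_ <- length(tracks[[1]])
  corr <- numeric(0)
  if (lambda > 0) {
    if (kind == "parallel") {
      for (j in seq_len(lambda)) {
        acc <- 0
        for (i in seq_len(T_ - j)) {
          d2 <- 0
          for (u in seq_along(tracks)) {
            d2 <- d2 + (tracks[[u]][i] - tracks[[u]][i + j])^2
          }
          acc <- acc + d2 / length(tracks)
        }
        corr <- c(corr, stats::setNames(acc / (T_ - j), paste0("theta", j)))
      }
    } else {
      for (j in seq_len(lambda)) {
        for (u in seq_along(tracks)) {
          acc <- 0
          for (i in seq_len(T_ - j)) {
            acc <- acc + tracks[[u]][i] * tracks[[u]][i + j]
          }
          corr <- c(
            corr,
            stats::setNames(acc / (T_ - j), paste0("tau.lag", j, ".", p$names[u]))
          )
        }
      }
    }
  }
  phi <- sum(corr)
  denom <- 1 + w * phi
  c(f / denom, (w * corr) / denom)
}
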