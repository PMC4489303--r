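# Shared plumbing for feature tibbles.
#
# A feature result (`pse_features`) is a tibble with one row per input
# sequence: an `id` column followed by one numeric column per feature, in
# the mode's canonical label order. Mode name and parameters travel as
# attributes so downstream writers and tidiers can reproduce them.

new_pse_features <- function(ids, values, labels, mode, alphabet, params) {
  stopifnot(is.matrix(values), ncol(values) == length(labels))
  if (any(!is.finite(values))) {
    rlang::abort("Internal error: non-finite feature values produced.")
  }
  colnames(values) <- labels
  out <- tibble::add_column(tibble::as_tibble(values), id = ids, .before = 1)
  attr(out, "mode") <- mode
  attr(out, "alphabet") <- alphabet
  attr(out, "params") <- params
  class(out) <- c("pse_features", class(tibble::tibble()))
  out
}

#' @export
print.pse_features <- function(x, ...) {
  p <- attr(x, "params")
  ptxt <- if (length(p)) {
    paste(names(p), vapply(p, function(v) paste(as.character(v), collapse = ","), ""),
      sep = "=", collapse = ", "
    )
  } else {
    ""
  }
  cat(sprintf(
    "# Feature vectors: mode %s (%s), %d sequence%s x %d features%s\n",
    attr(x, "mode") %||% "?", attr(x, "alphabet") %||% "?",
    nrow(x), if (nrow(x) == 1) "" else "s", ncol(x) - 1L,
    if (nzchar(ptxt)) paste0(" [", ptxt, "]") else ""
  ))
  NextMethod()
}

#' Feature labels of a feature-vector tibble
#'
#' @param x A `pse_features` tibble.
#' @return Character vector of feature names (all columns except `id`).
#' @export
feature_labels <- function(x) {
  setdiff(names(x), "id")
}

#' Feature values as a numeric matrix
#'
#' @param x A `pse_features` tibble.
#' @return Numeric matrix, sequences in rows (rownames = ids), features
#'   in columns.
#' @export
feature_matrix <- function(x) {
  if (!is.data.frame(x) || !"id" %in% names(x)) {
    rlang::abort("`x` must be a feature tibble with an `id` column.")
  }
  m <- as.matrix(x[, setdiff(names(x), "id"), drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- x$id
  m
}

# Resolve props for the correlation/pseudo engines: validate table,
# standardize unless already done (or unless the caller opts out).
resolve_props <- function(props, alphabet, standardize = TRUE) {
  props <- check_props(props, alphabet = alphabet)
  if (standardize && !isTRUE(attr(props, "normalized"))) {
    props <- normalize_index(props)
  }
  props
}

# vapply over sequences returning one row per element, robust to the
# single-feature case (where vapply yields a plain vector).
rows_vapply <- function(x, f, n_out) {
  if (n_out == 0L) {
    return(matrix(0, nrow = length(x), ncol = 0L))
  }
  m <- vapply(x, f, numeric(n_out))
  if (n_out == 1L) matrix(m, ncol = 1L) else t(m)
}

# Per-sequence property track: values of each selected property at each
# length-g window. Returns T x n_props matrix.
property_track <- function(s, pm, g, oligos) {
  L <- nchar(s)
  T_ <- L - g + 1L
  win <- substring(s, seq_len(T_), seq_len(T_) + g - 1L)
  idx <- match(win, oligos)
  t(pm[, idx, drop = FALSE])
}
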