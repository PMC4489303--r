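# Mode registry: binds the 28 published mode names to engine
# configurations. Each entry records the alphabet, category, engine,
# fixed configuration (composition tuple size, correlation oligomer
# length, coupling kind, default properties) and the parameter schema.

registry_entries <- function() {
  entry <- function(mode, alphabet, category, engine,
                    comp_k = NULL, corr_g = NULL, kind = NULL,
                    props_g = NULL, default_props = NULL,
                    needs_k = FALSE, needs_lag = FALSE,
                    needs_lambda = FALSE, uses_w = FALSE,
                    dim_fn, dim_text) {
    list(
      mode = mode, alphabet = alphabet, category = category, engine = engine,
      comp_k = comp_k, corr_g = corr_g, kind = kind, props_g = props_g,
      default_props = default_props, needs_k = needs_k, needs_lag = needs_lag,
      needs_lambda = needs_lambda, uses_w = uses_w,
      dim_fn = dim_fn, dim_text = dim_text
    )
  }
  rc_classes <- function(k) if (k %% 2 == 1) 4^k / 2 else (4^k + 4^(k / 2)) / 2

  kmer_modes <- lapply(c("DNA", "RNA", "PROTEIN"), function(a) {
    A <- length(pse_alphabet(a))
    entry("Kmer", a, "composition", "kmer",
      needs_k = TRUE,
      dim_fn = function(k, lag, lambda, np) A^k, dim_text = sprintf("%d^k", A)
    )
  })
  autocorr_mode <- function(mode, alphabet, engine, g) {
    dim_fn <- switch(engine,
      ac = function(k, lag, lambda, np) np * lag,
      cc = function(k, lag, lambda, np) np * (np - 1) * lag,
      acc = function(k, lag, lambda, np) np^2 * lag
    )
    dim_text <- switch(engine,
      ac = "n_props * lag", cc = "n_props * (n_props - 1) * lag",
      acc = "n_props^2 * lag"
    )
    entry(mode, alphabet, "autocorrelation", engine,
      props_g = g, needs_lag = TRUE, dim_fn = dim_fn, dim_text = dim_text
    )
  }
  pseudo_mode <- function(mode, alphabet, kind, comp_k, corr_g,
                          default_props, needs_k = FALSE) {
    A <- length(pse_alphabet(alphabet))
    if (kind == "parallel") {
      dim_fn <- function(k, lag, lambda, np) A^k + lambda
      dim_text <- sprintf("%d^k + lambda", A)
    } else {
      dim_fn <- function(k, lag, lambda, np) A^k + lambda * np
      dim_text <- sprintf("%d^k + lambda * n_props", A)
    }
    entry(mode, alphabet, "pseudo", "pseudo",
      comp_k = comp_k, corr_g = corr_g, kind = kind, props_g = corr_g,
      default_props = default_props, needs_k = needs_k,
      needs_lambda = TRUE, uses_w = TRUE,
      dim_fn = dim_fn, dim_text = dim_text
    )
  }

  dna6 <- default_prop_names("DNA", 2)
  rna6 <- default_prop_names("RNA", 2)
  tri2 <- default_prop_names("DNA", 3)
  aac3 <- default_prop_names("PROTEIN", 1, "parallel")
  aac2 <- default_prop_names("PROTEIN", 1, "series")

  c(
    # ---- DNA (14)
    kmer_modes[1],
    list(entry("RevKmer", "DNA", "composition", "revkmer",
      needs_k = TRUE,
      dim_fn = function(k, lag, lambda, np) rc_classes(k),
      dim_text = "4^k/2 (odd k); (4^k + 4^(k/2))/2 (even k)"
    )),
    list(
      autocorr_mode("DAC", "DNA", "ac", 2L),
      autocorr_mode("DCC", "DNA", "cc", 2L),
      autocorr_mode("DACC", "DNA", "acc", 2L),
      autocorr_mode("TAC", "DNA", "ac", 3L),
      autocorr_mode("TCC", "DNA", "cc", 3L),
      autocorr_mode("TACC", "DNA", "acc", 3L),
      pseudo_mode("PseDNC", "DNA", "parallel", 2L, 2L, dna6),
      pseudo_mode("PseKNC", "DNA", "parallel", NULL, 2L, dna6, needs_k = TRUE),
      pseudo_mode("PC-PseDNC-General", "DNA", "parallel", 2L, 2L, dna6),
      pseudo_mode("PC-PseTNC-General", "DNA", "parallel", 3L, 3L, tri2),
      pseudo_mode("SC-PseDNC-General", "DNA", "series", 2L, 2L, dna6),
      pseudo_mode("SC-PseTNC-General", "DNA", "series", 3L, 3L, tri2)
    ),
    # ---- RNA (6)
    kmer_modes[2],
    list(
      autocorr_mode("DAC", "RNA", "ac", 2L),
      autocorr_mode("DCC", "RNA", "cc", 2L),
      autocorr_mode("DACC", "RNA", "acc", 2L),
      pseudo_mode("PC-PseDNC-General", "RNA", "parallel", 2L, 2L, rna6),
      pseudo_mode("SC-PseDNC-General", "RNA", "series", 2L, 2L, rna6)
    ),
    # ---- protein (8)
    kmer_modes[3],
    list(
      autocorr_mode("AC", "PROTEIN", "ac", 1L),
      autocorr_mode("CC", "PROTEIN", "cc", 1L),
      autocorr_mode("ACC", "PROTEIN", "acc", 1L),
      pseudo_mode("PC-PseAAC", "PROTEIN", "parallel", 1L, 1L, aac3),
      pseudo_mode("SC-PseAAC", "PROTEIN", "series", 1L, 1L, aac2),
      pseudo_mode("PC-PseAAC-General", "PROTEIN", "parallel", 1L, 1L, aac3),
      pseudo_mode("SC-PseAAC-General", "PROTEIN", "series", 1L, 1L, aac2)
    )
  )
}

.registry_cache <- new.env(parent = emptyenv())

registry <- function() {
  if (is.null(.registry_cache$entries)) {
    .registry_cache$entries <- registry_entries()
  }
  .registry_cache$entries
}

registry_lookup <- function(mode, alphabet) {
  entries <- registry()
  for (e in entries) {
    if (identical(e$mode, mode) && identical(e$alphabet, alphabet)) {
      return(e)
    }
  }
  valid <- vapply(
    Filter(function(e) e$alphabet == alphabet, entries),
    `[[`, "", "mode"
  )
  rlang::abort(sprintf(
    "Unknown mode \"%s\" for %s sequences. Valid modes: %s.",
    mode, alphabet, paste(valid, collapse = ", ")
  ))
}

# Web-server parameter caps on k, used as defaults (override with
# `allow_large_k` for the uncapped stand-alone behaviour).
k_cap <- function(alphabet) if (alphabet == "PROTEIN") 3L else 6L

#' List the available feature modes
#'
#' The registry exposes 28 modes: 14 for DNA, 6 for RNA and 8 for
#' protein sequences, spanning three categories (composition,
#' autocorrelation, pseudo composition).
#'
#' @param alphabet Optional filter: `"DNA"`, `"RNA"` or `"PROTEIN"`.
#' @return A tibble with columns `mode`, `alphabet`, `category`,
#'   `parameters` (the parameter schema in words), `dimension` (the
#'   dimension formula) and `default_properties` (list column; `NULL`
#'   where explicit selection is required).
#' @examples
#' nrow(list_modes())        # 28
#' nrow(list_modes("DNA"))   # 14
#' @export
list_modes <- function(alphabet = NULL) {
  entries <- registry()
  if (!is.null(alphabet)) {
    alphabet <- match_alphabet(alphabet)
    entries <- Filter(function(e) e$alphabet == alphabet, entries)
  }
  tibble::tibble(
    mode = vapply(entries, `[[`, "", "mode"),
    alphabet = vapply(entries, `[[`, "", "alphabet"),
    category = vapply(entries, `[[`, "", "category"),
    parameters = vapply(entries, function(e) {
      parts <- c(
        if (e$needs_k) sprintf("k (1..%d)", k_cap(e$alphabet)),
        if (e$needs_lag) "lag (>= 1)",
        if (e$needs_lambda) "lambda (>= 0)",
        if (e$uses_w) "w (>= 0, default 0.05)",
        if (!is.null(e$props_g)) "properties"
      )
      paste(parts, collapse = ", ")
    }, ""),
    dimension = vapply(entries, `[[`, "", "dim_text"),
    default_properties = lapply(entries, `[[`, "default_props")
  )
}

#' Compute feature vectors for a registered mode
#'
#' The single entry point over all 28 modes: validates the parameters
#' against the mode's schema, resolves built-in or user-defined
#' properties, checks every sequence against the mode's length
#' requirements (all-or-nothing: no sequence is silently dropped) and
#' dispatches to the engine. Identical inputs give bitwise-identical
#' outputs.
#'
#' @param seqs Sequence tibble with a declared alphabet matching the
#'   mode.
#' @param mode Mode name as published, e.g. `"Kmer"`, `"RevKmer"`,
#'   `"DAC"`, `"TACC"`, `"PseDNC"`, `"PseKNC"`, `"PC-PseDNC-General"`,
#'   `"SC-PseAAC"` (see [list_modes()]).
#' @param k K-mer / composition tuple size, where the mode takes one.
#'   Capped at 6 (nucleic) or 3 (protein) unless `allow_large_k`.
#' @param lag Maximum correlation distance (autocorrelation modes).
#' @param lambda Number of pseudo-component tiers (pseudo modes; no
#'   silent default since legality depends on sequence length).
#' @param w Pseudo-component mixing weight (default 0.05).
#' @param props Property selection for autocorrelation/pseudo modes:
#'   a character vector of built-in property names, or a [pse_props]
#'   table. Pseudo modes fall back to their documented defaults;
#'   autocorrelation modes require an explicit selection.
#' @param props_file Path to a user-defined index file (see
#'   [parse_user_index()]); overrides `props`.
#' @param raw_counts Composition modes: emit raw window counts instead
#'   of frequencies.
#' @param standardize Standardize raw property values before use.
#' @param allow_large_k Lift the web-form cap on `k` (stand-alone
#'   behaviour).
#' @return A `pse_features` tibble, one row per sequence; all rows share
#'   the mode's dimension and labels.
#' @examples
#' s <- validate_alphabet(read_fasta(">x\nACGTACGTACGTACGT\n"), "DNA")
#' extract_features(s, "PseDNC", lambda = 10, w = 0.05)  # 26 features
#' @export
extract_features <- function(seqs, mode, k = NULL, lag = NULL, lambda = NULL,
                             w = NULL, props = NULL, props_file = NULL,
                             raw_counts = FALSE, standardize = TRUE,
                             allow_large_k = FALSE) {
  seqs <- check_seq_tbl(seqs)
  alphabet <- seq_alphabet(seqs)
  if (length(mode) != 1L || !is.character(mode)) {
    rlang::abort("`mode` must be a single mode name; see `list_modes()`.")
  }
  e <- registry_lookup(mode, alphabet)

  if (e$needs_k) {
    if (is.null(k)) {
      rlang::abort(sprintf("Mode %s requires `k`.", mode))
    }
    cap <- if (allow_large_k) .Machine$integer.max else k_cap(alphabet)
    k <- check_count(k, "k", min = 1L, max = cap)
  }
  if (e$needs_lag) {
    if (is.null(lag)) {
      rlang::abort(sprintf("Mode %s requires `lag`.", mode))
    }
    lag <- check_count(lag, "lag", min = 1L)
  }
  if (e$needs_lambda) {
    if (is.null(lambda)) {
      rlang::abort(sprintf(
        "Mode %s requires `lambda` (its legal range depends on sequence length, so there is no silent default).",
        mode
      ))
    }
    lambda <- check_count(lambda, "lambda", min = 0L)
  }
  w <- if (e$uses_w) check_number(w %||% 0.05, "w", min = 0) else NULL

  resolved_props <- if (!is.null(e$props_g)) {
    resolve_mode_props(e, alphabet, props, props_file)
  } else {
    NULL
  }

  out <- switch(e$engine,
    kmer = kmer_vector(seqs, k, raw_counts = raw_counts),
    revkmer = revkmer_vector(seqs, k, raw_counts = raw_counts),
    ac = auto_covariance(seqs, resolved_props, lag, standardize),
    cc = cross_covariance(seqs, resolved_props, lag, standardize),
    acc = auto_cross_covariance(seqs, resolved_props, lag, standardize),
    pseudo = pseudo_composition(seqs, resolved_props,
      k = e$comp_k %||% k, lambda = lambda, w = w,
      kind = e$kind, standardize = standardize, mode_name = mode
    )
  )
  attr(out, "mode") <- mode
  out
}

resolve_mode_props <- function(e, alphabet, props, props_file) {
  if (!is.null(props_file)) {
    return(parse_user_index(props_file, alphabet, e$props_g))
  }
  if (inherits(props, "pse_props") || is.data.frame(props)) {
    p <- check_props(props, alphabet = alphabet)
    if (attr(p, "oligo_len") != e$props_g) {
      rlang::abort(sprintf(
        "Mode %s correlates length-%d oligomers but `props` has oligomer length %d.",
        e$mode, e$props_g, attr(p, "oligo_len")
      ))
    }
    return(p)
  }
  if (is.character(props)) {
    return(select_props(load_builtin(alphabet, e$props_g), props))
  }
  if (!is.null(props)) {
    rlang::abort("`props` must be a character vector of property names or a property table.")
  }
  if (is.null(e$default_props)) {
    rlang::abort(sprintf(
      "Mode %s has no canonical default property set; select properties explicitly via `props` or `props_file` (see `load_builtin()`).",
      e$mode
    ))
  }
  select_props(load_builtin(alphabet, e$props_g), e$default_props)
}
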