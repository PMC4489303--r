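#' Parallel-correlation factors (theta)
#'
#' Computes the sequence-order correlation tiers of the
#' parallel-correlation pseudo compositions (PseDNC, PseKNC, PC-PseAAC
#' and the PC-\*-General modes). The coupling factor between two windows
#' `i` and `j` averages the squared property differences over the
#' selected properties,
#' `Theta(i, j) = (1/n_props) * sum_u (P_u(i) - P_u(j))^2`,
#' and tier `j` is its mean over all windows `lag = j` apart:
#' `theta_j = sum_{i=1}^{T-j} Theta(i, i+j) / (T - j)`, for
#' `j = 1..lambda`. All theta are non-negative.
#'
#' @param seqs Sequence tibble with a declared alphabet.
#' @param props A [pse_props] table; its oligomer length sets the window
#'   length `g` of the correlation track.
#' @param lambda Number of correlation tiers, `1 <= lambda <= T - 1`
#'   (`T = L - g + 1`) for every sequence. `lambda = 0` is allowed and
#'   yields zero columns.
#' @param standardize Standardize raw property tables first (default).
#' @return A tibble with one row per sequence: `id` plus columns
#'   `theta1..theta<lambda>`; attribute `kind = "parallel"`.
#' @examples
#' s <- validate_alphabet(read_fasta(">x\nACGTACGT\n"), "DNA")
#' parallel_theta(s, load_builtin("DNA", 2)[1:6, ], lambda = 3)
#' @export
parallel_theta <- function(seqs, props, lambda, standardize = TRUE) {
  ctx <- pseudo_corr_context(seqs, props, lambda)
  props <- resolve_props(props, ctx$alphabet, standardize)
  pm <- prop_matrix(props)
  oligos <- pse_oligomers(ctx$alphabet, ctx$g)
  labels <- if (ctx$lambda > 0) paste0("theta", seq_len(ctx$lambda)) else character(0)
  values <- rows_vapply(seqs$seq, function(s) {
    tr <- property_track(s, pm, ctx$g, oligos)
    vapply(seq_len(ctx$lambda), function(j) {
      T_ <- nrow(tr)
      d <- tr[seq_len(T_ - j), , drop = FALSE] - tr[seq_len(T_ - j) + j, , drop = FALSE]
      mean(rowMeans(d^2))
    }, numeric(1))
  }, ctx$lambda)
  profile_tbl(seqs$id, values, labels, "parallel", ctx, props$property)
}

#' Series-correlation factors (tau)
#'
#' Computes the correlation tiers of the series-correlation pseudo
#' compositions (SC-PseAAC and the SC-\*-General modes). Unlike the
#' parallel form, each property contributes its own tier per lag via the
#' property-product coupling:
#' `tau_{(j-1)*n_props + u} = sum_{i=1}^{T-j} P_u(i) * P_u(i+j) / (T - j)`
#' for lag `j = 1..lambda` and property `u = 1..n_props`, ordered
#' lag-major, property-minor.
#'
#' @inheritParams parallel_theta
#' @return A tibble with `lambda * n_props` value columns labelled
#'   `tau.lag<j>.<property>`; attribute `kind = "series"`.
#' @export
series_tau <- function(seqs, props, lambda, standardize = TRUE) {
  ctx <- pseudo_corr_context(seqs, props, lambda)
  props <- resolve_props(props, ctx$alphabet, standardize)
  pm <- prop_matrix(props)
  oligos <- pse_oligomers(ctx$alphabet, ctx$g)
  labels <- unlist(lapply(seq_len(ctx$lambda), function(j) {
    paste0("tau.lag", j, ".", props$property)
  }))
  if (is.null(labels)) labels <- character(0)
  values <- rows_vapply(seqs$seq, function(s) {
    tr <- property_track(s, pm, ctx$g, oligos)
    unlist(lapply(seq_len(ctx$lambda), function(j) {
      T_ <- nrow(tr)
      colSums(
        tr[seq_len(T_ - j), , drop = FALSE] * tr[seq_len(T_ - j) + j, , drop = FALSE]
      ) / (T_ - j)
    }))
  }, length(labels))
  profile_tbl(seqs$id, values, labels, "series", ctx, props$property)
}

profile_tbl <- function(ids, values, labels, kind, ctx, prop_names) {
  colnames(values) <- labels
  out <- tibble::add_column(tibble::as_tibble(values), id = ids, .before = 1)
  attr(out, "kind") <- kind
  attr(out, "lambda") <- ctx$lambda
  attr(out, "g") <- ctx$g
  attr(out, "properties") <- prop_names
  class(out) <- c("pse_profile", class(tibble::tibble()))
  out
}

pseudo_corr_context <- function(seqs, props, lambda) {
  seqs <- check_seq_tbl(seqs)
  alphabet <- seq_alphabet(seqs)
  props <- check_props(props, alphabet = alphabet)
  lambda <- check_count(lambda, "lambda", min = 0L)
  g <- attr(props, "oligo_len")
  if (lambda > 0) {
    Ls <- nchar(seqs$seq)
    max_legal <- Ls - g # lambda <= T - 1
    short <- lambda > max_legal
    if (any(short)) {
      rlang::abort(sprintf(
        "lambda = %d exceeds the maximum legal value for sequence(s): %s.",
        lambda,
        paste(sprintf("'%s' (max lambda = %d)", seqs$id[short], max_legal[short]),
          collapse = ", "
        )
      ))
    }
  }
  list(alphabet = alphabet, g = g, lambda = lambda)
}

#' Pseudo-component composition vectors
#'
#' The general engine behind all ten pseudo-composition modes. A
#' k-tuple composition vector `f` (normalized to sum 1) is blended with
#' `lambda` sequence-order correlation tiers `c_1..c_m` (theta for
#' parallel correlation, tau for series correlation; `m = lambda` or
#' `lambda * n_props`) through the mixing weight `w`:
#' \deqn{d_u = f_u / (1 + w \Phi), \quad u \le A^k}
#' \deqn{d_{A^k + v} = w c_v / (1 + w \Phi), \quad v = 1..m}
#' where `Phi = sum_v c_v`. Every vector sums to 1; the pseudo components
#' carry total mass `w * Phi / (1 + w * Phi)`, which is strictly
#' increasing in `w` whenever `Phi > 0`.
#'
#' The oligomer length of the correlation track (`corr_g`) defaults to
#' the property table's oligomer length and is independent of the
#' composition tuple size `k`: PseKNC, for instance, counts k-tuples but
#' correlates dinucleotides.
#'
#' @inheritParams parallel_theta
#' @param k Composition tuple size (`A^k` composition components).
#' @param lambda Number of correlation tiers (`lambda = 0` gives the
#'   bare composition vector).
#' @param w Non-negative mixing weight (default 0.05, the value used by
#'   both published worked examples).
#' @param kind `"parallel"` (squared-difference coupling, one theta per
#'   tier) or `"series"` (property-product coupling, one tau per tier
#'   and property).
#' @param mode_name Label stored on the result (defaults to a generic
#'   name; the mode registry passes the published mode names).
#' @return A `pse_features` tibble with `A^k + lambda` (parallel) or
#'   `A^k + lambda * n_props` (series) columns.
#' @examples
#' s <- validate_alphabet(read_fasta(">x\nACGTACGTACGTACGT\n"), "DNA")
#' p <- select_props(load_builtin("DNA", 2),
#'                   c("Twist", "Tilt", "Roll", "Shift", "Slide", "Rise"))
#' v <- pseudo_composition(s, p, k = 2, lambda = 10, w = 0.05)
#' ncol(v) - 1  # 26
#' @export
pseudo_composition <- function(seqs, props, k, lambda, w = 0.05,
                               kind = c("parallel", "series"),
                               standardize = TRUE, mode_name = NULL) {
  kind <- match.arg(kind)
  seqs <- check_seq_tbl(seqs)
  alphabet <- seq_alphabet(seqs)
  k <- check_count(k, "k", min = 1L)
  w <- check_number(w, "w", min = 0)

  comp <- kmer_vector(seqs, k)
  profile <- if (kind == "parallel") {
    parallel_theta(seqs, props, lambda, standardize)
  } else {
    series_tau(seqs, props, lambda, standardize)
  }
  cm <- as.matrix(profile[, setdiff(names(profile), "id"), drop = FALSE])
  fm <- feature_matrix(comp)

  phi <- rowSums(cm)
  denom <- 1 + w * phi
  values <- cbind(fm / denom, (w * cm) / denom)
  labels <- c(feature_labels(comp), colnames(cm))

  new_pse_features(seqs$id, values, labels,
    mode = mode_name %||% paste0("Pse-", kind),
    alphabet = alphabet,
    params = list(
      k = k, lambda = attr(profile, "lambda"), w = w, kind = kind,
      corr_g = attr(profile, "g"), properties = attr(profile, "properties")
    )
  )
}
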