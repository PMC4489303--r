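#' Autocovariance features
#'
#' One engine, parameterized by the oligomer length of the property
#' table, implements all nine published autocorrelation modes: with
#' dinucleotide properties on DNA/RNA it is DAC, with trinucleotide
#' properties TAC, with amino-acid properties AC (and likewise for the
#' cross- and combined variants).
#'
#' For each selected property `u` the sequence is turned into a track
#' `P_u(1..T)` of standardized property values at each length-`g` window
#' (`T = L - g + 1`). The autocovariance at lag `l` is
#' `AC(u, l) = sum_{i=1}^{T-l} (P_u(i) - m_u) (P_u(i+l) - m_u) / (T - l)`
#' where `m_u` is the mean of the sequence's own track and the
#' denominator is the number of summed pairs `T - l` (not `T - l - 1`);
#' the literature varies, so the convention is fixed here and documented.
#' Features are ordered property-major, lag-minor.
#'
#' @param seqs Sequence tibble with a declared alphabet.
#' @param props A [pse_props] table whose alphabet matches `seqs`; its
#'   oligomer length sets `g`. Raw tables are standardized first (see
#'   `standardize`).
#' @param lag_max Largest lag, at least 1 and at most `T - 1` for every
#'   sequence.
#' @param standardize Standardize `props` to zero mean / unit variance
#'   before use (default). Tables already standardized are left as-is.
#' @return A `pse_features` tibble with `n_props * lag_max` columns.
#' @examples
#' s <- validate_alphabet(read_fasta(">x\nACGTACGT\n"), "DNA")
#' p <- select_props(load_builtin("DNA", 2), c("Twist", "Roll"))
#' auto_covariance(s, p, lag_max = 3)
#' @export
auto_covariance <- function(seqs, props, lag_max, standardize = TRUE) {
  ctx <- covariance_context(seqs, props, lag_max, standardize, min_props = 1L)
  labels <- as.vector(vapply(
    ctx$prop_names,
    function(u) paste0(u, ".lag", seq_len(ctx$lag_max)),
    character(ctx$lag_max)
  ))
  values <- rows_vapply(seqs$seq, function(s) {
    tr <- property_track(s, ctx$pm, ctx$g, ctx$oligos)
    dev <- sweep(tr, 2, colMeans(tr))
    unlist(lapply(seq_len(ncol(dev)), function(u) {
      vapply(seq_len(ctx$lag_max), function(l) {
        lagged_mean_product(dev[, u], dev[, u], l)
      }, numeric(1))
    }))
  }, length(labels))
  new_pse_features(seqs$id, values, labels,
    mode = "AC", alphabet = ctx$alphabet,
    params = list(lag = ctx$lag_max, properties = ctx$prop_names, g = ctx$g)
  )
}

#' Cross-covariance features
#'
#' Same track construction as [auto_covariance()], but correlating two
#' *different* properties: for each ordered pair `(u1, u2)`, `u1 != u2`,
#' `CC(u1, u2, l) = sum_{i=1}^{T-l} (P_u1(i) - m_u1) (P_u2(i+l) - m_u2) / (T - l)`.
#' Pairs are enumerated property-major in input order with lag innermost;
#' the dimension is `n_props * (n_props - 1) * lag_max`.
#'
#' @inheritParams auto_covariance
#' @return A `pse_features` tibble.
#' @export
cross_covariance <- function(seqs, props, lag_max, standardize = TRUE) {
  ctx <- covariance_context(seqs, props, lag_max, standardize, min_props = 2L)
  pairs <- ordered_pairs(ctx$prop_names)
  labels <- unlist(lapply(seq_len(nrow(pairs)), function(p) {
    paste0(pairs$u1[p], ".", pairs$u2[p], ".lag", seq_len(ctx$lag_max))
  }))
  values <- rows_vapply(seqs$seq, function(s) {
    tr <- property_track(s, ctx$pm, ctx$g, ctx$oligos)
    dev <- sweep(tr, 2, colMeans(tr))
    unlist(lapply(seq_len(nrow(pairs)), function(p) {
      vapply(seq_len(ctx$lag_max), function(l) {
        lagged_mean_product(dev[, pairs$i1[p]], dev[, pairs$i2[p]], l)
      }, numeric(1))
    }))
  }, length(labels))
  new_pse_features(seqs$id, values, labels,
    mode = "CC", alphabet = ctx$alphabet,
    params = list(lag = ctx$lag_max, properties = ctx$prop_names, g = ctx$g)
  )
}

#' Combined auto- and cross-covariance features
#'
#' Concatenation of [auto_covariance()] then [cross_covariance()] on the
#' same inputs; dimension `n_props^2 * lag_max`.
#'
#' @inheritParams cross_covariance
#' @return A `pse_features` tibble.
#' @export
auto_cross_covariance <- function(seqs, props, lag_max, standardize = TRUE) {
  ac <- auto_covariance(seqs, props, lag_max, standardize)
  cc <- cross_covariance(seqs, props, lag_max, standardize)
  values <- cbind(feature_matrix(ac), feature_matrix(cc))
  new_pse_features(ac$id, values, c(feature_labels(ac), feature_labels(cc)),
    mode = "ACC", alphabet = attr(ac, "alphabet"),
    params = attr(ac, "params")
  )
}

# mean over summed pairs: sum(x[i] * y[i + l]) / (n - l)
lagged_mean_product <- function(x, y, l) {
  n <- length(x)
  sum(x[seq_len(n - l)] * y[seq_len(n - l) + l]) / (n - l)
}

ordered_pairs <- function(nm) {
  n <- length(nm)
  grid <- expand.grid(i2 = seq_len(n), i1 = seq_len(n))[, c("i1", "i2")]
  grid <- grid[grid$i1 != grid$i2, , drop = FALSE]
  data.frame(
    i1 = grid$i1, i2 = grid$i2,
    u1 = nm[grid$i1], u2 = nm[grid$i2],
    stringsAsFactors = FALSE
  )
}

covariance_context <- function(seqs, props, lag_max, standardize, min_props) {
  seqs <- check_seq_tbl(seqs)
  alphabet <- seq_alphabet(seqs)
  props <- resolve_props(props, alphabet, standardize)
  if (nrow(props) < min_props) {
    rlang::abort(sprintf(
      "At least %d propert%s required (cross covariance correlates distinct properties).",
      min_props, if (min_props == 1) "y is" else "ies are"
    ))
  }
  lag_max <- check_count(lag_max, "lag_max", min = 1L)
  g <- attr(props, "oligo_len")
  # need at least one pair at the largest lag: lag_max <= T - 1 = L - g
  check_seq_lengths(seqs,
    min_len = g + lag_max,
    what = sprintf("lag_max = %d with length-%d oligomers (need L >= g + lag_max)", lag_max, g)
  )
  list(
    alphabet = alphabet, g = g, lag_max = lag_max,
    pm = prop_matrix(props), prop_names = props$property,
    oligos = pse_oligomers(alphabet, g)
  )
}
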