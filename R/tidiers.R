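#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a feature-vector tibble into long form
#'
#' @param x A `pse_features` tibble.
#' @param ... Unused.
#' @return A long tibble with columns `id`, `index` (1-based feature
#'   position), `feature` and `value`.
#' @examples
#' s <- validate_alphabet(read_fasta(">x\nACGT\n"), "DNA")
#' tidy(kmer_vector(s, 1))
#' @method tidy pse_features
#' @export
tidy.pse_features <- function(x, ...) {
  labs <- feature_labels(x)
  out <- tidyr::pivot_longer(
    tibble::as_tibble(x),
    cols = -"id", names_to = "feature", values_to = "value"
  )
  out$index <- match(out$feature, labs)
  dplyr::select(out, "id", "index", "feature", "value")
}

#' One-row summary of a feature computation
#'
#' @param x A `pse_features` tibble.
#' @param ... Unused.
#' @return A one-row tibble: `mode`, `alphabet`, `n_sequences`,
#'   `dimension`, and the parameter values used (`k`, `lag`, `lambda`,
#'   `w`, `n_properties`; `NA` where not applicable).
#' @method glance pse_features
#' @export
glance.pse_features <- function(x, ...) {
  p <- attr(x, "params") %||% list()
  tibble::tibble(
    mode = attr(x, "mode") %||% NA_character_,
    alphabet = attr(x, "alphabet") %||% NA_character_,
    n_sequences = nrow(x),
    dimension = ncol(x) - 1L,
    k = p$k %||% NA_integer_,
    lag = p$lag %||% NA_integer_,
    lambda = p$lambda %||% NA_integer_,
    w = p$w %||% NA_real_,
    n_properties = if (is.null(p$properties)) NA_integer_ else length(p$properties)
  )
}

#' Heat-map style plot of feature vectors
#'
#' A ggplot2 tile view of one sequence's feature vector laid out
#' row-major (the same grid as [heatmap_matrix()]): column index on the
#' horizontal axis, row index on the vertical axis, value as fill.
#'
#' @param object A `pse_features` tibble.
#' @param ncols Grid width; defaults to `ceiling(sqrt(dimension))`.
#' @param sequence Which sequence to plot (index or id).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot pse_features
#' @export
autoplot.pse_features <- function(object, ncols = NULL, sequence = 1L, ...) {
  dim_ <- ncol(object) - 1L
  if (is.null(ncols)) ncols <- max(1L, ceiling(sqrt(dim_)))
  grid <- heatmap_matrix(object, ncols = ncols, sequence = sequence)
  labs <- attr(grid, "labels")
  df <- tibble::tibble(
    row = as.vector(row(grid)),
    col = as.vector(col(grid)),
    value = as.vector(grid),
    feature = as.vector(labs)
  )
  df <- df[!is.na(df$value), , drop = FALSE]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row, fill = .data$value)) +
    ggplot2::geom_tile(colour = "grey85") +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(
      x = "column index", y = "row index", fill = "value",
      title = sprintf(
        "%s feature vector (%d features)",
        attr(object, "mode") %||% "feature", dim_
      )
    ) +
    ggplot2::theme_minimal()
}

#' @importFrom rlang .data
NULL
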