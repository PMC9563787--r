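#' Plot a decoded block
#'
#' Tile view of the `q x q` block after decoding: full calls show their
#' genotype, half-calls the known allele, and indeterminate cells are marked
#' missing — the block-level picture of what pooling reveals at one marker.
#'
#' @param object A `decoded_block`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.decoded_block <- function(object, ...) {
  df <- tidy(object)
  df$label <- dplyr::case_when(
    df$status == "full" ~ as.character(df$gt),
    df$status == "half_alt" ~ "./m",
    df$status == "half_ref" ~ "M/.",
    TRUE ~ "./."
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col_pool, y = .data$row_pool,
                                   fill = .data$status)) +
    ggplot2::geom_tile(colour = "grey30") +
    ggplot2::geom_text(ggplot2::aes(label = .data$label)) +
    ggplot2::scale_y_reverse(breaks = seq_len(object$q)) +
    ggplot2::scale_x_continuous(breaks = seq_len(object$q), position = "top") +
    ggplot2::labs(x = "column pool", y = "row pool", fill = NULL) +
    ggplot2::theme_minimal()
}

#' Plot decoding status proportions per MAF bin
#'
#' Stacked proportions of fully decoded, half-called and missing genotypes
#' across MAF bins for a pooled scenario — the pooled-data counterpart of a
#' missingness profile, showing the negative relationship between MAF and
#' decodability.
#'
#' @param bundle A pooled `scenario_bundle`.
#' @param boundaries MAF bin boundaries.
#' @return A ggplot object.
#' @export
plot_decoding_by_maf <- function(bundle,
                                 boundaries = c(0, 0.02, 0.04, 0.06, 0.1, 0.2, 0.4, 0.5)) {
  stopifnot(inherits(bundle, "scenario_bundle"), bundle$scenario == "pooled")
  df <- bundle$manifest |>
    dplyr::left_join(bundle$pop$markers[, c("marker_id", "maf_study")], by = "marker_id") |>
    dplyr::mutate(bin = cut(.data$maf_study, breaks = boundaries, include.lowest = TRUE)) |>
    dplyr::count(.data$bin, .data$status) |>
    dplyr::group_by(.data$bin) |>
    dplyr::mutate(prop = .data$n / sum(.data$n)) |>
    dplyr::ungroup()
  ggplot2::ggplot(df, ggplot2::aes(x = .data$bin, y = .data$prop, fill = .data$status)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "study MAF bin", y = "proportion of genotypes", fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
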