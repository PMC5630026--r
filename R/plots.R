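# ggplot2 views of the main result types.

#' Bar chart of conservation labels
#'
#' @param calls Tibble from [classify_conservation()].
#' @return A ggplot object.
#' @export
plot_conservation <- function(calls) {
  calls |>
    count(.data$label) |>
    mutate(percent = 100 * .data$n / sum(.data$n)) |>
    ggplot2::ggplot(ggplot2::aes(x = stats::reorder(.data$label, -.data$n),
                                 y = .data$percent)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = NULL, y = "% of CREs",
                  title = "Conservation of CRE histone-modification state") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' Divergence distributions per species
#'
#' @param divergence Tibble from [pairwise_divergence()].
#' @return A ggplot object.
#' @export
plot_divergence <- function(divergence) {
  divergence |>
    filter(!is.na(.data$divergence)) |>
    ggplot2::ggplot(ggplot2::aes(x = .data$species, y = .data$divergence)) +
    ggplot2::geom_boxplot(outlier.size = 0.4, fill = "grey85") +
    ggplot2::labs(x = NULL, y = "pairwise divergence vs human") +
    ggplot2::theme_minimal()
}

#' Fold enrichment of TE subfamilies in CREs
#'
#' @param enrichment Tibble from [enrichment_test()].
#' @return A ggplot object.
#' @export
plot_te_enrichment <- function(enrichment) {
  enrichment |>
    ggplot2::ggplot(ggplot2::aes(x = stats::reorder(.data$subfamily,
                                                    .data$fold),
                                 y = .data$fold, fill = .data$enriched)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::geom_hline(yintercept = 1, linetype = 2) +
    ggplot2::labs(x = NULL, y = "observed / expected CRE overlaps",
                  fill = "FDR < 1%") +
    ggplot2::theme_minimal()
}

#' Fraction of differential features per comparison
#'
#' @param results Stacked [diff_histone()] or [diff_expression()] tables.
#' @return A ggplot object.
#' @export
plot_comparison_fractions <- function(results) {
  results |>
    filter(.data$status == "ok") |>
    group_by(.data$comparison_id) |>
    summarise(fraction = mean(.data$significant), .groups = "drop") |>
    ggplot2::ggplot(ggplot2::aes(
      x = stats::reorder(.data$comparison_id, .data$fraction),
      y = 100 * .data$fraction)) +
    ggplot2::geom_col(fill = "darkorange") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "% differential features") +
    ggplot2::theme_minimal()
}
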