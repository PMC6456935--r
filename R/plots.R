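#' Boxplots of a diversity metric by group
#'
#' @param profiles Tibble from [diversity_table()].
#' @param metadata Metadata tibble with `sample_id`, `group`.
#' @param metric Metric column to plot.
#' @return A ggplot object.
#' @export
plot_diversity <- function(profiles, metadata, metric = "observed_otus") {
  metadata <- validate_metadata(metadata)
  joined <- dplyr::inner_join(profiles, metadata[, c("sample_id", "group")],
                              by = "sample_id")
  joined$group <- factor(joined$group, levels = GROUP_LEVELS)
  ggplot2::ggplot(joined, ggplot2::aes(x = .data$group, y = .data[[metric]],
                                       fill = .data$group)) +
    ggplot2::geom_boxplot(outlier.shape = 21) +
    ggplot2::labs(x = NULL, y = metric) +
    ggplot2::guides(fill = "none") +
    ggplot2::theme_minimal()
}

#' Group-mean cumulative dominance curves
#'
#' @param dominance Tibble from [dominance_summary()].
#' @return A ggplot object.
#' @export
plot_dominance <- function(dominance) {
  dominance$group <- factor(dominance$group, levels = GROUP_LEVELS)
  ggplot2::ggplot(dominance, ggplot2::aes(x = .data$k, y = .data$fraction,
                                          colour = .data$group)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "top k OTUs", y = "cumulative abundance fraction") +
    ggplot2::theme_minimal()
}

#' Volcano plot of a differential analysis
#'
#' Signed log2 fold change (positive = enriched in the first group)
#' against -log10 q, with the significant calls highlighted.
#'
#' @param object An `apex_diff` result.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot apex_diff
#' @export
autoplot.apex_diff <- function(object, ...) {
  df <- tidy(object)
  df$signed_lfc <- ifelse(df$direction == "up_in_a", 1, -1) * log2(df$fold_change)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$signed_lfc,
                                   y = -log10(pmax(.data$q_value, 1e-300)),
                                   colour = .data$significant)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60", `TRUE` = "firebrick")) +
    ggplot2::labs(
      x = sprintf("log2 fold change (%s vs %s)",
                  attr(object, "group_a"), attr(object, "group_b")),
      y = "-log10 q-value", colour = "significant") +
    ggplot2::theme_minimal()
}

#' Shared-fraction boxplots by overlap category
#'
#' @param records Tibble from [pairwise_overlap()].
#' @param measure `"com_richness"` or `"com_abundance"`.
#' @return A ggplot object.
#' @export
plot_overlap <- function(records, measure = c("com_richness", "com_abundance")) {
  measure <- match.arg(measure)
  ggplot2::ggplot(records, ggplot2::aes(x = .data$category,
                                        y = .data[[measure]],
                                        fill = .data$category)) +
    ggplot2::geom_boxplot() +
    ggplot2::labs(x = NULL, y = measure) +
    ggplot2::guides(fill = "none") +
    ggplot2::theme_minimal()
}

#' k-core index distribution of a co-occurrence network
#'
#' @param object A `corr_network`.
#' @param ... Unused.
#' @return A ggplot object (bar chart of node counts per k-core index).
#' @method autoplot corr_network
#' @export
autoplot.corr_network <- function(object, ...) {
  ggplot2::ggplot(object$nodes, ggplot2::aes(x = factor(.data$k_core))) +
    ggplot2::geom_bar(fill = "steelblue") +
    ggplot2::labs(x = "k-core index", y = "OTUs") +
    ggplot2::theme_minimal()
}
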