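#' Heatmap of a consensus matrix
#'
#' Items are ordered by the consensus dendrogram (average linkage on
#' `1 - consensus`), so stable clusters appear as blocks along the diagonal.
#'
#' @param object A `consensus_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.consensus_result <- function(object, ...) {
  ord <- stats::hclust(stats::as.dist(1 - object$consensus),
                       method = "average")$order
  ids <- rownames(object$consensus)[ord]
  df <- tidyr::expand_grid(row = ids, col = ids)
  df$value <- object$consensus[cbind(df$row, df$col)]
  df$row <- factor(df$row, levels = ids)
  df$col <- factor(df$col, levels = rev(ids))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$row, y = .data$col,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = "white",
                                 high = if (object$algorithm == "som")
                                   "firebrick" else "navy",
                                 limits = c(0, 1), name = "consensus") +
    ggplot2::labs(title = sprintf("%s, %s, k = %d", object$dataset,
                                  object$algorithm, object$k),
                  x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text = ggplot2::element_blank(),
                   panel.grid = ggplot2::element_blank())
}

#' Heatmap of signature cell-type enrichment profiles
#'
#' @param profiles Matrix from [profile_signatures()].
#' @param standardized Plot the row-standardized copy. Default `TRUE`.
#' @return A ggplot object.
#' @export
plot_signature_profiles <- function(profiles, standardized = TRUE) {
  m <- if (standardized) attr(profiles, "standardized") else
    unclass(profiles)
  df <- tidyr::expand_grid(signature = rownames(m), group = colnames(m))
  df$score <- m[cbind(df$signature, df$group)]
  df$group <- factor(df$group, levels = colnames(m))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$group, y = .data$signature,
                                   fill = .data$score)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "navy", mid = "white",
                                  high = "firebrick", midpoint = 0) +
    ggplot2::labs(x = NULL, y = NULL,
                  fill = if (standardized) "z-score" else "score") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60,
                                                       hjust = 1))
}

#' Consensus summary statistics across candidate k
#'
#' Plots the CDF-area curve and its relative increase for a
#' [consensus_cluster()] run, the statistics [select_k()] decides on.
#'
#' @param results A `consensus_set`.
#' @return A ggplot object.
#' @export
plot_consensus_summary <- function(results) {
  s <- tidy.consensus_set(results)
  df <- tidyr::pivot_longer(s[, c("k", "area", "delta")],
                            c("area", "delta"),
                            names_to = "statistic")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$k, y = .data$value)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::facet_wrap(~statistic, scales = "free_y") +
    ggplot2::theme_minimal() +
    ggplot2::labs(y = NULL)
}
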