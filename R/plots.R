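#' @importFrom ggplot2 ggplot aes autoplot geom_tile geom_point geom_segment
#'   geom_line geom_ribbon geom_errorbarh geom_hline geom_vline facet_wrap
#'   scale_fill_gradient2 labs theme_minimal
NULL

#' @export
ggplot2::autoplot

#' Heatmap of the regularized partial-correlation matrix
#'
#' @param object A `"symptom_network"`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.symptom_network <- function(object, ...) {
  df <- tidy(object, all = TRUE)
  df$from <- factor(df$from, levels = object$labels)
  df$to <- factor(df$to, levels = rev(object$labels))
  ggplot(df, aes(x = .data$from, y = .data$to, fill = .data$weight)) +
    geom_tile() +
    scale_fill_gradient2(low = "#b2182b", mid = "white", high = "#2166ac",
                         limits = c(-1, 1) * max(abs(df$weight), 0.1)) +
    labs(x = NULL, y = NULL, fill = "weight",
         title = sprintf("Partial-correlation network (%d edges, lambda = %.3g)",
                         object$n_edges, object$lambda)) +
    theme_minimal()
}

#' Lollipop chart of centrality indices
#'
#' @param centrality A [centrality_table()] tibble.
#' @param indices Columns to show (default EI and bridge EI).
#' @return A ggplot, one facet per index, nodes ordered by EI.
#' @export
plot_centrality <- function(centrality, indices = c("ei", "bridge_ei")) {
  indices <- intersect(indices, names(centrality))
  ord <- centrality$node[order(centrality$ei)]
  df <- tidyr::pivot_longer(centrality[, c("node", indices)],
                            cols = dplyr::all_of(indices),
                            names_to = "index", values_to = "value")
  df$node <- factor(df$node, levels = ord)
  ggplot(df, aes(x = .data$value, y = .data$node)) +
    geom_segment(aes(x = 0, xend = .data$value, yend = .data$node),
                 color = "grey60") +
    geom_point() +
    facet_wrap(~index, scales = "free_x") +
    labs(x = NULL, y = NULL, title = "Node centrality") +
    theme_minimal()
}

#' Stability plot for the case-dropping bootstrap
#'
#' Mean subsample/full-sample centrality correlation per drop proportion, with
#' the central 90% band across subsamples and the 0.7 threshold line.
#'
#' @param object A `"cs_result"`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.cs_result <- function(object, ...) {
  df <- object$record |>
    dplyr::group_by(.data$index, .data$drop) |>
    dplyr::summarise(mean_r = mean(.data$correlation),
                     lo = stats::quantile(.data$correlation, 0.05),
                     hi = stats::quantile(.data$correlation, 0.95),
                     .groups = "drop")
  ggplot(df, aes(x = .data$drop, y = .data$mean_r, color = .data$index,
                 fill = .data$index)) +
    geom_ribbon(aes(ymin = .data$lo, ymax = .data$hi), alpha = 0.2,
                color = NA) +
    geom_line() + geom_point() +
    geom_hline(yintercept = object$threshold, linetype = 2) +
    labs(x = "proportion of cases dropped",
         y = "correlation with full-sample centrality",
         title = "Case-dropping stability") +
    theme_minimal()
}

#' Edge-weight bootstrap interval plot
#'
#' @param object An `"edge_bootstrap"`.
#' @param nonzero_only Show only edges nonzero in the sample network
#'   (default `TRUE`).
#' @param ... Unused.
#' @return A ggplot of sample weights with bootstrap quantile intervals.
#' @export
autoplot.edge_bootstrap <- function(object, nonzero_only = TRUE, ...) {
  df <- object$edges
  if (nonzero_only) df <- df[df$sample != 0, ]
  df$edge <- paste(df$from, df$to, sep = "--")
  df$edge <- factor(df$edge, levels = df$edge[order(df$sample)])
  ggplot(df, aes(y = .data$edge)) +
    geom_errorbarh(aes(xmin = .data$ci_low, xmax = .data$ci_high),
                   height = 0, color = "grey50") +
    geom_point(aes(x = .data$boot_mean), color = "grey40", size = 0.8) +
    geom_point(aes(x = .data$sample), color = "#b2182b", size = 1) +
    geom_vline(xintercept = 0, linetype = 3) +
    labs(x = "edge weight (sample = red, bootstrap mean = grey)", y = NULL,
         title = sprintf("Bootstrap edge accuracy (B = %d)", object$B)) +
    theme_minimal()
}
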