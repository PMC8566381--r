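#' Plot a level tree as a 2D dendrogram
#'
#' Soma at the top (level 0), children one level down; optional nodal
#' polarity coloring.
#'
#' @param object A `level_tree` or `reduced_tree`.
#' @param polarity Optional tibble from [propagate_polarity()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot level_tree
#' @export
autoplot.level_tree <- function(object, polarity = NULL, ...) {
  tree <- object
  kids <- tree_children(tree)
  xpos <- numeric(nrow(tree))
  leaf_x <- 0
  assign_x <- function(v) {
    ch <- kids[[v]]
    if (length(ch) == 0L) {
      leaf_x <<- leaf_x + 1
      xpos[v] <<- leaf_x
    } else {
      for (c2 in ch) assign_x(c2)
      xpos[v] <<- mean(xpos[ch])
    }
  }
  assign_x(1L)
  df <- tibble::tibble(
    node_id = tree$node_id, x = xpos[tree$node_id],
    y = -tree$level, parent = tree$parent
  )
  df$xend <- df$x[match(df$parent, df$node_id)]
  df$yend <- df$y[match(df$parent, df$node_id)]
  if (!is.null(polarity)) {
    df$polarity <- polarity$polarity[match(df$node_id, polarity$node_id)]
  } else {
    df$polarity <- "unknown"
  }
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_segment(
      data = df[!is.na(df$parent), ],
      ggplot2::aes(xend = .data$xend, yend = .data$yend),
      color = "grey60"
    ) +
    ggplot2::geom_point(ggplot2::aes(color = .data$polarity), size = 2) +
    ggplot2::scale_color_manual(values = c(
      axon = "#2166ac", dendrite = "#b2182b", dividing = "#e6b800",
      unknown = "grey40"
    )) +
    ggplot2::labs(x = NULL, y = "level", color = NULL) +
    ggplot2::theme_minimal()
}

#' Feature distributions by polarity class
#'
#' Histogram of one feature for axon versus dendrite nodes, the view in
#' which the class separation (axons farther from the soma by normalized
#' path length, dendrites in wigglier clusters) is visible.
#'
#' @param features Feature rows ([extract_features()] output, labeled).
#' @param feature Feature column to plot.
#' @return A ggplot object.
#' @export
plot_feature_distribution <- function(features, feature = "nl_s") {
  df <- features[features$polarity %in% c("axon", "dendrite"), ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data[[feature]],
                                   fill = .data$polarity)) +
    ggplot2::geom_histogram(position = "identity", alpha = 0.55, bins = 40) +
    ggplot2::scale_fill_manual(values = c(axon = "#2166ac",
                                          dendrite = "#b2182b")) +
    ggplot2::labs(x = feature, fill = NULL) +
    ggplot2::theme_minimal()
}

#' Confusion-matrix heat map of a terminal score
#'
#' @param object An `npin_score`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot npin_score
#' @export
autoplot.npin_score <- function(object, ...) {
  ggplot2::ggplot(object$confusion,
                  ggplot2::aes(x = .data$predicted, y = .data$truth,
                               fill = .data$n)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$n), color = "white") +
    ggplot2::scale_y_discrete(limits = rev) +
    ggplot2::labs(x = "predicted polarity", y = "actual polarity") +
    ggplot2::guides(fill = "none") +
    ggplot2::theme_minimal()
}
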