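#' Plot within- vs between-habitat replicate distances
#' @param object A `replicate_qc`.
#' @param ... Unused.
#' @return A ggplot: boxplots of the two Bray-Curtis distance sets.
#' @export
autoplot.replicate_qc <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$comparison, y = .data$distance)) +
    ggplot2::geom_boxplot(outlier.shape = 1) +
    ggplot2::labs(x = NULL, y = "Bray-Curtis dissimilarity",
                  title = sprintf("Replicate QC: t = %.2f, p = %.2g",
                                  object$statistic, object$p_value)) +
    ggplot2::theme_minimal()
}

dendro_segments <- function(h) {
  n <- length(h$labels)
  x_leaf <- numeric(n); x_leaf[h$order] <- seq_len(n)
  xc <- numeric(nrow(h$merge)); hc <- h$height
  segs <- vector("list", nrow(h$merge))
  child <- function(j) if (j < 0) c(x_leaf[-j], 0) else c(xc[j], hc[j])
  for (i in seq_len(nrow(h$merge))) {
    a <- child(h$merge[i, 1]); b <- child(h$merge[i, 2])
    xc[i] <- mean(c(a[1], b[1]))
    segs[[i]] <- tibble::tibble(
      x = c(a[1], b[1], a[1]), xend = c(a[1], b[1], b[1]),
      y = c(a[2], b[2], hc[i]), yend = c(hc[i], hc[i], hc[i])
    )
  }
  list(segments = dplyr::bind_rows(segs),
       leaves = tibble::tibble(label = h$labels[h$order], x = seq_len(n)))
}

#' Plot a habitat dendrogram
#' @param object A `habitat_dendro`.
#' @param ... Unused.
#' @return A ggplot dendrogram with habitats on the x axis and Bray-Curtis
#'   merge height on the y axis.
#' @export
autoplot.habitat_dendro <- function(object, ...) {
  d <- dendro_segments(object$hclust)
  ggplot2::ggplot() +
    ggplot2::geom_segment(data = d$segments,
                          ggplot2::aes(x = .data$x, xend = .data$xend,
                                       y = .data$y, yend = .data$yend)) +
    ggplot2::scale_x_continuous(breaks = d$leaves$x, labels = d$leaves$label) +
    ggplot2::labs(x = NULL, y = "Bray-Curtis dissimilarity") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5,
                                                       hjust = 1))
}

#' Plot a co-occurrence network
#' @param object A `co_network`.
#' @param seed Layout seed (Fruchterman-Reingold), for reproducible plots.
#' @param ... Unused.
#' @return A ggplot of the network; node size tracks degree and colour the
#'   domain when available.
#' @export
autoplot.co_network <- function(object, seed = 1L, ...) {
  xy <- withr::with_seed(seed, igraph::layout_with_fr(object$graph))
  nodes <- dplyr::bind_cols(object$nodes,
                            tibble::tibble(x = xy[, 1], y = xy[, 2]))
  e <- object$edges
  e$xa <- nodes$x[match(e$otu_a, nodes$otu_id)]
  e$ya <- nodes$y[match(e$otu_a, nodes$otu_id)]
  e$xb <- nodes$x[match(e$otu_b, nodes$otu_id)]
  e$yb <- nodes$y[match(e$otu_b, nodes$otu_id)]
  p <- ggplot2::ggplot() +
    ggplot2::geom_segment(data = e,
                          ggplot2::aes(x = .data$xa, y = .data$ya,
                                       xend = .data$xb, yend = .data$yb),
                          linewidth = 0.2, alpha = 0.4)
  aes_pt <- if ("domain" %in% names(nodes)) {
    ggplot2::aes(x = .data$x, y = .data$y, size = .data$degree,
                 colour = .data$domain)
  } else {
    ggplot2::aes(x = .data$x, y = .data$y, size = .data$degree)
  }
  p + ggplot2::geom_point(data = nodes, aes_pt) +
    ggplot2::theme_void() +
    ggplot2::labs(size = "degree", colour = "domain")
}

#' Taxon-abundance dot plot
#'
#' The bubble-plot view of [taxon_aggregate()] output: habitats on the x
#' axis, taxa on the y axis, point size proportional to relative abundance.
#'
#' @param data Long tibble from [taxon_aggregate()].
#' @return A ggplot.
#' @export
plot_taxon_dotplot <- function(data) {
  ggplot2::ggplot(data[data$rel_abundance > 0, ],
                  ggplot2::aes(x = .data$habitat_id, y = .data$taxon,
                               size = .data$rel_abundance)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$domain), scales = "free_y",
                        space = "free_y") +
    ggplot2::scale_size_area(max_size = 8) +
    ggplot2::labs(x = NULL, y = NULL, size = "relative\nabundance") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5,
                                                       hjust = 1))
}

#' Breadth dot plot (generalists or specialists)
#'
#' Dot plot of per-habitat relative abundance from [breadth_summary()];
#' non-detections of generalists are drawn as crosses.
#'
#' @param data Long tibble from [breadth_summary()], typically filtered to
#'   one breadth class.
#' @return A ggplot.
#' @export
plot_breadth_dotplot <- function(data) {
  ggplot2::ggplot(data, ggplot2::aes(x = .data$habitat_id, y = .data$otu_id)) +
    ggplot2::geom_point(data = data[data$detected, ],
                        ggplot2::aes(size = .data$rel_abundance), alpha = 0.8) +
    ggplot2::geom_point(data = data[!data$detected, ], shape = 4, size = 2) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$domain), scales = "free_y",
                        space = "free_y") +
    ggplot2::scale_size_area(max_size = 8) +
    ggplot2::labs(x = NULL, y = NULL, size = "relative\nabundance") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5,
                                                       hjust = 1))
}
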