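#' Plot a mineral x carbon x dilution Fe-reduction grid
#'
#' Percent of total Fe(III) reduced against decimal dilution, one panel
#' per mineral, coloured by carbon source; replicate enrichments are
#' averaged.
#'
#' @param grid Enrichment table from [generate_fe_grid()] (or with the
#'   same columns).
#' @return A ggplot object.
#' @export
plot_fe_grid <- function(grid) {
  avg <- grid |>
    dplyr::group_by(.data$mineral, .data$carbon, .data$dilution_exponent) |>
    dplyr::summarise(percent_reduced = mean(.data$percent_reduced),
                     .groups = "drop")
  ggplot2::ggplot(avg, ggplot2::aes(x = .data$dilution_exponent,
                                    y = .data$percent_reduced,
                                    colour = .data$carbon)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(ggplot2::vars(.data$mineral)) +
    ggplot2::labs(x = "sediment dilution (10^-x)",
                  y = "Fe(III) reduced (% of total Fe)",
                  colour = "carbon source") +
    ggplot2::ylim(0, 100) +
    ggplot2::theme_minimal()
}

#' Heatmap of a community matrix
#'
#' Relative abundance of each taxon group per sample, the standard
#' community-fingerprint overview.
#'
#' @param comm A `trf_community` from [build_community_matrix()].
#' @return A ggplot object.
#' @export
plot_community <- function(comm) {
  long <- tidyr::pivot_longer(as_tibble(comm), -"sample_id",
                              names_to = "group", values_to = "rel_area")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$sample_id, y = .data$group,
                                     fill = .data$rel_area)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = "relative\npeak area") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5,
                                                       hjust = 1))
}

#' @export
autoplot.trf_community <- function(object, ...) plot_community(object)

#' Dendrogram plot of a UPGMA tree
#'
#' @param object A tree from [upgma()].
#' @param ... Unused.
#' @return A ggplot object drawing the merge tree with height as the
#'   vertical axis (Bray-Curtis scale for trees built on [bray_curtis()]
#'   output).
#' @export
autoplot.trf_upgma <- function(object, ...) {
  hc <- stats::as.hclust(object)
  n <- length(hc$labels)
  # x position of each leaf in plotting order, then of each merge node
  leaf_x <- match(seq_len(n), hc$order)
  node_x <- numeric(length(hc$height))
  node_y <- hc$height
  pos <- function(id) if (id < 0) c(leaf_x[-id], 0) else c(node_x[id], node_y[id])
  segs <- vector("list", length(hc$height))
  for (i in seq_along(hc$height)) {
    a <- pos(hc$merge[i, 1]); b <- pos(hc$merge[i, 2])
    node_x[i] <- (a[1] + b[1]) / 2
    segs[[i]] <- tibble(
      x = c(a[1], a[1], b[1]),
      xend = c(a[1], b[1], b[1]),
      y = c(a[2], hc$height[i], hc$height[i]),
      yend = c(hc$height[i], hc$height[i], b[2])
    )
  }
  labs <- tibble(x = leaf_x, label = hc$labels)
  ggplot2::ggplot(dplyr::bind_rows(segs)) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$x, xend = .data$xend,
                                       y = .data$y, yend = .data$yend)) +
    ggplot2::scale_x_continuous(breaks = labs$x, labels = labs$label) +
    ggplot2::labs(x = NULL, y = "cophenetic dissimilarity") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5,
                                                       hjust = 1),
                   panel.grid.major.x = ggplot2::element_blank())
}
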