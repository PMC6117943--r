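#' Plot a differential network over its background cluster
#'
#' Background edges and nodes in grey; active nodes coloured on the
#' red-white-blue regulation scale and sized by |weight|; active edges
#' weighted by their edge weight. Requires background coordinates.
#'
#' @param object A `differential_network` (see [active_subnetwork()]),
#'   ideally after [encode_visuals()].
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.differential_network <- function(object, ...) {
  bg <- object$background
  if (!all(is.finite(bg$nodes$x) & is.finite(bg$nodes$y))) {
    abort("background nodes lack coordinates; run assign_layout() first")
  }
  if (is.null(object$encode_scale)) object <- encode_visuals(object, scale = 1)
  pos <- select(bg$nodes, "node_id", "x", "y")
  seg <- function(edges) {
    edges |>
      left_join(rename(pos, x0 = "x", y0 = "y"), by = c(source_id = "node_id")) |>
      left_join(rename(pos, x1 = "x", y1 = "y"), by = c(target_id = "node_id"))
  }
  act <- left_join(object$nodes, pos, by = "node_id")
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = seg(bg$edges),
      ggplot2::aes(x = .data$x0, y = .data$y0, xend = .data$x1, yend = .data$y1),
      colour = "grey80", linewidth = 0.3
    ) +
    ggplot2::geom_point(
      data = pos, ggplot2::aes(x = .data$x, y = .data$y),
      colour = "grey70", size = 1
    ) +
    ggplot2::geom_segment(
      data = seg(object$edges),
      ggplot2::aes(
        x = .data$x0, y = .data$y0, xend = .data$x1, yend = .data$y1,
        linewidth = .data$edge_weight, linetype = .data$interaction_type
      ),
      colour = "grey30"
    ) +
    ggplot2::geom_point(
      data = act,
      ggplot2::aes(x = .data$x, y = .data$y, fill = .data$colour_value,
        size = .data$size),
      shape = 21, colour = "grey20"
    ) +
    ggplot2::scale_fill_gradient2(
      low = "#2166AC", mid = "#FFFFFF", high = "#B2182B", midpoint = 0,
      limits = c(-object$encode_scale, object$encode_scale),
      name = "weight (logFC)"
    ) +
    ggplot2::scale_linewidth(range = c(0.3, 1.6), guide = "none") +
    ggplot2::scale_size_identity() +
    ggplot2::scale_linetype_manual(
      values = c(activation = "solid", inhibition = "solid",
        binding = "dashed", unknown = "dotted"),
      name = "interaction"
    ) +
    ggplot2::coord_equal() +
    ggplot2::theme_void() +
    ggplot2::labs(title = paste0("condition: ", object$condition_label))
}

#' Plot the activity profile of a frame sequence
#'
#' Number of visible nodes and edges per frame along the condition axis —
#' a quick view of modules switching on and off during the animation.
#'
#' @param object A `frame_sequence` (see [build_frames()]).
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.frame_sequence <- function(object, ...) {
  counts <- bind_rows(
    object$node_frames |>
      group_by(.data$t) |>
      summarise(n = sum(.data$visible), .groups = "drop") |>
      mutate(element = "nodes"),
    object$edge_frames |>
      group_by(.data$t) |>
      summarise(n = sum(.data$visible), .groups = "drop") |>
      mutate(element = "edges")
  )
  ggplot2::ggplot(counts, ggplot2::aes(x = .data$t, y = .data$n,
    colour = .data$element)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(
      xintercept = seq_along(object$condition_labels) - 1,
      linetype = "dotted", colour = "grey60"
    ) +
    ggplot2::scale_x_continuous(
      breaks = seq_along(object$condition_labels) - 1,
      labels = object$condition_labels
    ) +
    ggplot2::labs(x = "condition axis", y = "visible elements",
      colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a clustered network coloured by cluster
#'
#' @param object A `clustered_network` from [clusterize()].
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.clustered_network <- function(object, ...) {
  pos <- object$nodes
  seg <- object$edges |>
    left_join(rename(select(pos, "node_id", "x", "y"), x0 = "x", y0 = "y"),
      by = c(source_id = "node_id")) |>
    left_join(rename(select(pos, "node_id", "x", "y"), x1 = "x", y1 = "y"),
      by = c(target_id = "node_id"))
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = seg,
      ggplot2::aes(x = .data$x0, y = .data$y0, xend = .data$x1, yend = .data$y1),
      colour = "grey80", linewidth = 0.3
    ) +
    ggplot2::geom_point(
      data = pos,
      ggplot2::aes(x = .data$x, y = .data$y,
        colour = factor(.data$cluster_label)),
      size = 1.5
    ) +
    ggplot2::facet_wrap(~ factor(cluster_label), scales = "free") +
    ggplot2::labs(colour = "cluster") +
    ggplot2::theme_void()
}
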