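#' Cut-off thresholds for condition-specific networks
#'
#' @param alpha Significance cutoff in `(0, 1]`; a node passes when its
#'   significance (e.g. adjusted p value) is strictly below `alpha`.
#' @param min_abs_weight Minimal absolute node weight (e.g. |logFC|);
#'   inclusive (`>=`).
#' @param min_degree Minimal background-cluster degree kept by
#'   [filter_min_degree()].
#' @param weight_is_interpolated Flag recording whether the thresholds are
#'   applied to interpolated weights (animation frames) rather than raw
#'   per-condition weights.
#' @return A list of class `dinet_thresholds`.
#' @export
thresholds <- function(alpha = 0.05, min_abs_weight = 0.5, min_degree = 0L,
                       weight_is_interpolated = FALSE) {
  stopifnot(alpha > 0, alpha <= 1, min_abs_weight >= 0, min_degree >= 0)
  structure(
    list(
      alpha = alpha, min_abs_weight = min_abs_weight,
      min_degree = as.integer(min_degree),
      weight_is_interpolated = isTRUE(weight_is_interpolated)
    ),
    class = "dinet_thresholds"
  )
}

#' Does a measurement pass the cut-off criteria?
#'
#' A node passes when its significance is strictly below `alpha` AND its
#' absolute weight is at least `min_abs_weight` (inclusive). Missing
#' measurements (NA weight or significance) never pass: absence of
#' evidence is not significance.
#'
#' @param weight Signed node weight(s), e.g. log2 fold change.
#' @param significance Significance value(s) in `[0, 1]`.
#' @param th A [thresholds()] object.
#' @return Logical vector.
#' @export
node_passes <- function(weight, significance, th = thresholds()) {
  ok <- !is.na(weight) & !is.na(significance) &
    significance < th$alpha & abs(weight) >= th$min_abs_weight
  ok
}

#' Edge weight from the weights of its two endpoints
#'
#' The saturating score `s / max(s, 1)` with
#' `s = |wn|/max(|wn|, 1) + |wm|/max(|wm|, 1)`. It lies in `[0, 1]`, is
#' symmetric in its arguments, equals `|wn| + |wm|` when both magnitudes
#' are below 1 and their sum is below 1, and saturates at 1 as soon as
#' either endpoint's |weight| reaches 1.
#'
#' @param wn,wm Signed weights of the two connected nodes (vectorised).
#' @return Edge weight(s) in `[0, 1]`.
#' @export
edge_weight <- function(wn, wm) {
  if (any(!is.finite(wn)) || any(!is.finite(wm))) {
    abort("edge_weight requires finite inputs")
  }
  s <- abs(wn) / pmax(abs(wn), 1) + abs(wm) / pmax(abs(wm), 1)
  s / pmax(s, 1)
}

#' Condition-specific active subnetwork of a cluster
#'
#' Applies the cut-off criteria to one condition's measurements over a
#' background cluster subgraph: active nodes are the measured nodes that
#' pass; an edge becomes active only when BOTH its endpoints pass, with
#' its weight computed by [edge_weight()]. Passing nodes whose neighbours
#' all fail are retained as isolated active nodes. Measurements for
#' identifiers absent from the cluster are ignored.
#'
#' @param subnet Background cluster subgraph (a `knowledge_network`,
#'   normally already checked with [check_module_size()]).
#' @param measurements Tibble `node_id`, `weight`, `significance` for one
#'   condition (see [condition_measurements()]).
#' @param th A [thresholds()] object.
#' @param condition_label Label recorded on the result.
#' @return A `differential_network`: list with `condition_label`, `nodes`
#'   (tibble `node_id`, `weight`, `significance`), `edges` (tibble
#'   `source_id`, `target_id`, `interaction_type`, `directed`,
#'   `edge_weight`), plus the `background` subnetwork, the full
#'   `measurements` table for the condition and the thresholds used.
#' @export
active_subnetwork <- function(subnet, measurements, th = thresholds(),
                              condition_label = NA_character_) {
  stopifnot(inherits(subnet, "knowledge_network"))
  m <- as_tibble(measurements)
  m <- filter(m, .data$node_id %in% subnet$nodes$node_id)
  pass <- m[node_passes(m$weight, m$significance, th), , drop = FALSE]
  active_edges <- filter(
    subnet$edges,
    .data$source_id %in% pass$node_id & .data$target_id %in% pass$node_id
  )
  w <- setNames(pass$weight, pass$node_id)
  if (nrow(active_edges) > 0) {
    active_edges$edge_weight <- unname(edge_weight(
      w[active_edges$source_id], w[active_edges$target_id]
    ))
  } else {
    active_edges$edge_weight <- numeric()
  }
  structure(
    list(
      condition_label = condition_label,
      nodes = select(pass, "node_id", "weight", "significance"),
      edges = active_edges,
      background = subnet,
      measurements = m,
      thresholds = th
    ),
    class = "differential_network"
  )
}

#' @export
print.differential_network <- function(x, ...) {
  cat(sprintf(
    "<differential_network> condition %s: %d active node(s), %d active edge(s) (background: %d/%d)\n",
    x$condition_label, nrow(x$nodes), nrow(x$edges),
    nrow(x$background$nodes), nrow(x$background$edges)
  ))
  invisible(x)
}

#' @rdname active_subnetwork
#' @param x A `differential_network`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.differential_network <- function(x, ...) x$nodes

#' @rdname active_subnetwork
#' @exportS3Method generics::glance
glance.differential_network <- function(x, ...) {
  tibble(
    condition = x$condition_label,
    n_active_nodes = nrow(x$nodes),
    n_active_edges = nrow(x$edges),
    n_background_nodes = nrow(x$background$nodes),
    n_background_edges = nrow(x$background$edges),
    mean_edge_weight = if (nrow(x$edges) > 0) mean(x$edges$edge_weight) else NA_real_
  )
}

#' Node size and colour encoding for display
#'
#' Node size grows with the absolute weight,
#' `size = base_size * (1 + |weight|/scale)`; the colour value is the
#' signed weight clipped to `[-scale, scale]`, to be mapped on a symmetric
#' diverging red-white-blue scale (positive/upregulated red, negative/
#' downregulated blue, zero white).
#'
#' @param diffnet A `differential_network`.
#' @param scale Positive scale (typically the maximal |weight| across the
#'   series, floored at 1).
#' @param base_size Base node size.
#' @return The `differential_network` with `size` and `colour_value`
#'   columns added to `nodes`.
#' @export
encode_visuals <- function(diffnet, scale = 1, base_size = 1) {
  stopifnot(inherits(diffnet, "differential_network"))
  if (!is.finite(scale) || scale <= 0) {
    abort("`scale` must be a positive finite number")
  }
  diffnet$nodes <- mutate(diffnet$nodes,
    size = base_size * (1 + abs(.data$weight) / scale),
    colour_value = pmin(pmax(.data$weight, -scale), scale)
  )
  diffnet$encode_scale <- scale
  diffnet$base_size <- base_size
  diffnet
}

#' Filter active nodes by background-cluster degree
#'
#' Display filter for large clusters: removes active nodes whose degree in
#' the background cluster (not in the differential network) is below `k`,
#' then prunes active edges left dangling.
#'
#' @param diffnet A `differential_network`.
#' @param k Minimal background degree (k = 0 is the identity).
#' @return The filtered `differential_network`.
#' @export
filter_min_degree <- function(diffnet, k = 0L) {
  stopifnot(inherits(diffnet, "differential_network"), k >= 0)
  if (k == 0) return(diffnet)
  deg <- node_degrees(diffnet$background)
  keep <- diffnet$nodes$node_id[deg[diffnet$nodes$node_id] >= k]
  diffnet$nodes <- filter(diffnet$nodes, .data$node_id %in% keep)
  diffnet$edges <- filter(
    diffnet$edges,
    .data$source_id %in% keep & .data$target_id %in% keep
  )
  diffnet
}

#' Module size guard for visualisation
#'
#' A module (cluster subgraph) is displayable when its loop-free edge
#' count lies between 2 and 16384 inclusive. Self-loops (e.g.
#' autocatalysis, autophosphorylation) are excluded from the count.
#'
#' @param subnet A `knowledge_network`.
#' @return Logical flag.
#' @export
check_module_size <- function(subnet) {
  stopifnot(inherits(subnet, "knowledge_network"))
  m <- sum(subnet$edges$source_id != subnet$edges$target_id)
  m >= 2 && m <= 16384
}

#' Functional-bin over-representation of a cluster
#'
#' One-sided hypergeometric over-representation test of each functional
#' bin within a cluster against the whole network, with Benjamini-
#' Hochberg adjustment across the bins tested in the cluster. Hierarchical
#' dot-separated bin codes are expanded to all ancestor bins (a node in
#' bin `1.2.3` also counts for `1.2` and `1`); a node may carry several
#' codes separated by `;` or `,`.
#'
#' @param cluster_nodes Character vector of node ids in the cluster.
#' @param network_nodes Character vector of all node ids (the universe);
#'   must contain the cluster.
#' @param annotation Tibble with `node_id` and `bin_code` columns, or a
#'   `knowledge_network` whose node table carries `bin_code`.
#' @return Tibble with one row per bin: `bin_code`,
#'   `in_cluster_with_bin` (k), `in_network_with_bin` (K), `cluster_size`
#'   (n), `network_size` (N), `p_value`, `adjusted_p`, sorted by
#'   `p_value`.
#' @export
bin_enrichment <- function(cluster_nodes, network_nodes, annotation) {
  if (inherits(annotation, "knowledge_network")) {
    annotation <- select(annotation$nodes, "node_id", "bin_code")
  }
  annotation <- filter(as_tibble(annotation), !is.na(.data$bin_code))
  if (!all(cluster_nodes %in% network_nodes)) {
    abort("cluster node set is not a subset of the network node set",
      class = "dinet_validation_error"
    )
  }
  ann <- annotation |>
    filter(.data$node_id %in% network_nodes) |>
    mutate(bin_code = strsplit(.data$bin_code, "[;,]\\s*")) |>
    tidyr::unnest("bin_code") |>
    mutate(bin_code = purrr::map(.data$bin_code, expand_bin_ancestors)) |>
    tidyr::unnest("bin_code") |>
    distinct(.data$node_id, .data$bin_code)
  N <- length(unique(network_nodes))
  n <- length(unique(cluster_nodes))
  per_bin <- ann |>
    group_by(.data$bin_code) |>
    summarise(
      in_network_with_bin = dplyr::n_distinct(.data$node_id),
      in_cluster_with_bin = dplyr::n_distinct(
        .data$node_id[.data$node_id %in% cluster_nodes]
      ),
      .groups = "drop"
    ) |>
    filter(.data$in_cluster_with_bin > 0)
  if (nrow(per_bin) == 0) {
    return(tibble(
      bin_code = character(), in_cluster_with_bin = integer(),
      in_network_with_bin = integer(), cluster_size = integer(),
      network_size = integer(), p_value = numeric(), adjusted_p = numeric()
    ))
  }
  per_bin |>
    mutate(
      cluster_size = n, network_size = N,
      p_value = phyper(.data$in_cluster_with_bin - 1,
        .data$in_network_with_bin, N - .data$in_network_with_bin, n,
        lower.tail = FALSE
      ),
      adjusted_p = p.adjust(.data$p_value, method = "BH")
    ) |>
    arrange(.data$p_value, .data$bin_code)
}

expand_bin_ancestors <- function(code) {
  parts <- strsplit(trimws(code), ".", fixed = TRUE)[[1]]
  vapply(seq_along(parts), function(i) paste(parts[seq_len(i)], collapse = "."),
    character(1))
}
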